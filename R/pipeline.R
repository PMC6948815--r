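#' Run the full drug-lncRNA association pipeline
#'
#' Executes the stages in order — drug signatures, coexpression model,
#' pair scoring, bilevel association, and (when survival records are
#' present) survival follow-up of the selected lncRNAs — and optionally
#' writes all result tables to `outdir`.  Inputs are sorted by feature and
#' sample identifier on entry, so results are invariant to the row order
#' of the input files; every remaining random step (negative subsampling,
#' CV folds) is controlled by the config's `rng_seed`, making reruns with
#' the same seed byte-identical.
#'
#' @param inputs a [simulate_bundle()]-shaped list (`lnc`, `genes`,
#'   `instances`, `treatments`, optional `survival`) or a directory path
#'   readable by [read_bundle()].
#' @param config a [pipeline_config()].
#' @param outdir optional output directory for the TSV reports.
#' @param grid SVM hyperparameter grid.
#' @param quiet suppress stage log messages.
#' @return Object of class `lncdrug_pipeline`: list with `signatures`,
#'   `coexpr`, `assoc_matrix`, `association`, `survival` (named list of
#'   `lnc_survival` per selected lncRNA with survival data), and `config`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), outdir = NULL,
                         grid = default_svm_grid(), quiet = FALSE) {
  config <- validate_config(config)
  if (is.character(inputs)) inputs <- read_bundle(inputs)
  say <- function(...) if (!quiet) message("[lncdrug] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  sort_features <- function(m)
    expr_matrix(unclass(m)[order(rownames(m)), sort(colnames(m)), drop = FALSE],
                raw_counts = isTRUE(attr(m, "raw_counts")))
  lnc <- sort_features(inputs$lnc)
  genes <- sort_features(inputs$genes)
  instances <- sort_features(inputs$instances)

  say("signature stage: ", nrow(instances), " genes x ", ncol(instances),
      " instances")
  sigs <- stage("signature",
                drug_signatures(instances, inputs$treatments, config))
  say("signature stage: ", length(sigs), " drug(s) kept")

  say("coexpression stage: ", nrow(lnc), " lncRNAs x ", nrow(genes), " genes")
  cx <- stage("coexpression",
              coexpr_model(lnc, genes, config, grid = grid,
                           seed = config$rng_seed))
  say("coexpression stage: ", cx$ds$n_pos, " positive / ", cx$ds$n_neg,
      " negative training pairs; C = ", format(cx$fit$C),
      ", gamma = ", format(cx$fit$gamma))
  am <- stage("scoring", predict(cx))

  assoc <- stage("association", associate_drugs(sigs, am, config))
  say("association stage: ",
      sum(vapply(assoc$drugs, function(d) length(d$selected), numeric(1))),
      " selected (drug, lncRNA) link(s)")

  surv <- NULL
  if (!is.null(inputs$survival)) {
    sel <- unique(unlist(lapply(assoc$drugs, `[[`, "selected")))
    cand <- if (length(sel)) sel else
      unique(vapply(assoc$drugs, function(d) d$rank[1], character(1)))
    surv <- list()
    for (l in cand) {
      res <- tryCatch(
        lnc_survival(unclass(lnc)[l, ], inputs$survival,
                     high = config$survival_high, low = config$survival_low,
                     lncRNA_id = l),
        error = function(e) e)
      if (inherits(res, "error")) {
        say("survival stage: ", l, " skipped (", conditionMessage(res), ")")
      } else {
        surv[[l]] <- res
      }
    }
    say("survival stage: ", length(surv), " lncRNA(s) tested")
  }

  out <- structure(list(signatures = sigs, coexpr = cx, assoc_matrix = am,
                        association = assoc, survival = surv,
                        config = config),
                   class = "lncdrug_pipeline")
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

#' @export
print.lncdrug_pipeline <- function(x, ...) {
  cat("<lncdrug_pipeline>\n")
  print(x$signatures)
  print(x$coexpr$fit)
  print(x$association)
  if (!is.null(x$survival)) for (s in x$survival) print(s)
  invisible(x)
}

#' Write all pipeline result tables
#'
#' Emits one `signature_<drug>.tsv` per drug, the association table
#' `associations.tsv`, and `survival_results.tsv` (lncRNA, n_high, n_low,
#' logrank_stat, p) when the survival stage ran.
#'
#' @param x an `lncdrug_pipeline`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (dn in names(x$signatures))
    write_signature_tsv(x$signatures[[dn]],
                        file.path(outdir, paste0("signature_", dn, ".tsv")))
  write_association_tsv(x$association, file.path(outdir, "associations.tsv"))
  if (!is.null(x$survival) && length(x$survival)) {
    tab <- do.call(rbind, lapply(x$survival, function(s) {
      data.frame(lncRNA = s$lncRNA_id, n_high = s$logrank$n_high,
                 n_low = s$logrank$n_low, logrank_stat = s$logrank$statistic,
                 p = s$logrank$p, stringsAsFactors = FALSE)
    }))
    utils::write.table(tab, file.path(outdir, "survival_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}
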