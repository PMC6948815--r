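#' Drugs with enough treatment instances
#'
#' Keeps drugs whose treated-instance count is strictly greater than
#' `min_instances` (the published panel used drugs with more than ten
#' treatment instances), sorted by name.
#'
#' @param treatments treatment table (see [read_treatment_table()]).
#' @param min_instances strict lower bound on the treated-instance count.
#' @return Character vector of drug names (possibly empty).
#' @export
select_drugs <- function(treatments, min_instances = 10) {
  treatments <- validate_treatment_table(treatments)
  treated <- treatments[treatments$group == "treated", , drop = FALSE]
  if (nrow(treated) == 0) return(character(0))
  counts <- table(treated$drug_name)
  sort(names(counts)[counts > min_instances])
}

#' Per-gene differential expression between treated and control instances
#'
#' Computes, for every gene, the log2 fold change (mean treated minus mean
#' control, the values being on the log2 scale) and a two-sided p-value,
#' Benjamini-Hochberg adjusted across genes.  The default test is the Welch
#' two-sample t-test; `method = "moderated"` pools the two group variances
#' per gene and shrinks them toward the across-gene mean variance with
#' prior weight `d0 = 3`, stabilising small-sample estimates in the spirit
#' of moderated t statistics.
#'
#' @param expr `expr_matrix` of instances (genes x instances).
#' @param treated_ids,control_ids disjoint instance id sets, each of size
#'   >= 2.
#' @param method `"welch"` or `"moderated"`.
#' @return `data.frame` with columns `gene_id`, `logFC`, `pvalue`,
#'   `adj_pvalue` (one row per gene, in matrix row order).
#' @export
differential_expression <- function(expr, treated_ids, control_ids,
                                    method = c("welch", "moderated")) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(intersect(treated_ids, control_ids)))
    stop("treated and control groups overlap: ",
         paste(intersect(treated_ids, control_ids), collapse = ", "))
  missing <- setdiff(c(treated_ids, control_ids), colnames(expr))
  if (length(missing))
    stop("instance id(s) not in matrix: ", paste(missing, collapse = ", "))
  if (length(treated_ids) < 2 || length(control_ids) < 2)
    stop("need >= 2 instances per group")

  xt <- unclass(expr)[, treated_ids, drop = FALSE]
  xc <- unclass(expr)[, control_ids, drop = FALSE]
  n1 <- ncol(xt); n2 <- ncol(xc)
  m1 <- rowMeans(xt); m2 <- rowMeans(xc)
  v1 <- rowSums((xt - m1)^2) / (n1 - 1)
  v2 <- rowSums((xc - m2)^2) / (n2 - 1)
  lfc <- m1 - m2

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- lfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  } else {
    df <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    d0 <- 3                       # prior weight pulling toward the mean variance
    s2_shrunk <- (d0 * mean(s2) + df * s2) / (d0 + df)
    tstat <- lfc / sqrt(s2_shrunk * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(abs(tstat), df + d0, lower.tail = FALSE)
  }
  # zero variance in both groups: no evidence either way
  p[!is.finite(p)] <- 1
  p[v1 == 0 & v2 == 0 & lfc == 0] <- 1
  p <- pmin(pmax(p, 1e-300), 1)
  data.frame(gene_id = rownames(expr), logFC = lfc, pvalue = p,
             adj_pvalue = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signed min-max-normalised signature coefficients
#'
#' Turns a differential-expression table into per-gene signature
#' coefficients: `sig_i = |logFC_i| * (-log10 p_i)` with `p_i` the
#' BH-adjusted p-value, and
#' `c_i = sign(logFC_i) * (sig_i - mu) / (nu - mu)` where `mu`, `nu` are
#' the minimum and maximum of `sig` over the genes.  Coefficients lie in
#' `[-1, 1]`; genes with `|c|` close to one form the drug's gene signature.
#' If all `sig` are equal (`nu == mu`) the signature is degenerate and all
#' coefficients are zero (warned).
#'
#' @param de differential-expression table from
#'   [differential_expression()].
#' @param log_base base of the `-log(p)` transform (10 by default).
#' @param use_adjusted_p use `adj_pvalue` (default) or the raw `pvalue`.
#' @return An object of class `drug_signature`: list with `gene_ids`, `c`,
#'   `sig`, `mu`, `nu`, `logFC`, `de`.
#' @export
signature_coefficients <- function(de, log_base = 10, use_adjusted_p = TRUE) {
  if (is.null(de) || nrow(de) == 0) stop("empty differential-expression table")
  p <- if (use_adjusted_p) de$adj_pvalue else de$pvalue
  if (any(p == 0)) {
    warning("p-values of 0 clamped to 1e-300 before log transform")
    p <- pmax(p, 1e-300)
  }
  sig <- abs(de$logFC) * (-log(p, base = log_base))
  mu <- min(sig); nu <- max(sig)
  if (nu > mu) {
    cc <- sign(de$logFC) * (sig - mu) / (nu - mu)
  } else {
    warning("degenerate signature: all sig values equal; coefficients set to 0")
    cc <- rep(0, length(sig))
  }
  structure(list(gene_ids = de$gene_id, c = stats::setNames(cc, de$gene_id),
                 sig = stats::setNames(sig, de$gene_id), mu = mu, nu = nu,
                 logFC = stats::setNames(de$logFC, de$gene_id), de = de),
            class = "drug_signature")
}

#' @export
print.drug_signature <- function(x, ...) {
  cat("<drug_signature> ", length(x$c), " genes; |c| >= 0.9 for ",
      sum(abs(x$c) >= 0.9), " gene(s)\n", sep = "")
  invisible(x)
}

#' Per-drug gene signatures from a treated-vs-control panel
#'
#' The first pipeline stage: selects drugs with enough treated instances,
#' pools each drug's treated instances against its control instances
#' (drug-specific controls when present, otherwise the shared pool), runs
#' [differential_expression()] and converts the result to
#' [signature_coefficients()].  Drugs whose signature is degenerate (all
#' coefficients zero) are dropped with a warning.
#'
#' @param expr `expr_matrix` of instances (genes x instances).
#' @param treatments treatment table.
#' @param config a [pipeline_config()].
#' @return Object of class `drug_signature_set`: named list of
#'   `drug_signature` objects plus attributes `drugs` and `config`.
#' @export
drug_signatures <- function(expr, treatments, config = pipeline_config()) {
  config <- validate_config(config)
  drugs <- select_drugs(treatments, config$min_treatment_instances)
  if (length(drugs) == 0)
    stop("no drug has more than ", config$min_treatment_instances,
         " treated instances")
  sigs <- list()
  for (d in drugs) {
    treated <- treatments$instance_id[treatments$group == "treated" &
                                        treatments$drug_name == d]
    controls <- control_instances(treatments, d)
    de <- differential_expression(expr, treated, controls,
                                  method = config$de_method)
    sg <- signature_coefficients(de, log_base = config$log_base,
                                 use_adjusted_p = config$use_adjusted_p)
    if (sg$nu == sg$mu) {
      warning("drug '", d, "' skipped: degenerate signature")
      next
    }
    sg$drug_name <- d
    sigs[[d]] <- sg
  }
  structure(sigs, drugs = names(sigs), config = config,
            class = "drug_signature_set")
}

#' @export
print.drug_signature_set <- function(x, ...) {
  cat("<drug_signature_set> ", length(x), " drug(s): ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
#' @describeIn drug_signatures genes x drugs matrix of signature
#'   coefficients.
#' @param object a `drug_signature_set`.
#' @param ... unused.
coef.drug_signature_set <- function(object, ...) {
  genes <- object[[1]]$gene_ids
  vapply(object, function(s) s$c[genes], numeric(length(genes)))
}

#' Write a signature table TSV
#'
#' Columns: `gene`, `logFC`, `pvalue`, `adj_pvalue`, `c`.
#'
#' @param sig a `drug_signature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(sig, path) {
  tab <- data.frame(gene = sig$de$gene_id, logFC = sig$de$logFC,
                    pvalue = sig$de$pvalue, adj_pvalue = sig$de$adj_pvalue,
                    c = unname(sig$c))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
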