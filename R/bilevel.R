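#' Upper-level association scores (closed form)
#'
#' For a drug with signature coefficients `c` and a decision-value matrix
#' `f` (lncRNAs x genes), the upper-level problem minimises over `d` the
#' separable weighted least squares
#' `sum_i |c_i| * (sign(c_i) * f_ij - d_j)^2` for every lncRNA `j`.  Its
#' unique minimiser is the weighted mean
#' `d_j = sum_i c_i f_ij / sum_i |c_i|`: genes with large positive
#' coefficients pull `d_j` toward their decision values, genes with large
#' negative coefficients toward the negated ones, and genes with `c_i = 0`
#' contribute nothing.  The gene sets of `c` and `f` are intersected first.
#'
#' @param sig a `drug_signature` (or a named numeric vector of
#'   coefficients).
#' @param assoc an `assoc_matrix` (or a named decision-value matrix,
#'   lncRNAs x genes).
#' @return Named numeric vector `d` over the lncRNAs.
#' @export
upper_solution <- function(sig, assoc) {
  cc <- if (inherits(sig, "drug_signature")) sig$c else sig
  f <- if (inherits(assoc, "assoc_matrix")) assoc$f else assoc
  genes <- intersect(names(cc), colnames(f))
  cc <- cc[genes]
  genes <- genes[cc != 0]
  if (length(genes) == 0)
    stop("empty signature: no shared gene with a nonzero coefficient")
  cc <- cc[genes]
  drop(f[, genes, drop = FALSE] %*% cc) / sum(abs(cc))
}

#' Upper-level scores by numeric minimisation (verification mode)
#'
#' Minimises the same weighted least-squares objective with a
#' gradient-supplied quasi-Newton search ([stats::nlm()]) started at zero,
#' mirroring the original implementation; retained purely to verify the
#' closed form.
#'
#' @inheritParams upper_solution
#' @param gradtol convergence tolerance passed to `nlm`.
#' @return Named numeric vector `d`.
#' @export
upper_solution_numeric <- function(sig, assoc, gradtol = 1e-12) {
  cc <- if (inherits(sig, "drug_signature")) sig$c else sig
  f <- if (inherits(assoc, "assoc_matrix")) assoc$f else assoc
  genes <- intersect(names(cc), colnames(f))
  cc <- cc[genes]
  genes <- genes[cc != 0]
  if (length(genes) == 0)
    stop("empty signature: no shared gene with a nonzero coefficient")
  cc <- cc[genes]
  f <- f[, genes, drop = FALSE]
  w <- abs(cc)
  target <- sweep(f, 2, sign(cc), "*")     # sign(c_i) * f_ij
  obj <- function(d) {
    resid <- sweep(-target, 1, d, "+")     # d_j - sign(c_i) f_ij
    val <- sum(sweep(resid^2, 2, w, "*"))
    attr(val, "gradient") <- 2 * drop(resid %*% w)
    val
  }
  res <- stats::nlm(obj, p = numeric(nrow(f)), gradtol = gradtol,
                    iterlim = 1000, check.analyticals = FALSE)
  stats::setNames(res$estimate, rownames(f))
}

#' Rank lncRNAs by score and apply the specificity filter
#'
#' lncRNAs are sorted by descending `d` with ties broken by identifier
#' (ascending); the `top_k` among them whose empirical specificity p-value
#' is below `selection_pvalue` are returned in rank order.
#'
#' @param d named score vector from [upper_solution()].
#' @param top_k number of top-ranked lncRNAs considered.
#' @param selection_pvalue strict upper bound on the empirical p.
#' @param empirical_p named p-value vector over (at least) the ranked
#'   lncRNAs.
#' @return Character vector of selected lncRNA ids (possibly empty), in
#'   rank order.
#' @export
rank_and_select <- function(d, top_k, selection_pvalue, empirical_p) {
  ord <- rank_lncrnas(d)
  top <- ord[seq_len(min(top_k, length(ord)))]
  top[empirical_p[top] < selection_pvalue]
}

# descending-d order, ties by identifier ascending
rank_lncrnas <- function(d) {
  names(d)[order(-d, names(d), method = "radix")]
}

#' Empirical specificity p-values from top-score lists
#'
#' The p-value of a lncRNA is the fraction of drugs in the panel whose
#' (unfiltered) top-k list contains it; lncRNAs appearing in no list are
#' assigned the floor `1 / n_drugs` so that p stays strictly positive.
#' Low values flag lncRNAs linked to few, specific drugs; a lncRNA pulled
#' up by every drug is unspecific (p near 1).
#'
#' @param top_lists list (one element per drug) of character vectors of
#'   top-k lncRNA ids.
#' @param lncRNA_ids ids to report p-values for (defaults to the union of
#'   the lists).
#' @return Named numeric vector of p-values in `(0, 1]`.
#' @export
empirical_pvalue <- function(top_lists, lncRNA_ids = NULL) {
  n_drugs <- length(top_lists)
  if (n_drugs == 0) stop("empty drug panel")
  if (is.null(lncRNA_ids)) lncRNA_ids <- sort(unique(unlist(top_lists)))
  counts <- vapply(lncRNA_ids, function(l) {
    sum(vapply(top_lists, function(tl) l %in% tl, logical(1)))
  }, numeric(1))
  pmax(counts, 1) / n_drugs
}

#' Signature-gene overlap of one lncRNA
#'
#' Number of genes that are simultaneously signature genes of the drug
#' (`|c_i| >=` `signature_gene_threshold`) and strongly associated with the
#' lncRNA (calibrated score `s_ij >=` `assoc_score_threshold`).
#'
#' @param sig a `drug_signature`.
#' @param assoc an `assoc_matrix`.
#' @param lncRNA_id the lncRNA to count for.
#' @param config a [pipeline_config()] supplying the two thresholds.
#' @return Integer overlap count.
#' @export
overlap_count <- function(sig, assoc, lncRNA_id, config = pipeline_config()) {
  if (!lncRNA_id %in% assoc$lncRNA_ids)
    stop("unknown lncRNA: ", lncRNA_id)
  genes <- intersect(names(sig$c), assoc$gene_ids)
  in_sig <- abs(sig$c[genes]) >= config$signature_gene_threshold
  strong <- assoc$s[lncRNA_id, genes] >= config$assoc_score_threshold
  sum(in_sig & strong)
}

#' Mid-rank percentile rank score of a predicted lncRNA
#'
#' Places the predicted lncRNA's signature-gene overlap among all lncRNAs:
#' `RS = (f_b + 0.5 * f_w) / N * 100`, where `f_b` counts lncRNAs with
#' strictly fewer overlapping genes, `f_w` counts those with equal overlap
#' (the predicted lncRNA itself included, so `f_w >= 1`), and `N` is the
#' number of lncRNAs.  Scores near 100 mean few competitors share as many
#' signature genes with the drug as the prediction does.
#'
#' @param overlaps named integer vector of per-lncRNA overlap counts.
#' @param predicted id of the predicted lncRNA (must be in `overlaps`).
#' @return List with `rs`, `f_b`, `f_w`, `n`.
#' @export
rank_score <- function(overlaps, predicted) {
  if (!predicted %in% names(overlaps))
    stop("predicted lncRNA '", predicted, "' not in overlap vector")
  o <- overlaps[[predicted]]
  f_b <- sum(overlaps < o)
  f_w <- sum(overlaps == o)
  list(rs = (f_b + 0.5 * f_w) / length(overlaps) * 100,
       f_b = f_b, f_w = f_w, n = length(overlaps))
}

#' Associate drugs with lncRNAs
#'
#' The upper-level stage: for every drug signature, solve the weighted
#' least-squares problem over the decision-value matrix
#' ([upper_solution()]), rank the lncRNAs, pool the per-drug top-k lists
#' into empirical specificity p-values, apply the top-k / p-value
#' selection, and score each selected lncRNA's signature-gene overlap with
#' the mid-rank percentile [rank_score()].
#'
#' @param sigs a `drug_signature_set` from [drug_signatures()].
#' @param assoc an `assoc_matrix` from [score_pairs()] /
#'   [predict.coexpr_model()].
#' @param config a [pipeline_config()].
#' @return Object of class `drug_assoc`: per-drug list with `d`, `rank`,
#'   `top`, `selected`, `rs`, `overlap`, plus shared `empirical_p` and the
#'   config.
#' @export
associate_drugs <- function(sigs, assoc, config = pipeline_config()) {
  stopifnot(inherits(sigs, "drug_signature_set"),
            inherits(assoc, "assoc_matrix"))
  config <- validate_config(config)
  per_drug <- lapply(sigs, function(sg) {
    d <- upper_solution(sg, assoc)
    ord <- rank_lncrnas(d)
    list(d = d, rank = ord, top = ord[seq_len(min(config$top_k, length(ord)))])
  })
  emp_p <- empirical_pvalue(lapply(per_drug, `[[`, "top"),
                            lncRNA_ids = assoc$lncRNA_ids)
  for (dn in names(per_drug)) {
    sel <- per_drug[[dn]]$top[emp_p[per_drug[[dn]]$top] < config$selection_pvalue]
    per_drug[[dn]]$selected <- sel
    ov <- vapply(assoc$lncRNA_ids, function(l)
      overlap_count(sigs[[dn]], assoc, l, config), numeric(1))
    per_drug[[dn]]$overlap <- ov
    per_drug[[dn]]$rs <- lapply(stats::setNames(nm = sel),
                                function(l) rank_score(ov, l))
  }
  structure(list(drugs = per_drug, empirical_p = emp_p,
                 lncRNA_ids = assoc$lncRNA_ids, config = config),
            class = "drug_assoc")
}

#' @export
print.drug_assoc <- function(x, ...) {
  cat("<drug_assoc> ", length(x$drugs), " drug(s) x ",
      length(x$lncRNA_ids), " lncRNAs\n", sep = "")
  for (dn in names(x$drugs)) {
    pd <- x$drugs[[dn]]
    cat("  ", dn, ": top hit ", pd$rank[1], " (d = ",
        signif(pd$d[pd$rank[1]], 4), "), ", length(pd$selected),
        " selected\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.drug_assoc <- function(object, ...) {
  as.data.frame(object)
}

#' @export
#' @describeIn associate_drugs long-format association table: one row per
#'   (drug, lncRNA) with score, rank, empirical p, rank score of selected
#'   hits and the overlap count.
#' @param x a `drug_assoc`.
#' @param row.names,optional,... ignored (S3 signature).
as.data.frame.drug_assoc <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  out <- do.call(rbind, lapply(names(x$drugs), function(dn) {
    pd <- x$drugs[[dn]]
    ids <- pd$rank
    data.frame(drug = dn, lncRNA = ids, d = unname(pd$d[ids]),
               rank = seq_along(ids),
               empirical_p = unname(x$empirical_p[ids]),
               selected = ids %in% pd$selected,
               RS = vapply(ids, function(l)
                 if (l %in% names(pd$rs)) pd$rs[[l]]$rs else NA_real_,
                 numeric(1)),
               n_overlap_genes = unname(pd$overlap[ids]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' @export
#' @describeIn associate_drugs lncRNA x drug matrix of association scores
#'   `d`.
#' @param object a `drug_assoc`.
coef.drug_assoc <- function(object, ...) {
  vapply(object$drugs, function(pd) pd$d[object$lncRNA_ids],
         numeric(length(object$lncRNA_ids)))
}

#' @export
plot.drug_assoc <- function(x, drug = names(x$drugs)[1], ...) {
  pd <- x$drugs[[drug]]
  d <- sort(pd$d, decreasing = TRUE)
  graphics::plot(seq_along(d), d, type = "h", xlab = "lncRNA rank",
                 ylab = "association score d",
                 main = paste0(drug, ": lncRNA association scores"), ...)
  sel <- which(names(d) %in% pd$selected)
  if (length(sel))
    graphics::points(sel, d[sel], pch = 19, col = "red")
  invisible(x)
}

#' Write the association table TSV
#'
#' Columns: `drug`, `lncRNA`, `d`, `rank`, `empirical_p`, `selected`, `RS`,
#' `n_overlap_genes`.
#'
#' @param x a `drug_assoc`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
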