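#' Expression matrix container
#'
#' A thin validated container for a features x samples expression matrix.
#' Values are log2-scale unless `raw_counts = TRUE`, in which case they are
#' non-negative counts left untransformed (use [log2_counts()] to transform).
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids character vector of unique row identifiers.
#' @param sample_ids character vector of unique column identifiers.
#' @param raw_counts logical; `TRUE` marks the values as untransformed counts.
#' @return An object of class `expr_matrix`: the numeric matrix with dimnames
#'   set and attributes `raw_counts`.
#' @export
expr_matrix <- function(values, feature_ids = rownames(values),
                        sample_ids = colnames(values), raw_counts = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(feature_ids))
    stop("number of rows (", nrow(values), ") does not match feature_ids (",
         length(feature_ids), ")")
  if (ncol(values) != length(sample_ids))
    stop("number of columns (", ncol(values), ") does not match sample_ids (",
         length(sample_ids), ")")
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    stop("duplicate feature identifier(s): ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite value at feature '", feature_ids[bad[1]],
         "', sample '", sample_ids[bad[2]], "'")
  }
  if (raw_counts && any(values < 0))
    stop("raw-counts matrix contains negative values")
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, raw_counts = raw_counts, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x), " features x ", ncol(x), " samples",
      if (isTRUE(attr(x, "raw_counts"))) " (raw counts)" else " (log2 scale)",
      "\n", sep = "")
  invisible(x)
}

#' Log2-transform a raw-counts expression matrix
#'
#' Applies `log2(x + 1)`; the pseudocount of one is the standard convention
#' for count matrices containing zeros.
#'
#' @param x an `expr_matrix` flagged as raw counts.
#' @return An `expr_matrix` on the log2 scale.
#' @export
log2_counts <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!isTRUE(attr(x, "raw_counts")))
    stop("matrix is not flagged as raw counts")
  expr_matrix(log2(unclass(x) + 1), rownames(x), colnames(x), raw_counts = FALSE)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated, UTF-8, unquoted table whose header row holds
#' sample identifiers and whose first column holds feature identifiers
#' (TCGA level-3 style layout).
#'
#' @param path file path.
#' @param raw_counts logical; flag the values as untransformed counts.
#' @return An [expr_matrix()].
#' @export
read_expression_tsv <- function(path, raw_counts = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected a feature-id column plus >=1 sample column in ", path)
  feature_ids <- tab[[1]]
  sample_ids <- colnames(tab)[-1]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample identifier(s) in header of ", path, ": ",
         paste(dup, collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric or non-finite cell '", vals[bad[1, 1], bad[1, 2]],
         "' at feature '", feature_ids[bad[1, 1]], "', sample '",
         sample_ids[bad[1, 2]], "' in ", path)
  }
  expr_matrix(num, feature_ids, sample_ids, raw_counts = raw_counts)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]: tab-separated, header row of sample
#' IDs, first column of feature IDs, no quoting.  Values are written with
#' full precision (`format(..., digits = 17)`) so a write-then-read
#' round-trip is bit-exact.
#'
#' @param x an `expr_matrix`.
#' @param path output file path.
#' @param id_column header name of the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, id_column = "feature_id") {
  stopifnot(inherits(x, "expr_matrix"))
  vals <- format(unclass(x), digits = 17, trim = TRUE, scientific = FALSE)
  tab <- cbind(rownames(x), vals)
  colnames(tab) <- c(id_column, colnames(x))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Restrict two expression matrices to their shared samples
#'
#' lncRNA and mRNA profiles typically come from different quantifications of
#' the same patients; this pairs them by sample identifier.  Both outputs
#' carry the intersection of the sample sets, in the same (sorted) column
#' order.
#'
#' @param lnc,mrna `expr_matrix` objects.
#' @return A list with elements `lnc`, `mrna` (column-aligned) and
#'   `n_shared`, the intersection size.
#' @export
align_samples <- function(lnc, mrna) {
  stopifnot(inherits(lnc, "expr_matrix"), inherits(mrna, "expr_matrix"))
  if (ncol(lnc) == 0 || ncol(mrna) == 0) stop("empty expression matrix")
  shared <- sort(intersect(colnames(lnc), colnames(mrna)))
  if (length(shared) == 0)
    stop("no shared samples between the two expression matrices")
  list(lnc = expr_matrix(unclass(lnc)[, shared, drop = FALSE],
                         rownames(lnc), shared,
                         raw_counts = isTRUE(attr(lnc, "raw_counts"))),
       mrna = expr_matrix(unclass(mrna)[, shared, drop = FALSE],
                          rownames(mrna), shared,
                          raw_counts = isTRUE(attr(mrna, "raw_counts"))),
       n_shared = length(shared))
}

#' Read a treatment design table
#'
#' Three tab-separated columns: `instance_id`, `drug_name`, `group`
#' (`treated` or `control`).  Every instance appears once; every drug with
#' treated instances must have at least one control instance available
#' (controls may be shared across drugs, marked by an empty drug name or
#' the drug name `vehicle`).
#'
#' @param path file path.
#' @return A `data.frame` with columns `instance_id`, `drug_name`, `group`.
#' @export
read_treatment_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_treatment_table(tab)
}

#' Validate a treatment design table
#'
#' @param tab data.frame with columns `instance_id`, `drug_name`, `group`.
#' @return The validated table (invisibly usable), with `group` checked.
#' @export
validate_treatment_table <- function(tab) {
  need <- c("instance_id", "drug_name", "group")
  if (!all(need %in% colnames(tab)))
    stop("treatment table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  dup <- unique(tab$instance_id[duplicated(tab$instance_id)])
  if (length(dup))
    stop("duplicate instance_id(s): ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(tab$group), c("treated", "control"))
  if (length(bad))
    stop("group must be 'treated' or 'control'; found: ",
         paste(bad, collapse = ", "))
  n_ctrl <- sum(tab$group == "control")
  drugs <- unique(tab$drug_name[tab$group == "treated"])
  for (d in drugs) {
    own <- sum(tab$group == "control" & tab$drug_name == d)
    if (own == 0 && n_ctrl == 0)
      stop("drug '", d, "' has treated instances but no control instance")
  }
  tab
}

#' Control instances available for one drug
#'
#' Drug-specific controls if any exist, otherwise the shared control pool.
#'
#' @param tab treatment table.
#' @param drug drug name.
#' @return Character vector of control instance ids.
#' @export
control_instances <- function(tab, drug) {
  own <- tab$instance_id[tab$group == "control" & tab$drug_name == drug]
  if (length(own)) return(own)
  tab$instance_id[tab$group == "control"]
}

#' Read patient survival records
#'
#' Tab-separated columns `patient_id`, `time`, `event` (1 = death observed,
#' 0 = censored).
#'
#' @param path file path.
#' @return `data.frame` with `patient_id` (character), `time` (numeric,
#'   non-negative) and `event` (integer 0/1).
#' @export
read_survival_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% colnames(tab)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  tab$patient_id <- as.character(tab$patient_id)
  tab$time <- as.numeric(tab$time)
  tab$event <- as.integer(tab$event)
  if (any(!is.finite(tab$time)) || any(tab$time < 0))
    stop("survival times must be finite and non-negative")
  if (!all(tab$event %in% c(0L, 1L)))
    stop("event must be 0 (censored) or 1 (death observed)")
  tab[, need]
}

#' Write a survival record table to TSV
#' @param records survival data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
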