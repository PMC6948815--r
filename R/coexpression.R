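#' Pearson correlation between every lncRNA and every gene
#'
#' Profiles must already be sample-aligned (see [align_samples()]).
#' Zero-variance profiles would make the correlation undefined; those
#' entries are recorded as 0 and flagged in the `zero_variance` attribute.
#'
#' @param lnc,mrna sample-aligned `expr_matrix` objects.
#' @return Numeric matrix (lncRNAs x genes) of correlations in `[-1, 1]`,
#'   with attribute `zero_variance` (logical matrix) marking entries set to
#'   0 for lack of variance.
#' @export
pcc_matrix <- function(lnc, mrna) {
  stopifnot(inherits(lnc, "expr_matrix"), inherits(mrna, "expr_matrix"))
  if (!identical(colnames(lnc), colnames(mrna)))
    stop("matrices are not sample-aligned; run align_samples() first")
  if (ncol(lnc) < 3) stop("need >= 3 samples for correlation")
  r <- suppressWarnings(stats::cor(t(unclass(lnc)), t(unclass(mrna))))
  flag <- is.na(r)
  r[flag] <- 0
  attr(r, "zero_variance") <- flag
  r
}

#' Concatenated-expression features for lncRNA-gene pairs
#'
#' Each pair is represented by the lncRNA's expression profile followed by
#' the gene's expression profile over the aligned samples (feature length
#' `2 * n_samples`).
#'
#' @param lnc,mrna sample-aligned `expr_matrix` objects.
#' @param pairs data.frame with columns `lncRNA_id`, `gene_id`.
#' @return Numeric matrix, one row per pair.
#' @export
pair_features <- function(lnc, mrna, pairs) {
  cbind(unclass(lnc)[pairs$lncRNA_id, , drop = FALSE],
        unclass(mrna)[pairs$gene_id, , drop = FALSE])
}

#' Build the labeled lncRNA-gene training set
#'
#' Positives are pairs whose PCC exceeds `pos_pcc_threshold`; negative
#' candidates are pairs with |PCC| below `neg_pcc_threshold` ("close to
#' zero"), subsampled without replacement to `neg_pos_ratio` times the
#' positive count.  All other pairs stay unlabeled and are scored later by
#' the trained model.
#'
#' @param pcc correlation matrix from [pcc_matrix()].
#' @param lnc,mrna the sample-aligned matrices the correlations came from.
#' @param config a [pipeline_config()]; thresholds and `neg_pos_ratio` are
#'   taken from it.
#' @param seed seed for the negative subsample.
#' @return Object of class `pair_dataset`: list with `pairs` (data.frame
#'   `lncRNA_id`, `gene_id`), `x` (feature matrix), `y` (+1/-1 labels),
#'   `n_samples`, `n_pos`, `n_neg`.
#' @export
build_training_set <- function(pcc, lnc, mrna, config = pipeline_config(),
                               seed = config$rng_seed) {
  config <- validate_config(config)
  if (!identical(dim(pcc), c(nrow(lnc), nrow(mrna))))
    stop("pcc dimensions do not match the expression matrices")
  pos_idx <- which(pcc > config$pos_pcc_threshold, arr.ind = TRUE)
  neg_idx <- which(abs(pcc) < config$neg_pcc_threshold, arr.ind = TRUE)
  if (nrow(pos_idx) == 0)
    stop("no positive pairs at PCC > ", config$pos_pcc_threshold,
         "; consider relaxing pos_pcc_threshold")
  n_neg <- round(config$neg_pos_ratio * nrow(pos_idx))
  if (nrow(neg_idx) < n_neg)
    stop("only ", nrow(neg_idx), " near-zero pairs at |PCC| < ",
         config$neg_pcc_threshold, " but ", n_neg,
         " negatives required; consider raising neg_pcc_threshold")
  # fix pair order before sampling so the draw depends only on (pcc, config, seed)
  ord <- order(neg_idx[, 1], neg_idx[, 2])
  neg_idx <- neg_idx[ord, , drop = FALSE]
  keep <- with_seed(seed, sample.int(nrow(neg_idx), n_neg))
  neg_idx <- neg_idx[sort(keep), , drop = FALSE]
  pos_idx <- pos_idx[order(pos_idx[, 1], pos_idx[, 2]), , drop = FALSE]

  pairs <- data.frame(
    lncRNA_id = rownames(lnc)[c(pos_idx[, 1], neg_idx[, 1])],
    gene_id = rownames(mrna)[c(pos_idx[, 2], neg_idx[, 2])],
    stringsAsFactors = FALSE)
  y <- c(rep(1, nrow(pos_idx)), rep(-1, nrow(neg_idx)))
  structure(list(pairs = pairs, x = pair_features(lnc, mrna, pairs), y = y,
                 n_samples = ncol(lnc), n_pos = nrow(pos_idx),
                 n_neg = nrow(neg_idx)),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat("<pair_dataset> ", length(x$y), " labeled pairs (",
      x$n_pos, " +, ", x$n_neg, " -), feature length ",
      ncol(x$x), "\n", sep = "")
  invisible(x)
}

#' Default hyperparameter grid for the pair classifier
#'
#' Box constraint `C` over `2^-5 ... 2^15` and RBF width `gamma` over
#' `2^-15 ... 2^1`, both by powers of four.
#'
#' @return List with numeric vectors `C` and `gamma`.
#' @export
default_svm_grid <- function() {
  list(C = 2^seq(-5, 15, by = 4), gamma = 2^seq(-15, 3, by = 4))
}

# reference RBF width: reciprocal lower-decile squared pairwise distance,
# i.e. the near-neighbour scale (the upper end of kernlab::sigest's range).
# The bulk median mixes mostly-unrelated pairs and puts the kernel at the
# edge of its near-linear regime, where the decision surface degenerates
# to an additive function of the two profile halves.
reference_gamma <- function(x, max_rows = 200, seed = 0) {
  if (nrow(x) > max_rows)
    x <- x[with_seed(seed, sample.int(nrow(x), max_rows)), , drop = FALSE]
  d2 <- stats::dist(x)^2
  m <- stats::quantile(d2[d2 > 0], 0.1, names = FALSE)
  if (!is.finite(m) || m <= 0) return(1 / ncol(x))
  1 / m
}

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# stratified fold assignment; retries until every fold sees both classes
stratified_folds <- function(y, k, seed, max_attempts = 10) {
  for (attempt in seq_len(max_attempts)) {
    fold <- with_seed(seed + attempt - 1, {
      f <- integer(length(y))
      for (cls in unique(y)) {
        idx <- which(y == cls)
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      f
    })
    ok <- all(vapply(seq_len(k), function(i) {
      length(unique(y[fold != i])) == 2
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build ", k, "-fold split with both classes in every ",
       "training fold after ", max_attempts, " attempts")
}

fit_svm_raw <- function(x, y, C, gamma, tolerance = 0.001) {
  e1071::svm(x, factor(y, levels = c(1, -1)), type = "C-classification",
             kernel = "radial", cost = C, gamma = gamma, scale = FALSE,
             tolerance = tolerance)
}

# decision values f(x) = sum_t alpha_t y_t K(x_t, x) + b from a fitted
# libsvm model, oriented so positive values mean class "1".  libsvm signs
# its decision for whichever class appears first in the training data
# (model$labels records the internal order), so the raw value is flipped
# when that class is "-1".
svm_decision <- function(model, x, gamma) {
  orient <- if (model$levels[model$labels[1]] == "1") 1 else -1
  k <- rbf_kernel(x, model$SV, gamma)
  orient * (drop(k %*% model$coefs) - model$rho)
}

#' Train the lncRNA-gene pair classifier
#'
#' Soft-margin RBF-kernel SVM (libsvm via \pkg{e1071}) on the labeled
#' pairs.  `C` and the kernel width are chosen by grid search maximising
#' the mean held-out AUC over an inner cross-validation; the final model is
#' refit on all labeled pairs.  Because held-out AUC is a ranking criterion,
#' many grid points can tie at the maximum (a nearly linear kernel ranks
#' the labeled pairs just as well as a local one while its decision surface
#' degenerates to an additive function of the two profile halves); ties are
#' therefore broken toward the kernel width closest to the near-neighbour
#' distance scale `gamma = 1 / quantile(||x - x'||^2, 0.1)` (the upper end
#' of the \pkg{kernlab} `sigest` range), at which the RBF kernel is
#' genuinely local, and then toward the largest
#' `C`: with separable training classes every sufficiently large box
#' constraint yields the same maximal-margin classifier, whereas a small
#' one caps all dual coefficients and flattens the decision surface toward
#' a kernel-mean score.  A Platt-style sigmoid mapping decision
#' values to `[0, 1]` is fit on out-of-fold decision values at the selected
#' hyperparameters, so calibrated scores never see their own training
#' predictions.
#'
#' @param ds a [build_training_set()] result (both classes present).
#' @param grid list with vectors `C` and `gamma`; see
#'   [default_svm_grid()].
#' @param inner_folds folds of the inner model-selection CV.
#' @param seed seed for the fold splits.
#' @param tolerance libsvm termination tolerance.
#' @return Object of class `coexpr_svm`: the fitted model plus `C`,
#'   `gamma`, `alpha` (dual coefficients, full length), `b`, `calibration`
#'   `(A, B)` with calibrated score `plogis(A * f + B)`, `cv_auc` of the
#'   selected grid point, and the training data reference.
#' @export
train_svm <- function(ds, grid = default_svm_grid(), inner_folds = 3,
                      seed = 1, tolerance = 0.001) {
  stopifnot(inherits(ds, "pair_dataset"))
  if (length(unique(ds$y)) < 2)
    stop("training set contains a single class")
  fold <- stratified_folds(ds$y, inner_folds, seed)
  combos <- expand.grid(C = grid$C, gamma = grid$gamma)
  # order so that the first AUC maximum is the combo nearest the
  # reference gamma (then largest C): the principled tie-break
  gamma_ref <- reference_gamma(ds$x)
  combos <- combos[order(abs(log(combos$gamma) - log(gamma_ref)), -combos$C), ]
  mean_auc <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    aucs <- vapply(seq_len(inner_folds), function(k) {
      tr <- fold != k
      m <- fit_svm_raw(ds$x[tr, , drop = FALSE], ds$y[tr],
                       combos$C[i], combos$gamma[i], tolerance)
      f <- svm_decision(m, ds$x[!tr, , drop = FALSE], combos$gamma[i])
      auc_score(f, ds$y[!tr])
    }, numeric(1))
    mean_auc[i] <- mean(aucs)
  }
  best <- which.max(mean_auc)   # first maximum: deterministic tie-break
  C <- combos$C[best]; gamma <- combos$gamma[best]

  # out-of-fold decision values at the chosen hyperparameters -> calibration
  oof <- numeric(length(ds$y))
  for (k in seq_len(inner_folds)) {
    tr <- fold != k
    m <- fit_svm_raw(ds$x[tr, , drop = FALSE], ds$y[tr], C, gamma, tolerance)
    oof[!tr] <- svm_decision(m, ds$x[!tr, , drop = FALSE], gamma)
  }
  calibration <- platt_calibration(oof, ds$y)

  model <- fit_svm_raw(ds$x, ds$y, C, gamma, tolerance)
  orient <- if (model$levels[model$labels[1]] == "1") 1 else -1
  alpha <- numeric(length(ds$y))
  alpha[model$index] <- abs(model$coefs)
  structure(list(model = model, C = C, gamma = gamma,
                 alpha = alpha, b = -orient * model$rho,
                 sv_index = model$index, calibration = calibration,
                 cv_auc = mean_auc[best], grid = grid, ds = ds),
            class = "coexpr_svm")
}

# Platt sigmoid s = plogis(A * f + B); slope constrained positive so the
# calibrated score is monotone in the decision value
platt_calibration <- function(f, y) {
  y01 <- as.integer(y > 0)
  fit <- suppressWarnings(stats::glm(y01 ~ f, family = stats::binomial()))
  A <- unname(stats::coef(fit)[2]); B <- unname(stats::coef(fit)[1])
  if (!is.finite(A) || A <= 0) {
    warning("calibration slope not positive; falling back to plogis(f)")
    A <- 1; B <- 0
  }
  c(A = A, B = B)
}

#' @export
print.coexpr_svm <- function(x, ...) {
  cat("<coexpr_svm> RBF SVM on ", length(x$ds$y), " labeled pairs; C = ",
      format(x$C), ", gamma = ", format(x$gamma), ", ",
      length(x$sv_index), " support vectors; inner-CV AUC = ",
      round(x$cv_auc, 4), "\n", sep = "")
  invisible(x)
}

#' Decision values and calibrated scores for arbitrary pair features
#'
#' @param object a `coexpr_svm`.
#' @param x feature matrix (rows are pairs, concatenated profiles).
#' @return List with `f` (decision values) and `s` (calibrated scores in
#'   `[0, 1]`).
#' @export
decision_values <- function(object, x) {
  stopifnot(inherits(object, "coexpr_svm"))
  if (ncol(x) != ncol(object$ds$x))
    stop("feature length ", ncol(x), " does not match training dimension ",
         ncol(object$ds$x))
  f <- svm_decision(object$model, x, object$gamma)
  list(f = f, s = stats::plogis(object$calibration["A"] * f +
                                  object$calibration["B"]))
}

#' Score every lncRNA-gene pair
#'
#' Applies the trained classifier to all pairs of the given matrices,
#' returning raw decision values `f` (consumed by the upper-level
#' association solver) and calibrated scores `s` in `[0, 1]` (used for the
#' overlap / threshold analyses).
#'
#' @param fit a [train_svm()] model.
#' @param lnc,mrna sample-aligned `expr_matrix` objects.
#' @return Object of class `assoc_matrix`: list with `f` and `s` (lncRNA x
#'   gene matrices), `lncRNA_ids`, `gene_ids`.
#' @export
score_pairs <- function(fit, lnc, mrna) {
  stopifnot(inherits(fit, "coexpr_svm"))
  if (2L * ncol(lnc) != ncol(fit$ds$x))
    stop("sample count ", ncol(lnc), " does not match training dimension (",
         ncol(fit$ds$x), " features)")
  n_l <- nrow(lnc); n_g <- nrow(mrna)
  f <- matrix(NA_real_, n_l, n_g, dimnames = list(rownames(lnc), rownames(mrna)))
  gene_block <- unclass(mrna)
  for (j in seq_len(n_l)) {       # one lncRNA at a time keeps memory flat
    x <- cbind(matrix(unclass(lnc)[j, ], n_g, ncol(lnc), byrow = TRUE),
               gene_block)
    f[j, ] <- svm_decision(fit$model, x, fit$gamma)
  }
  s <- stats::plogis(fit$calibration["A"] * f + fit$calibration["B"])
  structure(list(f = f, s = s, lncRNA_ids = rownames(lnc),
                 gene_ids = rownames(mrna)),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat("<assoc_matrix> ", length(x$lncRNA_ids), " lncRNAs x ",
      length(x$gene_ids), " genes; calibrated scores in [",
      round(min(x$s), 3), ", ", round(max(x$s), 3), "]\n", sep = "")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with mid-rank handling of ties.
#'
#' @param scores numeric prediction scores.
#' @param labels labels; positives are `> 0` (or `TRUE`).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: precision is accumulated at every positive
#' encountered when sweeping the scores in descending order (ties broken by
#' original position, deterministically).
#'
#' @inheritParams auc_score
#' @return AUPR in `(0, 1]`.
#' @export
aupr_score <- function(scores, labels) {
  pos <- labels > 0
  if (!any(pos)) return(NA_real_)
  ord <- order(-scores, seq_along(scores))
  hit <- pos[ord]
  prec <- cumsum(hit) / seq_along(hit)
  sum(prec[hit]) / sum(hit)
}

#' Confusion-matrix classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy, precision
#' `TP/(TP+FP)` and the F-measure defined as the geometric mean
#' `sqrt(Sn * Sp)`.
#'
#' @param tp,fn,tn,fp confusion-matrix counts.
#' @return Named list with `acc`, `sn`, `sp`, `pre`, `f_measure`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  sn <- tp / (tp + fn); sp <- tn / (tn + fp)
  list(acc = (tp + tn) / (tp + fn + tn + fp), sn = sn, sp = sp,
       pre = tp / (tp + fp), f_measure = sqrt(sn * sp))
}

#' Cross-validated performance of the pair classifier
#'
#' Stratified outer cross-validation; within each training fold the full
#' [train_svm()] procedure (inner grid search and calibration) is rerun, so
#' the held-out predictions never inform hyperparameter choice.  Metrics
#' are pooled over all held-out predictions: AUC and AUPR on the decision
#' values, and the confusion-matrix metrics at threshold 0.5 on the
#' calibrated score.
#'
#' @param ds a [build_training_set()] result with `n >= outer_folds` per
#'   class.
#' @param outer_folds number of evaluation folds.
#' @param seed seed for the fold splits.
#' @param grid,inner_folds,tolerance passed to [train_svm()].
#' @return Object of class `cv_metrics`: list with `auc`, `aupr`, `acc`,
#'   `sn`, `sp`, `pre`, `f_measure`, plus the pooled `scores`, `decisions`
#'   and `labels`.
#' @export
evaluate_cv <- function(ds, outer_folds = 5, seed = 1,
                        grid = default_svm_grid(), inner_folds = 3,
                        tolerance = 0.001) {
  stopifnot(inherits(ds, "pair_dataset"))
  if (length(unique(ds$y)) < 2) stop("training set contains a single class")
  if (length(ds$y) < outer_folds) stop("fewer labeled pairs than folds")
  fold <- stratified_folds(ds$y, outer_folds, seed)
  f_all <- numeric(length(ds$y)); s_all <- numeric(length(ds$y))
  for (k in seq_len(outer_folds)) {
    tr <- fold != k
    sub <- structure(list(pairs = ds$pairs[tr, , drop = FALSE],
                          x = ds$x[tr, , drop = FALSE], y = ds$y[tr],
                          n_samples = ds$n_samples,
                          n_pos = sum(ds$y[tr] > 0),
                          n_neg = sum(ds$y[tr] < 0)),
                     class = "pair_dataset")
    m <- train_svm(sub, grid = grid, inner_folds = inner_folds,
                   seed = seed + k, tolerance = tolerance)
    pred <- decision_values(m, ds$x[!tr, , drop = FALSE])
    f_all[!tr] <- pred$f; s_all[!tr] <- pred$s
  }
  pos <- ds$y > 0; hard <- s_all >= 0.5
  cm <- confusion_metrics(tp = sum(hard & pos), fn = sum(!hard & pos),
                          tn = sum(!hard & !pos), fp = sum(hard & !pos))
  structure(c(list(auc = auc_score(f_all, ds$y),
                   aupr = aupr_score(f_all, ds$y)),
              cm,
              list(scores = s_all, decisions = f_all, labels = ds$y)),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat("<cv_metrics>\n")
  for (k in c("auc", "aupr", "acc", "sn", "sp", "pre", "f_measure"))
    cat(sprintf("  %-10s %.4f\n", k, x[[k]]))
  invisible(x)
}

#' Fit the coexpression imputation model for a cohort
#'
#' One-call wrapper over the coexpression stage: aligns the two matrices by
#' sample, computes the PCC matrix, builds the labeled training set at the
#' configured thresholds, and trains the calibrated pair classifier.
#'
#' @param lnc,mrna lncRNA and gene `expr_matrix` objects over the same
#'   patients (any sample order).
#' @param config a [pipeline_config()].
#' @param grid hyperparameter grid, see [default_svm_grid()].
#' @param seed seed for subsampling and fold splits (defaults to the
#'   config's `rng_seed`).
#' @return Object of class `coexpr_model`: list with the trained `fit`
#'   (class `coexpr_svm`), `pcc`, `ds`, and the aligned `lnc` / `mrna`
#'   matrices.
#' @export
coexpr_model <- function(lnc, mrna, config = pipeline_config(),
                         grid = default_svm_grid(), seed = config$rng_seed) {
  config <- validate_config(config)
  al <- align_samples(lnc, mrna)
  pcc <- pcc_matrix(al$lnc, al$mrna)
  ds <- build_training_set(pcc, al$lnc, al$mrna, config, seed = seed)
  fit <- train_svm(ds, grid = grid, seed = seed)
  structure(list(fit = fit, pcc = pcc, ds = ds, lnc = al$lnc,
                 mrna = al$mrna, config = config),
            class = "coexpr_model")
}

#' @export
print.coexpr_model <- function(x, ...) {
  cat("<coexpr_model> ", nrow(x$lnc), " lncRNAs x ", nrow(x$mrna),
      " genes over ", ncol(x$lnc), " shared samples; ",
      x$ds$n_pos, " positive and ", x$ds$n_neg, " negative training pairs\n",
      sep = "")
  print(x$fit)
  invisible(x)
}

#' @export
#' @describeIn coexpr_model score all lncRNA-gene pairs of the cohort (or
#'   of new aligned matrices passed as `lnc` / `mrna`).
#' @param object a `coexpr_model`.
#' @param ... optional `lnc` and `mrna` replacement matrices.
predict.coexpr_model <- function(object, ...) {
  dots <- list(...)
  lnc <- if (!is.null(dots$lnc)) dots$lnc else object$lnc
  mrna <- if (!is.null(dots$mrna)) dots$mrna else object$mrna
  score_pairs(object$fit, lnc, mrna)
}
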