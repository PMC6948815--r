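#' Pipeline configuration
#'
#' All tunable thresholds of the association pipeline in one validated
#' list.  Defaults follow the published protocol: positives are
#' lncRNA-gene pairs with Pearson correlation above 0.7, negatives have
#' |PCC| below 2e-6, drugs enter the panel with strictly more than ten
#' treated instances, signature genes have |c| >= 0.9, associated genes
#' have calibrated SVM score >= 0.9, the top five lncRNAs per drug with
#' empirical specificity p below 0.05 are selected, and survival groups
#' are expression > 6 (high) versus < 2 (low).
#'
#' On cohorts of a few hundred patients the near-zero band `2e-6` is
#' narrower than the sampling spread of a null correlation (about
#' `1/sqrt(n)`); raise `neg_pcc_threshold` (e.g. to 0.05) so the negative
#' pool is populated.
#'
#' @param pos_pcc_threshold positives: PCC strictly above this.
#' @param neg_pcc_threshold negatives: |PCC| strictly below this.
#' @param min_treatment_instances drugs kept when treated-instance count is
#'   strictly greater than this.
#' @param signature_gene_threshold signature genes: |c| at least this.
#' @param assoc_score_threshold associated genes: calibrated score at least
#'   this.
#' @param top_k lncRNAs taken per drug for ranking and the specificity
#'   p-value.
#' @param selection_pvalue empirical-p cutoff for the final selection.
#' @param survival_high,survival_low expression thresholds for the high /
#'   low survival groups (strict inequalities; patients in between are
#'   excluded).
#' @param rng_seed integer seed controlling every random step.
#' @param neg_pos_ratio negatives subsampled to this multiple of the
#'   positive count.
#' @param log_base base used for `-log(adjusted p)` in the signature score.
#' @param de_method `"welch"` or `"moderated"` differential-expression test.
#' @param use_adjusted_p use BH-adjusted p in the signature score (the
#'   published definition); `FALSE` switches to the raw p.
#' @return A validated list of class `lncdrug_config`.
#' @export
pipeline_config <- function(pos_pcc_threshold = 0.7,
                            neg_pcc_threshold = 2e-6,
                            min_treatment_instances = 10,
                            signature_gene_threshold = 0.9,
                            assoc_score_threshold = 0.9,
                            top_k = 5,
                            selection_pvalue = 0.05,
                            survival_high = 6,
                            survival_low = 2,
                            rng_seed = 1L,
                            neg_pos_ratio = 1,
                            log_base = 10,
                            de_method = c("welch", "moderated"),
                            use_adjusted_p = TRUE) {
  cfg <- list(pos_pcc_threshold = pos_pcc_threshold,
              neg_pcc_threshold = neg_pcc_threshold,
              min_treatment_instances = min_treatment_instances,
              signature_gene_threshold = signature_gene_threshold,
              assoc_score_threshold = assoc_score_threshold,
              top_k = top_k,
              selection_pvalue = selection_pvalue,
              survival_high = survival_high,
              survival_low = survival_low,
              rng_seed = as.integer(rng_seed),
              neg_pos_ratio = neg_pos_ratio,
              log_base = log_base,
              de_method = match.arg(de_method),
              use_adjusted_p = isTRUE(use_adjusted_p))
  validate_config(cfg)
}

#' Configuration for synthetic cohorts
#'
#' [pipeline_config()] with two groups of settings adapted to the
#' distributions the synthetic generator produces.  The near-zero
#' negative band is widened to `|PCC| < 0.05`: with a few hundred
#' patients the sampling spread of a null correlation is about
#' `1/sqrt(n)` (0.07 at n = 200), so the published band of `2e-6` —
#' appropriate when millions of pairs are screened — would select
#' essentially no negatives.  The survival thresholds move to 5 / 3, one
#' marginal standard deviation around the generator's baseline of 4; this
#' follows the same principle as choosing clinical thresholds from the
#' observed expression distribution.
#'
#' @param rng_seed integer seed.
#' @param ... further overrides passed to [pipeline_config()].
#' @return A validated `lncdrug_config`.
#' @export
synthetic_config <- function(rng_seed = 1L, ...) {
  pipeline_config(neg_pcc_threshold = 0.05, survival_high = 5,
                  survival_low = 3, rng_seed = rng_seed, ...)
}

#' Validate a pipeline configuration
#' @param cfg list with the fields of [pipeline_config()].
#' @return The config, classed `lncdrug_config`; errors on invalid values.
#' @export
validate_config <- function(cfg) {
  num1 <- function(field) {
    v <- cfg[[field]]
    if (is.null(v) || length(v) != 1 || !is.finite(as.numeric(v)))
      stop("config field '", field, "' must be a single finite number")
    as.numeric(v)
  }
  pos <- num1("pos_pcc_threshold"); neg <- num1("neg_pcc_threshold")
  if (!(0 < neg && neg < pos && pos <= 1))
    stop("need 0 < neg_pcc_threshold < pos_pcc_threshold <= 1")
  if (num1("survival_low") >= num1("survival_high"))
    stop("need survival_low < survival_high")
  if (num1("top_k") < 1) stop("top_k must be >= 1")
  if (num1("min_treatment_instances") < 0)
    stop("min_treatment_instances must be non-negative")
  if (num1("selection_pvalue") <= 0 || num1("selection_pvalue") > 1)
    stop("selection_pvalue must lie in (0, 1]")
  if (num1("neg_pos_ratio") <= 0) stop("neg_pos_ratio must be positive")
  if (num1("log_base") <= 1) stop("log_base must exceed 1")
  structure(cfg, class = "lncdrug_config")
}

#' Read a configuration file
#'
#' Flat key-value YAML mirroring the [pipeline_config()] field names;
#' missing keys take their defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A validated `lncdrug_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a configuration file
#' @param cfg a `lncdrug_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.lncdrug_config <- function(x, ...) {
  cat("<lncdrug_config>\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}

# run `code` with a private RNG stream; caller's .Random.seed is untouched
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}
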