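#' Dichotomize patients by lncRNA expression
#'
#' Strict thresholds: value strictly above `high` is "high", strictly
#' below `low` is "low", anything in between (boundaries included) is
#' "excluded".  The defaults 6 and 2 suit log2-scale expression in the
#' 0-12 range; per-lncRNA overrides can be passed when the expression
#' distribution warrants it.
#'
#' @param values numeric expression values (named by patient).
#' @param high,low thresholds with `low < high`.
#' @return Character vector of group labels (`high` / `low` / `excluded`),
#'   names preserved.
#' @export
dichotomize <- function(values, high = 6, low = 2) {
  if (low >= high) stop("need low < high")
  out <- rep("excluded", length(values))
  out[values > high] <- "high"
  out[values < low] <- "low"
  names(out) <- names(values)
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival probability as a right-continuous step function over the
#' distinct observed event times; censored patients leave the risk set
#' without contributing a factor (events at tied times are processed
#' first, the standard convention).
#'
#' @param records data.frame with columns `time` and `event` (1 = death
#'   observed, 0 = censored).
#' @return `data.frame` with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` — one row per distinct observed time, starting
#'   from `S(0) = 1` implicitly.
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0) stop("no survival records")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard 1-df chi-square log-rank statistic comparing the survival of
#' the high- and low-expression groups, with its upper-tail p-value.
#'
#' @param high,low data.frames with columns `time`, `event`.
#' @return List with `statistic` (chi-square), `df` (1), `p`, and the
#'   group sizes `n_high`, `n_low`.
#' @export
logrank_test <- function(high, low) {
  if (nrow(high) == 0) stop("high-expression group is empty")
  if (nrow(low) == 0) stop("low-expression group is empty")
  dat <- rbind(cbind(high[, c("time", "event")], group = "high"),
               cbind(low[, c("time", "event")], group = "low"))
  if (sum(dat$event) == 0) stop("no events in either group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  stat <- sd$chisq
  list(statistic = stat, df = 1,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n_high = nrow(high), n_low = nrow(low))
}

#' Survival separation by lncRNA expression group
#'
#' Splits patients into high / low expression groups ([dichotomize()]),
#' estimates a Kaplan-Meier curve per group and tests their separation
#' with the log-rank test.
#'
#' @param values named expression values of one lncRNA (names are patient
#'   ids).
#' @param records survival data.frame with `patient_id`, `time`, `event`.
#' @param high,low dichotomization thresholds.
#' @param lncRNA_id label carried into the result.
#' @return Object of class `lnc_survival`: list with `lncRNA_id`, `group`
#'   labels, per-group `km` estimates, and the `logrank` result.
#' @export
lnc_survival <- function(values, records, high = 6, low = 2,
                         lncRNA_id = "lncRNA") {
  shared <- intersect(names(values), records$patient_id)
  if (length(shared) == 0) stop("no patients shared between expression and survival data")
  values <- values[shared]
  records <- records[match(shared, records$patient_id), ]
  grp <- dichotomize(values, high = high, low = low)
  hi <- records[grp == "high", , drop = FALSE]
  lo <- records[grp == "low", , drop = FALSE]
  if (nrow(hi) == 0) stop("high-expression group is empty")
  if (nrow(lo) == 0) stop("low-expression group is empty")
  structure(list(lncRNA_id = lncRNA_id, group = grp,
                 km = list(high = km_estimate(hi), low = km_estimate(lo)),
                 logrank = logrank_test(hi, lo)),
            class = "lnc_survival")
}

#' @export
print.lnc_survival <- function(x, ...) {
  lr <- x$logrank
  cat("<lnc_survival> ", x$lncRNA_id, ": ", lr$n_high, " high vs ",
      lr$n_low, " low patients; log-rank chi-square = ",
      round(lr$statistic, 3), ", p = ", signif(lr$p, 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.lnc_survival <- function(x, ...) {
  km_hi <- x$km$high; km_lo <- x$km$low
  step_xy <- function(km) {
    list(x = c(0, rep(km$time, each = 2)),
         y = c(1, 1, rep(km$surv, each = 2)[-2 * nrow(km)]))
  }
  hi <- step_xy(km_hi); lo <- step_xy(km_lo)
  graphics::plot(hi$x, hi$y, type = "l", col = "red", ylim = c(0, 1),
                 xlab = "time", ylab = "survival probability",
                 main = paste0(x$lncRNA_id, " (log-rank p = ",
                               signif(x$logrank$p, 3), ")"), ...)
  graphics::lines(lo$x, lo$y, col = "blue")
  graphics::legend("bottomleft", legend = c("high expression", "low expression"),
                   col = c("red", "blue"), lty = 1, bty = "n")
  invisible(x)
}
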