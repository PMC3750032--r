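# Validation statistics: Bland-Altman agreement between acquisition schemes
# and sensitivity/specificity of MSA screening reads.

#' Bland-Altman agreement between paired FA measurements
#'
#' For paired measurements of the same ROI under two acquisition schemes
#' (12 vs 30 motion-probing-gradient directions), computes the differences
#' `d = fa_12 - fa_30`, their mean, and the 95% prediction interval for a
#' new difference in the classical Bland-Altman form
#' `mean(d) +/- z * sd(d)` (sample SD, denominator `n - 1`), plus the
#' Pearson correlation between the two schemes with its two-sided p-value.
#' If either side is constant the correlation is undefined and returned as
#' `NA` with `constant_input = TRUE`, never fabricated.
#'
#' @param pairs data.frame with numeric columns `fa_12` and `fa_30`
#'   (complete pairs; an optional `roi_group` column is carried through).
#' @param level prediction-interval level, default 0.95.
#' @return object of class `agreement_result` with `mean_diff`,
#'   `pi_diff_low`, `pi_diff_high`, `pearson_r`, `r_pvalue`, `n`,
#'   `constant_input`.
#' @export
bland_altman <- function(pairs, level = 0.95) {
  stopifnot(is.data.frame(pairs), all(c("fa_12", "fa_30") %in% names(pairs)))
  x <- as.numeric(pairs$fa_12); y <- as.numeric(pairs$fa_30)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("bland_altman: pairs must be complete (no missing side)")
  n <- length(x)
  if (n < 3L) stop("bland_altman: need at least 3 pairs")
  d <- x - y
  md <- mean(d)
  s <- sd(d)
  z <- qnorm((1 + level) / 2)
  constant <- sd(x) == 0 || sd(y) == 0
  if (constant) {
    warning("constant measurements on one side: correlation undefined")
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(cor.test(x, y))
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(mean_diff = md, pi_diff_low = md - z * s,
                 pi_diff_high = md + z * s, sd_diff = s,
                 pearson_r = r, r_pvalue = p, n = n, level = level,
                 constant_input = constant),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> n = %d: mean diff %.4f, %g%% PI (%.4f, %.4f), r = %s (p = %s)\n",
    x$n, x$mean_diff, 100 * x$level, x$pi_diff_low, x$pi_diff_high,
    format(x$pearson_r, digits = 4), format(x$r_pvalue, digits = 3)))
  invisible(x)
}

#' Confusion summary of an MSA screening read
#'
#' Compares a reader's MSA / non-MSA calls against the truth, with MSA as
#' the positive class. Sensitivity and specificity are kept as exact
#' percentages and additionally rounded half-up to whole percent for
#' reporting (the presentation convention of rater tables).
#'
#' @param truth named character vector (or factor), subject id -> `"MSA"` /
#'   `"non-MSA"`.
#' @param calls same structure; must cover exactly the same subjects.
#' @return object of class `confusion_result` with counts `tp`, `fp`, `tn`,
#'   `fn`, exact `sensitivity` / `specificity` and their `_reported`
#'   integer versions.
#' @export
screening_confusion <- function(truth, calls) {
  truth <- unlist(truth); calls <- unlist(calls)
  if (is.null(names(truth)) || is.null(names(calls)))
    stop("truth and calls must be named by subject id")
  extra <- setdiff(names(calls), names(truth))
  if (length(extra))
    stop("subject(s) in calls missing from truth: ",
         paste(extra, collapse = ", "))
  if (!setequal(names(truth), names(calls)))
    stop("subject(s) in truth missing from calls: ",
         paste(setdiff(names(truth), names(calls)), collapse = ", "))
  calls <- calls[names(truth)]
  ok <- c("MSA", "non-MSA")
  if (!all(truth %in% ok) || !all(calls %in% ok))
    stop("labels must be 'MSA' or 'non-MSA'")
  tp <- sum(truth == "MSA" & calls == "MSA")
  fn <- sum(truth == "MSA" & calls == "non-MSA")
  tn <- sum(truth == "non-MSA" & calls == "non-MSA")
  fp <- sum(truth == "non-MSA" & calls == "MSA")
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 sensitivity_reported = round_half_up(sens),
                 specificity_reported = round_half_up(spec)),
            class = "confusion_result")
}

#' @export
print.confusion_result <- function(x, ...) {
  cat(sprintf(
    "<confusion_result> tp %d fp %d tn %d fn %d: sensitivity %g%% (%.2f), specificity %g%% (%.2f)\n",
    x$tp, x$fp, x$tn, x$fn, x$sensitivity_reported, x$sensitivity,
    x$specificity_reported, x$specificity))
  invisible(x)
}

#' Average per-rater screening performance
#'
#' Arithmetic mean of per-rater sensitivity and specificity percentages,
#' rounded half-up to whole percent for reporting. Accepts either a list of
#' [screening_confusion()] results (their reported integer values are
#' averaged, matching how rater tables are printed) or a data.frame with
#' `sensitivity` and `specificity` columns of printed percentages.
#'
#' @param results list of `confusion_result`, or data.frame.
#' @return list with `mean_sensitivity` and `mean_specificity` (reported
#'   integers) and their `_exact` counterparts.
#' @export
rater_summary <- function(results) {
  if (is.data.frame(results)) {
    if (nrow(results) == 0L) stop("rater_summary: need at least one rater")
    sens <- as.numeric(results$sensitivity)
    spec <- as.numeric(results$specificity)
  } else if (is.list(results) && length(results) &&
             all(vapply(results, inherits, TRUE, "confusion_result"))) {
    sens <- vapply(results, `[[`, 0, "sensitivity_reported")
    spec <- vapply(results, `[[`, 0, "specificity_reported")
  } else {
    stop("rater_summary: need a non-empty list of confusion_result objects ",
         "or a data.frame with sensitivity/specificity columns")
  }
  if (any(!is.finite(sens)) || any(!is.finite(spec)))
    stop("rater_summary: non-finite rater values")
  list(mean_sensitivity = round_half_up(mean(sens)),
       mean_specificity = round_half_up(mean(spec)),
       mean_sensitivity_exact = mean(sens),
       mean_specificity_exact = mean(spec))
}

#' Published rater performance table
#'
#' Sensitivity and specificity (percent) of the four blinded readers who
#' classified subjects as MSA vs non-MSA using only LUT-colorized FA maps
#' (17 MSA, 13 Parkinson disease, 17 healthy subjects).
#'
#' @return data.frame with columns `rater`, `experience_years`,
#'   `sensitivity`, `specificity`.
#' @export
rater_reference_values <- function() {
  data.frame(
    rater = c("IL", "AR", "JK", "JV"),
    experience_years = c(0, 2, 5, 20),
    sensitivity = c(77, 100, 76, 65),
    specificity = c(70, 80, 86, 100),
    stringsAsFactors = FALSE
  )
}
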