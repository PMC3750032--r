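# Random-intercept linear mixed model per ROI group: population mean,
# variance components and the 95% prediction interval used as LUT anchors.

#' Fit the per-group random-intercept model
#'
#' Fits `y_ij = mu + b_i + e_ij` with subject effect `b_i ~ N(0, tau2)` and
#' residual `e_ij ~ N(0, sigma2)` to the FA observations of one ROI group,
#' treating a subject's repeated ROI measurements as dependent repeat
#' observations of that group. `method = "reml"` maximizes the restricted
#' likelihood (via \pkg{lme4}); `method = "moments"` uses the closed-form
#' one-way ANOVA estimators: `sigma2 = MSE` (within-subject mean square) and
#' `tau2 = max(0, (MSB - MSE) / k)` where `k` is the per-subject ROI count,
#' adjusted for imbalance as `k = (N - sum(n_i^2)/N) / (m - 1)`. Negative
#' variance estimates are truncated at zero. The 95% prediction interval is
#' filled in via [prediction_interval()].
#'
#' Centered fixed covariates (e.g. age) may be added with `covariates`
#' (REML only); the reported mean and interval are then evaluated at the
#' covariate mean.
#'
#' @param table an `fa_table` (see [measurement_table()]).
#' @param roi_group group to fit.
#' @param mpg_scheme 12 or 30.
#' @param method `"reml"` (default) or `"moments"`.
#' @param roi_labels optional subset of ROI labels (e.g. genu only).
#' @param covariates optional numeric column names used as fixed effects.
#' @param level prediction-interval level, default 0.95.
#' @return object of class `ri_fit` with fields `roi_group`, `mu_hat`,
#'   `tau2_hat`, `sigma2_hat`, `pi_low`, `pi_high`, `mu_var`, `n_subjects`,
#'   `n_obs`, `method`.
#' @export
fit_random_intercept <- function(table, roi_group, mpg_scheme = 12L,
                                 method = c("reml", "moments"),
                                 roi_labels = NULL, covariates = NULL,
                                 level = 0.95) {
  method <- match.arg(method)
  validate_measurement_table(table)
  sub <- table[table$roi_group == roi_group &
               table$mpg_scheme == as.integer(mpg_scheme), , drop = FALSE]
  if (!is.null(roi_labels))
    sub <- sub[sub$roi_label %in% roi_labels, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no observations for group ", roi_group, " at ", mpg_scheme, " MPG")
  subj <- factor(sub$subject_id)
  m <- nlevels(subj)
  if (m < 2L)
    stop("degenerate design: group ", roi_group,
         " has a single subject; between-subject variance is unidentifiable")
  y <- sub$fa
  N <- length(y)

  if (var(y) < 1e-20) {
    # constant data: both variance components are exactly zero
    fit <- new_ri_fit(roi_group, mpg_scheme, mu_hat = y[1],
                      tau2_hat = 0, sigma2_hat = 0, mu_var = 0,
                      n_subjects = m, n_obs = N, method = method)
  } else if (method == "moments") {
    if (!is.null(covariates))
      stop("covariates are only supported with method = 'reml'")
    ybar_i <- tapply(y, subj, mean)
    n_i <- tabulate(subj)
    ybar <- mean(y)
    msb <- sum(n_i * (ybar_i - ybar)^2) / (m - 1)
    mse <- sum((y - ybar_i[subj])^2) / (N - m)
    k_tilde <- (N - sum(n_i^2) / N) / (m - 1)
    tau2 <- max(0, (msb - mse) / k_tilde)
    fit <- new_ri_fit(roi_group, mpg_scheme, mu_hat = ybar,
                      tau2_hat = tau2, sigma2_hat = mse,
                      mu_var = msb / N,
                      n_subjects = m, n_obs = N, method = method)
  } else {
    dat <- data.frame(fa = y, subject = subj)
    fixed <- "1"
    if (!is.null(covariates)) {
      for (cv in covariates) {
        if (!cv %in% names(sub)) stop("covariate column not found: ", cv)
        dat[[cv]] <- as.numeric(sub[[cv]]) - mean(as.numeric(sub[[cv]]))
      }
      fixed <- paste(c("1", covariates), collapse = " + ")
    }
    f <- stats::as.formula(paste0("fa ~ ", fixed, " + (1 | subject)"))
    mod <- suppressMessages(suppressWarnings(
      lme4::lmer(f, data = dat, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    vc <- lme4::VarCorr(mod)
    fit <- new_ri_fit(roi_group, mpg_scheme,
                      mu_hat = unname(lme4::fixef(mod)[1]),
                      tau2_hat = unname(vc$subject[1, 1]),
                      sigma2_hat = stats::sigma(mod)^2,
                      mu_var = as.matrix(stats::vcov(mod))[1, 1],
                      n_subjects = m, n_obs = N, method = method)
  }
  pi <- prediction_interval(fit, level = level)
  fit$pi_low <- pi[1]
  fit$pi_high <- pi[2]
  fit$level <- level
  fit
}

new_ri_fit <- function(roi_group, mpg_scheme, mu_hat, tau2_hat, sigma2_hat,
                       mu_var, n_subjects, n_obs, method) {
  structure(list(roi_group = roi_group, mpg_scheme = as.integer(mpg_scheme),
                 mu_hat = mu_hat,
                 tau2_hat = max(0, tau2_hat), sigma2_hat = max(0, sigma2_hat),
                 mu_var = mu_var, pi_low = NA_real_, pi_high = NA_real_,
                 level = NA_real_, n_subjects = n_subjects, n_obs = n_obs,
                 method = method),
            class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf(
    "<ri_fit %s, %d MPG, %s> mu = %.4f, tau2 = %.3e, sigma2 = %.3e, %g%% PI (%.4f, %.4f), %d subjects / %d obs\n",
    x$roi_group, x$mpg_scheme, x$method, x$mu_hat, x$tau2_hat, x$sigma2_hat,
    100 * x$level, x$pi_low, x$pi_high, x$n_subjects, x$n_obs))
  invisible(x)
}

#' Prediction interval for a new observation on a new subject
#'
#' Returns `mu_hat +/- q * sqrt(tau2_hat + sigma2_hat)`, the interval
#' expected to contain a single new FA observation from a new subject. By
#' default `q` is the standard-normal quantile and the sampling variance of
#' `mu_hat` is excluded — at normative cohort sizes (76 subjects) both
#' corrections are negligible; flags expose them. Bounds are not clipped to
#' \[0, 1\] (the LUT builder clips).
#'
#' @param fit an `ri_fit`.
#' @param level coverage probability in (0, 1).
#' @param include_fixed_uncertainty add `mu_var` to the predictive variance.
#' @param use_t use a Student-t quantile with `n_subjects - 1` df.
#' @return numeric `c(low, high)`, symmetric about `mu_hat`.
#' @export
prediction_interval <- function(fit, level = 0.95,
                                include_fixed_uncertainty = FALSE,
                                use_t = FALSE) {
  stopifnot(inherits(fit, "ri_fit"), level > 0, level < 1)
  v <- fit$tau2_hat + fit$sigma2_hat
  if (include_fixed_uncertainty) v <- v + fit$mu_var
  p <- (1 + level) / 2
  q <- if (use_t) qt(p, df = fit$n_subjects - 1) else qnorm(p)
  half <- q * sqrt(v)
  c(fit$mu_hat - half, fit$mu_hat + half)
}

#' Fit every ROI group of a measurement table
#'
#' Fits [fit_random_intercept()] to each ROI group present at the given MPG
#' scheme. The four LUT groups (`BG`, `GM`, `CC_FREEHAND`, `CC_CROI`) must
#' all be present unless `require_lut_groups = FALSE`; the `CC_CROI` fit
#' pools genu and splenium records, reflecting that the circular-ROI anchor
#' targets densely packed fibers rather than one anatomical structure.
#'
#' @inheritParams fit_random_intercept
#' @param require_lut_groups error if any LUT group is absent.
#' @return named list of `ri_fit`, one per group present.
#' @export
fit_all_groups <- function(table, mpg_scheme = 12L,
                           method = c("reml", "moments"),
                           require_lut_groups = TRUE, level = 0.95) {
  method <- match.arg(method)
  validate_measurement_table(table)
  present <- unique(table$roi_group[table$mpg_scheme == as.integer(mpg_scheme)])
  if (require_lut_groups) {
    missing <- setdiff(LUT_GROUPS, present)
    if (length(missing))
      stop("missing required LUT group(s): ", paste(missing, collapse = ", "))
  }
  lapply(setNames(present, present), function(g)
    fit_random_intercept(table, g, mpg_scheme, method = method, level = level))
}

#' Serialize fits to JSON
#'
#' @param fits named list of `ri_fit` (from [fit_all_groups()]).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  if (inherits(fits, "ri_fit")) fits <- setNames(list(fits), fits$roi_group)
  jsonlite::write_json(lapply(fits, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fits_json
#' @export
read_fits_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) structure(as.list(x), class = "ri_fit"))
}
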