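# Stratified non-linear MR on individual-level data: IV-free exposure
# strata, localized average causal effects (LACE), piecewise-linear and
# fractional-polynomial dose-response curves, heterogeneity and trend tests.

#' Stratify a cohort on the IV-free exposure
#'
#' Removes the fitted linear effect of the genetic score (and any
#' covariates) from the exposure and ranks individuals into `q`
#' equal-count strata on the residual. Stratifying on this "IV-free"
#' exposure, rather than the raw exposure, avoids the collider bias that
#' conditioning on a common consequence of the score and confounders
#' would induce.
#'
#' @param cohort data.frame with at least the score and exposure columns
#'   and a binary outcome column.
#' @param q Number of strata (>= 2); at least 50 individuals per stratum
#'   are required.
#' @param score_col,exposure_col,covariate_cols Column names.
#' @return `cohort` with added columns `iv_free_exposure` and `stratum`
#'   (integer 1..q, 1 = lowest residual exposure).
#' @export
iv_free_strata <- function(cohort, q = 10L, score_col = "score",
                           exposure_col = "exposure",
                           covariate_cols = NULL) {
  n <- nrow(cohort)
  if (q < 2L) stop("q must be at least 2", call. = FALSE)
  if (q > n / 50) stop("strata too small: q exceeds n/50", call. = FALSE)
  rhs <- paste(c(score_col, covariate_cols), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(exposure_col, "~", rhs)),
                   data = cohort)
  res <- stats::residuals(fit)
  cohort$iv_free_exposure <- res
  # equal-count strata by rank; ties broken by original order
  cohort$stratum <- as.integer(ceiling(rank(res, ties.method = "first") * q / n))
  attr(cohort, "nlmr_cols") <- list(score = score_col,
                                    exposure = exposure_col,
                                    covariates = covariate_cols)
  cohort
}

#' Localized average causal effects per stratum
#'
#' Within each stratum, the LACE is the ratio of the logistic regression
#' coefficient of the outcome on the genetic score (with covariates) to
#' the linear regression coefficient of the exposure on the score in the
#' full sample, with first-order SE `se(numerator)/|denominator|`. Strata
#' without both cases and controls are flagged unusable and excluded from
#' curve fitting with a warning.
#'
#' @param cohort Output of [iv_free_strata()].
#' @param outcome_col Name of the binary outcome column.
#' @return data.frame of class `lace_table`: `stratum`, `x_low`, `x_high`,
#'   `x_mid` (raw exposure range and mean), `lace`, `se`, `n`, `n_cases`,
#'   `usable`; the full-sample score-exposure coefficient is attached as
#'   attribute `denominator`.
#' @export
lace_per_stratum <- function(cohort, outcome_col = "outcome") {
  cols <- attr(cohort, "nlmr_cols")
  if (is.null(cols)) stop("cohort must come from iv_free_strata()",
                          call. = FALSE)
  rhs <- paste(c(cols$score, cols$covariates), collapse = " + ")
  denom_fit <- stats::lm(stats::as.formula(paste(cols$exposure, "~", rhs)),
                         data = cohort)
  denom <- stats::coef(denom_fit)[[cols$score]]

  strata <- sort(unique(cohort$stratum))
  out <- lapply(strata, function(s) {
    d <- cohort[cohort$stratum == s, ]
    n_cases <- sum(d[[outcome_col]])
    usable <- n_cases > 0 && n_cases < nrow(d)
    lace <- se <- NA_real_
    if (usable) {
      gfit <- stats::glm(
        stats::as.formula(paste(outcome_col, "~", rhs)),
        family = stats::binomial(), data = d)
      co <- summary(gfit)$coefficients
      lace <- co[cols$score, "Estimate"] / denom
      se <- co[cols$score, "Std. Error"] / abs(denom)
    }
    data.frame(stratum = s,
               x_low = min(d[[cols$exposure]]),
               x_high = max(d[[cols$exposure]]),
               x_mid = mean(d[[cols$exposure]]),
               lace = lace, se = se, n = nrow(d), n_cases = n_cases,
               usable = usable)
  })
  out <- do.call(rbind, out)
  if (any(!out$usable))
    warning(sum(!out$usable),
            " stratum/strata without both cases and controls excluded",
            call. = FALSE)
  attr(out, "denominator") <- denom
  class(out) <- c("lace_table", class(out))
  out
}

#' Piecewise-linear causal curve from stratum estimates
#'
#' Builds the cumulative log-OR curve whose slope within each stratum's
#' raw-exposure range equals that stratum's LACE, continuous across
#' boundaries and anchored at zero at the reference exposure (the
#' midpoint of the lowest stratum). Pointwise variances accumulate the
#' per-segment `(width * se)^2` terms.
#'
#' @param laces A `lace_table` (unusable strata are skipped).
#' @param ref Reference exposure; defaults to the first usable stratum's
#'   midpoint.
#' @return List of class `piecewise_curve` with data.frame `curve`
#'   (`x`, `y`, `se`, `ci_low`, `ci_high` at stratum boundaries) and the
#'   per-stratum `segments`.
#' @export
piecewise_fit <- function(laces, ref = NULL) {
  d <- laces[laces$usable, , drop = FALSE]
  if (nrow(d) < 2L) stop("at least 2 usable strata required", call. = FALSE)
  d <- d[order(d$x_mid), ]
  if (is.null(ref)) ref <- d$x_mid[1L]

  # knots: boundaries between consecutive strata, plus outer limits
  x <- c(d$x_low[1L], (d$x_high[-nrow(d)] + d$x_low[-1L]) / 2, d$x_high[nrow(d)])
  width <- diff(x)
  y <- c(0, cumsum(d$lace * width))
  v <- c(0, cumsum(d$se^2 * width^2))
  # shift so that the curve is zero at the reference exposure
  y_ref <- stats::approx(x, y, xout = ref, rule = 2)$y
  y <- y - y_ref
  se <- sqrt(v)
  curve <- data.frame(x = x, y = y, se = se,
                      ci_low = y - 1.96 * se, ci_high = y + 1.96 * se)
  structure(list(curve = curve, segments = d, ref = ref),
            class = "piecewise_curve")
}

# Derivative-space basis of a fractional polynomial term x^p (log x for
# p = 0): d/dx x^p = p * x^(p-1), d/dx log x = 1/x. Constant factors are
# absorbed into the coefficient, so the regression basis is x^(p-1).
#' @keywords internal
#' @noRd
fp_deriv_basis <- function(x, p) x^(p - 1)

#' Fractional-polynomial fit of stratum estimates with non-linearity test
#'
#' Models the LACE (the local slope of the exposure-outcome log-OR curve)
#' as the derivative of a fractional polynomial of the exposure over the
#' conventional power grid, fitted by weighted least squares with weights
#' `1/se^2`. Power 1 contributes a constant LACE, so the linear
#' exposure-outcome model is the constant-only reference. The best power
#' set is chosen by minimum weighted residual sum of squares within each
#' degree; degree 2 is adopted only when it improves on degree 1 by a
#' chi-square test on 2 df at the 0.05 level. `p_nonlinearity` compares
#' the best degree-1 model against the constant reference on 1 df (the
#' stratified-MR fractional-polynomial convention).
#'
#' @param laces A `lace_table`.
#' @param powers Power grid; 0 denotes the log term.
#' @param max_degree 1 or 2.
#' @return Object of class `fp_model`: `degree`, `powers`, `coefficients`,
#'   `vcov`, `p_nonlinearity`, `q_quantiles`, plus the weighted RSS of the
#'   linear reference and best fits.
#' @export
fp_fit_and_test <- function(laces, powers = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3),
                            max_degree = 2L) {
  d <- laces[laces$usable, , drop = FALSE]
  if (nrow(d) < max_degree + 2L)
    stop("too few usable strata for the fractional polynomial fit",
         call. = FALSE)
  if (any(d$x_mid <= 0))
    stop("exposure midpoints must be positive for fractional powers",
         call. = FALSE)
  x <- d$x_mid; y <- d$lace; w <- 1 / d$se^2

  wfit <- function(B) {
    B <- as.matrix(B)
    XtWX <- crossprod(B, w * B)
    co <- solve(XtWX, crossprod(B, w * y))
    rss <- sum(w * (y - B %*% co)^2)
    list(coef = drop(co), vcov = solve(XtWX), rss = rss)
  }

  lin <- wfit(fp_deriv_basis(x, 1))  # constant LACE

  fits1 <- lapply(powers, function(p) c(list(powers = p),
                                        wfit(fp_deriv_basis(x, p))))
  best1 <- fits1[[which.min(vapply(fits1, `[[`, numeric(1), "rss"))]]

  best <- best1; degree <- 1L
  if (max_degree >= 2L) {
    pairs <- utils::combn(powers, 2, simplify = FALSE)
    fits2 <- lapply(pairs, function(pp)
      c(list(powers = pp),
        wfit(cbind(fp_deriv_basis(x, pp[1L]), fp_deriv_basis(x, pp[2L])))))
    best2 <- fits2[[which.min(vapply(fits2, `[[`, numeric(1), "rss"))]]
    if (stats::pchisq(max(best1$rss - best2$rss, 0), df = 2,
                      lower.tail = FALSE) < 0.05) {
      best <- best2; degree <- 2L
    }
  }

  p_nonlin <- stats::pchisq(max(lin$rss - best1$rss, 0), df = 1,
                            lower.tail = FALSE)
  structure(list(degree = degree, powers = best$powers,
                 coefficients = best$coef, vcov = best$vcov,
                 p_nonlinearity = p_nonlin,
                 q_quantiles = nrow(laces),
                 rss_linear = lin$rss, rss_best = best$rss),
            class = "fp_model")
}

#' @export
print.fp_model <- function(x, ...) {
  cat(sprintf("Fractional polynomial (degree %d, powers %s) over %d strata\n",
              x$degree, paste(x$powers, collapse = ", "), x$q_quantiles))
  cat(sprintf("  non-linearity p = %.3g\n", x$p_nonlinearity))
  invisible(x)
}

#' Instrument heterogeneity and trend tests across strata
#'
#' Cochran's Q test of LACE homogeneity across strata (weights `1/se^2`)
#' and a meta-regression trend test of the LACE on the stratum exposure
#' midpoint.
#'
#' @param laces A `lace_table` with >= 3 usable strata.
#' @return List: `q`, `q_df`, `q_pvalue`, `trend_beta`, `trend_se`,
#'   `trend_pvalue`.
#' @export
iv_heterogeneity_tests <- function(laces) {
  d <- laces[laces$usable, , drop = FALSE]
  if (nrow(d) < 2L) stop("at least 2 usable strata required", call. = FALSE)
  w <- 1 / d$se^2
  pooled <- sum(w * d$lace) / sum(w)
  q <- sum(w * (d$lace - pooled)^2)
  q_df <- nrow(d) - 1L

  # weighted meta-regression of LACE on exposure midpoint
  X <- cbind(1, d$x_mid)
  XtWX <- crossprod(X, w * X)
  co <- solve(XtWX, crossprod(X, w * d$lace))
  V <- solve(XtWX)
  trend_beta <- co[2L]
  trend_se <- sqrt(V[2L, 2L])
  list(q = q, q_df = q_df,
       q_pvalue = stats::pchisq(q, df = q_df, lower.tail = FALSE),
       trend_beta = trend_beta, trend_se = trend_se,
       trend_pvalue = beta_to_p(trend_beta, trend_se))
}
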