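# Observational arm: covariate adjustment with rank-based inverse-normal
# transformation, logistic exposure-outcome models, fractional-polynomial
# closed-test model selection, and AIC comparison (including a GAM fit).

#' Covariate adjustment and rank-based inverse-normal transformation
#'
#' Regresses the exposure on the covariates, then maps the residual ranks
#' through the normal quantile function with the Blom offset:
#' `qnorm((rank - offset)/(n - 2*offset + 1))`. Ties share the average
#' rank. The result is unitless with mean ~0 and SD ~1 and is invariant
#' to affine transformations of the input.
#'
#' @param exposure Numeric vector (n >= 10, non-constant).
#' @param covariates Optional data.frame of adjustment covariates.
#' @param offset Rank offset; 0.375 is the Blom convention.
#' @return Numeric vector of transformed values, with the covariate names
#'   used attached as attribute `"covariates"`.
#' @export
adjust_and_int <- function(exposure, covariates = NULL, offset = 0.375) {
  n <- length(exposure)
  if (n < 10L) stop("at least 10 observations required", call. = FALSE)
  if (stats::var(exposure) == 0) stop("constant exposure", call. = FALSE)
  res <- if (is.null(covariates) || length(covariates) == 0L) {
    exposure - mean(exposure)
  } else {
    covariates <- as.data.frame(covariates)
    stats::residuals(stats::lm(exposure ~ ., data = covariates))
  }
  r <- rank(res, ties.method = "average")
  out <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  attr(out, "covariates") <- if (is.null(covariates)) character(0)
  else names(covariates)
  out
}

#' Logistic regression odds ratio per 1 SD of exposure
#'
#' Maximum-likelihood logistic fit of a binary outcome on a (typically
#' rank-inverse-normalised) exposure, optionally with covariates.
#'
#' @param outcome Binary 0/1 vector with both classes present.
#' @param exposure Numeric vector.
#' @param covariates Optional data.frame of covariates.
#' @return List: `or`, `ci_low`, `ci_high` (95%), `beta`, `se`, `pvalue`.
#' @export
logistic_or <- function(outcome, exposure, covariates = NULL) {
  if (length(unique(outcome)) != 2L)
    stop("both outcome classes must be present", call. = FALSE)
  dat <- data.frame(.y = outcome, .x = exposure)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat))
  separated <- all(abs(stats::fitted(fit) - outcome) < 1e-6)
  if (!fit$converged || separated ||
      any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
    stop("logistic fit unusable: complete separation or non-convergence",
         call. = FALSE)
  co <- summary(fit)$coefficients
  beta <- co[".x", "Estimate"]; se <- co[".x", "Std. Error"]
  ci <- or_ci(beta, se)
  list(or = exp(beta), ci_low = ci[1L], ci_high = ci[2L],
       beta = beta, se = se, pvalue = co[".x", "Pr(>|z|)"])
}

# Fractional-polynomial basis of the exposure: x^p (log x for p = 0);
# a repeated power p contributes x^p and x^p * log x.
#' @keywords internal
#' @noRd
fp_basis <- function(x, powers) {
  cols <- list()
  seen <- c()
  for (p in powers) {
    term <- if (p == 0) log(x) else x^p
    if (p %in% seen) term <- term * log(x)
    seen <- c(seen, p)
    cols[[length(cols) + 1L]] <- term
  }
  B <- do.call(cbind, cols)
  colnames(B) <- paste0("fp", seq_len(ncol(B)))
  B
}

#' Fractional-polynomial closed-test model selection (logistic outcome)
#'
#' The closed test procedure of multivariable fractional polynomials:
#' (1) the best-fitting degree-2 fractional polynomial (FP2) is compared
#' against the covariate-only null model on 4 df — no association if not
#' significant; (2) FP2 against the linear model on 3 df — linear if not
#' significant; (3) FP2 against the best FP1 on 2 df — FP1 if not
#' significant, FP2 otherwise. Deviance-based chi-square tests with the
#' conventional degrees of freedom that charge each estimated power as
#' one parameter. The exposure is shifted to be strictly positive if
#' needed for logarithmic/negative powers.
#'
#' @param outcome Binary 0/1 vector.
#' @param exposure Numeric vector.
#' @param covariates Optional data.frame.
#' @param powers Power grid (0 = log).
#' @param alpha Level of each closed-test stage.
#' @return List of class `mfp_fit`: `selected` (`"null"`, `"linear"`,
#'   `"fp1"`, `"fp2"`), `powers` of the selected model, `pvalues` (the
#'   three stage tests), and `comparison` (a data.frame of model, df,
#'   deviance, aic with attribute-free minimum marked in `selected_aic`).
#' @export
mfp_closed_test <- function(outcome, exposure, covariates = NULL,
                            powers = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3),
                            alpha = 0.05) {
  shift <- if (min(exposure) <= 0) -min(exposure) + 1 else 0
  x <- exposure + shift
  base <- if (is.null(covariates)) data.frame(.y = outcome)
  else cbind(data.frame(.y = outcome), as.data.frame(covariates))

  fit_with <- function(B) {
    dat <- if (is.null(B)) base else cbind(base, as.data.frame(B))
    stats::glm(.y ~ ., family = stats::binomial(), data = dat)
  }
  null_fit <- fit_with(NULL)
  lin_fit <- fit_with(fp_basis(x, 1))

  fp1_sets <- as.list(powers)
  fp2_sets <- c(utils::combn(powers, 2, simplify = FALSE),
                lapply(powers, function(p) c(p, p)))
  best_of <- function(sets) {
    fits <- lapply(sets, function(pp) fit_with(fp_basis(x, pp)))
    dev <- vapply(fits, stats::deviance, numeric(1))
    i <- which.min(dev)
    list(powers = sets[[i]], fit = fits[[i]], deviance = dev[i])
  }
  fp1 <- best_of(fp1_sets)
  fp2 <- best_of(fp2_sets)

  p_overall <- stats::pchisq(stats::deviance(null_fit) - fp2$deviance,
                             df = 4, lower.tail = FALSE)
  p_nonlin <- stats::pchisq(stats::deviance(lin_fit) - fp2$deviance,
                            df = 3, lower.tail = FALSE)
  p_fp2_vs_fp1 <- stats::pchisq(fp1$deviance - fp2$deviance,
                                df = 2, lower.tail = FALSE)

  selected <- if (p_overall >= alpha) "null"
  else if (p_nonlin >= alpha) "linear"
  else if (p_fp2_vs_fp1 >= alpha) "fp1"
  else "fp2"
  sel_powers <- switch(selected, null = numeric(0), linear = 1,
                       fp1 = fp1$powers, fp2 = fp2$powers)

  comparison <- data.frame(
    model = c("null", "linear", "fp1", "fp2"),
    powers = c("", "1", paste(fp1$powers, collapse = ","),
               paste(fp2$powers, collapse = ",")),
    deviance = c(stats::deviance(null_fit), stats::deviance(lin_fit),
                 fp1$deviance, fp2$deviance),
    aic = c(stats::AIC(null_fit), stats::AIC(lin_fit),
            stats::AIC(fp1$fit), stats::AIC(fp2$fit)),
    stringsAsFactors = FALSE)
  comparison$selected_aic <- comparison$aic == min(comparison$aic)

  structure(list(selected = selected, powers = sel_powers,
                 pvalues = list(overall = p_overall,
                                nonlinearity = p_nonlin,
                                fp2_vs_fp1 = p_fp2_vs_fp1),
                 comparison = comparison, shift = shift),
            class = "mfp_fit")
}

#' @export
print.mfp_fit <- function(x, ...) {
  cat(sprintf("Fractional-polynomial closed test: selected '%s'", x$selected))
  if (length(x$powers)) cat(" (powers ", paste(x$powers, collapse = ", "), ")",
                            sep = "")
  cat("\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

#' AIC comparison of linear, fractional-polynomial and GAM fits
#'
#' Convenience wrapper fitting the linear logistic model, the best
#' fractional polynomials from [mfp_closed_test()], and a spline-smoothed
#' generalised additive model (via `mgcv::gam`), and comparing them by
#' AIC (lower is better).
#'
#' @inheritParams mfp_closed_test
#' @return data.frame of class `fit_comparison` with `model`, `aic`,
#'   and `selected` marking the minimum-AIC model.
#' @export
aic_model_comparison <- function(outcome, exposure, covariates = NULL,
                                 powers = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)) {
  mfp <- mfp_closed_test(outcome, exposure, covariates, powers)
  dat <- data.frame(.y = outcome, .x = exposure)
  covs <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    covs <- names(covariates)
  }
  fml <- stats::as.formula(paste(
    ".y ~ s(.x)",
    if (length(covs)) paste("+", paste(covs, collapse = " + ")) else ""))
  gam_fit <- mgcv::gam(fml, family = stats::binomial(), data = dat)
  out <- rbind(mfp$comparison[, c("model", "aic")],
               data.frame(model = "gam", aic = stats::AIC(gam_fit)))
  out$selected <- out$aic == min(out$aic)
  class(out) <- c("fit_comparison", class(out))
  out
}
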