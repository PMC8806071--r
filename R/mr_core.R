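# Two-sample MR estimators and diagnostics: Wald ratio, IVW, MR-Egger,
# weighted median, Rucker model selection, Steiger directionality,
# analytic power for binary outcomes, and between-estimate heterogeneity.

#' @keywords internal
#' @noRd
mr_result <- function(method, beta, se, n_snps, q = NA_real_, q_df = NA_real_,
                      intercept = NA_real_, intercept_se = NA_real_) {
  structure(list(
    method = method, beta = beta, se = se,
    pvalue = beta_to_p(beta, se),
    or_ = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    n_snps = n_snps,
    q = q, q_df = q_df,
    q_pvalue = if (is.na(q)) NA_real_ else
      stats::pchisq(q, df = q_df, lower.tail = FALSE),
    intercept = intercept, intercept_se = intercept_se,
    intercept_pvalue = if (is.na(intercept)) NA_real_ else
      beta_to_p(intercept, intercept_se)
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR estimate (%s, %d SNPs)\n", x$method, x$n_snps))
  cat(sprintf("  beta = %.4g (SE %.4g), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$beta, x$se, x$or_, x$ci_low, x$ci_high, x$pvalue))
  if (!is.na(x$q))
    cat(sprintf("  Q = %.3f on %d df, p = %.3g\n", x$q, x$q_df, x$q_pvalue))
  if (!is.na(x$intercept))
    cat(sprintf("  intercept = %.4g (SE %.4g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pvalue))
  invisible(x)
}

#' @keywords internal
#' @noRd
hset_data <- function(set) {
  if (inherits(set, "harmonized_set")) set$data
  else as.data.frame(set)
}

#' Wald ratio estimate for a single variant
#'
#' The per-SNP causal estimate `by/bx` with first-order standard error
#' `sy/|bx|`; `second_order = TRUE` adds the exposure-uncertainty term
#' `by^2 * sx^2 / bx^4` under the variance.
#'
#' @param bx,sx SNP-exposure effect and its SE (`sx` may be `NA` for the
#'   first-order SE).
#' @param by,sy SNP-outcome effect and its SE.
#' @param second_order Include the exposure-error term in the SE.
#' @return An `mr_result`.
#' @export
wald_ratio <- function(bx, sx = NA_real_, by, sy, second_order = FALSE) {
  if (bx == 0) stop("undefined ratio: bx = 0", call. = FALSE)
  beta <- by / bx
  v <- sy^2 / bx^2
  if (second_order) {
    if (is.na(sx)) stop("second-order SE requires sx", call. = FALSE)
    v <- v + by^2 * sx^2 / bx^4
  }
  mr_result("wald", beta, sqrt(v), n_snps = 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of SNP-outcome effects on SNP-exposure effects
#' through the origin with weights `1/sy^2`. The default is the
#' fixed-effect estimator (residual scale fixed at 1);
#' `random_effects = TRUE` inflates the SE by the multiplicative
#' overdispersion factor `max(1, sqrt(Q/df))`. Cochran's Q is the weighted
#' residual sum of squares on `n_snps - 1` degrees of freedom. With a
#' single SNP the estimate reduces exactly to the Wald ratio.
#'
#' @param set A `harmonized_set` or data.frame with columns
#'   `bx`, `sx`, `by`, `sy`.
#' @param random_effects Use multiplicative random-effects SE.
#' @return An `mr_result` with Q diagnostics.
#' @export
mr_ivw <- function(set, random_effects = FALSE) {
  d <- hset_data(set)
  n <- nrow(d)
  if (n < 1L) stop("at least one SNP required", call. = FALSE)
  if (n == 1L) return(wald_ratio(d$bx, d$sx, d$by, d$sy))
  w <- 1 / d$sy^2
  beta <- sum(w * d$bx * d$by) / sum(w * d$bx^2)
  se <- 1 / sqrt(sum(w * d$bx^2))
  q <- sum(w * (d$by - beta * d$bx)^2)
  q_df <- n - 1L
  if (random_effects) se <- se * max(1, sqrt(q / q_df))
  out <- mr_result("ivw", beta, se, n_snps = n, q = q, q_df = q_df)
  out
}

#' MR-Egger regression
#'
#' Weighted (`1/sy^2`) linear regression of SNP-outcome on SNP-exposure
#' effects with an unconstrained intercept, after fixing the orientation so
#' that all `bx >= 0` (negating `by` alongside). The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates average
#' directional pleiotropy. Q' is the weighted residual sum of squares on
#' `n_snps - 2` degrees of freedom; SEs use residual scale fixed at 1
#' (`random_effects = TRUE` inflates by `max(1, sqrt(Q'/df))`).
#'
#' @inheritParams mr_ivw
#' @return An `mr_result` with intercept and Q' diagnostics.
#' @export
mr_egger <- function(set, random_effects = FALSE) {
  d <- hset_data(set)
  n <- nrow(d)
  if (n < 3L) stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  flip <- sign(d$bx); flip[flip == 0] <- 1
  bx <- d$bx * flip
  by <- d$by * flip
  w <- 1 / d$sy^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coefs <- solve(XtWX, crossprod(X, w * by))
  V <- solve(XtWX)
  resid <- by - X %*% coefs
  q <- sum(w * resid^2)
  q_df <- n - 2L
  scale <- if (random_effects) max(1, sqrt(q / q_df)) else 1
  mr_result("egger", beta = coefs[2L], se = sqrt(V[2L, 2L]) * scale,
            n_snps = n, q = q, q_df = q_df,
            intercept = coefs[1L], intercept_se = sqrt(V[1L, 1L]) * scale)
}

# Weighted median of `x` with weights `w`, linearly interpolated at
# standardized cumulative weight 0.5 (the convention of the weighted-median
# MR estimator).
#' @keywords internal
#' @noRd
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  if (cw[1L] >= 0.5) return(x[1L])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  below <- max(which(cw < 0.5))
  x[below] + (x[below + 1L] - x[below]) *
    (0.5 - cw[below]) / (cw[below + 1L] - cw[below])
}

#' Weighted median MR estimate
#'
#' The weighted median of per-SNP Wald ratios with weights equal to the
#' inverse variance of each ratio (first-order). The standard error is
#' obtained by parametric bootstrap: `bx` and `by` are resampled from
#' normal distributions centred on their estimates with SDs `sx`, `sy`,
#' and the weighted median recomputed. Consistent when up to half of the
#' instrument weight comes from invalid instruments.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap resamples for the SE.
#' @param seed Seed for the bootstrap (mandatory for reproducibility).
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(set, n_boot = 5000L, seed) {
  d <- hset_data(set)
  n <- nrow(d)
  if (n < 3L) stop("weighted median requires at least 3 SNPs", call. = FALSE)
  if (missing(seed)) stop("a bootstrap seed is required", call. = FALSE)
  ratio <- d$by / d$bx
  w <- d$bx^2 / d$sy^2   # 1 / Var(by/bx), first-order
  est <- weighted_median_point(ratio, w)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx_s <- stats::rnorm(n, d$bx, d$sx)
      by_s <- stats::rnorm(n, d$by, d$sy)
      weighted_median_point(by_s / bx_s, bx_s^2 / d$sy^2)
    }, numeric(1))
  })
  mr_result("weighted_median", est, stats::sd(boot), n_snps = n)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
#' @keywords internal
#' @noRd
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Rucker framework model selection between IVW and MR-Egger
#'
#' Chooses the estimator with the least unexplained heterogeneity while
#' weighing power against pleiotropy: if the IVW Cochran's Q is not
#' significant at `alpha_q`, IVW is selected; otherwise, if the reduction
#' in heterogeneity from adding the Egger intercept (`Q - Q'`, chi-square
#' on 1 df) is significant and the intercept itself is significant,
#' MR-Egger is selected; otherwise IVW is retained.
#'
#' @param ivw_res,egger_res `mr_result` objects computed on the same
#'   instrument set.
#' @param alpha_q Significance level for the heterogeneity tests.
#' @return List with `method` (`"ivw"` or `"egger"`) and `rationale`
#'   (Q, Q', their ratio, the Q - Q' test p, and the intercept p).
#' @export
rucker_select <- function(ivw_res, egger_res, alpha_q = 0.05) {
  stopifnot(inherits(ivw_res, "mr_result"), inherits(egger_res, "mr_result"))
  q <- ivw_res$q; qp <- egger_res$q
  q_diff <- max(q - qp, 0)
  q_diff_p <- stats::pchisq(q_diff, df = 1, lower.tail = FALSE)
  rationale <- list(q = q, q_egger = qp, q_ratio = qp / q,
                    q_pvalue = ivw_res$q_pvalue,
                    q_diff = q_diff, q_diff_pvalue = q_diff_p,
                    intercept_pvalue = egger_res$intercept_pvalue)
  method <- if (ivw_res$q_pvalue >= alpha_q) "ivw"
  else if (q_diff_p < alpha_q && egger_res$intercept_pvalue < alpha_q) "egger"
  else "ivw"
  list(method = method, rationale = rationale)
}

# Per-SNP variance explained: 2f(1-f)beta^2 for a trait in SD units with
# known allele frequency; t^2/(t^2 + n - 2) fallback otherwise.
#' @keywords internal
#' @noRd
snp_r2 <- function(beta, se, eaf, n, trait_type) {
  r2 <- rep(NA_real_, length(beta))
  use_eaf <- trait_type == "continuous" & !is.na(eaf)
  r2[use_eaf] <- 2 * eaf[use_eaf] * (1 - eaf[use_eaf]) * beta[use_eaf]^2
  t2 <- (beta / se)^2
  r2[!use_eaf] <- t2[!use_eaf] / (t2[!use_eaf] + n - 2)
  r2
}

#' MR-Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure against
#' the variance they explain in the outcome. The causal direction
#' exposure -> outcome is supported when the former exceeds the latter;
#' the p-value comes from the z-comparison of the two Fisher-transformed
#' multiple correlations.
#'
#' @inheritParams mr_ivw
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param trait_types Length-2 character: types (`"continuous"`/`"binary"`)
#'   of the exposure and outcome traits.
#' @return List with `r2_exposure`, `r2_outcome`, `direction_ok`, `pvalue`.
#' @export
mr_steiger <- function(set, n_exposure, n_outcome,
                       trait_types = c("continuous", "binary")) {
  d <- hset_data(set)
  r2x <- snp_r2(d$bx, d$sx, d$eaf, n_exposure, trait_types[1L])
  r2y <- snp_r2(d$by, d$sy, d$eaf, n_outcome, trait_types[2L])
  bad <- is.na(r2x) | is.na(r2y)
  if (any(bad))
    stop("r2 not computable for SNP(s): ",
         paste(d$variant_id[bad], collapse = ", "), call. = FALSE)
  r2x_tot <- min(sum(r2x), 0.999)
  r2y_tot <- min(sum(r2y), 0.999)
  rx <- sqrt(r2x_tot); ry <- sqrt(r2y_tot)
  z <- (atanh(rx) - atanh(ry)) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  list(r2_exposure = r2x_tot, r2_outcome = r2y_tot,
       direction_ok = r2x_tot > r2y_tot, pvalue = z_to_p(z))
}

#' Analytic power for two-sample MR with a binary outcome
#'
#' Normal-test approximation: the SE of the causal log OR is
#' `1/sqrt(n * r2 * cf * (1 - cf))` where `n` is the outcome GWAS size,
#' `cf` the case fraction and `r2` the variance in the exposure explained
#' by the instrument. Power at two-sided level `alpha` follows from the
#' standard normal shift alternative; at `or_true = 1` it equals `alpha`.
#'
#' @param n Outcome GWAS sample size (cases + controls).
#' @param case_fraction Proportion of cases.
#' @param r2_instrument Instrument variance explained in the exposure.
#' @param or_true True odds ratio per SD of exposure.
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
power_binary <- function(n, case_fraction, r2_instrument, or_true,
                         alpha = 0.05) {
  stopifnot_scalar_prob(case_fraction, "case_fraction")
  stopifnot_scalar_prob(r2_instrument, "r2_instrument")
  stopifnot_scalar_prob(alpha, "alpha")
  se <- 1 / sqrt(n * r2_instrument * case_fraction * (1 - case_fraction))
  za <- stats::qnorm(1 - alpha / 2)
  shift <- log(or_true) / se
  stats::pnorm(-za + shift) + stats::pnorm(-za - shift)
}

#' Heterogeneity test between two estimates
#'
#' z-test of the difference of two independent estimates:
#' `z = (beta1 - beta2)/sqrt(se1^2 + se2^2)`, two-sided normal p.
#'
#' @param beta1,se1,beta2,se2 Estimates and standard errors.
#' @return List with `z` and `p_het`.
#' @export
het_between <- function(beta1, se1, beta2, se2) {
  stopifnot(se1 > 0, se2 > 0)
  z <- (beta1 - beta2) / sqrt(se1^2 + se2^2)
  list(z = z, p_het = z_to_p(z))
}
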