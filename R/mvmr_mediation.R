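# Multivariable MR and two-step mediation MR: product-of-coefficients
# indirect effects, proportion mediated, and delta-method intervals.

#' Harmonise several exposures and one outcome to a common instrument set
#'
#' Takes the union-of-instruments design of multivariable MR restricted to
#' variants available in every table: each exposure and the outcome are
#' harmonised to the alleles of the first exposure.
#'
#' @param exposures Named list of [sumstats] objects (>= 2 exposures).
#' @param outcome A [sumstats] object.
#' @param ... Passed to [harmonize()] (palindrome policy, eaf window).
#' @return Object of class `mvmr_set`: `exposure_labels`, `outcome_label`,
#'   `bx`/`sx` matrices (SNP x exposure), `by`/`sy` vectors, `variant_id`.
#' @export
harmonize_mvmr <- function(exposures, outcome, ...) {
  stopifnot(length(exposures) >= 2L)
  labels <- names(exposures)
  if (is.null(labels))
    labels <- vapply(exposures, function(e) e$trait_label, character(1))
  ref <- exposures[[1L]]
  sets <- lapply(exposures[-1L], function(e) harmonize(ref, e, ...))
  oset <- harmonize(ref, outcome, ...)
  ids <- Reduce(intersect, c(list(oset$data$variant_id),
                             lapply(sets, function(s) s$data$variant_id)))
  if (length(ids) == 0L)
    stop("no overlapping instruments across all exposures and the outcome",
         call. = FALSE)
  ref_rows <- ref$data[match(ids, ref$data$variant_id), ]
  bx <- cbind(ref_rows$beta,
              vapply(sets, function(s)
                s$data$by[match(ids, s$data$variant_id)], numeric(length(ids))))
  sx <- cbind(ref_rows$se,
              vapply(sets, function(s)
                s$data$sy[match(ids, s$data$variant_id)], numeric(length(ids))))
  colnames(bx) <- colnames(sx) <- labels
  orow <- match(ids, oset$data$variant_id)
  structure(list(exposure_labels = labels,
                 outcome_label = outcome$trait_label,
                 variant_id = ids, bx = bx, sx = sx,
                 by = oset$data$by[orow], sy = oset$data$sy[orow]),
            class = "mvmr_set")
}

#' Multivariable IVW regression
#'
#' Weighted (`1/sy^2`) regression of SNP-outcome effects on the matrix of
#' per-SNP exposure effects without an intercept; each slope is the effect
#' of that exposure on the outcome conditional on the co-included
#' exposures. SEs use residual scale fixed at 1 by default
#' (`random_effects = TRUE` applies the multiplicative overdispersion
#' factor). An exposure whose instrument effects are all zero is dropped
#' with a warning (its estimate is `NA`); collinearity among non-degenerate
#' exposures raises an error naming them.
#'
#' @param set An `mvmr_set`, or a list with elements `bx` (matrix), `by`,
#'   `sy` (vectors) and optionally `exposure_labels`.
#' @param random_effects Multiplicative random-effects SEs.
#' @return Object of class `mvmr_result`: data.frame `estimates` with one
#'   row per exposure (`exposure`, `beta`, `se`, `pvalue`,
#'   `conditional_f`), plus `n_snps`, `q`, `q_df`.
#' @export
mvmr_ivw <- function(set, random_effects = FALSE) {
  bx <- as.matrix(set$bx)
  by <- set$by; sy <- set$sy
  labels <- if (!is.null(set$exposure_labels)) set$exposure_labels
  else colnames(bx)
  if (is.null(labels)) labels <- paste0("exposure_", seq_len(ncol(bx)))
  k <- ncol(bx); n <- nrow(bx)
  if (n < k + 1L)
    stop("multivariable IVW needs at least one more SNP than exposures",
         call. = FALSE)

  zero_col <- apply(bx, 2L, function(x) all(x == 0))
  if (any(zero_col))
    warning("exposure(s) with all-zero instrument effects dropped: ",
            paste(labels[zero_col], collapse = ", "), call. = FALSE)
  use <- which(!zero_col)
  X <- bx[, use, drop = FALSE]
  if (qr(X)$rank < ncol(X))
    stop("collinear exposures: ", paste(labels[use], collapse = ", "),
         call. = FALSE)

  w <- 1 / sy^2
  XtWX <- crossprod(X, w * X)
  coefs <- drop(solve(XtWX, crossprod(X, w * by)))
  V <- solve(XtWX)
  resid <- by - drop(X %*% coefs)
  q <- sum(w * resid^2)
  q_df <- n - ncol(X)
  scale <- if (random_effects) max(1, sqrt(q / q_df)) else 1
  se <- sqrt(diag(V)) * scale

  # conditional instrument strength: F-stat of each exposure's effects
  # residualised on the other exposures' effects
  cond_f <- vapply(seq_along(use), function(j) {
    if (length(use) == 1L) return(mean((X[, j] / set$sx[, use[j]])^2))
    r <- stats::lm.fit(X[, -j, drop = FALSE], X[, j])$residuals
    mean((r / set$sx[, use[j]])^2)
  }, numeric(1))

  est <- data.frame(exposure = labels, beta = NA_real_, se = NA_real_,
                    pvalue = NA_real_, conditional_f = NA_real_,
                    stringsAsFactors = FALSE)
  est$beta[use] <- coefs
  est$se[use] <- se
  est$pvalue[use] <- beta_to_p(coefs, se)
  est$conditional_f[use] <- cond_f
  structure(list(estimates = est, n_snps = n, q = q, q_df = q_df),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable IVW (%d SNPs)\n", x$n_snps))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

#' Two-step mediation MR by the product of coefficients
#'
#' Combines the total effect `c` of the exposure on the outcome, the
#' exposure-to-mediator effect `a`, and the mediator-to-outcome effect `b`
#' conditional on the exposure (from multivariable MR) into the indirect
#' effect `a*b` and the proportion mediated `a*b/c`. The SE of the
#' proportion uses the first-order delta method treating a, b, c as
#' independent:
#' `sqrt((b*se_a/c)^2 + (a*se_b/c)^2 + (a*b*se_c/c^2)^2)`.
#' The 95% CI is `proportion +/- 1.96*SE`; `proportion_ci` is additionally
#' truncated to \[0, 1\] for reporting while the raw bounds are preserved.
#'
#' @param a,se_a Exposure -> mediator effect (SD per SD) and SE.
#' @param b,se_b Mediator -> outcome effect conditional on the exposure
#'   (log OR per SD) and SE.
#' @param c,se_c Total exposure -> outcome effect (log OR per SD) and SE.
#' @param direct,se_direct Optional exposure -> outcome effect conditional
#'   on the mediator (from multivariable MR); defaults to `c - a*b`
#'   (difference method) with `NA` SE.
#' @return Object of class `mediation_result`.
#' @export
two_step_mediation <- function(a, se_a, b, se_b, c, se_c,
                               direct = NULL, se_direct = NA_real_) {
  if (c == 0) stop("undefined proportion: total effect c = 0", call. = FALSE)
  indirect <- a * b
  indirect_se <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  proportion <- indirect / c
  proportion_se <- sqrt((b * se_a / c)^2 + (a * se_b / c)^2 +
                          (a * b * se_c / c^2)^2)
  ci_raw <- proportion + c(-1.96, 1.96) * proportion_se
  if (is.null(direct)) direct <- c - indirect
  structure(list(
    a = a, se_a = se_a, b = b, se_b = se_b, c = c, se_c = se_c,
    indirect = indirect, indirect_se = indirect_se,
    direct = direct, se_direct = se_direct,
    proportion = proportion, proportion_se = proportion_se,
    proportion_ci_raw = ci_raw,
    proportion_ci = pmin(pmax(ci_raw, 0), 1)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step mediation MR (product of coefficients)\n")
  cat(sprintf("  total c = %.3f (SE %.3f); a = %.3f (SE %.3f); b = %.3f (SE %.3f)\n",
              x$c, x$se_c, x$a, x$se_a, x$b, x$se_b))
  cat(sprintf("  indirect a*b = %.3f; proportion mediated = %.1f%% (95%% CI %.1f%%-%.1f%%)\n",
              x$indirect, 100 * x$proportion,
              100 * x$proportion_ci[1L], 100 * x$proportion_ci[2L]))
  invisible(x)
}

#' Convert a log odds ratio to an odds ratio
#'
#' @param log_or Log odds ratio(s).
#' @return `exp(log_or)`.
#' @export
or_from_log <- function(log_or) exp(log_or)

#' Mediation analysis over a grid of exposure-mediator-outcome triples
#'
#' Applies [two_step_mediation()] to each triple that passes the
#' significance gates: the total effect must be significant after FDR
#' adjustment across the grid (`fdr_level`), and both path coefficients
#' must be significant at unadjusted `gate_p`. Skipped triples are
#' recorded with the failed gate as the reason.
#'
#' @param triples data.frame with columns `exposure`, `mediator`,
#'   `outcome`, `a`, `se_a`, `b`, `se_b`, `c`, `se_c`.
#' @param gate_p Unadjusted significance gate for the a and b paths.
#' @param fdr_level FDR gate for the total effect.
#' @return List with `results` (named list of `mediation_result`) and
#'   `skipped` (data.frame `exposure`, `mediator`, `outcome`, `reason`).
#' @export
mediation_grid <- function(triples, gate_p = 0.05, fdr_level = 0.05) {
  need <- c("exposure", "mediator", "outcome",
            "a", "se_a", "b", "se_b", "c", "se_c")
  stopifnot(all(need %in% names(triples)))
  p_c <- beta_to_p(triples$c, triples$se_c)
  q_c <- bh_fdr(p_c)
  p_a <- beta_to_p(triples$a, triples$se_a)
  p_b <- beta_to_p(triples$b, triples$se_b)

  results <- list()
  skipped <- triples[0, c("exposure", "mediator", "outcome")]
  skipped$reason <- character(0)
  for (i in seq_len(nrow(triples))) {
    reason <- if (q_c[i] >= fdr_level) "total effect not significant"
    else if (p_a[i] >= gate_p) "exposure-mediator path not significant"
    else if (p_b[i] >= gate_p) "mediator-outcome path not significant"
    else NA_character_
    key <- paste(triples$exposure[i], triples$mediator[i],
                 triples$outcome[i], sep = " | ")
    if (is.na(reason)) {
      results[[key]] <- two_step_mediation(
        triples$a[i], triples$se_a[i], triples$b[i], triples$se_b[i],
        triples$c[i], triples$se_c[i])
    } else {
      skipped <- rbind(skipped, data.frame(
        exposure = triples$exposure[i], mediator = triples$mediator[i],
        outcome = triples$outcome[i], reason = reason,
        stringsAsFactors = FALSE))
    }
  }
  list(results = results, skipped = skipped)
}
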