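# Mixture-model clustering of per-SNP Wald-ratio estimates into null,
# substantial, and junk components, fitted by multi-start EM with
# known per-SNP sampling variances.

# Mixture log-likelihood and responsibilities for a given set of
# substantial means. Components: null N(0, se^2), substantial N(mu_k, se^2),
# junk N(0, junk_var).
#' @keywords internal
#' @noRd
mixture_loglik_matrix <- function(theta, se, mu, junk_var) {
  dens <- cbind(
    stats::dnorm(theta, 0, se),
    if (length(mu)) vapply(mu, function(m) stats::dnorm(theta, m, se),
                           numeric(length(theta))),
    stats::dnorm(theta, 0, sqrt(junk_var))
  )
  dens
}

#' @keywords internal
#' @noRd
em_fit_k <- function(theta, se, k, junk_var, mu_init, tol, max_iter) {
  n <- length(theta)
  n_comp <- k + 2L
  pi_k <- rep(1 / n_comp, n_comp)
  mu <- mu_init
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- mixture_loglik_matrix(theta, se, mu, junk_var)
    num <- sweep(dens, 2L, pi_k, `*`)
    rowsum_ <- rowSums(num)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    resp <- num / rowsum_
    ll <- sum(log(rowsum_))
    pi_k <- colMeans(resp)
    if (k > 0L) {
      for (j in seq_len(k)) {
        r <- resp[, 1L + j]
        wsum <- sum(r / se^2)
        mu[j] <- if (wsum > 0) sum(r * theta / se^2) / wsum else mu[j]
      }
    }
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) {
      return(list(loglik = ll, mu = mu, pi = pi_k, resp = resp,
                  converged = TRUE, iterations = iter))
    }
    ll_old <- ll
  }
  list(loglik = ll_old, mu = mu, pi = pi_k, resp = resp,
       converged = FALSE, iterations = max_iter)
}

#' Mixture-model clustering of per-SNP causal estimates
#'
#' Fits, by expectation-maximisation, a mixture of (i) a null component
#' centred at zero with each SNP's own sampling variance, (ii) `k`
#' "substantial" components at estimated shared means with per-SNP
#' sampling variance, and (iii) a broad zero-mean "junk" component for
#' outlying estimates that group with nothing (variance `junk_scale`
#' times the largest `se^2`, floored at the empirical variance of
#' `theta`). The number of substantial components is chosen by AIC over
#' `0..max_k` (AIC rather than BIC: with a broad junk component in the
#' model, BIC's heavier penalty routinely absorbs genuinely separated
#' clusters into junk; both criteria are returned), with candidates
#' containing a singleton substantial cluster disqualified (an
#' ungroupable variant is junk by definition);
#' each candidate is fitted from `n_starts` seeded initialisations drawn
#' from the observed estimates, so the fit is deterministic given `seed`.
#'
#' @param theta Per-SNP causal estimates (Wald ratios).
#' @param se Their standard errors (> 0).
#' @param variant_id Optional variant identifiers.
#' @param max_k Maximum number of substantial clusters considered.
#' @param seed Seed for the multi-start initialisation.
#' @param junk_scale Junk-component variance as a multiple of `max(se^2)`.
#' @param n_starts EM starts per candidate `k`.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations per start.
#' @return Object of class `mr_clust_fit`: `k`, `means`, `proportions`,
#'   `aic`/`bic` (per candidate k), `assignments` (data.frame `variant_id`,
#'   `cluster_id`, `cluster_type`, `probability`, `cluster_mean`),
#'   `probabilities` (SNP x component matrix), `converged`.
#' @export
fit_mixture <- function(theta, se, variant_id = NULL, max_k = 5L, seed = 1L,
                        junk_scale = 10, n_starts = 10L, tol = 1e-8,
                        max_iter = 1000L) {
  n <- length(theta)
  stopifnot(length(se) == n, all(se > 0))
  if (n < 5L) stop("at least 5 SNPs required", call. = FALSE)
  if (is.null(variant_id)) variant_id <- paste0("snp_", seq_len(n))
  # The junk component must be broad enough to absorb estimates far from
  # every cluster, so its variance is floored at the empirical spread of
  # theta (not just the sampling noise).
  junk_var <- max(junk_scale * max(se^2), stats::var(theta))

  fits <- withr_seed(seed, {
    lapply(0:max_k, function(k) {
      starts <- lapply(seq_len(n_starts), function(s) {
        mu0 <- if (k == 0L) numeric(0)
        else if (s == 1L)  # one deterministic spread-quantile start
          stats::quantile(theta, probs = seq(0.1, 0.9, length.out = k),
                          names = FALSE)
        else               # remaining starts seeded from observed estimates
          sample(theta, k)
        em_fit_k(theta, se, k, junk_var, mu0, tol, max_iter)
      })
      lls <- vapply(starts, `[[`, numeric(1), "loglik")
      conv <- vapply(starts, `[[`, logical(1), "converged")
      # prefer the best converged start; fall back to the best overall
      best <- if (any(conv)) starts[[which(conv)[which.max(lls[conv])]]]
      else starts[[which.max(lls)]]
      best$k <- k
      # free parameters: k means + (k + 1) mixing proportions
      npar <- 2 * k + 1
      best$bic <- -2 * best$loglik + npar * log(n)
      best$aic <- -2 * best$loglik + 2 * npar
      # a "substantial" component holding a single SNP is a contradiction
      # in terms (junk = cannot be grouped with other variants): disqualify
      if (k > 0L) {
        hard <- max.col(best$resp)
        sizes <- tabulate(hard, nbins = k + 2L)[1L + seq_len(k)]
        if (any(sizes < 2L)) best$aic <- best$bic <- Inf
      }
      best
    })
  })

  aic <- vapply(fits, `[[`, numeric(1), "aic")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(aic)]]
  if (!best$converged)
    stop("EM did not converge within ", max_iter, " iterations (k = ",
         best$k, ", loglik trace ended at ", signif(best$loglik, 8), ")",
         call. = FALSE)

  # Post-selection merging: substantial components whose means are not
  # separated beyond estimation error (3 z-units) describe one cluster;
  # a component indistinguishable from zero belongs to the null. After
  # merging, responsibilities are settled by one further EM pass.
  repeat {
    k <- best$k
    if (k == 0L) break
    se_mu <- vapply(seq_len(k), function(j) {
      1 / sqrt(sum(best$resp[, 1L + j] / se^2))
    }, numeric(1))
    mu <- best$mu
    drop_j <- which(abs(mu) < 3 * se_mu)
    if (length(drop_j) > 0L) {
      mu <- mu[-drop_j[1L]]
    } else if (k >= 2L) {
      pairs <- utils::combn(k, 2)
      z <- abs(mu[pairs[1, ]] - mu[pairs[2, ]]) /
        sqrt(se_mu[pairs[1, ]]^2 + se_mu[pairs[2, ]]^2)
      if (any(z < 3)) {
        p <- pairs[, which.min(z)]
        mu <- c(mu[-p], mean(mu[p]))
      } else break
    } else break
    refit <- em_fit_k(theta, se, length(mu), junk_var, mu, tol, max_iter)
    refit$k <- length(mu)
    best <- refit
  }
  k <- best$k
  comp_type <- c("null", if (k > 0L) rep("substantial", k), "junk")
  comp_id <- c("null", if (k > 0L) paste0("substantial_", seq_len(k)), "junk")
  comp_mean <- c(0, if (k > 0L) best$mu, 0)
  hard <- max.col(best$resp)
  assignments <- data.frame(
    variant_id = variant_id,
    cluster_id = comp_id[hard],
    cluster_type = comp_type[hard],
    probability = best$resp[cbind(seq_len(n), hard)],
    cluster_mean = comp_mean[hard],
    stringsAsFactors = FALSE)
  colnames(best$resp) <- comp_id

  structure(list(k = k, means = if (k > 0L) best$mu else numeric(0),
                 proportions = stats::setNames(best$pi, comp_id),
                 aic = stats::setNames(aic, paste0("k", 0:max_k)),
                 bic = stats::setNames(bic, paste0("k", 0:max_k)),
                 assignments = assignments, probabilities = best$resp,
                 junk_var = junk_var, converged = best$converged),
            class = "mr_clust_fit")
}

#' @export
print.mr_clust_fit <- function(x, ...) {
  cat(sprintf("Mixture clustering of %d SNPs: %d substantial cluster(s)\n",
              nrow(x$assignments), x$k))
  if (x$k > 0L)
    cat("  substantial means:", paste(signif(x$means, 4), collapse = ", "),
        "\n")
  print(table(x$assignments$cluster_type))
  invisible(x)
}

#' Members of substantial clusters at an assignment threshold
#'
#' Returns, per substantial cluster, the SNPs whose posterior probability
#' of membership in that cluster meets the threshold, with the cluster's
#' effect direction.
#'
#' @param fit An `mr_clust_fit`.
#' @param threshold Minimum posterior probability (default 0.80).
#' @return Named list (one element per substantial cluster) of data.frames
#'   with `variant_id`, `probability`, `cluster_mean`, `sign` (`"+"`/`"-"`).
#' @export
substantial_members <- function(fit, threshold = 0.80) {
  stopifnot(inherits(fit, "mr_clust_fit"))
  if (fit$k == 0L) return(list())
  out <- list()
  for (j in seq_len(fit$k)) {
    id <- paste0("substantial_", j)
    p <- fit$probabilities[, id]
    sel <- p >= threshold
    out[[id]] <- data.frame(
      variant_id = fit$assignments$variant_id[sel],
      probability = p[sel],
      cluster_mean = fit$means[j],
      sign = if (fit$means[j] >= 0) "+" else "-",
      stringsAsFactors = FALSE)
  }
  out
}
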