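# Two-sample MR estimators and diagnostics.

test_that("Wald ratio matches its closed form, including edge cases", {
  w <- wald_ratio(bx = 0.1, by = 0.05, sy = 0.1)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 1.0)
  expect_equal(wald_ratio(bx = 0.1, by = 0, sy = 0.1)$beta, 0)
  expect_error(wald_ratio(bx = 0, by = 0.1, sy = 0.1), "bx = 0")

  set.seed(1)
  for (i in 1:20) {
    bx <- rnorm(1); if (bx == 0) next
    by <- rnorm(1); sy <- runif(1, 0.01, 1); sx <- runif(1, 0.01, 0.2)
    w <- wald_ratio(bx, sx, by, sy)
    expect_equal(w$beta, by / bx)
    expect_equal(w$se, sy / abs(bx))
    w2 <- wald_ratio(bx, sx, by, sy, second_order = TRUE)
    expect_equal(w2$se, sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4))
    expect_equal(w$or_, exp(w$beta))
    expect_lte(w$ci_low, w$or_); expect_gte(w$ci_high, w$or_)
  }
})

test_that("IVW equals the through-origin WLS oracle and the Wald ratio at 1 SNP", {
  h1 <- make_hset(bx = 0.08, sx = 0.01, by = 0.02, sy = 0.05)
  expect_identical(mr_ivw(h1)$beta, wald_ratio(0.08, 0.01, 0.02, 0.05)$beta)
  expect_identical(mr_ivw(h1)$se, wald_ratio(0.08, 0.01, 0.02, 0.05)$se)

  set.seed(2)
  h <- draw_instruments(5, theta = 0.3)
  res <- mr_ivw(h)
  oracle <- lm(by ~ 0 + bx, data = h$data, weights = 1 / h$data$sy^2)
  expect_equal(res$beta, unname(coef(oracle)))
  # fixed-effect SE: residual scale pinned at 1
  expect_equal(res$se, 1 / sqrt(sum(h$data$bx^2 / h$data$sy^2)))
  expect_equal(res$q,
               sum((h$data$by - res$beta * h$data$bx)^2 / h$data$sy^2))
  expect_equal(res$q_df, 4L)

  # random-effects toggle only ever inflates the SE
  expect_gte(mr_ivw(h, random_effects = TRUE)$se, res$se)
})

test_that("IVW is unbiased and Q calibrated under no pleiotropy", {
  # precise instruments (sx ~ 0) so Q is exactly chi-square under the null
  set.seed(3)
  reps <- t(replicate(400, {
    h <- draw_instruments(50, theta = 0.25, sx = 1e-6)
    r <- mr_ivw(h)
    c(z = (r$beta - 0.25) / r$se, qp = r$q_pvalue)
  }))
  expect_lt(abs(mean(reps[, "z"])), 0.15)
  expect_lt(abs(sd(reps[, "z"]) - 1), 0.15)
  # Q p-values approximately uniform: mean and tail mass
  expect_lt(abs(mean(reps[, "qp"]) - 0.5), 0.05)
  expect_lt(abs(mean(reps[, "qp"] < 0.1) - 0.1), 0.05)
})

test_that("MR-Egger equals the weighted-regression oracle after orientation fixing", {
  set.seed(4)
  h <- draw_instruments(12, theta = 0.4)
  h$data$bx[c(2, 5)] <- -h$data$bx[c(2, 5)]
  h$data$by[c(2, 5)] <- -h$data$by[c(2, 5)]
  res <- mr_egger(h)
  d <- h$data
  flip <- sign(d$bx)
  oracle <- lm(I(by * flip) ~ I(bx * flip), data = d, weights = 1 / d$sy^2)
  expect_equal(res$beta, unname(coef(oracle)[2]))
  expect_equal(res$intercept, unname(coef(oracle)[1]))
  # fixed-scale SEs: vcov of the WLS fit with sigma^2 = 1
  X <- cbind(1, d$bx * flip)
  V <- solve(crossprod(X, X / d$sy^2))
  expect_equal(res$se, sqrt(V[2, 2]))
  expect_equal(res$intercept_se, sqrt(V[1, 1]))
  expect_equal(res$q_df, 10L)
  expect_error(mr_egger(make_hset(1:2 / 10, 0.01, 1:2 / 20, 0.02)),
               "at least 3")
})

test_that("estimators respect sign-flip invariances and Q >= Q'", {
  set.seed(5)
  for (i in 1:10) {
    h <- draw_instruments(20, theta = 0.2, pleio = rnorm(20, 0, 0.005))
    flip <- sample(c(-1, 1), 20, replace = TRUE)
    hf <- make_hset(h$data$bx * flip, h$data$sx, h$data$by * flip, h$data$sy)
    expect_equal(mr_ivw(hf)$beta, mr_ivw(h)$beta)
    # Egger is invariant only once orientation is fixed, which both share
    expect_equal(mr_egger(hf)$beta, mr_egger(h)$beta)
    expect_gte(mr_ivw(h)$q, mr_egger(h)$q)
  }
})

test_that("Egger recovers directional pleiotropy in the intercept", {
  set.seed(6)
  ints <- replicate(300, mr_egger(
    draw_instruments(40, theta = 0.2, sx = 1e-6, pleio = 0.02))$intercept)
  expect_lt(abs(mean(ints) - 0.02), 3 * sd(ints) / sqrt(300))
})

test_that("weighted median matches the brute-force oracle and is seed-stable", {
  # all ratios identical
  h <- make_hset(bx = rep(0.1, 5), sx = 0.01, by = rep(0.03, 5), sy = 0.02)
  expect_equal(mr_weighted_median(h, n_boot = 100, seed = 1)$beta, 0.3)

  # known ratios/weights: interpolated weighted median at cumulative 0.5
  ratios <- c(1, 2, 3, 4, 10)
  w <- c(0.1, 0.3, 0.2, 0.25, 0.15)
  bx <- rep(1, 5); sy <- sqrt(bx^2 / w)
  h2 <- make_hset(bx, 0.01, by = ratios, sy = sy)
  brute <- function(x, wt) {
    o <- order(x); x <- x[o]; wt <- wt[o]
    s <- (cumsum(wt) - wt / 2) / sum(wt)
    approx(s, x, xout = 0.5)$y
  }
  expect_equal(mr_weighted_median(h2, n_boot = 100, seed = 1)$beta,
               brute(ratios, w))

  # bootstrap SE stable within 5% across seeds at n_boot = 5000
  set.seed(7)
  h3 <- draw_instruments(30, theta = 0.3)
  se_a <- mr_weighted_median(h3, n_boot = 5000, seed = 11)$se
  se_b <- mr_weighted_median(h3, n_boot = 5000, seed = 99)$se
  expect_lt(abs(se_a - se_b) / se_a, 0.05)
  expect_error(mr_weighted_median(h3, n_boot = 100), "seed")
})

test_that("weighted median resists invalid instruments where IVW is biased", {
  # 30 SNPs, 40% invalid with directional pleiotropy large relative to the
  # per-ratio noise: the weighted median's defining robustness regime
  set.seed(8)
  pleio <- c(rep(0.03, 12), rep(0, 18))
  h <- draw_instruments(30, theta = 0.25, sy = 0.002, pleio = pleio)
  ivw <- mr_ivw(h)
  wm <- mr_weighted_median(h, n_boot = 2000, seed = 1)
  # IVW is pulled far outside its own confidence range ...
  expect_gt(abs(ivw$beta - 0.25), 3 * ivw$se)
  # ... while the weighted median stays within 3 SE of the truth
  expect_lt(abs(wm$beta - 0.25), 3 * wm$se)

  # aggregate bias ordering over replicates
  est <- t(replicate(40, {
    h <- draw_instruments(30, theta = 0.25, sy = 0.002, pleio = pleio)
    c(ivw = mr_ivw(h)$beta,
      wm = mr_weighted_median(h, n_boot = 50, seed = 1)$beta)
  }))
  expect_gt(abs(mean(est[, "ivw"]) - 0.25),
            3 * abs(mean(est[, "wm"]) - 0.25))
})

test_that("Rucker selection follows the Q / Q' / intercept decision tree", {
  mk <- function(q, q_df, int_p_small) {
    iv <- structure(list(q = q, q_df = q_df,
                         q_pvalue = pchisq(q, q_df, lower.tail = FALSE)),
                    class = "mr_result")
    eg <- structure(list(q = q * 0.5,
                         q_pvalue = pchisq(q * 0.5, q_df - 1,
                                           lower.tail = FALSE),
                         intercept_pvalue = if (int_p_small) 0.001 else 0.6),
                    class = "mr_result")
    rucker_select(iv, eg)
  }
  expect_equal(mk(10, 10, TRUE)$method, "ivw")     # Q not significant
  expect_equal(mk(60, 10, TRUE)$method, "egger")   # Q sig, Q-Q' sig, int sig
  expect_equal(mk(60, 10, FALSE)$method, "ivw")    # intercept not significant

  # the published diagnostic regime: Q'/Q > 0.876 and intercept p > 0.0547
  # always resolves to IVW regardless of the absolute Q
  for (q in c(20, 80, 300)) {
    iv <- structure(list(q = q, q_df = 20,
                         q_pvalue = pchisq(q, 20, lower.tail = FALSE)),
                    class = "mr_result")
    eg <- structure(list(q = q * 0.9, intercept_pvalue = 0.0548),
                    class = "mr_result")
    sel <- rucker_select(iv, eg)
    expect_equal(sel$method, "ivw")
    expect_gt(sel$rationale$q_ratio, 0.876)
  }

  # no-pleiotropy simulation: IVW selected in at least 1 - alpha of
  # replicates (Egger needs all three gates to fire jointly)
  set.seed(9)
  picks <- replicate(300, {
    h <- draw_instruments(30, theta = 0.2, sx = 1e-6)
    rucker_select(mr_ivw(h), mr_egger(h))$method
  })
  expect_gte(mean(picks == "ivw"), 0.93)
})

test_that("Steiger directionality compares variance explained", {
  # strong exposure instrument, negligible outcome signal
  h <- make_hset(bx = rep(0.2, 10), sx = 0.01, by = rep(0.002, 10),
                 sy = 0.01, eaf = rep(0.3, 10))
  s <- mr_steiger(h, n_exposure = 50000, n_outcome = 50000)
  expect_true(s$direction_ok)
  expect_lt(s$pvalue, 1e-10)
  expect_equal(s$r2_exposure, 10 * 2 * 0.3 * 0.7 * 0.2^2)

  # symmetric case: p near 1
  hs <- make_hset(bx = rep(0.1, 5), sx = 0.01, by = rep(0.1, 5), sy = 0.01,
                  eaf = rep(0.3, 5))
  ss <- mr_steiger(hs, 50000, 50000, trait_types = c("continuous", "continuous"))
  expect_equal(ss$pvalue, 1)

  # missing eaf with continuous traits falls back to t^2/(t^2 + n - 2)
  hna <- make_hset(bx = 0.2, sx = 0.01, by = 0.01, sy = 0.01)
  sna <- mr_steiger(hna, 5000, 5000)
  expect_equal(sna$r2_exposure, 400 / (400 + 4998))

  # simulated exposure -> outcome chains support the correct direction
  set.seed(10)
  ok <- replicate(100, {
    bx <- abs(rnorm(20, 0.15, 0.02))
    h <- make_hset(rnorm(20, bx, 0.01), 0.01, rnorm(20, 0.3 * bx, 0.01),
                   0.01, eaf = runif(20, 0.2, 0.5))
    mr_steiger(h, 50000, 50000,
               trait_types = c("continuous", "continuous"))$direction_ok
  })
  expect_gt(mean(ok), 0.95)
})

test_that("binary-outcome power is calibrated at the null and monotone", {
  expect_equal(power_binary(50000, 0.1, 0.02, or_true = 1), 0.05)
  expect_equal(power_binary(50000, 0.1, 0.02, 1, alpha = 0.01), 0.01)

  grid_n <- sapply(c(1e4, 5e4, 2e5), power_binary, case_fraction = 0.1,
                   r2_instrument = 0.02, or_true = 1.1)
  expect_true(all(diff(grid_n) > 0))
  grid_r2 <- sapply(c(0.005, 0.02, 0.08), function(r2)
    power_binary(5e4, 0.1, r2, 1.1))
  expect_true(all(diff(grid_r2) > 0))
  expect_gt(power_binary(5e4, 0.1, 0.02, 1.3),
            power_binary(5e4, 0.1, 0.02, 1.1))
  # symmetric in direction of effect
  expect_equal(power_binary(5e4, 0.1, 0.02, 1 / 1.2),
               power_binary(5e4, 0.1, 0.02, 1.2))

  # Monte-Carlo oracle: simulate the sampling distribution of the estimate
  set.seed(11)
  n <- 50000; cf <- 0.5; r2 <- 0.02; or <- 1.2
  se <- 1 / sqrt(n * r2 * cf * (1 - cf))
  mc <- mean(abs(rnorm(40000, log(or), se) / se) > qnorm(0.975))
  expect_equal(power_binary(n, cf, r2, or), mc, tolerance = 0.03)
})

test_that("between-estimate heterogeneity z-test is exact", {
  expect_equal(het_between(0.3, 0.1, 0.3, 0.2)$p_het, 1)
  hb <- het_between(0.2, 0.1, 0.0, 0.1)
  expect_equal(hb$z, 0.2 / sqrt(0.02))
  expect_equal(hb$z, 1.414, tolerance = 1e-3)
  # under resampling from the null the p-values are uniform
  set.seed(12)
  ps <- replicate(2000, {
    b <- rnorm(2, 0.1, c(0.05, 0.12))
    het_between(b[1], 0.05, b[2], 0.12)$p_het
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.015)
})
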