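# Reading, validation, harmonisation and meta-analysis of GWAS summary
# statistics.

test_that("well-formed tables parse, invalid rows are rejected with reasons", {
  df <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                   effect_allele = c("A", "C", "G"),
                   other_allele = c("G", "T", "A"),
                   eaf = c(0.2, 0.5, 0.8), beta = c(0.1, -0.2, 0),
                   se = c(0.01, 0.02, 0.03), pvalue = c(0.5, 0.1, 1),
                   n = 1000)
  ss <- sumstats(df, "bmi")
  expect_equal(nrow(ss$data), 3L)
  expect_equal(nrow(ss$rejects), 0L)

  bad <- rbind(df, data.frame(variant_id = c("rs4", "rs5", "rs1", "rs6"),
                              effect_allele = c("A", "AT", "A", "C"),
                              other_allele = c("G", "G", "G", "T"),
                              eaf = c(0.2, 0.2, 0.2, 1.4),
                              beta = 0.1, se = c(0, 0.1, 0.1, 0.1),
                              pvalue = 0.5, n = 1000))
  ss2 <- sumstats(bad, "bmi")
  expect_equal(nrow(ss2$data), 3L)
  expect_setequal(ss2$rejects$reason,
                  c("nonpositive SE", "allele not a single nucleotide",
                    "duplicate variant_id", "eaf outside [0,1]"))
  expect_equal(ss2$rejects$reason[ss2$rejects$variant_id == "rs4"],
               "nonpositive SE")
})

test_that("dialect aliases parse identically to the canonical header", {
  df <- data.frame(SNP = c("rs1", "rs2"), A1 = c("A", "C"), A2 = c("G", "T"),
                   freq = c(0.3, 0.4), b = c(0.12, -0.05),
                   std_err = c(0.01, 0.02), p = c(0.1, 0.2), N = 5000)
  f_alias <- tempfile(fileext = ".tsv")
  write.table(df, f_alias, sep = "\t", quote = FALSE, row.names = FALSE)
  aliased <- read_sumstats(
    f_alias, sumstats_dialect(variant_id = "SNP", effect_allele = "A1",
                              other_allele = "A2", eaf = "freq", beta = "b",
                              se = "std_err", pvalue = "p", n = "N"),
    trait_label = "t")

  f_canon <- tempfile(fileext = ".tsv")
  write_sumstats(aliased, f_canon)
  canonical <- read_sumstats(f_canon, trait_label = "t")
  expect_equal(canonical$data, aliased$data)

  expect_error(read_sumstats(f_alias, sumstats_dialect(), trait_label = "t"),
               "not found")
})

test_that("harmonisation follows the allele truth table", {
  # enumerate all non-palindromic configurations against hand-written truth
  exposure <- make_sumstats(paste0("rs", 1:5), ea = rep("A", 5),
                            oa = rep("G", 5), beta = 0.1, se = 0.01,
                            eaf = 0.3)
  outcome <- make_sumstats(
    paste0("rs", 1:5),
    ea = c("A", "G", "T", "C", "A"),
    oa = c("G", "A", "C", "T", "C"),
    beta = 0.05, se = 0.02, eaf = 0.3)
  h <- harmonize(exposure, outcome)
  # rs1 match: +0.05; rs2 swap: -0.05; rs3 strand flip (A/G ~ T/C): +0.05;
  # rs4 flip+swap: -0.05; rs5 mismatch: dropped
  expect_equal(h$data$variant_id, paste0("rs", 1:4))
  expect_equal(h$data$by, c(0.05, -0.05, 0.05, -0.05))
  expect_equal(h$dropped$reason, "allele mismatch")

  # palindromic SNPs: ambiguous eaf dropped, informative eaf aligned by side
  exp_p <- make_sumstats(c("p1", "p2", "p3", "p4", "np"),
                         ea = c("A", "A", "A", "A", "A"),
                         oa = c("T", "T", "T", "T", "G"),
                         beta = 0.1, se = 0.01,
                         eaf = c(0.48, 0.10, 0.10, NA, 0.3))
  out_p <- make_sumstats(c("p1", "p2", "p3", "p4", "np"),
                         ea = c("A", "A", "A", "A", "A"),
                         oa = c("T", "T", "T", "T", "G"),
                         beta = 0.05, se = 0.02,
                         eaf = c(0.48, 0.12, 0.88, 0.10, 0.3))
  hp <- harmonize(exp_p, out_p, palindrome_policy = "infer-by-eaf",
                  eaf_window = 0.08)
  expect_equal(hp$data$variant_id, c("p2", "p3", "np"))
  expect_equal(hp$data$by, c(0.05, -0.05, 0.05))  # same side kept, other flipped
  expect_equal(hp$dropped$reason[hp$dropped$variant_id == "p1"],
               "palindromic, ambiguous frequency")
  expect_equal(hp$dropped$reason[hp$dropped$variant_id == "p4"],
               "palindromic, missing eaf")

  hd <- harmonize(exp_p, out_p, palindrome_policy = "drop")
  expect_equal(hd$data$variant_id, "np")  # every palindromic SNP dropped
  expect_equal(hd$dropped$reason[hd$dropped$variant_id == "p1"],
               "palindromic, ambiguous frequency")
  expect_setequal(hd$dropped$reason[hd$dropped$variant_id %in% c("p2", "p3")],
                  "palindromic")

  # variant absent from the outcome
  out_missing <- make_sumstats("rs1", "A", "G", 0.05, 0.02, eaf = 0.3)
  hm <- harmonize(exposure, out_missing)
  expect_true(all(hm$dropped$reason[hm$dropped$variant_id != "rs1"] ==
                    "absent from outcome"))

  expect_error(harmonize(exposure, make_sumstats("zz9", "A", "G", 0.1, 0.1)),
               "no overlapping instruments")
})

test_that("harmonisation is idempotent and equivariant to outcome allele flips", {
  set.seed(11)
  n <- 30
  eas <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  oas <- vapply(eas, function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1),
                character(1))
  exposure <- make_sumstats(paste0("rs", 1:n), eas, oas,
                            beta = rnorm(n, 0.05, 0.01), se = 0.01,
                            eaf = runif(n, 0.05, 0.45))
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  outcome <- make_sumstats(paste0("rs", 1:n),
                           ifelse(swap, oas, eas), ifelse(swap, eas, oas),
                           beta = ifelse(swap, -1, 1) * rnorm(n, 0.02, 0.01),
                           se = 0.02,
                           eaf = ifelse(swap, 1 - exposure$data$eaf,
                                        exposure$data$eaf))

  h1 <- harmonize(exposure, outcome)
  # re-harmonising the already-aligned output must change nothing
  out2 <- make_sumstats(h1$data$variant_id,
                        exposure$data$effect_allele[match(h1$data$variant_id,
                                                          exposure$data$variant_id)],
                        exposure$data$other_allele[match(h1$data$variant_id,
                                                         exposure$data$variant_id)],
                        beta = h1$data$by, se = h1$data$sy,
                        eaf = h1$data$eaf)
  h2 <- harmonize(exposure, out2)
  expect_equal(h2$data$by, h1$data$by)
  expect_equal(h2$data$variant_id, h1$data$variant_id)

  # flipping every outcome allele pair negates by, retention set unchanged
  flipped <- make_sumstats(outcome$data$variant_id,
                           outcome$data$other_allele,
                           outcome$data$effect_allele,
                           beta = -outcome$data$beta, se = outcome$data$se,
                           eaf = 1 - outcome$data$eaf)
  h3 <- harmonize(exposure, flipped)
  expect_equal(h3$data$variant_id, h1$data$variant_id)
  expect_equal(h3$data$by, h1$data$by)
})

test_that("fixed-effect IVW meta-analysis matches the WLS oracle", {
  one <- make_sumstats("rs1", "A", "G", 0.1, 0.1)
  expect_identical(meta_analyze_fixed_ivw(list(one)), one)

  two_a <- make_sumstats("rs1", "A", "G", 0.1, 0.1)
  two_b <- make_sumstats("rs1", "A", "G", 0.3, 0.1)
  pooled <- meta_analyze_fixed_ivw(list(two_a, two_b))
  expect_equal(pooled$data$beta, 0.2)
  expect_equal(pooled$data$se, 0.1 / sqrt(2))

  # 3 studies, unequal SEs: oracle = WLS fit of a constant
  betas <- c(0.12, 0.20, 0.05); ses <- c(0.02, 0.05, 0.08)
  tabs <- lapply(seq_along(betas), function(i)
    make_sumstats("rs1", "A", "G", betas[i], ses[i]))
  pooled3 <- meta_analyze_fixed_ivw(tabs)
  oracle <- lm(betas ~ 1, weights = 1 / ses^2)
  expect_equal(pooled3$data$beta, unname(coef(oracle)[1]))
  expect_equal(pooled3$data$se, 1 / sqrt(sum(1 / ses^2)))
  # pooled SE never larger than the smallest input SE
  expect_lte(pooled3$data$se, min(ses))

  # pooling K identical studies divides the SE by sqrt(K)
  k <- 4L
  same <- replicate(k, make_sumstats("rs1", "A", "G", 0.1, 0.06),
                    simplify = FALSE)
  pk <- meta_analyze_fixed_ivw(same)
  expect_equal(pk$data$se, 0.06 / sqrt(k))
  expect_equal(pk$data$beta, 0.1)

  # single-source variants are carried through and flagged
  extra <- make_sumstats(c("rs1", "rs9"), "A", "G", c(0.1, 0.5), 0.1)
  pmix <- meta_analyze_fixed_ivw(list(two_a, extra))
  expect_equal(pmix$data$n_studies[pmix$data$variant_id == "rs9"], 1)
  expect_equal(pmix$data$beta[pmix$data$variant_id == "rs9"], 0.5)

  # swapped alleles in the second study are re-aligned before pooling
  swapped <- make_sumstats("rs1", "G", "A", -0.3, 0.1)
  pswap <- meta_analyze_fixed_ivw(list(two_a, swapped))
  expect_equal(pswap$data$beta, 0.2)
})

test_that("instrument F-statistic is the mean squared effect-to-SE ratio", {
  expect_equal(instrument_f(0.1, 0.05)$f_statistic, 4.0)
  expect_equal(instrument_f(c(0.2, 0.4), c(0.1, 0.1))$f_statistic, 10.0)
  expect_error(instrument_f(numeric(0), numeric(0)), "at least one")

  # simulation: per-SNP z = true_z + N(0,1) noise, so E[F] = mean(true_z^2) + 1
  set.seed(4)
  true_z <- rnorm(100, 6, 1)
  reps <- replicate(300, {
    z <- true_z + rnorm(100)
    instrument_f(z, rep(1, 100))$f_statistic
  })
  expect_equal(mean(reps), mean(true_z^2) + 1, tolerance = 0.02)
})
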