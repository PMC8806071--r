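# Shared fixture builders: quick summary-statistics tables and harmonised
# sets constructed in code.

make_sumstats <- function(variant_id, ea, oa, beta, se,
                          eaf = NA_real_, n = NA_real_,
                          label = "trait", type = "continuous") {
  sumstats(data.frame(variant_id = variant_id, effect_allele = ea,
                      other_allele = oa, eaf = eaf, beta = beta, se = se,
                      pvalue = 2 * pnorm(-abs(beta / se)), n = n,
                      stringsAsFactors = FALSE),
           trait_label = label, trait_type = type)
}

# harmonised-set data.frame straight from vectors (bypasses allele logic)
make_hset <- function(bx, sx, by, sy, eaf = NA_real_) {
  structure(list(exposure_label = "x", outcome_label = "y",
                 data = data.frame(variant_id = paste0("rs", seq_along(bx)),
                                   bx = bx, sx = sx, by = by, sy = sy,
                                   eaf = eaf),
                 dropped = data.frame(variant_id = character(0),
                                      reason = character(0))),
            class = "harmonized_set")
}

# summary-level two-sample instrument draw: true slope theta, optional
# per-SNP direct (pleiotropic) effects on the outcome
draw_instruments <- function(n_snps, theta, bx_mean = 0.05, bx_sd = 0.01,
                             sx = 0.005, sy = 0.01, pleio = 0) {
  bx_true <- abs(rnorm(n_snps, bx_mean, bx_sd))
  bx <- rnorm(n_snps, bx_true, sx)
  by <- rnorm(n_snps, theta * bx_true + pleio, sy)
  make_hset(bx, rep(sx, n_snps), by, rep(sy, n_snps))
}
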