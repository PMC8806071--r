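# GWAS summary statistics: reading, validation, allele harmonisation,
# fixed-effect meta-analysis, and instrument-strength diagnostics.

CANONICAL_COLS <- c("variant_id", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pvalue", "n")

#' Column mapping for summary-statistics files
#'
#' Maps the canonical column names used throughout the package onto the
#' (arbitrary) header names of a delimited summary-statistics file.
#'
#' @param variant_id,effect_allele,other_allele,eaf,beta,se,pvalue,n Column
#'   names in the file holding each canonical field. `eaf`, `pvalue` and `n`
#'   may be `NA` if absent from the file.
#' @return Named character vector, canonical name -> file column name.
#' @export
sumstats_dialect <- function(variant_id = "variant_id",
                             effect_allele = "effect_allele",
                             other_allele = "other_allele",
                             eaf = "eaf", beta = "beta", se = "se",
                             pvalue = "pvalue", n = "n") {
  c(variant_id = variant_id, effect_allele = effect_allele,
    other_allele = other_allele, eaf = eaf, beta = beta, se = se,
    pvalue = pvalue, n = n)
}

#' Construct a validated summary-statistics table
#'
#' Validates per-variant association records against the field invariants
#' (positive SE, frequencies and p-values in \[0, 1\], non-identical
#' single-nucleotide alleles, unique variant identifiers). Rows failing a
#' check are collected with a reason, never silently dropped.
#'
#' @param data data.frame with (a superset of) the canonical columns
#'   `variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`. Missing `eaf`/`pvalue`/`n` columns are filled with `NA`.
#' @param trait_label Trait name.
#' @param trait_type `"continuous"` (beta in SD units) or `"binary"`
#'   (beta = log odds ratio).
#' @param provenance Free-text source tag.
#' @return Object of class `sumstats`: list with `trait_label`, `trait_type`,
#'   `data` (validated records), `rejects` (data.frame of `variant_id`,
#'   `reason`), `provenance`.
#' @export
sumstats <- function(data, trait_label, trait_type = c("continuous", "binary"),
                     provenance = "") {
  trait_type <- match.arg(trait_type)
  for (col in c("variant_id", "effect_allele", "other_allele", "beta", "se")) {
    if (!col %in% names(data))
      stop(sprintf("mandatory column '%s' missing", col), call. = FALSE)
  }
  for (col in c("eaf", "pvalue", "n")) if (!col %in% names(data)) data[[col]] <- NA_real_
  data <- data[CANONICAL_COLS]
  data$variant_id <- as.character(data$variant_id)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n"))
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))

  reason <- rep(NA_character_, nrow(data))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(is.na(data$beta), "unparseable or missing beta")
  flag(is.na(data$se), "unparseable or missing SE")
  flag(!is.na(data$se) & data$se <= 0, "nonpositive SE")
  flag(!data$effect_allele %in% c("A", "C", "G", "T") |
         !data$other_allele %in% c("A", "C", "G", "T"),
       "allele not a single nucleotide")
  flag(data$effect_allele == data$other_allele, "identical alleles")
  flag(!is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1), "eaf outside [0,1]")
  flag(!is.na(data$pvalue) & (data$pvalue < 0 | data$pvalue > 1),
       "pvalue outside [0,1]")
  flag(duplicated(data$variant_id), "duplicate variant_id")

  bad <- !is.na(reason)
  rejects <- data.frame(variant_id = data$variant_id[bad],
                        reason = reason[bad], stringsAsFactors = FALSE)
  structure(list(trait_label = trait_label, trait_type = trait_type,
                 data = data[!bad, , drop = FALSE],
                 rejects = rejects, provenance = provenance),
            class = "sumstats")
}

#' Read GWAS summary statistics from a delimited text file
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @param trait_label,trait_type,provenance Passed to [sumstats()].
#' @param sep Field separator (tab by default).
#' @return A validated [sumstats] object.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          trait_label = basename(path),
                          trait_type = c("continuous", "binary"),
                          provenance = path, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(dialect)) {
    src <- dialect[[canon]]
    if (is.na(src) || !nzchar(src)) next
    if (!src %in% names(raw)) {
      if (canon %in% c("eaf", "pvalue", "n")) next
      stop(sprintf("column '%s' (mapped to '%s') not found in %s",
                   src, canon, path), call. = FALSE)
    }
    out[[canon]] <- raw[[src]]
  }
  sumstats(out, trait_label = trait_label, trait_type = trait_type,
           provenance = provenance)
}

#' Write summary statistics in the canonical TSV dialect
#'
#' Writes the validated records as tab-delimited text and, when any rows
#' were rejected at validation, a JSON sidecar (`<path>.rejects.json`)
#' listing the dropped variants and reasons.
#'
#' @param x A [sumstats] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  utils::write.table(x$data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(x$rejects) > 0)
    jsonlite::write_json(x$rejects, paste0(path, ".rejects.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s trait)\n", x$trait_label,
              x$trait_type))
  cat(sprintf("  %d variants retained, %d rejected\n",
              nrow(x$data), nrow(x$rejects)))
  invisible(x)
}

# Classify how the outcome alleles relate to the exposure alleles.
# Returns one of "match", "swap", "flip", "flip_swap", "mismatch".
#' @keywords internal
#' @noRd
allele_configuration <- function(ea_x, oa_x, ea_y, oa_y) {
  if (ea_x == ea_y && oa_x == oa_y) return("match")
  if (ea_x == oa_y && oa_x == ea_y) return("swap")
  cea <- complement_allele(ea_y); coa <- complement_allele(oa_y)
  if (ea_x == cea && oa_x == coa) return("flip")
  if (ea_x == coa && oa_x == cea) return("flip_swap")
  "mismatch"
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns per-variant outcome effects to the exposure's effect allele.
#' Directly matching alleles are kept as-is; swapped effect/other alleles
#' negate the outcome beta and complement its frequency; strand flips
#' (complementary alleles) are resolved before comparison. Palindromic
#' (A/T, C/G) variants cannot be strand-resolved from alleles alone:
#' under the default `"infer-by-eaf"` policy they are aligned using the
#' effect-allele frequency when it is informative, and dropped as ambiguous
#' when `min(eaf, 1 - eaf)` is within `eaf_window` of 0.5 or when either
#' frequency is missing; under `"drop"` all palindromic variants are dropped.
#'
#' @param exposure,outcome [sumstats] objects; the exposure records define
#'   the instrument set.
#' @param palindrome_policy `"infer-by-eaf"` (default) or `"drop"`.
#' @param eaf_window Half-width of the ambiguous frequency band around 0.5.
#' @return Object of class `harmonized_set`: `exposure_label`,
#'   `outcome_label`, `data` (per-SNP `variant_id`, `bx`, `sx`, `by`, `sy`,
#'   `eaf`), and `dropped` (data.frame of `variant_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer-by-eaf", "drop"),
                      eaf_window = 0.08) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  palindrome_policy <- match.arg(palindrome_policy)
  ex <- exposure$data
  oy <- outcome$data
  idx <- match(ex$variant_id, oy$variant_id)

  keep <- logical(nrow(ex))
  by <- sy <- numeric(nrow(ex))
  reason <- rep(NA_character_, nrow(ex))

  for (i in seq_len(nrow(ex))) {
    j <- idx[i]
    if (is.na(j)) { reason[i] <- "absent from outcome"; next }
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- oy$effect_allele[j]; oa_y <- oy$other_allele[j]
    b <- oy$beta[j]; s <- oy$se[j]

    if (is_palindromic(ea_x, oa_x)) {
      eaf_x <- ex$eaf[i]; eaf_y <- oy$eaf[j]
      if (is.na(eaf_x) || is.na(eaf_y)) {
        reason[i] <- "palindromic, missing eaf"; next
      }
      ambiguous <- abs(min(eaf_x, 1 - eaf_x) - 0.5) <= eaf_window ||
        abs(min(eaf_y, 1 - eaf_y) - 0.5) <= eaf_window
      if (ambiguous) { reason[i] <- "palindromic, ambiguous frequency"; next }
      if (palindrome_policy == "drop") { reason[i] <- "palindromic"; next }
      # For a palindromic SNP the allele labels cannot distinguish strand;
      # align by frequency: same side of 0.5 means same allele.
      same_side <- (eaf_x < 0.5) == (eaf_y < 0.5)
      if (!same_side) b <- -b
      keep[i] <- TRUE; by[i] <- b; sy[i] <- s
      next
    }

    cfg <- allele_configuration(ea_x, oa_x, ea_y, oa_y)
    if (cfg == "mismatch") { reason[i] <- "allele mismatch"; next }
    if (cfg %in% c("swap", "flip_swap")) b <- -b
    keep[i] <- TRUE; by[i] <- b; sy[i] <- s
  }

  if (!any(keep)) stop("no overlapping instruments after harmonisation",
                       call. = FALSE)
  dat <- data.frame(variant_id = ex$variant_id[keep],
                    bx = ex$beta[keep], sx = ex$se[keep],
                    by = by[keep], sy = sy[keep],
                    eaf = ex$eaf[keep], stringsAsFactors = FALSE)
  dropped <- data.frame(variant_id = ex$variant_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  structure(list(exposure_label = exposure$trait_label,
                 outcome_label = outcome$trait_label,
                 data = dat, dropped = dropped,
                 eaf_window = eaf_window,
                 palindrome_policy = palindrome_policy),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonised instrument set: %s -> %s\n", x$exposure_label,
              x$outcome_label))
  cat(sprintf("  %d SNPs retained, %d dropped\n", nrow(x$data),
              nrow(x$dropped)))
  invisible(x)
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Pools per-variant effects across studies with weights `1/se^2`:
#' pooled beta = sum(beta_i/se_i^2)/sum(1/se_i^2), pooled
#' se = 1/sqrt(sum(1/se_i^2)), p from a two-sided normal test. Input tables
#' must already be expressed for a common effect allele (tables whose
#' alleles are swapped relative to the first table are re-aligned; genuine
#' allele mismatches are dropped). Variants present in only one table are
#' carried through and flagged in the `n_studies` column.
#'
#' @param tables List of [sumstats] objects for the same trait.
#' @return A [sumstats] object with pooled records; `n_studies` records how
#'   many studies contributed to each variant.
#' @export
meta_analyze_fixed_ivw <- function(tables) {
  stopifnot(length(tables) >= 1, all(vapply(tables, inherits, TRUE, "sumstats")))
  if (length(tables) == 1L) return(tables[[1L]])

  ref <- tables[[1L]]$data
  ids <- unique(unlist(lapply(tables, function(t) t$data$variant_id)))
  # reference allele pair per variant: first table it appears in
  ea <- oa <- setNames(rep(NA_character_, length(ids)), ids)
  eaf <- setNames(rep(NA_real_, length(ids)), ids)
  w_sum <- bw_sum <- n_sum <- k <- setNames(numeric(length(ids)), ids)

  for (tab in tables) {
    d <- tab$data
    for (i in seq_len(nrow(d))) {
      id <- d$variant_id[i]
      b <- d$beta[i]
      if (is.na(ea[id])) {
        ea[id] <- d$effect_allele[i]; oa[id] <- d$other_allele[i]
        eaf[id] <- d$eaf[i]
      } else {
        cfg <- allele_configuration(ea[id], oa[id],
                                    d$effect_allele[i], d$other_allele[i])
        if (cfg == "mismatch") next
        if (cfg %in% c("swap", "flip_swap")) b <- -b
      }
      w <- 1 / d$se[i]^2
      w_sum[id] <- w_sum[id] + w
      bw_sum[id] <- bw_sum[id] + w * b
      n_sum[id] <- n_sum[id] + if (is.na(d$n[i])) 0 else d$n[i]
      k[id] <- k[id] + 1
    }
  }

  beta <- bw_sum / w_sum
  se <- 1 / sqrt(w_sum)
  out <- data.frame(variant_id = ids, effect_allele = unname(ea[ids]),
                    other_allele = unname(oa[ids]), eaf = unname(eaf[ids]),
                    beta = unname(beta[ids]), se = unname(se[ids]),
                    pvalue = beta_to_p(unname(beta[ids]), unname(se[ids])),
                    n = unname(n_sum[ids]), stringsAsFactors = FALSE)
  res <- sumstats(out, trait_label = tables[[1L]]$trait_label,
                  trait_type = tables[[1L]]$trait_type,
                  provenance = paste0("fixed-effect IVW meta-analysis of ",
                                      length(tables), " studies"))
  res$data$n_studies <- unname(k[res$data$variant_id])
  res
}

#' Subset a summary-statistics table to selected variants
#'
#' @param x A [sumstats] object.
#' @param variant_ids Variant identifiers to keep.
#' @return A [sumstats] object restricted to the requested variants.
#' @export
subset_sumstats <- function(x, variant_ids) {
  stopifnot(inherits(x, "sumstats"))
  x$data <- x$data[x$data$variant_id %in% variant_ids, , drop = FALSE]
  x
}

#' Select genome-wide significant instruments
#'
#' Restricts a summary-statistics table to variants whose association
#' p-value (recomputed from beta/se by a two-sided normal test) passes the
#' significance threshold. The default threshold of 5e-9 is the stricter
#' genome-wide level appropriate for densely imputed GWAS. LD clumping is
#' assumed to have been done upstream (instruments pre-pruned).
#'
#' @param x A [sumstats] object.
#' @param p_threshold Significance threshold.
#' @return A [sumstats] object containing the instruments.
#' @export
select_instruments <- function(x, p_threshold = 5e-9) {
  stopifnot(inherits(x, "sumstats"))
  p <- beta_to_p(x$data$beta, x$data$se)
  x$data <- x$data[p < p_threshold, , drop = FALSE]
  x
}

#' Instrument strength diagnostics
#'
#' The instrument F-statistic is the mean of squared per-SNP effect-to-SE
#' ratios, `mean((beta/se)^2)`; values below ~10 indicate weak instruments.
#' When effect-allele frequencies are supplied, the variance explained is
#' approximated as `sum(2*eaf*(1-eaf)*beta^2)` (exposure in SD units).
#'
#' @param beta,se Numeric vectors of per-SNP instrument effects and SEs, or
#'   `beta` may be a [sumstats] object (then `se`/`eaf` are taken from it).
#' @param eaf Optional effect-allele frequencies.
#' @return List with `n_snps`, `f_statistic`, `variance_explained`
#'   (`NA` without frequencies).
#' @export
instrument_f <- function(beta, se = NULL, eaf = NULL) {
  if (inherits(beta, "sumstats")) {
    se <- beta$data$se; eaf <- beta$data$eaf; beta <- beta$data$beta
  }
  if (length(beta) < 1L) stop("at least one SNP required", call. = FALSE)
  stopifnot(length(beta) == length(se), all(se > 0))
  r2 <- if (!is.null(eaf) && !all(is.na(eaf)))
    sum(2 * eaf * (1 - eaf) * beta^2, na.rm = TRUE) else NA_real_
  list(n_snps = length(beta),
       f_statistic = mean((beta / se)^2),
       variance_explained = r2)
}
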