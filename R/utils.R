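# Shared internal helpers.

#' @keywords internal
#' @noRd
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

#' @keywords internal
#' @noRd
beta_to_p <- function(beta, se) z_to_p(beta / se)

# Watson-Crick complement of single-nucleotide alleles.
#' @keywords internal
#' @noRd
complement_allele <- function(a) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[a])
}

#' @keywords internal
#' @noRd
is_palindromic <- function(a1, a2) complement_allele(a1) == a2

#' @keywords internal
#' @noRd
stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# 95% normal-theory bounds on the log scale, returned on the OR scale.
#' @keywords internal
#' @noRd
or_ci <- function(beta, se, level_z = 1.96) {
  c(exp(beta - level_z * se), exp(beta + level_z * se))
}
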