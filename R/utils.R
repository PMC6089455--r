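# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic stream splitting: every stochastic operation derives its own
# 31-bit seed from the user seed plus an operation label, so that e.g. the
# genotype draw and the phenotype draw of one scenario never share a stream.
.sub_seed <- function(seed, label) {
  ints <- utf8ToInt(label)
  h <- sum(ints * seq_along(ints))
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 16807) %% 2147483647)
}

.ALLELES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(ea, oa) unname(.COMP[ea] == oa)

.check_alleles <- function(ea, oa, where = "summary statistics") {
  bad <- !(ea %in% .ALLELES) | !(oa %in% .ALLELES) | ea == oa
  if (any(bad)) {
    stop(sprintf("invalid allele coding in %s for %d record(s)", where, sum(bad)))
  }
  invisible(TRUE)
}

# Normal-theory 95% bounds used throughout (the conventional two-sided 5%
# critical value, kept at this printed precision so CI arithmetic is exact).
.Z95 <- 1.959964

#' Recover a standard error from a reported 95% confidence interval
#'
#' Many published association results are reported as an estimate with a 95%
#' confidence interval rather than a standard error. Under normal sampling
#' theory the standard error is the CI width divided by twice the 5%
#' two-sided critical value.
#'
#' @param lower,upper Numeric vectors of CI bounds (lower < upper).
#' @return Numeric vector of standard errors, `(upper - lower) / 3.919928`.
#' @examples
#' ci_to_se(-0.13, -0.02)
#' @export
ci_to_se <- function(lower, upper) {
  if (any(upper <= lower)) stop("upper CI bound must exceed lower bound")
  (upper - lower) / (2 * .Z95)
}

.required_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}
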