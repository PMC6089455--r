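# Pairwise LD tables and greedy p-value-ordered LD clumping.

#' Construct a pairwise LD table
#'
#' Unordered SNP-pair records with squared correlation `r2`; lookups are
#' symmetric and `r2(snp, snp) = 1` is implied.
#'
#' @param df `data.frame` with columns `snp_a`, `snp_b`, `r2`.
#' @return The table with class `ld_table` prepended.
#' @export
ld_table <- function(df) {
  .required_cols(df, c("snp_a", "snp_b", "r2"), "LD table")
  if (any(!is.finite(df$r2)) || any(df$r2 < 0) || any(df$r2 > 1)) {
    stop("r2 must be finite and inside [0, 1]")
  }
  out <- as.data.frame(df)
  class(out) <- c("ld_table", "data.frame")
  out
}

#' Empirical LD table from a genotype panel
#'
#' Squared Pearson correlations between dosage columns, restricted to pairs
#' on the same chromosome within `window_kb`. Missing dosages are handled
#' pairwise.
#'
#' @param panel A [genotype_panel()].
#' @param window_kb Maximum |bp distance| in kb for a pair to be recorded.
#' @return An [ld_table()].
#' @export
ld_from_panel <- function(panel, window_kb = Inf) {
  stopifnot(inherits(panel, "genotype_panel"))
  cc <- suppressWarnings(stats::cor(panel$dosage, use = "pairwise.complete.obs"))
  m <- ncol(cc)
  pairs <- which(upper.tri(cc), arr.ind = TRUE)
  meta <- panel$snps
  keep <- meta$chr[pairs[, 1]] == meta$chr[pairs[, 2]] &
    abs(meta$bp[pairs[, 1]] - meta$bp[pairs[, 2]]) <= window_kb * 1000
  pairs <- pairs[keep, , drop = FALSE]
  r2 <- cc[pairs]^2
  r2[is.na(r2)] <- 0 # constant column: treat as unlinked
  ld_table(data.frame(snp_a = meta$snp[pairs[, 1]],
                      snp_b = meta$snp[pairs[, 2]],
                      r2 = r2, stringsAsFactors = FALSE))
}

# Symmetric vectorized lookup; absent pairs give NA.
.ld_lookup <- function(ld, a, b) {
  key <- paste(ld$snp_a, ld$snp_b, sep = "\r")
  rkey <- paste(ld$snp_b, ld$snp_a, sep = "\r")
  q <- paste(a, b, sep = "\r")
  hit <- match(q, key)
  miss <- is.na(hit)
  hit[miss] <- match(q[miss], rkey)
  out <- ld$r2[hit]
  out[a == b] <- 1
  out
}

#' Greedy LD clumping of summary statistics
#'
#' After filtering to `p <= p_max`, repeatedly takes the remaining SNP with
#' the lowest p-value as an index SNP and removes every remaining SNP on the
#' same chromosome within `window_kb` kb (closed interval on |bp distance|)
#' whose `r2` with the index is `>= r2_max`. Ties on p are broken by
#' ascending `(chr, bp)`. Pairs inside the window that are absent from the
#' LD table count as `r2 = 0` with a warning (or an error when
#' `strict = TRUE`).
#'
#' @param stats Summary-statistic `data.frame` (needs `snp`, `chr`, `bp`, `p`).
#' @param ld An [ld_table()].
#' @param r2_max LD threshold; neighbours at or above it are removed.
#' @param window_kb Window half-width in kb.
#' @param p_max Largest p-value eligible for clumping.
#' @param strict Error (rather than warn) on missing LD pairs in-window.
#' @return The index-SNP rows of `stats`, ordered by ascending p.
#' @export
clump <- function(stats, ld, r2_max = 0.1, window_kb = 250, p_max = 1,
                  strict = FALSE) {
  .required_cols(stats, c("snp", "chr", "bp", "p"), "summary statistics")
  stopifnot(inherits(ld, "ld_table"))
  f <- stats[!is.na(stats$p) & stats$p <= p_max, , drop = FALSE]
  if (!nrow(f)) return(f)
  f <- f[order(f$p, f$chr, f$bp), , drop = FALSE]
  keep <- character(0)
  warned <- FALSE
  while (nrow(f)) {
    idx <- f[1, ]
    keep <- c(keep, idx$snp)
    f <- f[-1, , drop = FALSE]
    if (!nrow(f)) break
    inwin <- f$chr == idx$chr & abs(f$bp - idx$bp) <= window_kb * 1000
    if (any(inwin)) {
      r2 <- .ld_lookup(ld, rep(idx$snp, sum(inwin)), f$snp[inwin])
      if (anyNA(r2)) {
        if (strict) {
          stop(sprintf("LD pair(s) missing for index SNP %s", idx$snp))
        }
        if (!warned) {
          warning("in-window SNP pair(s) absent from LD table treated as r2 = 0")
          warned <- TRUE
        }
        r2[is.na(r2)] <- 0
      }
      drop <- inwin
      drop[inwin] <- r2 >= r2_max
      f <- f[!drop, , drop = FALSE]
    }
  }
  out <- stats[match(keep, stats$snp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
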