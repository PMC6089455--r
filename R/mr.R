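# Two-sample Mendelian randomization on harmonized summary statistics:
# Wald ratios, inverse-variance weighting with heterogeneity, MR-Egger,
# weighted median, weighted mode, leave-one-out and Steiger directionality.
#
# First-order weights are used throughout (the ratio variance ignores the
# exposure-side standard error), matching the convention of the standard
# two-sample MR toolkits; the exposure se still feeds the parametric
# bootstrap of the median and mode estimators.

#' Harmonize exposure and outcome summary statistics into an MR dataset
#'
#' Matches SNPs by id; when an exposure SNP is absent from the outcome and an
#' LD table is supplied, the best available proxy (largest `r2 >
#' proxy_r2_min`, ties broken by lowest bp) present in the outcome is
#' substituted and recorded. Outcome effects are aligned to the exposure
#' effect allele (sign flip on allele swap, strand complementing where
#' needed). Palindromic SNPs (A/T, C/G) are resolved by allele frequency:
#' kept when both EAFs are outside the ambiguity zone, with a sign flip when
#' they fall on opposite sides of 0.5, and dropped otherwise. Unresolvable
#' allele pairs are dropped. Dropped SNPs are reported in the `dropped`
#' attribute.
#'
#' @param exposure,outcome Summary-statistic `data.frame`s (`snp`, `ea`,
#'   `oa`, `beta`, `se`, optionally `eaf`, `n`, `bp`).
#' @param ld Optional [ld_table()] for proxy lookup.
#' @param proxy_r2_min Minimum r2 for a proxy substitution.
#' @param ambiguous_eaf Length-2 open interval of EAFs within which a
#'   palindromic SNP is considered unresolvable.
#' @return A `data.frame` of class `mr_dataset`: `snp`, `bx`, `se_bx`, `by`,
#'   `se_by`, `ea`, `oa`, `eaf`, `n_x`, `n_y`, `proxy`, `proxy_r2`.
#' @export
harmonize <- function(exposure, outcome, ld = NULL, proxy_r2_min = 0.9,
                      ambiguous_eaf = c(0.42, 0.58)) {
  .required_cols(exposure, c("snp", "ea", "oa", "beta", "se"), "exposure stats")
  .required_cols(outcome, c("snp", "ea", "oa", "beta", "se"), "outcome stats")
  if (!nrow(exposure)) stop("need at least one exposure SNP")
  getcol <- function(df, col) if (col %in% names(df)) df[[col]] else NA_real_

  rows <- list(); dropped <- character(0)
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    j <- match(ex$snp, outcome$snp)
    proxy <- NA_character_; proxy_r2 <- NA_real_
    if (is.na(j) && !is.null(ld)) {
      cand <- ld[(ld$snp_a == ex$snp | ld$snp_b == ex$snp) &
                   ld$r2 > proxy_r2_min, , drop = FALSE]
      if (nrow(cand)) {
        cand$other <- ifelse(cand$snp_a == ex$snp, cand$snp_b, cand$snp_a)
        cand <- cand[cand$other %in% outcome$snp, , drop = FALSE]
        if (nrow(cand)) {
          obp <- getcol(outcome, "bp")[match(cand$other, outcome$snp)]
          cand <- cand[order(-cand$r2, obp), , drop = FALSE]
          proxy <- cand$other[1]
          proxy_r2 <- cand$r2[1]
          j <- match(proxy, outcome$snp)
        }
      }
    }
    if (is.na(j)) { dropped <- c(dropped, ex$snp); next }
    ou <- outcome[j, ]

    eaf_x <- getcol(exposure, "eaf")[i]
    eaf_y <- getcol(outcome, "eaf")[j]
    if (!is.na(proxy)) {
      # A proxy's alleles are not those of the index SNP; orient its effect
      # by allele frequency when possible, otherwise keep as reported.
      sign <- 1
      if (!is.na(eaf_x) && !is.na(eaf_y) &&
          (eaf_x < 0.5) != (eaf_y < 0.5)) sign <- -1
    } else {
      sign <- .allele_sign(ex$ea, ex$oa, ou$ea, ou$oa)
      if (is.na(sign)) { dropped <- c(dropped, ex$snp); next }
      if (.is_palindromic(ex$ea, ex$oa)) {
        eaf_y_aligned <- if (sign > 0) eaf_y else 1 - eaf_y
        inzone <- function(f) is.na(f) ||
          (f > ambiguous_eaf[1] && f < ambiguous_eaf[2])
        if (inzone(eaf_x) || inzone(eaf_y_aligned)) {
          dropped <- c(dropped, ex$snp); next
        }
        # Name alignment is meaningless across strands for palindromes: use
        # frequency agreement of the name-aligned orientation instead.
        if ((eaf_x < 0.5) != (eaf_y_aligned < 0.5)) sign <- -sign
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      snp = ex$snp, bx = ex$beta, se_bx = ex$se,
      by = sign * ou$beta, se_by = ou$se,
      ea = ex$ea, oa = ex$oa, eaf = eaf_x,
      n_x = getcol(exposure, "n")[i], n_y = getcol(outcome, "n")[j],
      proxy = proxy, proxy_r2 = proxy_r2,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no SNPs survived harmonization")
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$snp)) stop("duplicate SNPs in harmonized dataset")
  if (any(out$se_bx <= 0 | out$se_by <= 0, na.rm = TRUE)) {
    stop("standard errors must be positive")
  }
  attr(out, "dropped") <- dropped
  class(out) <- c("mr_dataset", "data.frame")
  out
}

.mr_result <- function(method, estimate, se, p, nsnp, ...) {
  ci <- c(estimate - .Z95 * se, estimate + .Z95 * se)
  structure(c(list(method = method, estimate = estimate, se = se,
                   ci_lower = ci[1], ci_upper = ci[2], p = p, nsnp = nsnp),
              list(...)),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: %.4f (95%% CI %.4f, %.4f), se %.4f, p = %.3g, nsnp = %d\n",
              x$method, x$estimate, x$ci_lower, x$ci_upper, x$se, x$p, x$nsnp))
  if (!is.null(x$q)) {
    cat(sprintf("  Q = %.3f (df %d), Q p = %.3g\n", x$q, x$q_df, x$q_p))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' Wald ratio for a single instrument
#'
#' `ratio = by / bx` with the first-order standard error `se_by / |bx|`.
#'
#' @param bx,se_bx Exposure effect and its se (`se_bx` unused first order).
#' @param by,se_by Outcome effect and its se.
#' @return `list(ratio, se)`.
#' @export
wald_ratio <- function(bx, se_bx, by, se_by) {
  if (bx == 0) stop("Wald ratio undefined for bx = 0")
  list(ratio = by / bx, se = se_by / abs(bx))
}

.as_mr_dataset <- function(data) {
  .required_cols(data, c("snp", "bx", "se_bx", "by", "se_by"), "MR dataset")
  data
}

#' Inverse-variance weighted MR estimate
#'
#' Weighted through-origin regression of outcome on exposure effects with
#' first-order weights `1 / se_by^2`:
#' `estimate = sum(bx by / se_by^2) / sum(bx^2 / se_by^2)`, fixed-effect
#' `se = sqrt(1 / sum(bx^2 / se_by^2))`, two-sided normal p. Cochran's
#' `Q = sum(((by - est * bx) / se_by)^2)` on `nsnp - 1` df measures
#' heterogeneity of the per-SNP ratios, and the multiplicative
#' random-effects se (`fixed se * max(1, sqrt(Q / (nsnp - 1)))`) is reported
#' alongside. A single SNP degrades to the Wald ratio with a note.
#'
#' @param data An [harmonize()]d dataset (or any data.frame with `snp`,
#'   `bx`, `se_bx`, `by`, `se_by`).
#' @param se_type `"fixed"` (default) or `"random"`: which se the headline
#'   estimate carries; both are always computed.
#' @return An `mr_result` with `q`, `q_df`, `q_p`, `se_fixed`, `se_random`.
#' @export
mr_ivw <- function(data, se_type = c("fixed", "random")) {
  data <- .as_mr_dataset(data)
  se_type <- match.arg(se_type)
  n <- nrow(data)
  if (all(data$bx == 0)) stop("IVW undefined: all exposure effects are zero")
  if (n == 1) {
    wr <- wald_ratio(data$bx, data$se_bx, data$by, data$se_by)
    return(.mr_result("ivw", wr$ratio, wr$se,
                      2 * stats::pnorm(-abs(wr$ratio / wr$se)), 1L,
                      q = 0, q_df = 0L, q_p = NA_real_,
                      se_fixed = wr$se, se_random = wr$se,
                      note = "single SNP: Wald ratio"))
  }
  w <- 1 / data$se_by^2
  est <- sum(w * data$bx * data$by) / sum(w * data$bx^2)
  se_fixed <- sqrt(1 / sum(w * data$bx^2))
  q <- sum(((data$by - est * data$bx) / data$se_by)^2)
  q_df <- n - 1L
  se_random <- se_fixed * max(1, sqrt(q / q_df))
  se <- if (se_type == "fixed") se_fixed else se_random
  .mr_result("ivw", est, se, 2 * stats::pnorm(-abs(est / se)), n,
             q = q, q_df = q_df,
             q_p = stats::pchisq(q, q_df, lower.tail = FALSE),
             se_fixed = se_fixed, se_random = se_random)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects *with* an
#' intercept, weights `1 / se_by^2`, after orienting every SNP so `bx >= 0`.
#' The slope is the pleiotropy-adjusted causal estimate and the intercept
#' estimates the average directional pleiotropic effect. Standard errors are
#' the WLS ones inflated by `max(1, sqrt(Q_residual / (n - 2)))`; p-values
#' are two-sided t on `n - 2` df.
#'
#' @param data An MR dataset with at least 3 SNPs.
#' @return An `mr_result` with `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(data) {
  data <- .as_mr_dataset(data)
  n <- nrow(data)
  if (n < 3) stop("MR-Egger needs at least 3 SNPs")
  flip <- data$bx < 0
  bx <- ifelse(flip, -data$bx, data$bx)
  by <- ifelse(flip, -data$by, data$by)
  if (stats::sd(bx) == 0) stop("zero spread in exposure effects: slope unidentified")
  w <- 1 / data$se_by^2
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swx2 - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swx2 * swy - swx * swxy) / det
  resid <- by - intercept - slope * bx
  q <- sum(w * resid^2)
  infl <- max(1, sqrt(q / (n - 2)))
  se_slope <- sqrt(sw / det) * infl
  se_int <- sqrt(swx2 / det) * infl
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), n - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), n - 2)
  .mr_result("mr_egger", slope, se_slope, p_slope, n,
             intercept = intercept, intercept_se = se_int, intercept_p = p_int,
             q = q, q_df = n - 2L,
             q_p = stats::pchisq(q, n - 2, lower.tail = FALSE))
}

# Weighted median of ratio estimates: order ratios, standardize cumulative
# weights s_j = (cumsum(w) - w/2) / sum(w), interpolate linearly at s = 0.5.
.weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(s)])
  j <- max(which(s < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

.boot_se <- function(data, estimator, n_boot, seed) {
  set.seed(.sub_seed(seed, "mr-bootstrap"))
  ests <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(nrow(data), data$bx, data$se_bx)
    by <- stats::rnorm(nrow(data), data$by, data$se_by)
    estimator(bx, by)
  }, numeric(1))
  stats::sd(ests)
}

#' Weighted median MR estimate
#'
#' Median of the per-SNP Wald ratios weighted by the inverse first-order
#' ratio variance (`w_j = bx_j^2 / se_by_j^2`), interpolated across the
#' standardized cumulative weights; consistent when at least half of the
#' total weight comes from valid instruments. The standard error is a
#' seeded parametric bootstrap (resampling both effect sides from their
#' reported normal sampling distributions) and the p-value uses the normal
#' approximation.
#'
#' @param data An MR dataset with at least 3 SNPs.
#' @param n_boot Bootstrap replicates (>= 1000 recommended).
#' @param seed Bootstrap seed.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = 1L) {
  data <- .as_mr_dataset(data)
  if (nrow(data) < 3) stop("weighted median needs at least 3 SNPs")
  est_fun <- function(bx, by) {
    ok <- bx != 0
    .weighted_median(by[ok] / bx[ok], bx[ok]^2 / data$se_by[ok]^2)
  }
  est <- est_fun(data$bx, data$by)
  se <- .boot_se(data, est_fun, n_boot, seed)
  .mr_result("weighted_median", est, se,
             2 * stats::pnorm(-abs(est / se)), nrow(data))
}

# Weighted Gaussian-kernel density over ratios, maximized on a dense grid.
.weighted_mode_point <- function(r, w, bandwidth_factor) {
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
  h <- bandwidth_factor * s
  if (!is.finite(h) || h <= 0) {
    # Degenerate spread: fall back to the weighted modal value itself.
    return(r[which.max(w)])
  }
  kde <- function(x) sum(w * stats::dnorm((x - r) / h))
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 2048)
  dens <- vapply(grid, kde, numeric(1))
  i <- which.max(dens)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  # refine the coarse global maximum to optimizer precision
  stats::optimize(kde, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

#' Weighted mode MR estimate
#'
#' Mode of the inverse-variance-weighted Gaussian kernel density over the
#' per-SNP Wald ratios; consistent when the largest cluster of instruments
#' is valid. The bandwidth is `bandwidth_factor` times the modified
#' Silverman rule `0.9 min(sd, mad) n^(-1/5)` on the ratios. Standard error
#' by seeded parametric bootstrap as in [mr_weighted_median()].
#'
#' @param data An MR dataset with at least 3 SNPs.
#' @param bandwidth_factor Multiplier on the default bandwidth.
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return An `mr_result`.
#' @export
mr_weighted_mode <- function(data, bandwidth_factor = 1, n_boot = 1000,
                             seed = 1L) {
  data <- .as_mr_dataset(data)
  if (nrow(data) < 3) stop("weighted mode needs at least 3 SNPs")
  est_fun <- function(bx, by) {
    ok <- bx != 0
    .weighted_mode_point(by[ok] / bx[ok], bx[ok]^2 / data$se_by[ok]^2,
                         bandwidth_factor)
  }
  est <- est_fun(data$bx, data$by)
  se <- .boot_se(data, est_fun, n_boot, seed)
  .mr_result("weighted_mode", est, se,
             2 * stats::pnorm(-abs(est / se)), nrow(data))
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate excluding each SNP in turn; a stable set of
#' estimates indicates no single instrument drives the result.
#'
#' @param data An MR dataset with at least 3 SNPs.
#' @return `data.frame(excluded, estimate, se, ci_lower, ci_upper, p)`.
#' @export
mr_leave_one_out <- function(data) {
  data <- .as_mr_dataset(data)
  if (nrow(data) < 3) stop("leave-one-out needs at least 3 SNPs")
  rows <- lapply(seq_len(nrow(data)), function(i) {
    r <- mr_ivw(data[-i, , drop = FALSE])
    data.frame(excluded = data$snp[i], estimate = r$estimate, se = r$se,
               ci_lower = r$ci_lower, ci_upper = r$ci_upper, p = r$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Steiger test of causal direction
#'
#' Compares the instrument variance explained on the exposure and outcome
#' sides through Fisher's z:
#' `z = (atanh(r_exp) - atanh(r_out)) / sqrt(1/(n_exp - 3) + 1/(n_out - 3))`
#' with `r = sqrt(r2)` per side. A positive z supports the
#' exposure-to-outcome direction.
#'
#' @param r2_exposure,r2_outcome Instrument variance explained, in `[0, 1)`.
#' @param n_exposure,n_outcome Sample sizes (> 3).
#' @return List of class `steiger_result`: `direction`
#'   (`"exposure->outcome"`, `"outcome->exposure"` or `"tied"`), `z`, `p`,
#'   and the inputs.
#' @export
steiger_direction <- function(r2_exposure, n_exposure, r2_outcome, n_outcome) {
  if (r2_exposure < 0 || r2_exposure >= 1 || r2_outcome < 0 || r2_outcome >= 1) {
    stop("r2 must be in [0, 1)")
  }
  if (n_exposure <= 3 || n_outcome <= 3) stop("n must exceed 3")
  r_exp <- sqrt(r2_exposure)
  r_out <- sqrt(r2_outcome)
  z <- (atanh(r_exp) - atanh(r_out)) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  direction <- if (r_exp > r_out) "exposure->outcome"
    else if (r_out > r_exp) "outcome->exposure" else "tied"
  structure(list(direction = direction, z = z, p = 2 * stats::pnorm(-abs(z)),
                 r2_exposure = r2_exposure, r2_outcome = r2_outcome,
                 n_exposure = n_exposure, n_outcome = n_outcome),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("Steiger: %s (z = %.3f, p = %.3g; r2 %.4g vs %.4g)\n",
              x$direction, x$z, x$p, x$r2_exposure, x$r2_outcome))
  invisible(x)
}

#' Instrument variance explained from summary statistics
#'
#' The z-statistic approximation `r2 ~ z^2 / (z^2 + n - 2)` per SNP, summed
#' over (approximately independent) instruments. For a binary trait analysed
#' on the observed scale this is an approximation and is flagged as such by
#' the callers that use it.
#'
#' @param beta,se Per-SNP effects and standard errors.
#' @param n Per-SNP (or scalar) sample size.
#' @return Total variance explained.
#' @export
instrument_r2 <- function(beta, se, n) {
  z2 <- (beta / se)^2
  sum(z2 / (z2 + n - 2))
}

#' Steiger directionality for a harmonized MR dataset
#'
#' Computes per-side instrument variance explained with [instrument_r2()]
#' and applies [steiger_direction()].
#'
#' @param data An [harmonize()]d dataset with `n_x` and `n_y` columns.
#' @param n_exposure,n_outcome Sample sizes; default to the dataset medians.
#' @return A `steiger_result`.
#' @export
mr_steiger <- function(data, n_exposure = stats::median(data$n_x),
                       n_outcome = stats::median(data$n_y)) {
  data <- .as_mr_dataset(data)
  r2x <- instrument_r2(data$bx, data$se_bx, n_exposure)
  r2y <- instrument_r2(data$by, data$se_by, n_outcome)
  steiger_direction(min(r2x, 0.999), n_exposure, min(r2y, 0.999), n_outcome)
}
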