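# Polygenic risk scores, the polygenic transmission disequilibrium test,
# p-value threshold selection, PRS-phenotype association and the
# minimum-detectable genetic-correlation power calculation.

#' Build score weights from discovery summary statistics
#'
#' @param stats Summary-statistic `data.frame` (typically already clumped).
#' @param p_source P-value inclusion threshold recorded as provenance.
#' @return `data.frame(snp, ea, weight, p_source)` with unique SNPs and
#'   finite weights.
#' @export
score_weights <- function(stats, p_source = NA_real_) {
  .required_cols(stats, c("snp", "ea", "beta"), "summary statistics")
  if (anyDuplicated(stats$snp)) stop("weight SNP ids must be unique")
  if (any(!is.finite(stats$beta))) stop("weights must be finite")
  data.frame(snp = stats$snp, ea = stats$ea,
             oa = if ("oa" %in% names(stats)) stats$oa else NA_character_,
             weight = stats$beta, p_source = p_source,
             stringsAsFactors = FALSE)
}

#' Compute polygenic risk scores
#'
#' `raw_i = sum_j w_j * dose_ij` with each dosage aligned to the weight's
#' effect allele (`2 - dose` when the panel's effect allele is the weight's
#' other allele, with strand complementing where needed). Weight SNPs absent
#' from the panel are dropped with a warning and counted; missing dosages are
#' imputed to `2 * eaf` (panel EAF, falling back to the observed mean
#' dosage). The standardized score has mean 0 and SD 1 over the scored
#' samples; a zero-variance raw score is flagged degenerate and the
#' standardized column is `NA`.
#'
#' @param panel A [genotype_panel()].
#' @param weights A [score_weights()] table.
#' @return `data.frame(sample, raw, std)` of class `prs_vector` with
#'   attributes `n_snps_used`, `dropped_snps`, `n_imputed` and `degenerate`.
#' @export
compute_prs <- function(panel, weights) {
  stopifnot(inherits(panel, "genotype_panel"))
  .required_cols(weights, c("snp", "ea", "weight"), "score weights")
  hit <- match(weights$snp, panel$snps$snp)
  dropped <- weights$snp[is.na(hit)]
  if (length(dropped) == nrow(weights)) {
    stop("no weight SNPs overlap the panel")
  }
  if (length(dropped)) {
    warning(sprintf("%d weight SNP(s) absent from panel and dropped",
                    length(dropped)))
  }
  w <- weights[!is.na(hit), , drop = FALSE]
  cols <- hit[!is.na(hit)]
  meta <- panel$snps[cols, , drop = FALSE]

  if (!is.null(w$oa) && !anyNA(w$oa)) {
    sign <- .allele_sign(w$ea, w$oa, meta$ea, meta$oa)
    if (anyNA(sign)) {
      stop(sprintf("panel/weight allele mismatch for: %s",
                   paste(w$snp[is.na(sign)], collapse = ", ")))
    }
  } else {
    # No other-allele column: align on the effect allele alone (match or its
    # strand complement = keep, otherwise flip).
    sign <- ifelse(meta$ea == w$ea | unname(.COMP[meta$ea]) == w$ea, 1, -1)
  }
  dos <- panel$dosage[, cols, drop = FALSE]
  n_imputed <- sum(is.na(dos))
  if (n_imputed) {
    for (j in which(colSums(is.na(dos)) > 0)) {
      fill <- 2 * meta$eaf[j]
      if (is.na(fill)) fill <- mean(dos[, j], na.rm = TRUE)
      dos[is.na(dos[, j]), j] <- fill
    }
  }
  # dose aligned to the weight's effect allele: dose if sign +1, 2 - dose if -1
  flip <- sign < 0
  if (any(flip)) {
    dos[, flip] <- 2 - dos[, flip, drop = FALSE]
  }
  raw <- as.numeric(dos %*% w$weight)
  sdr <- stats::sd(raw)
  degenerate <- !is.finite(sdr) || sdr == 0
  std <- if (degenerate) rep(NA_real_, length(raw)) else (raw - mean(raw)) / sdr
  out <- data.frame(sample = rownames(panel$dosage), raw = raw, std = std,
                    stringsAsFactors = FALSE)
  class(out) <- c("prs_vector", "data.frame")
  attr(out, "n_snps_used") <- nrow(w)
  attr(out, "dropped_snps") <- dropped
  attr(out, "n_imputed") <- n_imputed
  attr(out, "degenerate") <- degenerate
  out
}

#' Polygenic transmission disequilibrium test
#'
#' One-sample t-test for over-transmission of polygenic scores from parents
#' to affected offspring: with mid-parent score `mid_i = (father_i +
#' mother_i)/2`, the deviation `d_i = (child_i - mid_i) / sd(mid)` is tested
#' against zero (`t = mean(d) / (sd(d)/sqrt(n))`, df `n - 1`, two-sided).
#' The normalizing `sd(mid)` is the SD of mid-parent scores within the
#' analyzed trios.
#'
#' @param child,father,mother Numeric per-trio raw scores (complete trios).
#' @param threshold Optional p-value threshold annotation carried through.
#' @return A list of class `ptdt_result`: `n`, `mean_deviation`, `t`, `df`,
#'   `p`, `threshold`.
#' @export
ptdt_test <- function(child, father, mother, threshold = NA_real_) {
  if (length(child) != length(father) || length(child) != length(mother)) {
    stop("child/father/mother score vectors must have equal length")
  }
  keep <- stats::complete.cases(child, father, mother)
  child <- child[keep]; father <- father[keep]; mother <- mother[keep]
  n <- length(child)
  if (n < 2) stop("need at least 2 complete trios")
  mid <- (father + mother) / 2
  s_mid <- stats::sd(mid)
  if (!is.finite(s_mid) || s_mid == 0) {
    stop("degenerate mid-parent score variance")
  }
  d <- (child - mid) / s_mid
  if (all(d == 0)) { # exact mid-parent transmission: no deviation signal
    return(structure(list(n = n, mean_deviation = 0, t = 0, df = n - 1L,
                          p = 1, threshold = threshold),
                     class = "ptdt_result"))
  }
  sd_d <- stats::sd(d)
  if (!is.finite(sd_d) || sd_d == 0) stop("degenerate deviation variance")
  t <- mean(d) / (sd_d / sqrt(n))
  structure(list(n = n, mean_deviation = mean(d), t = t, df = n - 1L,
                 p = 2 * stats::pt(-abs(t), n - 1),
                 threshold = threshold),
            class = "ptdt_result")
}

#' @export
print.ptdt_result <- function(x, ...) {
  cat(sprintf("pTDT: n = %d, mean deviation = %.4f, t = %.3f (df %d), p = %.3g\n",
              x$n, x$mean_deviation, x$t, x$df, x$p))
  invisible(x)
}

#' Select the PRS p-value inclusion threshold by polygenic TDT
#'
#' For each candidate threshold the discovery statistics are clumped
#' (`r2 < r2_max` within `window_kb`), scores are built for children and
#' parents of affected-offspring trios, and the polygenic TDT measures
#' over-transmission. Trios with an affected parent (or a missing parent) are
#' excluded. The selected threshold maximizes the pTDT t statistic, i.e. the
#' strongest over-transmission signal; grid points admitting no SNPs are
#' reported as `NA` rows rather than failing.
#'
#' @param discovery Discovery summary statistics.
#' @param panel,trios Output of [simulate_trios()] or equivalent real data.
#' @param ld [ld_table()] used for clumping.
#' @param thresholds Candidate p-value grid.
#' @param r2_max,window_kb Clumping parameters.
#' @return List of class `threshold_selection`: `best_threshold`, `results`
#'   (one row per grid point: `threshold`, `n_snps`, `n_trios`,
#'   `mean_deviation`, `t`, `p`).
#' @export
select_threshold <- function(discovery, panel, trios, ld,
                             thresholds = c(5e-8, 1e-7, 1e-6, 1e-5, 1e-4,
                                            1e-3, 0.01, 0.05, 0.5, 1),
                             r2_max = 0.1, window_kb = 250) {
  stopifnot(length(thresholds) >= 1)
  use <- !is.na(trios$father) & !is.na(trios$mother) &
    !trios$father_affected & !trios$mother_affected
  tr <- trios[use, , drop = FALSE]
  if (nrow(tr) < 2) stop("fewer than 2 usable (complete, unaffected-parent) trios")

  rows <- lapply(thresholds, function(thr) {
    sel <- clump(discovery, ld, r2_max = r2_max, window_kb = window_kb,
                 p_max = thr)
    if (!nrow(sel)) {
      return(data.frame(threshold = thr, n_snps = 0L, n_trios = nrow(tr),
                        mean_deviation = NA_real_, t = NA_real_, p = NA_real_))
    }
    prs <- compute_prs(panel, score_weights(sel, p_source = thr))
    raw <- stats::setNames(prs$raw, prs$sample)
    res <- ptdt_test(raw[tr$child], raw[tr$father], raw[tr$mother],
                     threshold = thr)
    data.frame(threshold = thr, n_snps = nrow(sel), n_trios = res$n,
               mean_deviation = res$mean_deviation, t = res$t, p = res$p)
  })
  results <- do.call(rbind, rows)
  best <- if (all(is.na(results$t))) NA_real_ else
    results$threshold[which.max(results$t)]
  structure(list(best_threshold = best, results = results),
            class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  cat("pTDT threshold selection\n")
  print(x$results, row.names = FALSE)
  cat(sprintf("selected threshold: %g\n", x$best_threshold))
  invisible(x)
}

#' Association of a polygenic score with a quantitative phenotype
#'
#' OLS of the phenotype on the standardized PRS plus covariates; the PRS
#' coefficient is the effect in phenotype units (mm) per SD of the score,
#' with a Wald 95% CI and a two-sided t p-value.
#'
#' @param prs A [compute_prs()] result.
#' @param pheno A [pheno_table()].
#' @param covariates Covariate columns; defaults as in [run_quant_gwas()].
#' @return List of class `prs_assoc`: `beta`, `se`, `ci`, `p`, `n`.
#' @export
prs_assoc <- function(prs, pheno,
                      covariates = intersect(c("sex", "age", "height",
                                               paste0("pc", 1:4)),
                                             names(pheno))) {
  if (isTRUE(attr(prs, "degenerate"))) stop("degenerate (zero-variance) PRS")
  d <- merge(as.data.frame(prs), as.data.frame(pheno), by = "sample")
  cols <- c("phenotype", "std", covariates)
  d <- d[stats::complete.cases(d[, cols, drop = FALSE]), , drop = FALSE]
  if (nrow(d) < length(covariates) + 2) {
    stop("too few complete samples for the covariate-adjusted fit")
  }
  fml <- stats::reformulate(c("std", covariates), response = "phenotype")
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients["std", ]
  beta <- sm[["Estimate"]]; se <- sm[["Std. Error"]]
  structure(list(beta = beta, se = se,
                 ci = c(beta - .Z95 * se, beta + .Z95 * se),
                 p = sm[["Pr(>|t|)"]], n = nrow(d)),
            class = "prs_assoc")
}

#' @export
print.prs_assoc <- function(x, ...) {
  cat(sprintf("PRS association: beta = %.4f mm/SD (95%% CI %.4f, %.4f), p = %.3g, n = %d\n",
              x$beta, x$ci[1], x$ci[2], x$p, x$n))
  invisible(x)
}

# E[X^2 ; |X| > c] for X ~ N(0, v).
.trunc_second_moment <- function(v, c) {
  if (v <= 0) return(0)
  a <- c / sqrt(v)
  v * (2 * a * stats::dnorm(a) + 2 * stats::pnorm(a, lower.tail = FALSE))
}

#' Minimum detectable score-phenotype correlation and genetic correlation
#'
#' Stage 1 (closed form): the smallest correlation between a polygenic score
#' and a phenotype detectable at the given alpha and power in a target sample
#' of size `n`, from the Fisher-z normal approximation
#' `r_min = tanh((z_{1-alpha/2} + z_{power}) / sqrt(n - 3))`.
#'
#' Stage 2 (model based, optional): maps `r_min` to the minimum genetic
#' covariance between the score's discovery trait and the phenotype under a
#' polygenic-score power model with normally distributed standardized SNP
#' effects: a fraction `pi1` of the `m_snps` SNPs carries effects with
#' per-SNP variance `h2_exposure / (m_snps * pi1)`, discovery estimates add
#' sampling noise `1 / n_discovery`, and SNPs enter the score when their
#' discovery p-value passes `p_threshold`. Writing `E2(v, c)` for the second
#' moment of an `N(0, v)` variable truncated to `|x| > c`,
#' `corr(score, Y) = cov_g * sqrt(E2_nonnull) / ((tau2 + s2) * sqrt(m_eff))`,
#' which is inverted for the covariance; dividing by
#' `sqrt(h2_exposure * h2_outcome)` converts covariance to genetic
#' correlation. The binary-exposure variance explained is on the observed
#' scale throughout (no liability-scale transformation).
#'
#' @param n Target (scoring) sample size, > 3.
#' @param alpha Two-sided significance level.
#' @param power Desired power.
#' @param h2_exposure,h2_outcome Heritabilities in (0, 1]; stage 2 runs only
#'   when both, `n_discovery` and `m_snps` are supplied.
#' @param n_discovery Discovery GWAS sample size.
#' @param m_snps Number of (independent) score SNPs before selection.
#' @param p_threshold Discovery p-value inclusion threshold.
#' @param pi1 Fraction of SNPs with nonzero effects (1 = no null mixture).
#' @return List of class `power_calc`: `r_min`, and when stage 2 applies,
#'   `covariance_min` and `genetic_correlation_min`.
#' @examples
#' min_detectable_correlation(n = 3707)$r_min
#' @export
min_detectable_correlation <- function(n, alpha = 0.05, power = 0.8,
                                       h2_exposure = NULL, h2_outcome = NULL,
                                       n_discovery = NULL, m_snps = NULL,
                                       p_threshold = 1, pi1 = 1) {
  if (n <= 3) stop("n must exceed 3 for the Fisher-z approximation")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must be in (0, 1)")
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  r_min <- tanh(z / sqrt(n - 3))
  out <- list(r_min = r_min, covariance_min = NA_real_,
              genetic_correlation_min = NA_real_)
  if (!is.null(h2_exposure) && !is.null(h2_outcome) &&
      !is.null(n_discovery) && !is.null(m_snps)) {
    if (h2_exposure <= 0 || h2_exposure > 1 || h2_outcome <= 0 || h2_outcome > 1) {
      stop("heritabilities must be in (0, 1]")
    }
    if (pi1 <= 0 || pi1 > 1) stop("pi1 must be in (0, 1]")
    tau2 <- h2_exposure / (m_snps * pi1)
    s2 <- 1 / n_discovery
    cthr <- stats::qnorm(1 - p_threshold / 2) / sqrt(n_discovery)
    e2_nonnull <- .trunc_second_moment(tau2 + s2, cthr)
    e2_null <- .trunc_second_moment(s2, cthr)
    var_score <- m_snps * (pi1 * e2_nonnull + (1 - pi1) * e2_null)
    if (e2_nonnull <= 0 || var_score <= 0) {
      stop("selection threshold admits no score variance")
    }
    # corr = cov * pi1 * m * (e2_nonnull / (m * pi1 * (tau2+s2))) / sqrt(var_score)
    scale <- e2_nonnull / (tau2 + s2) / sqrt(var_score)
    out$covariance_min <- r_min / scale
    out$genetic_correlation_min <-
      out$covariance_min / sqrt(h2_exposure * h2_outcome)
  }
  structure(out, class = "power_calc")
}
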