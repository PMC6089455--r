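# Single-SNP association engines and fixed-effect inverse-variance
# meta-analysis of summary statistics.
#
# All engines return one row per SNP in the common summary-statistic layout
# (snp, chr, bp, ea, oa, eaf, beta, se, p, n, study) so their outputs can be
# fed straight into meta_analyse(), clump(), PRS weighting and MR
# harmonization. `beta` is a log odds ratio for the binary engines and mm per
# effect allele for the quantitative engine.

.sumstats_skeleton <- function(meta, n, study) {
  data.frame(snp = meta$snp, chr = meta$chr, bp = meta$bp,
             ea = meta$ea, oa = meta$oa, eaf = meta$eaf,
             beta = NA_real_, se = NA_real_, p = NA_real_,
             n = n, study = study, flag = "ok",
             stringsAsFactors = FALSE)
}

#' Transmission disequilibrium test on affected-offspring trios and duos
#'
#' For each SNP, counts transmissions (`b`) and non-transmissions (`c`) of
#' the effect allele from heterozygous parents to the affected child, using
#' the per-parent transmitted-allele annotations recorded by
#' [simulate_trios()]. Homozygous parents are uninformative and masked (duo)
#' parents are skipped. The test statistic is the McNemar-type chi-square
#' `(b - c)^2 / (b + c)` on 1 df; the allelic log odds ratio is `log(b / c)`
#' with `se = sqrt(1/b + 1/c)`, so TDT results are directly meta-analysable
#' with case-control log odds ratios. When `b` or `c` is zero a 0.5
#' continuity correction is applied and the row is flagged `"corrected"`;
#' SNPs with no informative transmissions are flagged `"uninformative"`, not
#' dropped.
#'
#' @param panel A [genotype_panel()] containing children and parents.
#' @param trios A [trio_set()] with transmission annotations; all children
#'   must be affected.
#' @return A summary-statistic `data.frame` with extra columns `b`, `c` and
#'   `chi2`.
#' @export
run_tdt <- function(panel, trios) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(trios, "trio_set"))
  if (!all(trios$child_affected)) stop("TDT requires every child affected")
  tf <- attr(trios, "transmit_father")
  tm <- attr(trios, "transmit_mother")
  if (is.null(tf) || is.null(tm)) {
    stop("trio set lacks transmitted-allele annotations")
  }
  ids <- c(trios$child, trios$father, trios$mother)
  if (!all(ids[!is.na(ids)] %in% rownames(panel$dosage))) {
    stop("trio set references samples absent from the panel")
  }
  dos <- panel$dosage
  rows_or_na <- function(ids) { # masked (duo) parents become all-NA rows
    idx <- match(ids, rownames(dos))
    out <- dos[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    out[is.na(idx), ] <- NA
    out
  }
  df <- rows_or_na(trios$father)
  dm <- rows_or_na(trios$mother)

  het_f <- !is.na(df) & df == 1 & !is.na(tf)
  het_m <- !is.na(dm) & dm == 1 & !is.na(tm)
  b <- colSums(het_f * tf, na.rm = TRUE) + colSums(het_m * tm, na.rm = TRUE)
  c_ <- colSums(het_f * (1 - tf), na.rm = TRUE) +
    colSums(het_m * (1 - tm), na.rm = TRUE)

  out <- .sumstats_skeleton(panel$snps, n = nrow(trios), study = "tdt")
  out$b <- as.numeric(b)
  out$c <- as.numeric(c_)
  tot <- out$b + out$c
  out$chi2 <- ifelse(tot > 0, (out$b - out$c)^2 / tot, NA_real_)
  out$p <- ifelse(tot > 0, stats::pchisq(out$chi2, 1, lower.tail = FALSE), NA_real_)
  zero <- tot > 0 & (out$b == 0 | out$c == 0)
  bb <- ifelse(zero, out$b + 0.5, out$b)
  cc <- ifelse(zero, out$c + 0.5, out$c)
  out$beta <- ifelse(tot > 0, log(bb / cc), NA_real_)
  out$se <- ifelse(tot > 0, sqrt(1 / bb + 1 / cc), NA_real_)
  out$flag[zero] <- "corrected"
  out$flag[tot == 0] <- "uninformative"
  out
}

#' Allelic case-control association test
#'
#' Per SNP, cross-tabulates effect/other allele counts in cases versus
#' controls (each sample contributes two alleles from its dosage) and reports
#' the allelic log odds ratio, `se = sqrt(sum of reciprocal cell counts)` and
#' a two-sided normal p-value. Any zero cell triggers the Haldane-Anscombe
#' 0.5 correction on all four cells (flag `"corrected"`); monomorphic SNPs
#' are additionally flagged `"monomorphic"`.
#'
#' @param panel A [genotype_panel()].
#' @param status Logical vector along the panel samples; `TRUE` = case.
#' @return A summary-statistic `data.frame`.
#' @export
run_case_control <- function(panel, status) {
  stopifnot(inherits(panel, "genotype_panel"))
  status <- as.logical(status)
  if (length(status) != nrow(panel$dosage)) {
    stop("status must have one entry per panel sample")
  }
  if (!any(status, na.rm = TRUE) || !any(!status, na.rm = TRUE)) {
    stop("need at least one case and one control")
  }
  dos <- panel$dosage
  keep <- !is.na(status)
  dos <- dos[keep, , drop = FALSE]
  status <- status[keep]

  n_case <- colSums(!is.na(dos[status, , drop = FALSE]))
  n_ctrl <- colSums(!is.na(dos[!status, , drop = FALSE]))
  a_case <- colSums(dos[status, , drop = FALSE], na.rm = TRUE)   # EA in cases
  a_ctrl <- colSums(dos[!status, , drop = FALSE], na.rm = TRUE)
  cells <- cbind(a_case, 2 * n_case - a_case, a_ctrl, 2 * n_ctrl - a_ctrl)

  out <- .sumstats_skeleton(panel$snps, n = nrow(dos), study = "cc")
  zero <- rowSums(cells == 0) > 0
  cells_c <- cells + 0.5 * zero
  out$beta <- log(cells_c[, 1] * cells_c[, 4] / (cells_c[, 2] * cells_c[, 3]))
  out$se <- sqrt(rowSums(1 / cells_c))
  z <- out$beta / out$se
  out$p <- 2 * stats::pnorm(-abs(z))
  out$eaf <- (cells[, 1] + cells[, 3]) / (2 * (n_case + n_ctrl))
  out$flag[zero] <- "corrected"
  mono <- (cells[, 1] + cells[, 3]) == 0 |
    (cells[, 2] + cells[, 4]) == 0
  out$flag[mono] <- "monomorphic"
  out
}

# Exact OLS per SNP by Frisch-Waugh: y and each dosage column are residualized
# on the covariate design (factorized once by the caller), then the slope,
# its t-based se and p follow in closed form with df = n - (k + 2).
.quant_fit <- function(yr, g, qrc, k) {
  gr <- qr.resid(qrc, g)
  sxx <- sum(gr^2)
  n <- length(yr)
  df <- n - k - 1L
  if (sxx < 1e-12 * max(1, sum(g^2))) {
    return(list(beta = 0, se = NA_real_, p = NA_real_, flag = "constant_dosage"))
  }
  beta <- sum(gr * yr) / sxx
  rss <- sum(yr^2) - beta^2 * sxx
  if (df <= 0) return(list(beta = beta, se = NA_real_, p = NA_real_, flag = "degenerate"))
  sigma2 <- max(rss, 0) / df
  se <- sqrt(sigma2 / sxx)
  if (se < 1e-10 * max(abs(beta), 1e-12)) {
    return(list(beta = beta, se = se, p = NA_real_, flag = "degenerate"))
  }
  list(beta = beta, se = se,
       p = 2 * stats::pt(-abs(beta / se), df), flag = "ok")
}

#' Covariate-adjusted quantitative-trait GWAS
#'
#' Ordinary least squares of the phenotype on each SNP dosage plus the
#' requested covariates. Samples with a missing phenotype or covariate are
#' dropped (complete-case); missing dosages are mean-imputed to `2 * eaf`.
#' Effects are in phenotype units (mm) per effect allele with t-based
#' two-sided p-values. Constant dosages are flagged `"constant_dosage"`
#' (beta 0, se undefined) and exact fits `"degenerate"`.
#'
#' @param panel A [genotype_panel()].
#' @param pheno A [pheno_table()] covering the panel samples.
#' @param covariates Character vector of covariate columns; defaults to
#'   whichever of `sex`, `age`, `height`, `pc1`..`pc4` are present.
#' @return A summary-statistic `data.frame`.
#' @export
run_quant_gwas <- function(panel, pheno,
                           covariates = intersect(c("sex", "age", "height",
                                                    paste0("pc", 1:4)),
                                                  names(pheno))) {
  stopifnot(inherits(panel, "genotype_panel"))
  .required_cols(pheno, c("sample", "phenotype"), "phenotype table")
  idx <- match(rownames(panel$dosage), pheno$sample)
  present <- !is.na(idx)
  ph <- pheno[idx[present], , drop = FALSE]
  dos <- panel$dosage[present, , drop = FALSE]

  cols <- c("phenotype", covariates)
  complete <- stats::complete.cases(ph[, cols, drop = FALSE])
  ph <- ph[complete, , drop = FALSE]
  dos <- dos[complete, , drop = FALSE]
  n <- nrow(dos)
  if (n < length(covariates) + 2) {
    stop("need at least (number of covariates + 2) complete samples")
  }

  if (anyNA(dos)) {
    for (j in which(colSums(is.na(dos)) > 0)) {
      fill <- 2 * panel$snps$eaf[j]
      if (is.na(fill)) fill <- mean(dos[, j], na.rm = TRUE)
      dos[is.na(dos[, j]), j] <- fill
    }
  }
  cmat <- cbind(`(intercept)` = rep(1, n))
  if (length(covariates)) {
    cmat <- cbind(cmat, as.matrix(ph[, covariates, drop = FALSE]))
  }
  y <- ph$phenotype
  qrc <- qr(cmat)
  if (qrc$rank < ncol(cmat)) {
    bad <- colnames(cmat)[qrc$pivot[-seq_len(qrc$rank)]]
    stop(sprintf("collinear covariate design (offending column(s): %s)",
                 paste(bad, collapse = ", ")))
  }
  yr <- qr.resid(qrc, y)

  out <- .sumstats_skeleton(panel$snps, n = n, study = "quant")
  for (j in seq_len(ncol(dos))) {
    fit <- .quant_fit(yr, dos[, j], qrc, ncol(cmat))
    out$beta[j] <- fit$beta
    out$se[j] <- fit$se
    out$p[j] <- fit$p
    out$flag[j] <- fit$flag
  }
  out
}

# Align study k's alleles to the reference study's; returns sign (+1 keep,
# -1 flip) or NA when unresolvable even after strand complementing.
.allele_sign <- function(ea_ref, oa_ref, ea, oa) {
  sign <- rep(NA_real_, length(ea))
  sign[ea == ea_ref & oa == oa_ref] <- 1
  sign[ea == oa_ref & oa == ea_ref] <- -1
  flip_ea <- unname(.COMP[ea])
  flip_oa <- unname(.COMP[oa])
  todo <- is.na(sign)
  sign[todo & flip_ea == ea_ref & flip_oa == oa_ref] <- 1
  todo <- is.na(sign)
  sign[todo & flip_ea == oa_ref & flip_oa == ea_ref] <- -1
  sign
}

#' Fixed-effect inverse-variance meta-analysis of summary statistics
#'
#' Pools aligned per-SNP effect sizes across studies with weights
#' `w_i = 1 / se_i^2`: pooled `beta = sum(w beta) / sum(w)`,
#' `se = sqrt(1 / sum(w))`, two-sided normal p. Alleles are harmonized to the
#' first study before pooling (sign flip when effect/other alleles are
#' swapped, strand complementing when needed); an unresolvable allele pair is
#' a hard error naming the SNPs. Cochran's Q (df = studies - 1) and I^2 are
#' reported per SNP, and `gws` flags genome-wide significance at `p < 5e-8`.
#'
#' @param stats A list of summary-statistic `data.frame`s (>= 2) sharing SNP
#'   ids; SNPs absent from any study are dropped.
#' @return A pooled summary-statistic `data.frame` with columns `q`, `q_df`,
#'   `q_p`, `i2`, `k_studies` and `gws` appended.
#' @examples
#' s1 <- data.frame(snp = "rs1", chr = 1, bp = 1, ea = "A", oa = "G",
#'                  eaf = 0.3, beta = -0.07, se = ci_to_se(-0.13, -0.02),
#'                  p = NA, n = 3707)
#' s2 <- data.frame(snp = "rs1", chr = 1, bp = 1, ea = "A", oa = "G",
#'                  eaf = 0.3, beta = -0.14, se = ci_to_se(-0.21, -0.07),
#'                  p = NA, n = 2097)
#' meta_analyse(list(s1, s2))$beta
#' @export
meta_analyse <- function(stats) {
  if (!is.list(stats) || length(stats) < 2) {
    stop("meta_analyse needs a list of at least two summary-statistic sets")
  }
  for (s in stats) .required_cols(s, c("snp", "ea", "oa", "beta", "se"),
                                  "summary statistics")
  ref <- stats[[1]]
  common <- Reduce(intersect, lapply(stats, function(s) s$snp))
  if (!length(common)) stop("no SNPs shared across studies")
  ref <- ref[match(common, ref$snp), , drop = FALSE]

  k <- length(stats)
  betas <- ses <- matrix(NA_real_, length(common), k)
  ns <- eafs <- matrix(NA_real_, length(common), k)
  for (i in seq_len(k)) {
    s <- stats[[i]][match(common, stats[[i]]$snp), , drop = FALSE]
    sign <- .allele_sign(ref$ea, ref$oa, s$ea, s$oa)
    if (anyNA(sign)) {
      stop(sprintf("allele mismatch not resolvable by swap/strand flip for: %s",
                   paste(common[is.na(sign)], collapse = ", ")))
    }
    betas[, i] <- sign * s$beta
    ses[, i] <- s$se
    ns[, i] <- if ("n" %in% names(s)) s$n else NA_real_
    ef <- if ("eaf" %in% names(s)) s$eaf else NA_real_
    eafs[, i] <- ifelse(sign > 0, ef, 1 - ef)
  }
  if (any(!is.na(ses) & ses <= 0)) stop("standard errors must be positive")

  w <- 1 / ses^2
  use <- is.finite(betas) & is.finite(w)
  w[!use] <- 0
  sw <- rowSums(w)
  beta <- rowSums(ifelse(use, w * betas, 0)) / sw
  se <- sqrt(1 / sw)
  q <- rowSums(ifelse(use, w * (betas - beta)^2, 0))
  q_df <- rowSums(use) - 1L
  out <- data.frame(
    snp = common,
    chr = if ("chr" %in% names(ref)) ref$chr else NA,
    bp = if ("bp" %in% names(ref)) ref$bp else NA,
    ea = ref$ea, oa = ref$oa,
    eaf = rowMeans(eafs, na.rm = TRUE),
    beta = beta, se = se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    n = rowSums(ns, na.rm = TRUE),
    study = "meta",
    q = q, q_df = q_df,
    q_p = ifelse(q_df > 0, stats::pchisq(q, q_df, lower.tail = FALSE), NA_real_),
    i2 = ifelse(q > 0, pmax(0, (q - q_df) / q) * 100, 0),
    k_studies = rowSums(use),
    stringsAsFactors = FALSE
  )
  out$gws <- !is.na(out$p) & out$p < 5e-8
  out
}
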