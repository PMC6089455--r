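test_that("PRS is the effect-allele-aligned dot product", {
  pan <- make_panel(matrix(c(2, 1), nrow = 1), eaf = c(0.5, 0.5))
  w <- data.frame(snp = c("rs1", "rs2"), ea = "A", oa = "G",
                  weight = c(0.2, -0.1), p_source = 1)
  prs <- compute_prs(pan, w)
  expect_equal(prs$raw, 0.3, tolerance = 1e-12)

  # flipped panel orientation for one SNP: same score after 2 - dose
  pan2 <- pan
  pan2$snps$ea[1] <- "G"; pan2$snps$oa[1] <- "A"
  pan2$dosage[, 1] <- 2 - pan2$dosage[, 1]
  prs2 <- compute_prs(pan2, w)
  expect_equal(prs2$raw, 0.3, tolerance = 1e-12)
})

test_that("PRS standardization, orientation invariance and degeneracy", {
  set.seed(31)
  dos <- matrix(rbinom(200 * 6, 2, 0.4), 200, 6)
  pan <- make_panel(dos)
  w <- data.frame(snp = paste0("rs", 1:6), ea = "A", oa = "G",
                  weight = rnorm(6), p_source = 1)
  prs <- compute_prs(pan, w)
  expect_lt(abs(mean(prs$std)), 1e-9)
  expect_lt(abs(sd(prs$std) - 1), 1e-9)

  flip <- c(1, 4)
  pan2 <- pan
  pan2$snps$ea[flip] <- "G"; pan2$snps$oa[flip] <- "A"
  pan2$snps$eaf[flip] <- 1 - pan2$snps$eaf[flip]
  pan2$dosage[, flip] <- 2 - pan2$dosage[, flip]
  prs2 <- compute_prs(pan2, w)
  expect_equal(prs2$std, prs$std, tolerance = 1e-9)

  w0 <- transform(w, weight = 0)
  prs0 <- compute_prs(pan, w0)
  expect_true(attr(prs0, "degenerate"))
  expect_true(all(prs0$raw == 0))
})

test_that("PRS drops absent SNPs with a warning and imputes missing dosages", {
  pan <- make_panel(matrix(c(0, 1, 2, NA), nrow = 2), eaf = c(0.25, 0.4))
  w <- data.frame(snp = c("rs1", "rs2", "rs9"), ea = "A", oa = "G",
                  weight = c(1, 1, 5), p_source = 1)
  expect_warning(prs <- compute_prs(pan, w), "dropped")
  expect_identical(attr(prs, "dropped_snps"), "rs9")
  expect_equal(attr(prs, "n_imputed"), 1L)
  expect_equal(prs$raw[2], 1 + 2 * 0.4, tolerance = 1e-12)

  w_none <- data.frame(snp = "rs9", ea = "A", oa = "G", weight = 1,
                       p_source = 1)
  expect_error(compute_prs(pan, w_none), "overlap")
})

test_that("pTDT reproduces the hand-computed one-sample t-test", {
  # mid-parent scores (0, 2, 4): sd 2; children chosen for deviations
  # d = (0.5, 1.5, 1.0)
  father <- c(0, 2, 4); mother <- c(0, 2, 4)
  child <- c(0, 2, 4) + c(0.5, 1.5, 1.0) * 2
  res <- ptdt_test(child, father, mother)
  expect_equal(res$mean_deviation, 1, tolerance = 1e-12)
  expect_equal(res$t, 1 / (0.5 / sqrt(3)), tolerance = 1e-12)
  expect_identical(res$df, 2L)
  expect_equal(res$p, 2 * pt(-res$t, 2), tolerance = 1e-12)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
})

test_that("pTDT degenerate cases: exact transmission and zero spread", {
  mid <- c(1, 2, 3)
  res <- ptdt_test(mid, mid, mid) # child equals mid-parent everywhere
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # constant nonzero deviation has no variance to test against
  expect_error(ptdt_test(mid + 1, mid, mid), "degenerate deviation")
  # constant mid-parent score cannot be normalized
  expect_error(ptdt_test(c(1, 2, 3), c(2, 2, 2), c(2, 2, 2)),
               "mid-parent")
})

test_that("pTDT detects over-transmission in ascertained trios", {
  sc <- sim_scenario(m_snps = 20, maf = 0.3, liability_betas = rep(0.15, 20),
                     prevalence = 0.05, seed = 51)
  tt <- simulate_trios(sc, 500)
  w <- data.frame(snp = tt$panel$snps$snp, ea = "A", oa = "G",
                  weight = sc$liability_betas, p_source = 1)
  prs <- compute_prs(tt$panel, w)
  raw <- setNames(prs$raw, prs$sample)
  res <- ptdt_test(raw[tt$trios$child], raw[tt$trios$father],
                   raw[tt$trios$mother])
  expect_gt(res$mean_deviation, 0)
  expect_lt(res$p, 0.01)
})

test_that("pTDT is powered under a rare, moderately heritable architecture", {
  # 2000 trios ascertained at prevalence 0.001 with liability h2 = 0.3
  beta <- sqrt(0.3 / (30 * 2 * 0.3 * 0.7))
  sc <- sim_scenario(m_snps = 30, maf = 0.3, liability_betas = rep(beta, 30),
                     prevalence = 0.001, seed = 71)
  expect_equal(sc$h2, 0.3, tolerance = 1e-12)
  tt <- simulate_trios(sc, 2000, max_attempts = 2e7)
  w <- data.frame(snp = tt$panel$snps$snp, ea = "A", oa = "G",
                  weight = rep(beta, 30), p_source = 1)
  prs <- compute_prs(tt$panel, w)
  raw <- setNames(prs$raw, prs$sample)
  res <- ptdt_test(raw[tt$trios$child], raw[tt$trios$father],
                   raw[tt$trios$mother])
  expect_gt(res$mean_deviation, 0)
  expect_lt(res$p, 0.01)
})

test_that("PRS association covers a known per-SD effect across replicates", {
  n_rep <- 100
  cover <- 0
  for (r in seq_len(n_rep)) {
    sc <- sim_scenario(m_snps = 15, maf = 0.3,
                       liability_betas = rep(0.15, 15), gamma = -0.1,
                       prevalence = 0.1, seed = 40000 + r)
    pan <- simulate_genotypes(sc, 4000)
    ph <- simulate_phenotypes(sc, pan)
    w <- data.frame(snp = pan$snps$snp, ea = "A", oa = "G",
                    weight = sc$liability_betas, p_source = 1)
    res <- prs_assoc(compute_prs(pan, w), ph)
    if (res$ci[1] <= -0.1 && -0.1 <= res$ci[2]) cover <- cover + 1
  }
  expect_gte(cover / n_rep, 0.90)
})

test_that("threshold selection picks the most over-transmitted grid point", {
  sc <- sim_scenario(m_snps = 30, maf = 0.3, liability_betas = rep(0.15, 30),
                     prevalence = 0.1, seed = 61)
  tt <- simulate_trios(sc, 300)
  ld <- ld_from_panel(tt$panel)
  disc <- make_stats(tt$panel$snps$snp, beta = sc$liability_betas, se = 0.03,
                     p = rep(1e-6, 30), bp = tt$panel$snps$bp)
  # single-point grid: that threshold is selected
  sel1 <- select_threshold(disc, tt$panel, tt$trios, ld, thresholds = 1e-5)
  expect_equal(sel1$best_threshold, 1e-5)
  # grid point admitting no SNPs yields an NA row, not an error
  sel2 <- select_threshold(disc, tt$panel, tt$trios, ld,
                           thresholds = c(1e-8, 1e-5))
  expect_identical(sel2$results$n_snps, c(0L, 30L))
  expect_true(is.na(sel2$results$t[1]))
  expect_equal(sel2$best_threshold, 1e-5)
})

test_that("threshold selection recovers a p < 1e-5 architecture in replicates", {
  # true effects live only among SNPs with discovery p below 1e-5; thresholds
  # at or just above that point should win most replicates
  grid <- c(1e-7, 1e-6, 1e-5, 1e-4, 1e-2, 0.5)
  m <- 60; n_true <- 10
  hits <- 0; n_rep <- 50
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    betas <- c(rep(0.3, n_true), rep(0, m - n_true))
    sc <- sim_scenario(m_snps = m, maf = 0.3, liability_betas = betas,
                       prevalence = 0.2, seed = 2000 + r)
    tt <- simulate_trios(sc, 500)
    # discovery effect sizes consistent with their p-values at se = 0.08, so
    # looser thresholds admit null SNPs with non-trivial diluting weights
    null_p <- 10^runif(m - n_true, -3.5, 0)
    null_beta <- qnorm(1 - null_p / 2) * 0.08 *
      sample(c(-1, 1), m - n_true, replace = TRUE)
    disc <- make_stats(tt$panel$snps$snp,
                       beta = c(betas[1:n_true] + rnorm(n_true, 0, 0.03),
                                null_beta),
                       se = 0.08,
                       p = c(10^runif(n_true, -6.5, -5.05), null_p),
                       bp = tt$panel$snps$bp)
    ld <- ld_from_panel(tt$panel)
    sel <- select_threshold(disc, tt$panel, tt$trios, ld, thresholds = grid)
    if (sel$best_threshold %in% c(1e-5, 1e-4)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("PRS association matches the closed-form slope and identities", {
  prs <- structure(data.frame(sample = c("S1", "S2", "S3"),
                              raw = c(0, 1, 2), std = c(-1, 0, 1)),
                   class = c("prs_vector", "data.frame"))
  ph <- pheno_table(data.frame(sample = c("S1", "S2", "S3"),
                               phenotype = c(1, 2, 3)))
  res <- suppressWarnings(prs_assoc(prs, ph, covariates = character(0)))
  expect_equal(res$beta, 1, tolerance = 1e-12)

  # per-SD effect equals raw-score effect times sd(raw)
  set.seed(71)
  n <- 300
  raw <- rnorm(n, 5, 2.3)
  std <- (raw - mean(raw)) / sd(raw)
  prs2 <- structure(data.frame(sample = paste0("S", 1:n), raw = raw,
                               std = std),
                    class = c("prs_vector", "data.frame"))
  ph2 <- pheno_table(data.frame(sample = paste0("S", 1:n),
                                phenotype = 10 - 0.3 * raw + rnorm(n)))
  res2 <- prs_assoc(prs2, ph2, covariates = character(0))
  raw_fit <- coef(lm(ph2$phenotype ~ raw))[2]
  expect_equal(res2$beta, unname(raw_fit) * sd(raw), tolerance = 1e-9)
})

test_that("PRS-phenotype null keeps the effect within sampling noise", {
  set.seed(81)
  sc <- sim_scenario(m_snps = 15, maf = 0.3, liability_betas = rep(0.2, 15),
                     gamma = 0, prevalence = 0.1, seed = 81)
  pan <- simulate_genotypes(sc, 20000)
  ph <- simulate_phenotypes(sc, pan)
  w <- data.frame(snp = pan$snps$snp, ea = "A", oa = "G",
                  weight = sc$liability_betas, p_source = 1)
  res <- prs_assoc(compute_prs(pan, w), ph)
  expect_lt(abs(res$beta), 3 * res$se)
})

test_that("minimum detectable correlation follows the Fisher-z closed form", {
  pc <- min_detectable_correlation(n = 3707)
  expect_equal(pc$r_min, tanh((qnorm(0.975) + qnorm(0.8)) / sqrt(3704)),
               tolerance = 1e-12)
  expect_equal(pc$r_min, 0.04600, tolerance = 1e-4)
  # consistency: r_min vanishes as n grows
  expect_lt(min_detectable_correlation(n = 1e9)$r_min, 1e-3)
  expect_error(min_detectable_correlation(n = 3), "exceed 3")
})

test_that("covariance-to-correlation conversion and the no-selection limit", {
  pc <- min_detectable_correlation(n = 4000, h2_exposure = 1, h2_outcome = 1,
                                   n_discovery = 5000, m_snps = 100,
                                   p_threshold = 1)
  # unit heritabilities: genetic correlation equals genetic covariance
  expect_equal(pc$genetic_correlation_min, pc$covariance_min,
               tolerance = 1e-12)
  # no selection: closed form r_min * sqrt(h2 + m/n_discovery)
  expect_equal(pc$covariance_min, pc$r_min * sqrt(1 + 100 / 5000),
               tolerance = 1e-9)
  # stricter selection can only demand a larger minimum covariance
  pc_sel <- min_detectable_correlation(n = 4000, h2_exposure = 0.3,
                                       h2_outcome = 0.2, n_discovery = 5000,
                                       m_snps = 100, p_threshold = 1e-5)
  pc_all <- min_detectable_correlation(n = 4000, h2_exposure = 0.3,
                                       h2_outcome = 0.2, n_discovery = 5000,
                                       m_snps = 100, p_threshold = 1)
  expect_gt(pc_sel$covariance_min, pc_all$covariance_min)
})
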