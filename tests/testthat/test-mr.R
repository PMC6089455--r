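test_that("harmonization aligns swapped alleles and applies the EAF rules", {
  ex <- make_stats("rs1", beta = 0.1, se = 0.02, ea = "A", oa = "G")
  ou <- make_stats("rs1", beta = 0.05, se = 0.01, ea = "G", oa = "A")
  h <- harmonize(ex, ou)
  expect_equal(h$by, -0.05, tolerance = 1e-12)

  # palindromic SNP with EAF 0.5 on both sides is ambiguous: dropped
  ex2 <- make_stats(c("rs1", "rs2"), beta = c(0.1, 0.2), se = 0.02,
                    ea = c("A", "A"), oa = c("G", "T"), eaf = c(0.3, 0.5))
  ou2 <- make_stats(c("rs1", "rs2"), beta = c(0.05, 0.07), se = 0.01,
                    ea = c("A", "A"), oa = c("G", "T"), eaf = c(0.3, 0.5))
  h2 <- harmonize(ex2, ou2)
  expect_identical(h2$snp, "rs1")
  expect_identical(attr(h2, "dropped"), "rs2")

  # palindromic but resolvable: EAFs on opposite sides of 0.5 flip the sign
  ex3 <- make_stats("rs1", beta = 0.1, se = 0.02, ea = "A", oa = "T",
                    eaf = 0.2)
  ou3 <- make_stats("rs1", beta = 0.05, se = 0.01, ea = "A", oa = "T",
                    eaf = 0.8)
  expect_equal(harmonize(ex3, ou3)$by, -0.05, tolerance = 1e-12)
  ou3b <- transform(ou3, eaf = 0.2)
  expect_equal(harmonize(ex3, ou3b)$by, 0.05, tolerance = 1e-12)
})

test_that("harmonization substitutes the best LD proxy and records it", {
  ex <- make_stats("rs1", beta = 0.1, se = 0.02)
  ou <- make_stats(c("rs10", "rs11"), beta = c(0.04, 0.09), se = 0.01,
                   bp = c(2000, 3000))
  ld <- ld_table(data.frame(snp_a = c("rs1", "rs1", "rs1"),
                            snp_b = c("rs10", "rs11", "rs12"),
                            r2 = c(0.92, 0.95, 0.99)))
  h <- harmonize(ex, ou, ld = ld, proxy_r2_min = 0.9)
  expect_identical(h$proxy, "rs11") # 0.95 beats 0.92; 0.99 SNP absent
  expect_equal(h$proxy_r2, 0.95)
  expect_equal(h$by, 0.09, tolerance = 1e-12)

  expect_error(harmonize(ex, ou[0, ]), "no SNPs survived")
})

test_that("Wald ratio follows the first-order formulas", {
  wr <- wald_ratio(0.2, 0.05, -0.022, 0.01)
  expect_equal(wr$ratio, -0.11, tolerance = 1e-12)
  expect_equal(wr$se, 0.05, tolerance = 1e-12)
  expect_equal(wald_ratio(0.2, 0.05, 0, 0.01)$ratio, 0)
  expect_error(wald_ratio(0, 0.05, 0.1, 0.01), "bx = 0")
})

test_that("IVW matches hand evaluation, exact fits and the 1-SNP reduction", {
  d <- make_mr_data(bx = c(1, 2), by = c(0.5, 1.0), se_by = 0.1)
  r <- mr_ivw(d)
  expect_equal(r$estimate, 0.5, tolerance = 1e-12)
  expect_equal(r$q, 0, tolerance = 1e-12)

  d2 <- make_mr_data(bx = c(1, 1), by = c(0.5, 0.7), se_by = 0.1)
  r2 <- mr_ivw(d2)
  expect_equal(r2$estimate, 0.6, tolerance = 1e-12)
  expect_equal(r2$se, sqrt(1 / 200), tolerance = 1e-12)
  expect_equal(r2$q, 2, tolerance = 1e-12)
  expect_equal(r2$q_p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r2$se_random, r2$se_fixed * sqrt(2), tolerance = 1e-12)

  d1 <- make_mr_data(bx = 0.2, by = -0.022, se_by = 0.01)
  r1 <- mr_ivw(d1)
  expect_equal(r1$estimate, -0.11, tolerance = 1e-12)
  expect_equal(r1$se, 0.05, tolerance = 1e-12)
  expect_error(mr_ivw(make_mr_data(bx = c(0, 0), by = c(1, 1))), "zero")
})

test_that("IVW equals the weighted through-origin normal equations", {
  set.seed(13)
  for (rep in 1:20) {
    k <- sample(3:15, 1)
    d <- make_mr_data(bx = rnorm(k, 0.2, 0.1), by = rnorm(k, 0, 0.1),
                      se_by = runif(k, 0.01, 0.2))
    fit <- lm(by ~ 0 + bx, data = d, weights = 1 / d$se_by^2)
    r <- mr_ivw(d)
    expect_equal(r$estimate, unname(coef(fit)), tolerance = 1e-10)
    expect_equal(r$se, sqrt(1 / sum(d$bx^2 / d$se_by^2)), tolerance = 1e-10)
  }
})

test_that("MR-Egger fits the exact colinear example and WLS oracle", {
  d <- make_mr_data(bx = c(1, 2, 3), by = c(0.3, 0.5, 0.7), se_by = 0.1)
  r <- mr_egger(d)
  expect_equal(r$estimate, 0.2, tolerance = 1e-12)
  expect_equal(r$intercept, 0.1, tolerance = 1e-12)
  expect_equal(r$q, 0, tolerance = 1e-10)

  # data through the origin: intercept vanishes
  d0 <- make_mr_data(bx = c(1, 2, 3), by = c(0.4, 0.8, 1.2), se_by = 0.1)
  expect_lt(abs(mr_egger(d0)$intercept), 1e-12)

  # against lm's weighted fit (inflation factor > 1 branch)
  set.seed(29)
  k <- 12
  d2 <- make_mr_data(bx = runif(k, 0.05, 0.4), by = rnorm(k, 0.1, 0.3),
                     se_by = runif(k, 0.02, 0.1))
  fit <- lm(by ~ bx, data = d2, weights = 1 / d2$se_by^2)
  r2 <- mr_egger(d2)
  expect_equal(r2$estimate, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(r2$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  sigma2 <- sum((1 / d2$se_by^2) * resid(fit)^2) / (k - 2)
  if (sigma2 > 1) { # lm's vcov uses the same multiplicative inflation
    expect_equal(r2$se, unname(sqrt(diag(vcov(fit)))[2]), tolerance = 1e-10)
  }
  expect_error(mr_egger(make_mr_data(bx = c(1, 2), by = c(1, 2))), "3 SNPs")
  expect_error(mr_egger(make_mr_data(bx = c(1, 1, 1), by = c(1, 2, 3))),
               "zero spread")
})

test_that("weighted median interpolates the standardized weight ladder", {
  d <- make_mr_data(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3), se_by = 1)
  r <- mr_weighted_median(d, n_boot = 200, seed = 3)
  expect_equal(r$estimate, 0.2, tolerance = 1e-12)

  # weights 0.98/0.01/0.01: hand interpolation gives ~0.10202
  se_by <- sqrt(1 / c(0.98, 0.01, 0.01))
  d2 <- make_mr_data(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3), se_by = se_by)
  r2 <- mr_weighted_median(d2, n_boot = 200, seed = 3)
  expect_equal(r2$estimate, 0.1 + 0.1 * (0.5 - 0.49) / (0.985 - 0.49),
               tolerance = 1e-9)

  # all weight on one SNP converges to that SNP's ratio
  d3 <- make_mr_data(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3),
                     se_by = c(1e-4, 10, 10))
  r3 <- mr_weighted_median(d3, n_boot = 200, seed = 3)
  expect_equal(r3$estimate, 0.1, tolerance = 1e-4)

  # identical ratios: estimate is that ratio with a small bootstrap se
  d4 <- make_mr_data(bx = c(1, 2, 4), by = 0.25 * c(1, 2, 4),
                     se_bx = 1e-6, se_by = 1e-6)
  r4 <- mr_weighted_median(d4, n_boot = 200, seed = 3)
  expect_equal(r4$estimate, 0.25, tolerance = 1e-9)
  expect_lt(r4$se, 1e-4)
  expect_error(mr_weighted_median(make_mr_data(1:2, 1:2)), "3 SNPs")
})

test_that("weighted mode finds the dominant ratio cluster", {
  d <- make_mr_data(bx = rep(1, 4), by = c(0.2, 0.2, 0.2, 0.9), se_by = 1)
  r <- mr_weighted_mode(d, n_boot = 200, seed = 5)
  expect_equal(r$estimate, 0.2, tolerance = 0.02)

  d2 <- make_mr_data(bx = c(1, 2, 4), by = 0.3 * c(1, 2, 4), se_by = 1)
  r2 <- mr_weighted_mode(d2, n_boot = 200, seed = 5)
  expect_equal(r2$estimate, 0.3, tolerance = 1e-9)
  expect_error(mr_weighted_mode(make_mr_data(1:2, 1:2)), "3 SNPs")
})

test_that("weighted mode equals dense grid-search KDE maximization", {
  set.seed(37)
  for (rep in 1:3) {
    ratios <- c(rnorm(6, 0.1, 0.01), rnorm(2, 0.5, 0.01))
    d <- make_mr_data(bx = rep(1, 8), by = ratios,
                      se_by = c(runif(6, 0.5, 0.7), runif(2, 1.5, 2)))
    r <- mr_weighted_mode(d, n_boot = 50, seed = 7)
    # independent dense-grid maximizer of the same weighted Gaussian KDE
    w <- d$bx^2 / d$se_by^2
    h <- 0.9 * min(sd(ratios), mad(ratios)) * 8^(-1 / 5)
    coarse <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 5000)
    dens <- sapply(coarse, function(x) sum(w * dnorm((x - ratios) / h)))
    centre <- coarse[which.max(dens)]
    fine <- seq(centre - 0.01, centre + 0.01, by = 1e-6)
    densf <- sapply(fine, function(x) sum(w * dnorm((x - ratios) / h)))
    expect_equal(r$estimate, fine[which.max(densf)], tolerance = 1e-5)
    expect_equal(r$estimate, 0.1, tolerance = 0.3) # dominant cluster, not 0.5
  }
})

test_that("estimators are invariant to jointly negating a SNP and scale in by", {
  set.seed(43)
  k <- 8
  d <- make_mr_data(bx = rnorm(k, 0.2, 0.05), by = rnorm(k, -0.05, 0.05),
                    se_bx = 0.01, se_by = runif(k, 0.02, 0.1))
  dn <- d
  flip <- c(2, 5)
  dn$bx[flip] <- -dn$bx[flip]
  dn$by[flip] <- -dn$by[flip]
  expect_equal(mr_ivw(dn)$estimate, mr_ivw(d)$estimate, tolerance = 1e-12)
  expect_equal(mr_egger(dn)$estimate, mr_egger(d)$estimate, tolerance = 1e-12)
  expect_equal(mr_egger(dn)$intercept, mr_egger(d)$intercept, tolerance = 1e-12)
  expect_equal(mr_weighted_median(dn, 100, 9)$estimate,
               mr_weighted_median(d, 100, 9)$estimate, tolerance = 1e-12)
  expect_equal(mr_weighted_mode(dn, n_boot = 50, seed = 9)$estimate,
               mr_weighted_mode(d, n_boot = 50, seed = 9)$estimate,
               tolerance = 1e-9)

  # scaling the outcome side by c scales every causal estimate by c
  cs <- -2.5
  ds <- transform(d, by = cs * by, se_by = abs(cs) * se_by)
  expect_equal(mr_ivw(ds)$estimate, cs * mr_ivw(d)$estimate, tolerance = 1e-10)
  expect_equal(mr_egger(ds)$estimate, cs * mr_egger(d)$estimate,
               tolerance = 1e-10)
  expect_equal(mr_weighted_median(ds, 100, 9)$estimate,
               cs * mr_weighted_median(d, 100, 9)$estimate, tolerance = 1e-9)
})

test_that("leave-one-out isolates the most influential instrument", {
  d <- make_mr_data(bx = rep(1, 3), by = rep(0.4, 3), se_by = 0.1)
  loo <- mr_leave_one_out(d)
  expect_true(all(abs(loo$estimate - 0.4) < 1e-12))

  d2 <- make_mr_data(bx = rep(1, 6), by = c(rep(0.2, 5), 1.4), se_by = 0.1)
  loo2 <- mr_leave_one_out(d2)
  full <- mr_ivw(d2)$estimate
  # direct recomputation oracle
  for (i in seq_len(6)) {
    expect_equal(loo2$estimate[i], mr_ivw(d2[-i, ])$estimate, tolerance = 1e-12)
  }
  expect_identical(loo2$excluded[which.max(abs(loo2$estimate - full))], "rs6")
  expect_error(mr_leave_one_out(d[1:2, ]), "3 SNPs")
})

test_that("Steiger direction follows the Fisher-z comparison", {
  s <- steiger_direction(0.2^2, 4000, 0.05^2, 4000)
  expect_equal(s$z, (atanh(0.2) - atanh(0.05)) / sqrt(2 / 3997),
               tolerance = 1e-12)
  expect_equal(s$z, 6.826, tolerance = 1e-3)
  expect_equal(s$p, 8.7e-12, tolerance = 0.02)
  expect_identical(s$direction, "exposure->outcome")

  tie <- steiger_direction(0.1, 1000, 0.1, 1000)
  expect_equal(tie$z, 0)
  expect_equal(tie$p, 1)
  expect_identical(tie$direction, "tied")

  rev <- steiger_direction(0.05^2, 4000, 0.2^2, 4000)
  expect_equal(rev$z, -s$z, tolerance = 1e-12)
  expect_identical(rev$direction, "outcome->exposure")
  expect_error(steiger_direction(1, 100, 0.5, 100), "r2")
  expect_error(steiger_direction(0.1, 3, 0.1, 100), "exceed 3")
})

test_that("IVW covers a known simulated causal effect", {
  set.seed(53)
  theta <- -0.11
  cover <- 0
  for (rep in 1:50) {
    k <- 15
    bx <- rnorm(k, 0.2, 0.05)
    se_by <- runif(k, 0.01, 0.03)
    by <- theta * bx + rnorm(k, 0, se_by)
    r <- mr_ivw(make_mr_data(bx, by, se_by = se_by))
    if (r$ci_lower <= theta && theta <= r$ci_upper) cover <- cover + 1
  }
  expect_gte(cover / 50, 0.85)
})
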