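# Generative simulator: block-LD genotypes, trios ascertained for an affected
# child under the liability-threshold model, and quantitative phenotypes.

# Draw an n x m dosage matrix under the scenario's block-LD model.
#
# Within a block every SNP copies a latent pair of block haplotypes; each
# haploid allele is inherited from the block haplotype with probability
# (1 - mu) and redrawn Bernoulli(maf) otherwise. Two SNPs then share only the
# copied part, so their haploid (and dosage) correlation is (1 - mu)^2.
# Matching a target within-block dosage r2 therefore needs
#   (1 - mu)^2 = sqrt(r2)   =>   mu = 1 - r2^(1/4),
# which the tests validate empirically.
.draw_dosages <- function(scenario, n) {
  m <- scenario$m_snps
  dos <- matrix(0L, n, m)
  blocks <- scenario$blocks
  for (b in unique(blocks$block)) {
    idx <- blocks$snp_index[blocks$block == b]
    p <- scenario$maf[idx[1]]
    if (length(idx) == 1L) {
      dos[, idx] <- stats::rbinom(n, 2L, p)
      next
    }
    mu <- 1 - blocks$r2[idx[1]]^0.25
    a1 <- stats::rbinom(n, 1L, p)
    a2 <- stats::rbinom(n, 1L, p)
    for (j in idx) {
      keep1 <- stats::runif(n) >= mu
      keep2 <- stats::runif(n) >= mu
      x1 <- ifelse(keep1, a1, stats::rbinom(n, 1L, p))
      x2 <- ifelse(keep2, a2, stats::rbinom(n, 1L, p))
      dos[, j] <- x1 + x2
    }
  }
  dos
}

.snp_metadata <- function(scenario) {
  blocks <- scenario$blocks
  within <- stats::ave(blocks$snp_index, blocks$block, FUN = seq_along)
  data.frame(
    snp = paste0("rs", seq_len(scenario$m_snps)),
    chr = 1L,
    bp = (blocks$block - 1) * 1e7 + 1e6 + (within - 1) * 5000,
    ea = "A", oa = "G",
    eaf = scenario$maf,
    stringsAsFactors = FALSE
  )
}

#' Simulate population genotypes
#'
#' Draws unrelated samples from the scenario's allele-frequency and LD-block
#' model. Deterministic for a fixed scenario and seed. Blocks are placed 10 Mb
#' apart on one chromosome (SNPs 5 kb apart within a block) so that
#' window-based operations see within-block pairs as neighbours and
#' cross-block pairs as distant.
#'
#' @param scenario A [sim_scenario()].
#' @param n Number of samples (>= 1).
#' @param seed Seed; defaults to the scenario seed.
#' @param sample_prefix Prefix for generated sample ids.
#' @return A [genotype_panel()].
#' @examples
#' sc <- sim_scenario(m_snps = 4, maf = c(0, 0.3, 0.5, 1))
#' p <- simulate_genotypes(sc, 100)
#' colMeans(p$dosage)
#' @export
simulate_genotypes <- function(scenario, n, seed = scenario$seed,
                               sample_prefix = "S") {
  stopifnot(inherits(scenario, "sim_scenario"))
  n <- as.integer(n)
  if (n < 1) stop("n must be >= 1")
  set.seed(.sub_seed(seed, "genotypes"))
  dos <- .draw_dosages(scenario, n)
  if (scenario$missing_rate > 0) {
    dos[stats::runif(length(dos)) < scenario$missing_rate] <- NA
  }
  rownames(dos) <- paste0(sample_prefix, seq_len(n))
  meta <- .snp_metadata(scenario)
  colnames(dos) <- meta$snp
  genotype_panel(meta, dos)
}

# Liability of individuals given their dosage matrix: all genetic loadings
# (mean-centred so the liability is zero-mean, matching the standard-normal
# formulation) plus the confounder's non-genetic part and the residual.
.draw_liability <- function(scenario, dos) {
  n <- nrow(dos)
  g_eff <- as.numeric(dos %*% scenario$eff_loadings) - scenario$mean_eff
  c_l <- scenario$confounder_effect[["liability"]]
  eps_u <- if (c_l != 0) stats::rnorm(n) else numeric(n)
  g_eff + c_l * eps_u + stats::rnorm(n, 0, scenario$env_sd)
}

#' Simulate trios ascertained for an affected child
#'
#' Parents are drawn from the population model; each parent transmits one
#' allele per SNP, sampled `Bernoulli(dosage / 2)` from the unphased dosage,
#' and the child dosage is the sum of the two transmitted alleles. The child
#' liability is computed under the scenario and the trio is retained only if
#' the child is affected (`L > T`); rejection sampling repeats until
#' `n_trios` trios are collected. Each parent's own liability determines its
#' affection flag. Transmitted alleles are recorded on the returned
#' [trio_set()] so the transmission disequilibrium test is exact rather than
#' inferred from genotype configurations.
#'
#' With `duo_rate > 0` a matching fraction of trios is degraded to duos by
#' masking one parent at random: the masked parent is removed from the panel
#' and its transmissions are set `NA`.
#'
#' @param scenario A [sim_scenario()].
#' @param n_trios Number of ascertained trios required (>= 1).
#' @param seed Seed; defaults to the scenario seed.
#' @param duo_rate Fraction of trios reduced to parent-offspring duos.
#' @param max_attempts Upper bound on candidate trios drawn; if it is reached
#'   while the empirical acceptance rate is below 1e-6 an ascertainment error
#'   is raised (the threshold is effectively unreachable).
#' @return `list(panel = genotype_panel, trios = trio_set)`; the panel holds
#'   children first, then retained parents.
#' @export
simulate_trios <- function(scenario, n_trios, seed = scenario$seed,
                           duo_rate = 0, max_attempts = 1e7) {
  stopifnot(inherits(scenario, "sim_scenario"))
  n_trios <- as.integer(n_trios)
  if (n_trios < 1) stop("n_trios must be >= 1")
  if (duo_rate < 0 || duo_rate > 1) stop("duo_rate must be in [0, 1]")
  set.seed(.sub_seed(seed, "trios"))

  m <- scenario$m_snps
  kept_f <- kept_m <- kept_c <- kept_tf <- kept_tm <- list()
  kept_lf <- kept_lm <- numeric(0)
  attempts <- 0
  accepted <- 0
  batch <- max(1000L, min(50000L, n_trios * 4L))
  repeat {
    nb <- batch
    df <- .draw_dosages(scenario, nb)
    dm <- .draw_dosages(scenario, nb)
    tf <- matrix(stats::rbinom(nb * m, 1L, as.vector(df) / 2), nb, m)
    tm <- matrix(stats::rbinom(nb * m, 1L, as.vector(dm) / 2), nb, m)
    dc <- tf + tm
    lf <- .draw_liability(scenario, df)
    lm <- .draw_liability(scenario, dm)
    lc <- .draw_liability(scenario, dc)
    ok <- which(lc > scenario$threshold)
    attempts <- attempts + nb
    if (length(ok)) {
      take <- ok[seq_len(min(length(ok), n_trios - accepted))]
      kept_f[[length(kept_f) + 1L]] <- df[take, , drop = FALSE]
      kept_m[[length(kept_m) + 1L]] <- dm[take, , drop = FALSE]
      kept_c[[length(kept_c) + 1L]] <- dc[take, , drop = FALSE]
      kept_tf[[length(kept_tf) + 1L]] <- tf[take, , drop = FALSE]
      kept_tm[[length(kept_tm) + 1L]] <- tm[take, , drop = FALSE]
      kept_lf <- c(kept_lf, lf[take])
      kept_lm <- c(kept_lm, lm[take])
      accepted <- accepted + length(take)
    }
    if (accepted >= n_trios) break
    if (attempts >= max_attempts) {
      stop(sprintf(paste0("ascertainment failed: %d of %d trios accepted ",
                          "after %d attempts (acceptance ~ %.2g)"),
                   accepted, n_trios, attempts, accepted / attempts))
    }
  }
  dos_c <- do.call(rbind, kept_c)
  dos_f <- do.call(rbind, kept_f)
  dos_m <- do.call(rbind, kept_m)
  tfm <- do.call(rbind, kept_tf)
  tmm <- do.call(rbind, kept_tm)

  child_id <- paste0("C", seq_len(n_trios))
  father_id <- paste0("F", seq_len(n_trios))
  mother_id <- paste0("M", seq_len(n_trios))

  tr <- data.frame(
    child = child_id, father = father_id, mother = mother_id,
    child_affected = TRUE,
    father_affected = kept_lf > scenario$threshold,
    mother_affected = kept_lm > scenario$threshold,
    stringsAsFactors = FALSE
  )

  if (duo_rate > 0) {
    mask <- stats::runif(n_trios) < duo_rate
    which_parent <- stats::runif(n_trios) < 0.5 # TRUE -> mask father
    drop_f <- mask & which_parent
    drop_m <- mask & !which_parent
    tr$father[drop_f] <- NA
    tr$father_affected[drop_f] <- NA
    tfm[drop_f, ] <- NA
    tr$mother[drop_m] <- NA
    tr$mother_affected[drop_m] <- NA
    tmm[drop_m, ] <- NA
  } else {
    drop_f <- drop_m <- rep(FALSE, n_trios)
  }

  dos <- rbind(dos_c,
               dos_f[!drop_f, , drop = FALSE],
               dos_m[!drop_m, , drop = FALSE])
  rownames(dos) <- c(child_id, father_id[!drop_f], mother_id[!drop_m])
  meta <- .snp_metadata(scenario)
  colnames(dos) <- meta$snp
  rownames(tfm) <- rownames(tmm) <- child_id
  colnames(tfm) <- colnames(tmm) <- meta$snp

  panel <- genotype_panel(meta, dos)
  trios <- trio_set(tr, panel, transmit_father = tfm, transmit_mother = tmm)
  list(panel = panel, trios = trios)
}

#' Simulate phenotypes, covariates and affection status for a panel
#'
#' Builds the quantitative phenotype
#' `Y = baseline + gamma * std(G_L) + c_Y * U + sum(reverse_betas * g) +
#'  covariate effects + N(0, pheno_sd^2)`
#' where `G_L = sum(liability_betas * g)` is standardized by its analytic
#' population moments, and `U = sum(confounder_betas * g) + N(0, 1)` is the
#' shared confounder. The same `U` realization feeds the liability
#' `L = G_L + c_L * U + reverse_effect * sum(reverse_betas * g) + N(0,
#' env_sd^2)`, whose threshold exceedance defines the `affected` column, so
#' confounding acts on trait and phenotype jointly. Covariates are sex
#' (Bernoulli 0.5), age (N(15.5, 0.3) years, a mid-adolescence clinic visit),
#' height (162 + 12 * sex + N(0, 7) cm) and four standard-normal principal
#' components.
#'
#' @param scenario A [sim_scenario()].
#' @param panel A [genotype_panel()] generated under the same scenario.
#' @param seed Seed; defaults to the scenario seed.
#' @return A [pheno_table()] with columns `sample`, `phenotype`, `sex`,
#'   `age`, `height`, `pc1`..`pc4`, plus the latent `liability` and the
#'   derived `affected` flag for downstream case-control sampling.
#' @export
simulate_phenotypes <- function(scenario, panel, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"), inherits(panel, "genotype_panel"))
  if (ncol(panel$dosage) != scenario$m_snps) {
    stop("panel SNP count does not match the scenario")
  }
  set.seed(.sub_seed(seed, "phenotypes"))
  dos <- panel$dosage
  if (anyNA(dos)) { # latent construction uses expected dosage for gaps
    for (j in which(colSums(is.na(dos)) > 0)) {
      dos[is.na(dos[, j]), j] <- 2 * panel$snps$eaf[j]
    }
  }
  n <- nrow(dos)
  g_score <- as.numeric(dos %*% scenario$liability_betas)
  g_std <- if (scenario$sd_score > 0) {
    (g_score - scenario$mean_score) / scenario$sd_score
  } else {
    numeric(n)
  }
  u <- as.numeric(dos %*% scenario$confounder_betas) - scenario$mean_u +
    stats::rnorm(n)
  y_g <- as.numeric(dos %*% scenario$reverse_betas) - scenario$mean_rev

  liability <- (g_score - scenario$mean_score) +
    scenario$confounder_effect[["liability"]] * u +
    scenario$reverse_effect * y_g +
    stats::rnorm(n, 0, scenario$env_sd)

  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::rnorm(n, 15.5, 0.3)
  height <- 162 + 12 * sex + stats::rnorm(n, 0, 7)
  pcs <- matrix(stats::rnorm(4 * n), n, 4)
  ce <- scenario$covariate_effects

  phenotype <- scenario$baseline_mm +
    scenario$gamma * g_std +
    scenario$confounder_effect[["phenotype"]] * u +
    y_g +
    ce$sex * sex + ce$age * (age - 15.5) + ce$height * (height - 168) +
    as.numeric(pcs %*% ce$pc) +
    stats::rnorm(n, 0, scenario$pheno_sd)

  pheno_table(data.frame(
    sample = rownames(dos), phenotype = phenotype,
    sex = sex, age = age, height = height,
    pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3], pc4 = pcs[, 4],
    liability = liability,
    affected = liability > scenario$threshold,
    stringsAsFactors = FALSE
  ))
}
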