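# Generative scenario on the liability scale.
#
# A scenario fully parameterizes the simulator: SNP allele frequencies and LD
# block structure, per-SNP additive effects on a standard-normal liability,
# the liability threshold (or equivalently the population prevalence), a
# causal effect of the standardized genetic liability score on a quantitative
# phenotype, an optional genetically-loaded confounder affecting both
# liability and phenotype, and optional SNPs acting directly on the phenotype
# with a feedback path into liability (reverse causation).

#' Define a generative liability-threshold scenario
#'
#' Encodes everything the simulator needs: a dichotomous trait arises when a
#' latent liability `L` (additive genetic score plus a confounder path, a
#' reverse-causal path, and Gaussian noise) exceeds a threshold `T`; a
#' quantitative phenotype `Y` (in mm) receives a causal contribution `gamma`
#' per standard deviation of the genetic liability score, a confounder
#' contribution, direct SNP effects (`reverse_betas`) and covariate effects.
#'
#' The liability is standardized by construction: unless `env_sd` is supplied,
#' the residual liability SD is chosen as `sqrt(1 - var(genetic + confounder
#' components))` so that `var(L) = 1` and the threshold can be parameterized
#' by a prevalence `K` through `T = qnorm(1 - K)`.
#'
#' LD is block-wise: SNPs inside a block are generated by copying a latent
#' block haplotype with a per-site mutation probability calibrated so the
#' pairwise dosage correlation squared matches the block's target `r2` (see
#' [simulate_genotypes()]). SNPs within a block must share an allele
#' frequency; blocks are mutually independent.
#'
#' @param m_snps Number of SNPs.
#' @param maf Per-SNP effect-allele frequency, recycled to `m_snps`. The
#'   closed interval `[0, 1]` is allowed; 0 and 1 give degenerate monomorphic
#'   columns.
#' @param ld_blocks Optional `data.frame(size, r2)`; consecutive SNPs are
#'   grouped into blocks of the given sizes with within-block target dosage
#'   `r2`. Sizes must sum to at most `m_snps`; remaining SNPs are independent.
#' @param liability_betas Per-SNP additive effect on liability (liability SD
#'   units per effect allele).
#' @param prevalence Population prevalence `K`; the threshold is
#'   `qnorm(1 - K) * sd(L)`. Supply either this or `threshold`, not both.
#' @param threshold Liability threshold `T` on the liability scale.
#' @param env_sd Residual liability SD. Default `NULL` solves
#'   `sqrt(1 - var(non-residual components))` so `var(L) = 1`.
#' @param gamma Causal effect of the standardized genetic liability score on
#'   the phenotype (mm per liability-score SD).
#' @param confounder_effect Length-2 numeric `(effect on liability, effect on
#'   phenotype)` scaling a shared confounder `U`.
#' @param confounder_betas Per-SNP loadings on the genetic part of the
#'   confounder `U = sum(u_j g_j) + N(0, 1)`.
#' @param reverse_betas Per-SNP direct effects on the phenotype (mm per
#'   allele), the instruments for the reverse direction.
#' @param reverse_effect Feedback of the genetic phenotype component
#'   `sum(reverse_betas * g)` into liability (liability units per mm),
#'   nonzero in reverse-causation scenarios.
#' @param covariate_effects Named list with elements `sex` (mm), `age`
#'   (mm/year), `height` (mm/cm) and `pc` (length-4, mm per PC unit) giving
#'   covariate effects on the phenotype.
#' @param baseline_mm Phenotype intercept in mm.
#' @param pheno_sd Residual phenotype SD in mm.
#' @param missing_rate Probability that a population dosage is masked missing.
#' @param seed Integer seed; all randomness in the simulator flows from it
#'   through a documented label-based splitting scheme.
#' @return An object of class `sim_scenario` with derived analytic quantities:
#'   `var_genetic` (variance of all genetic liability components),
#'   `h2` (liability-scale heritability), `sd_score`/`mean_score` (moments of
#'   the genetic liability score `G_L = sum(beta_j g_j)`), `var_liability`,
#'   and the resolved `threshold` and `prevalence`.
#' @seealso [simulate_genotypes()], [simulate_trios()], [simulate_phenotypes()]
#' @examples
#' sc <- sim_scenario(m_snps = 10, maf = 0.3,
#'                    liability_betas = rep(0.2, 10), prevalence = 0.01)
#' sc$h2
#' @export
sim_scenario <- function(m_snps,
                         maf = 0.3,
                         ld_blocks = NULL,
                         liability_betas = numeric(m_snps),
                         prevalence = NULL,
                         threshold = NULL,
                         env_sd = NULL,
                         gamma = 0,
                         confounder_effect = c(0, 0),
                         confounder_betas = numeric(m_snps),
                         reverse_betas = numeric(m_snps),
                         reverse_effect = 0,
                         covariate_effects = list(sex = 0.5, age = 0.05,
                                                  height = 0.01,
                                                  pc = c(0, 0, 0, 0)),
                         baseline_mm = 10,
                         pheno_sd = 1.2,
                         missing_rate = 0,
                         seed = 1L) {
  m_snps <- as.integer(m_snps)
  if (m_snps < 1) stop("m_snps must be >= 1")
  maf <- rep_len(as.numeric(maf), m_snps)
  if (any(!is.finite(maf)) || any(maf < 0) || any(maf > 1)) {
    stop("maf must be finite and inside [0, 1]")
  }

  blocks <- .resolve_blocks(ld_blocks, m_snps, maf)

  liability_betas <- rep_len(as.numeric(liability_betas), m_snps)
  confounder_betas <- rep_len(as.numeric(confounder_betas), m_snps)
  reverse_betas <- rep_len(as.numeric(reverse_betas), m_snps)
  for (v in list(liability_betas, confounder_betas, reverse_betas,
                 gamma, confounder_effect, reverse_effect)) {
    if (any(!is.finite(v))) stop("all effect parameters must be finite")
  }
  if (length(confounder_effect) != 2) {
    stop("confounder_effect must be length 2: (effect on liability, effect on phenotype)")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (pheno_sd <= 0) stop("pheno_sd must be > 0")

  c_l <- confounder_effect[[1]]
  c_y <- confounder_effect[[2]]

  # Total per-SNP loading on liability through all genetic paths.
  eff <- liability_betas + c_l * confounder_betas + reverse_effect * reverse_betas
  var_genetic <- .quad_form(eff, maf, blocks)
  sd_score <- sqrt(.quad_form(liability_betas, maf, blocks))
  mean_score <- sum(liability_betas * 2 * maf)

  # The confounder carries unit non-genetic variance by convention.
  var_nonresid <- var_genetic + c_l^2
  if (is.null(env_sd)) {
    if (var_nonresid >= 1) {
      stop(sprintf(paste0("non-residual liability variance is %.3f >= 1; ",
                          "reduce effect sizes or supply env_sd explicitly"),
                   var_nonresid))
    }
    env_sd <- sqrt(1 - var_nonresid)
  }
  if (!is.finite(env_sd) || env_sd <= 0) stop("env_sd must be > 0")
  var_liability <- var_nonresid + env_sd^2
  sd_liability <- sqrt(var_liability)

  if (!is.null(prevalence) && !is.null(threshold)) {
    stop("supply either prevalence or threshold, not both")
  }
  if (is.null(prevalence) && is.null(threshold)) prevalence <- 0.1
  if (is.null(threshold)) {
    if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
    threshold <- stats::qnorm(1 - prevalence) * sd_liability
  } else {
    prevalence <- stats::pnorm(threshold / sd_liability, lower.tail = FALSE)
  }

  ce <- covariate_effects
  ce$sex <- ce$sex %||% 0
  ce$age <- ce$age %||% 0
  ce$height <- ce$height %||% 0
  ce$pc <- rep_len(ce$pc %||% 0, 4)

  structure(list(
    m_snps = m_snps, maf = maf, blocks = blocks,
    liability_betas = liability_betas,
    threshold = threshold, prevalence = prevalence,
    env_sd = env_sd,
    gamma = gamma,
    confounder_effect = c(liability = c_l, phenotype = c_y),
    confounder_betas = confounder_betas,
    reverse_betas = reverse_betas,
    reverse_effect = reverse_effect,
    covariate_effects = ce,
    baseline_mm = baseline_mm, pheno_sd = pheno_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed),
    eff_loadings = eff,
    mean_eff = sum(eff * 2 * maf),
    mean_u = sum(confounder_betas * 2 * maf),
    mean_rev = sum(reverse_betas * 2 * maf),
    var_genetic = var_genetic,
    var_liability = var_liability,
    h2 = var_genetic / var_liability,
    sd_score = sd_score, mean_score = mean_score
  ), class = "sim_scenario")
}

# Expand the block specification to a per-SNP block id and per-block
# parameters; enforce equal allele frequency within multi-SNP blocks (the
# haplotype-copy generator needs it for exact marginal frequencies).
.resolve_blocks <- function(ld_blocks, m_snps, maf) {
  if (is.null(ld_blocks)) {
    return(data.frame(block = seq_len(m_snps), size = 1L, r2 = 1,
                      snp_index = seq_len(m_snps)))
  }
  ld_blocks <- as.data.frame(ld_blocks)
  .required_cols(ld_blocks, c("size", "r2"), "ld_blocks")
  sizes <- as.integer(ld_blocks$size)
  r2 <- as.numeric(ld_blocks$r2)
  if (any(sizes < 1)) stop("block sizes must be >= 1")
  if (sum(sizes) > m_snps) stop("block sizes sum to more than m_snps")
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop("block r2 must be finite and inside [0, 1]")
  }
  block_id <- c(rep(seq_along(sizes), sizes),
                seq(length(sizes) + 1L, length.out = m_snps - sum(sizes)))
  block_r2 <- c(r2, rep(1, m_snps - sum(sizes)))[block_id]
  out <- data.frame(block = block_id,
                    size = as.integer(ave(block_id, block_id, FUN = length)),
                    r2 = block_r2,
                    snp_index = seq_len(m_snps))
  for (b in unique(out$block[out$size > 1])) {
    p <- maf[out$snp_index[out$block == b]]
    if (length(unique(p)) > 1) {
      stop("SNPs within one LD block must share an allele frequency")
    }
  }
  out
}

# Variance of a weighted dosage sum a'g under the block-LD model:
# var(g_j) = 2 p q; within-block dosage correlation sqrt(r2); blocks
# independent.
.quad_form <- function(a, maf, blocks) {
  v <- 2 * maf * (1 - maf)
  total <- sum(a^2 * v)
  for (b in unique(blocks$block[blocks$size > 1])) {
    idx <- blocks$snp_index[blocks$block == b]
    r <- sqrt(blocks$r2[blocks$snp_index == idx[1]])
    s <- sqrt(v[idx])
    as_ <- a[idx] * s
    total <- total + r * (sum(as_)^2 - sum(as_^2))
  }
  total
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Liability-threshold scenario\n")
  cat(sprintf("  SNPs: %d (%d LD block(s)); seed %d\n",
              x$m_snps, length(unique(x$blocks$block)), x$seed))
  cat(sprintf("  liability h2 = %.3f, var(L) = %.3f, threshold T = %.3f (K = %.4g)\n",
              x$h2, x$var_liability, x$threshold, x$prevalence))
  cat(sprintf("  gamma = %.3f mm/SD, confounder (L, Y) = (%.3f, %.3f), reverse effect = %.3f\n",
              x$gamma, x$confounder_effect[1], x$confounder_effect[2],
              x$reverse_effect))
  invisible(x)
}
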