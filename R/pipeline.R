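# End-to-end bidirectional MR study on simulated data: canonical generative
# scenarios and the full pipeline (cohort -> case-control and quantitative
# GWAS -> instrument selection -> bidirectional MR -> scenario call).

#' Canonical generative scenarios for a bidirectional MR study
#'
#' Builds a [sim_scenario()] representing one of three data-generating
#' mechanisms for the overlap between a dichotomous trait's genetic
#' liability and a quantitative phenotype:
#'
#' * `"A"` (liability subphenotype): the liability score causally shifts the
#'   phenotype (`gamma` mm per score SD); no confounding, no reverse path.
#' * `"B"` (confounded): no causal path (`gamma = 0`); half of the
#'   trait-associated SNPs also load on a shared confounder that affects
#'   both liability and phenotype, so their phenotype effects are
#'   heterogeneous relative to their liability effects.
#' * `"C"` (bidirectional): scenario A plus a set of SNPs acting directly on
#'   the phenotype whose genetic component feeds back into liability.
#'
#' All three share the same marker layout: `n_instruments` trait SNPs plus
#' `n_reverse` phenotype SNPs (inert outside scenario C), all independent,
#' with allele frequency `maf`. Defaults give a liability-scale SNP
#' architecture of modest per-allele effects (h2 about 0.12 over the
#' instruments) and a trait prevalence of 0.1, sized so that a cohort of a
#' few tens of thousands yields well-powered instruments on both sides.
#'
#' @param type `"A"`, `"B"` or `"C"`.
#' @param n_instruments Trait-associated SNPs.
#' @param n_reverse Phenotype-associated SNPs (reverse instruments).
#' @param maf Shared allele frequency.
#' @param beta Per-allele liability effect of trait SNPs.
#' @param gamma Causal effect (mm per liability-score SD; scenarios A and C).
#' @param confounder_loading Per-SNP confounder loading (scenario B).
#' @param reverse_beta Per-allele direct phenotype effect of reverse SNPs
#'   (scenario C).
#' @param reverse_effect Feedback of the genetic phenotype component into
#'   liability (scenario C).
#' @param prevalence Trait prevalence.
#' @param seed Scenario seed.
#' @return A `sim_scenario` with a `study_type` attribute.
#' @export
mr_study_scenario <- function(type = c("A", "B", "C"),
                              n_instruments = 20, n_reverse = 4,
                              maf = 0.3, beta = 0.12, gamma = -0.11,
                              confounder_loading = 0.1,
                              reverse_beta = 0.15, reverse_effect = 0.3,
                              prevalence = 0.1, seed = 1L) {
  type <- match.arg(type)
  m <- n_instruments + n_reverse
  lb <- c(rep(beta, n_instruments), rep(0, n_reverse))
  cb <- rep(0, m)
  rb <- rep(0, m)
  ga <- gamma
  ce <- c(0, 0)
  re <- 0
  if (type == "B") {
    ga <- 0
    half <- seq_len(floor(n_instruments / 2))
    cb[half] <- confounder_loading
    ce <- c(0.5, 0.7) # confounder affects liability and phenotype jointly
  }
  if (type == "C") {
    rb[n_instruments + seq_len(n_reverse)] <- reverse_beta
    re <- reverse_effect
  }
  sc <- sim_scenario(m_snps = m, maf = maf,
                     liability_betas = lb,
                     confounder_betas = cb, confounder_effect = ce,
                     reverse_betas = rb, reverse_effect = re,
                     gamma = ga, prevalence = prevalence, seed = seed)
  attr(sc, "study_type") <- type
  sc
}

#' Run a bidirectional MR study on a simulated cohort
#'
#' The full pipeline on one simulated population cohort:
#' 1. draw genotypes and phenotypes (with affection status) for `n` samples;
#' 2. case-control GWAS of the trait and covariate-adjusted quantitative
#'    GWAS of the phenotype on the same cohort;
#' 3. forward instruments: trait GWAS hits at `p_instrument`, LD-clumped at
#'    `r2 < 0.1` within 250 kb; reverse instruments: phenotype GWAS hits at
#'    `p_instrument`, clumped at `r2 < 0.001` within 500 kb;
#' 4. harmonization, forward IVW + MR-Egger, reverse IVW, Steiger
#'    directionality (observed-scale variance explained for the binary
#'    side); reverse instruments are Steiger-filtered, dropping SNPs that
#'    explain no more variance in the phenotype than in the trait (such
#'    SNPs are primary trait instruments leaking through the phenotype
#'    GWAS, not phenotype instruments);
#' 5. scenario classification with [classify_scenario()].
#'
#' @param scenario A [sim_scenario()], typically from [mr_study_scenario()].
#' @param n Cohort size.
#' @param seed Seed for the cohort draw.
#' @param p_instrument Instrument selection p-value threshold.
#' @param alpha Shared decision threshold for the classifier.
#' @return List of class `bidirectional_study`: `forward_ivw`,
#'   `forward_egger`, `reverse_ivw`, `steiger`, `call`, plus the instrument
#'   counts `n_forward`, `n_reverse`.
#' @export
bidirectional_study <- function(scenario, n = 20000, seed = scenario$seed,
                                p_instrument = 5e-8, alpha = 0.05) {
  panel <- simulate_genotypes(scenario, n, seed = seed)
  pheno <- simulate_phenotypes(scenario, panel, seed = seed)
  cc <- run_case_control(panel, pheno$affected)
  qg <- run_quant_gwas(panel, pheno)
  ld <- ld_from_panel(panel)

  fwd_sel <- clump(cc, ld, r2_max = 0.1, window_kb = 250, p_max = p_instrument)
  rev_sel <- clump(qg, ld, r2_max = 0.001, window_kb = 500, p_max = p_instrument)

  forward_ivw <- forward_egger <- reverse_ivw <- steiger <- NULL
  n_cc <- cc$n[1]
  n_qg <- qg$n[1]
  if (nrow(fwd_sel) >= 2) {
    fwd <- harmonize(fwd_sel, qg)
    forward_ivw <- mr_ivw(fwd)
    if (nrow(fwd) >= 3) forward_egger <- mr_egger(fwd)
    steiger <- mr_steiger(fwd, n_exposure = n_cc, n_outcome = n_qg)
  }
  if (nrow(rev_sel) >= 1) {
    rev <- harmonize(rev_sel, cc)
    # Steiger filter: keep SNPs explaining more variance in the phenotype
    # (their exposure here) than in the trait.
    r2_ph <- (rev$bx / rev$se_bx)^2 /
      ((rev$bx / rev$se_bx)^2 + n_qg - 2)
    r2_tr <- (rev$by / rev$se_by)^2 /
      ((rev$by / rev$se_by)^2 + n_cc - 2)
    rev <- rev[r2_ph > r2_tr, , drop = FALSE]
    if (nrow(rev) >= 1) reverse_ivw <- mr_ivw(rev)
  }
  call <- if (is.null(forward_ivw)) {
    structure(list(label = "null", forward_signif = FALSE, homogeneous = NA,
                   intercept_null = NA, reverse_signif = NA,
                   steiger_forward = NA,
                   narrative = "no usable forward instruments"),
              class = "scenario_call")
  } else {
    classify_scenario(forward_ivw, forward_egger, reverse_ivw, steiger,
                      alpha_effect = alpha, alpha_heterogeneity = alpha,
                      alpha_pleiotropy = alpha)
  }
  structure(list(forward_ivw = forward_ivw, forward_egger = forward_egger,
                 reverse_ivw = reverse_ivw, steiger = steiger, call = call,
                 n_forward = nrow(fwd_sel), n_reverse = nrow(rev_sel)),
            class = "bidirectional_study")
}

#' @export
print.bidirectional_study <- function(x, ...) {
  cat(sprintf("Bidirectional MR study (%d forward / %d reverse instruments)\n",
              x$n_forward, x$n_reverse))
  if (!is.null(x$forward_ivw)) { cat("forward  "); print(x$forward_ivw) }
  if (!is.null(x$reverse_ivw)) { cat("reverse  "); print(x$reverse_ivw) }
  if (!is.null(x$steiger)) print(x$steiger)
  print(x$call)
  invisible(x)
}
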