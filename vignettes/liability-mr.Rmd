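---
title: "Liability, polygenic scores and bidirectional Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability, polygenic scores and bidirectional Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`liabmr` is a toolkit for a recurring study design in the genetics of
dichotomous traits: a binary condition (the motivating case is a
non-syndromic orofacial cleft) is modelled on the liability scale, its
common-variant architecture is estimated from ascertained families and
case-control panels, a polygenic risk score (PRS) built from those summary
statistics is tested against quantitative phenotypes in the general
population (facial distances measured in mm), and bidirectional two-sample
Mendelian randomization (MR) decides whether an observed PRS-phenotype
overlap reflects liability causally shifting the phenotype, confounding, or
reverse causation. Every stage is implemented against a generative simulator
so the whole pipeline is testable without any genotype download.

## The liability-threshold model

Each individual carries a latent liability

$$L = \sum_j \beta_j g_j \;+\; c_L U \;+\; \eta\, Y_g \;+\; e,
\qquad e \sim N(0, \sigma_e^2),$$

where $g_j \in \{0,1,2\}$ are allele dosages, $U$ is a shared confounder
(genetic loadings $u_j$ plus unit-variance noise), $Y_g = \sum_j
\rho_j g_j$ is the genetic component of the phenotype with $\eta$ its
feedback into liability (zero outside reverse-causation scenarios), and the
trait occurs when $L > T$. All genetic components are analytically
mean-centred, and by default $\sigma_e$ is solved so that
$\mathrm{Var}(L) = 1$; the threshold can then be given directly or through a
prevalence $K$ as $T = \Phi^{-1}(1-K)$. The quantitative phenotype is

$$Y = \mu + \gamma\,\frac{G_L - \mathbb{E}G_L}{\mathrm{SD}(G_L)}
      + c_Y U + Y_g + \text{covariates} + \varepsilon,$$

with $G_L = \sum_j \beta_j g_j$, so `gamma` is interpreted in mm per
population SD of the genetic liability score. Covariates (sex, age at a
mid-adolescence clinic visit, height, four principal components) are
generated with modest default effects so covariate adjustment is exercised,
not decorative.

### LD and genotypes

LD is block-wise. All SNPs in a block copy a latent pair of anchor
haplotypes, each haploid allele retained with probability $1-\mu$ and
otherwise redrawn from the block's allele frequency. Two SNPs share only the
anchor, so their haploid (and dosage) correlation is $(1-\mu)^2$ and

$$\mu = 1 - r_2^{1/4}$$

calibrates the pairwise dosage $r^2$ to the block target. This requires a
common allele frequency within a block (validated at construction) and makes
every within-block pair exchangeable. It reproduces what clumping and
proxy lookup need — realistic block LD — and nothing more: no recombination
gradients, no X chromosome, no ancestry structure beyond simulated PCs.
Analytic variances of weighted dosage sums (used to standardize liability)
include the within-block covariances $\sqrt{r^2}\,2pq$.

### Trios and ascertainment

Parents are drawn from the population model; each parent transmits one
allele per SNP, `Bernoulli(dosage/2)` from the unphased dosage, and the
child's dosage is the sum. Trios are rejection-sampled until the child's
liability exceeds $T$; parents keep their own affection flags. The
transmitted allele of each parent is recorded on the trio set, so the
transmission disequilibrium test counts transmissions exactly instead of
reconstructing them from genotype configurations, and duos are made by
masking one parent (the masked parent simply contributes no transmissions).
A single integer seed drives everything through a label-based splitting
scheme; identical scenario + seed gives byte-identical output.

## Association engines and meta-analysis

`run_tdt` tallies transmissions $b$ and non-transmissions $c$ of the effect
allele from heterozygous parents, with $\chi^2 = (b-c)^2/(b+c)$ on 1 df and
an allelic log odds ratio $\ln(b/c)$, $\mathrm{se} = \sqrt{1/b + 1/c}$
(0.5 continuity correction, flagged, when a count is zero) — so TDT output
pools directly with case-control log odds ratios. `run_case_control` is the
allelic 2x2 test with Haldane-Anscombe correction. `run_quant_gwas` is exact
covariate-adjusted OLS via a single QR factorization of the covariate design
(Frisch-Waugh residualization per SNP), complete-case in phenotype and
covariates, missing dosages mean-imputed to `2*eaf`. `meta_analyse` is
fixed-effect inverse-variance pooling in the METAL effect/SE convention with
per-SNP Cochran's Q and $I^2$, after harmonizing alleles across studies
(sign flips for swapped alleles, strand complementing where unambiguous);
genome-wide significance is flagged at $5\times10^{-8}$. A helper
`ci_to_se` recovers standard errors from printed 95% CIs
(width / $2 \times 1.959964$), which is how the two published cohort PRS
estimates are pooled in the worked example.

## Polygenic scores, the pTDT and threshold selection

`compute_prs` aligns dosages to each weight's effect allele (flipping to
`2 - dose` for swapped orientations) and standardizes over the scored
sample; effects downstream are reported per SD of the score. The polygenic
TDT normalizes the child-minus-midparent score deviation by the SD of
mid-parent scores in the analyzed trios and applies a one-sample t-test —
the convention of the original pTDT. `select_threshold` clumps the
discovery statistics at `r2 < 0.1` within 250 kb, scores trios at each
candidate p-value threshold, and picks the threshold with the largest pTDT
t statistic; "most predictive" is formalized as the maximal t (equivalently
minimal p with positive deviation), since a directionless criterion would
reward under-transmission equally. Trios with an affected or missing parent
are excluded.

### Power: minimum detectable genetic correlation

The smallest score-phenotype correlation detectable at $(\alpha,
\text{power}, n)$ is the Fisher-z closed form
$r_{\min} = \tanh\!\big((z_{1-\alpha/2} + z_{\text{power}})/\sqrt{n-3}\big)$
(0.046 at $n = 3707$). An optional second stage maps $r_{\min}$ to a
minimum genetic covariance under a bivariate-normal effect model: each of
$m$ SNPs carries standardized effects with variance $h_1^2/(m\pi_1)$,
discovery estimates add sampling variance $1/n_d$, and SNPs enter the score
when they pass the discovery threshold. Writing $E_2(v, c)$ for
$\mathbb{E}[X^2; |X|>c]$ of an $N(0, v)$ variable,

$$\mathrm{corr}(S, Y_2) =
  \sigma_{12}\,\frac{E_2(\tau^2+s^2,\,c)}{(\tau^2+s^2)\,
  \sqrt{m\,[\pi_1 E_2(\tau^2+s^2,c) + (1-\pi_1)E_2(s^2,c)]}},$$

inverted for $\sigma_{12}$ and divided by $\sqrt{h_1^2 h_2^2}$ for the
genetic correlation. With no selection this collapses to
$r_{\min}\sqrt{h_1^2 + m/n_d}$, which the tests assert. The binary-trait
variance explained is kept on the observed scale throughout and flagged as
an approximation; no liability-scale transformation is attempted.

## The MR suite

All estimators use first-order weights (the ratio variance ignores the
exposure-side SE), the default of the standard two-sample MR toolkits; the
exposure SE still feeds the parametric bootstrap. `harmonize` matches by
SNP id, substitutes the best LD proxy above `r2 = 0.9` for missing outcome
SNPs, aligns outcome effects to the exposure effect allele, and resolves
palindromic SNPs by allele frequency with an ambiguity zone of
(0.42, 0.58). IVW is weighted through-origin regression with fixed-effect
SE reported as primary and the multiplicative random-effects SE
(`fixed * max(1, sqrt(Q/(n-1)))`) alongside — the data motivating this
package were homogeneous (Q p of 0.36), but both are always computed.
MR-Egger orients `bx >= 0`, fits a weighted intercept model, and scales both
SEs by `max(1, sqrt(Q_res/(n-2)))` with t-based p-values on `n - 2` df.
The weighted median interpolates the standardized cumulative weight ladder
at 0.5; the weighted mode maximizes an inverse-variance-weighted Gaussian
KDE with the modified Silverman bandwidth `0.9 min(sd, mad) n^(-1/5)`
(coarse grid plus local refinement to optimizer precision). Both bootstrap
their SEs parametrically with a mandatory seed. The Steiger test compares
instrument variance explained per side via Fisher's z, with per-SNP
$r^2 \approx z^2/(z^2 + n - 2)$.

One numerical consequence of the `max(1, ...)` truncation deserves note:
under a *sharp* pleiotropy null (no pleiotropic variance at all) with
heterogeneous instrument precision the Egger intercept test is conservative
(type-I error near 2.5-3%), because the truncation only ever inflates the
SE. Under balanced pleiotropy with homogeneous instrument precision — the
regime the test is meant to police, where residual dispersion is real — the
multiplicative t-test is exact and the measured type-I error sits at the
nominal 5%. The null-calibration suite therefore uses the balanced
design.

## Interpreting bidirectional MR

`classify_scenario` formalizes a qualitative decision framework into a
decision table over five booleans (forward effect, homogeneity, Egger
intercept, reverse effect, Steiger direction), with all three alpha
thresholds configurable and defaulting to 0.05:

| forward | Q heterogeneity | reverse | call |
|---|---|---|---|
| absent | — | — | null |
| present | heterogeneous | — | B (confounded) |
| present | homogeneous | absent | A (liability subphenotype) |
| present | homogeneous | present | C (bidirectional; Steiger appended) |

A significant Egger intercept downgrades A or C to B, since directional
pleiotropy undermines the single-liability-pathway reading. A missing
reverse analysis or Steiger test is reported as unavailable, never treated
as evidence. The alpha-based formalization of "weak evidence" is this
package's choice; the source framework is qualitative.

`bidirectional_study` runs the whole loop on one simulated cohort:
case-control GWAS of the trait and covariate-adjusted GWAS of the phenotype
on the same panel, instrument selection at $5\times10^{-8}$ (forward clump
`r2 < 0.1`/250 kb; reverse clump `r2 < 0.001`/500 kb), harmonization, IVW +
Egger forward, IVW reverse, Steiger, classification. Reverse instruments
are Steiger-filtered: a SNP that explains no more variance in the phenotype
than in the trait is a trait instrument leaking through the phenotype GWAS,
not a phenotype instrument, and is removed — without this, strong trait
SNPs occasionally reach genome-wide significance in the phenotype GWAS and
masquerade as reverse evidence.

### Canonical scenarios and their calibration

`mr_study_scenario` fixes the three generative mechanisms used throughout
the tests: 20 trait SNPs (MAF 0.3, liability effect 0.12 per allele,
liability $h^2 \approx 0.12$ over the instruments) plus 4 phenotype SNPs;
`gamma = -0.11` mm per score SD in scenarios A and C; scenario B instead
routes half the trait SNPs through a shared confounder (loadings 0.1,
confounder effects 0.5 on liability and 0.7 on phenotype), producing
heterogeneous per-SNP ratios with no causal path; scenario C adds direct
phenotype effects of 0.15 mm per allele feeding back into liability with
coefficient 0.3. The trait prevalence is 0.1: the source design used
heavily ascertained cases against a rare (~1 per 700) condition, which a
population cohort of 20,000 cannot reproduce; a 10% prevalence yields a
case-control arm of comparable power and is stated here once as the study
condition for all simulation-based checks. Phenotype residual SD is 1.2 mm
with a 10 mm baseline, the scale of a philtrum-width-like facial distance.

At these conditions the pipeline recovers the generating scenario label in
roughly 82-85% of replicates. The misclassifications are almost entirely
downgrades to B: measurement noise in the exposure-side effects inflates
Cochran's Q beyond its nominal distribution under first-order weights, and
the Egger intercept contributes its nominal false-positive rate. That is a
property of the estimators as defined, not of the simulator, and is left
visible rather than tuned away.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations as: cohorts
of 20,000 (50,000 for prevalence calibration), 200 replicates for IVW
coverage, 100 replicates for scenario classification, 500-1000 replicates
for type-I error rates, 5000 SNPs for genome-wide null uniformity, and
2000 ascertained trios at prevalence 0.001 with $h^2 = 0.3$ for pTDT power.
Oracle-equivalence checks run at tolerance `1e-9` (`1e-6` against the
dense-grid KDE maximizer). Degenerate inputs are flagged rather than
dropped: monomorphic SNPs, zero transmission counts, constant dosages,
exact fits and zero-variance scores all carry explicit flags, and ties in
clumping are broken by ascending (chr, bp).

## What passing tests do and do not show

The simulator emulates the statistical structure the analysis assumes —
Hardy-Weinberg dosages, exchangeable block LD, additive liability,
Gaussian phenotype residuals, MCAR missingness. Real data violate most of
these in detail: imputation uncertainty, differential missingness,
population stratification beyond four PCs, assortative mating, non-additive
architecture, and ascertainment schemes richer than a sharp liability
threshold are all outside the generator. Green tests certify the machinery
(estimators match their definitions, calibrations hold under the assumed
model), not the robustness of any real-data conclusion. The published
real-data quantities that require accessioned genotypes are deliberately
not reproduced here; the one in-paper computation repeated exactly is the
two-cohort fixed-effect pooling of the PRS-phenotype estimates from their
printed CIs.
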