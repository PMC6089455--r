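# Shared fixture builders: everything is generated in code at test time.

# Minimal panel from a dosage matrix; metadata defaults are editable.
make_panel <- function(dosage, ea = "A", oa = "G", eaf = NULL,
                       chr = 1L, bp = NULL) {
  m <- ncol(dosage)
  if (is.null(bp)) bp <- seq_len(m) * 1000
  if (is.null(eaf)) eaf <- colMeans(dosage, na.rm = TRUE) / 2
  snps <- data.frame(snp = paste0("rs", seq_len(m)), chr = chr, bp = bp,
                     ea = rep_len(ea, m), oa = rep_len(oa, m), eaf = eaf,
                     stringsAsFactors = FALSE)
  colnames(dosage) <- snps$snp
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  genotype_panel(snps, dosage)
}

# Quick summary-statistic rows.
make_stats <- function(snp, beta, se, p = NULL, ea = "A", oa = "G",
                       chr = 1L, bp = NULL, eaf = 0.3, n = 1000) {
  k <- length(snp)
  if (is.null(bp)) bp <- seq_len(k) * 1000
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  data.frame(snp = snp, chr = rep_len(chr, k), bp = bp,
             ea = rep_len(ea, k), oa = rep_len(oa, k),
             eaf = rep_len(eaf, k), beta = beta, se = se, p = p,
             n = rep_len(n, k), stringsAsFactors = FALSE)
}

# MR dataset straight from effect vectors.
make_mr_data <- function(bx, by, se_bx = 0.01, se_by = 0.1) {
  k <- length(bx)
  structure(data.frame(snp = paste0("rs", seq_len(k)),
                       bx = bx, se_bx = rep_len(se_bx, k),
                       by = by, se_by = rep_len(se_by, k),
                       ea = "A", oa = "G", eaf = 0.3,
                       n_x = 4000, n_y = 4000,
                       proxy = NA_character_, proxy_r2 = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("mr_dataset", "data.frame"))
}

# mr_result-shaped stub for the classifier tests.
stub_result <- function(p, q_p = NULL, intercept_p = NULL,
                        estimate = -0.1, se = 0.05) {
  out <- list(method = "stub", estimate = estimate, se = se,
              ci_lower = estimate - 1.96 * se, ci_upper = estimate + 1.96 * se,
              p = p, nsnp = 6L)
  if (!is.null(q_p)) { out$q <- 1; out$q_df <- 5L; out$q_p <- q_p }
  if (!is.null(intercept_p)) {
    out$intercept <- 0.01; out$intercept_se <- 0.01; out$intercept_p <- intercept_p
  }
  structure(out, class = "mr_result")
}
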