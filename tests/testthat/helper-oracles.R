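# Independent reference implementation of greedy p-ordered clumping used as
# an oracle: literal restatement of the rule, no shared code with clump().
oracle_clump <- function(stats, ld_df, r2_max, window_kb, p_max) {
  pool <- stats[!is.na(stats$p) & stats$p <= p_max, ]
  pool <- pool[order(pool$p, pool$chr, pool$bp), ]
  kept <- character(0)
  while (nrow(pool) > 0) {
    top <- pool[1, ]
    kept <- c(kept, top$snp)
    survives <- logical(nrow(pool))
    for (i in seq_len(nrow(pool))) {
      s <- pool[i, ]
      if (s$snp == top$snp) next
      if (s$chr != top$chr || abs(s$bp - top$bp) > window_kb * 1000) {
        survives[i] <- TRUE
        next
      }
      hit <- ld_df[(ld_df$snp_a == top$snp & ld_df$snp_b == s$snp) |
                     (ld_df$snp_b == top$snp & ld_df$snp_a == s$snp), ]
      r2 <- if (nrow(hit)) hit$r2[1] else 0
      survives[i] <- r2 < r2_max
    }
    pool <- pool[survives, ]
  }
  kept
}

# Random clumping instance shared by the unit and acceptance oracle checks.
random_clump_instance <- function(m) {
  s <- make_stats(paste0("rs", 1:m), beta = 1, se = 1,
                  p = runif(m, 1e-10, 1),
                  chr = sample(1:2, m, replace = TRUE),
                  bp = sort(sample(1:2000, m)) * 1000)
  s <- s[order(s$chr, s$bp), ]
  pairs <- t(combn(s$snp, 2))
  ld <- ld_table(data.frame(snp_a = pairs[, 1], snp_b = pairs[, 2],
                            r2 = sample(c(0, runif(nrow(pairs))),
                                        nrow(pairs), replace = TRUE)))
  list(stats = s, ld = ld)
}
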