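# Independent oracles and shared genotype fixtures.

# Brute-force two-sided exact test: enumerate every table with the observed
# margins via log-binomial coefficients (no dhyper), summing the point
# probabilities not exceeding the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  N <- m + n
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(1)
  }
  xs <- max(0, k - n):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(N, k)
  lobs <- lchoose(m, a) + lchoose(n, c) - lchoose(N, k)
  min(1, sum(exp(logp[logp <= lobs + log1p(1e-7)])))
}

# Standard plant material used across tests.
repulsion_het <- function(r = 0.06) {
  plant_genotype("Tcb1-s", "tcb1", su1 = c("Su1", "su1"), r = r)
}
donor_tcb1_purple <- function() {
  plant_genotype("tcb1", "tcb1", r1 = c("R1-sc", "R1-sc"))
}
donor_tester_yellow <- function() {
  plant_genotype("Tcb1-s", "Tcb1-s", r1 = c("r1-r", "r1-r"))
}

# Build a long-format Ct table with given per-biological-replicate relative
# expression values for one line (reference at baseline, no noise).
ct_table_from_bio_levels <- function(line, levels, baseline = 20) {
  rows <- lapply(seq_along(levels), function(b) {
    data.frame(
      sample_id = sprintf("%s_b%d_t%d_%s", line, b, rep(1:3, 2),
                          rep(c("tgt", "ref"), each = 3)),
      line_name = line,
      gene = rep(c("target", "reference"), each = 3),
      biological_rep = b,
      technical_rep = rep(1:3, 2),
      ct = c(rep(baseline - log2(levels[b]), 3), rep(baseline, 3)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
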