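library(pupilql)
set.seed(99)
n_sim <- 500
fwe <- 0L
sizes <- integer(0)
for (s in seq_len(n_sim)) {
  mat <- matrix(rnorm(34 * 70), 34, 70)
  ct <- cluster_permutation_test(mat, n_perm = 500, seed = s)
  if (any(ct$clusters$p_corrected < 0.05)) fwe <- fwe + 1L
}
cat("fwe:", fwe / n_sim, "\n")
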