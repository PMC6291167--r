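library(testthat); library(pupilql)
test_that("repro", {
  set.seed(99)
  fwe <- 0L
  for (s in 1:500) {
    mat <- matrix(rnorm(34 * 70), 34, 70)
    ct <- cluster_permutation_test(mat, n_perm = 500, seed = s)
    if (any(ct$clusters$p_corrected < 0.05)) fwe <- fwe + 1L
  }
  cat("fwe in test_that:", fwe/500, "\n")
  expect_true(TRUE)
})
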