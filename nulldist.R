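library(pupilql)
set.seed(1)
# distribution of the max cluster size under the true null (iid normal)
maxes <- integer(2000)
tcrit <- qt(0.975, 33)
for (s in 1:2000) {
  mat <- matrix(rnorm(34*70), 34, 70)
  tv <- colMeans(mat)/(apply(mat,2,sd)/sqrt(34))
  r <- rle(abs(tv) > tcrit)
  m <- r$lengths[r$values]
  maxes[s] <- if (length(m)) max(m) else 0L
}
print(table(maxes)/2000)
for (m in 1:6) cat("P(max >=", m, ") =", mean(maxes >= m), "\n")
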