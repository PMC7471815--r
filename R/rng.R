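## Seeded RNG primitives shared (draw-for-draw) by the R rules and the C++
## engine. Every stochastic decision in the simulator reduces to uniform
## variates consumed one at a time, so a given seed yields one fixed event
## stream regardless of which implementation executes it.

# Fisher-Yates permutation of 1..n; consumes n-1 uniforms (none for n < 2).
fy_permute <- function(n) {
  perm <- seq_len(n)
  if (n >= 2L) {
    for (i in n:2L) {
      j <- 1L + floor(runif(1) * i)
      tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
    }
  }
  perm
}

# Uniform sample of k of 1..K without replacement (partial Fisher-Yates);
# consumes exactly k uniforms.
fy_select <- function(K, k) {
  idx <- seq_len(K)
  if (k > K) k <- K
  for (i in seq_len(k)) {
    j <- i + floor(runif(1) * (K - i + 1L))
    tmp <- idx[i]; idx[i] <- idx[j]; idx[j] <- tmp
  }
  idx[seq_len(k)]
}

# One index uniform on 1..k; always consumes one uniform (k >= 1).
pick_one <- function(k) {
  1L + as.integer(floor(runif(1) * k))
}
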