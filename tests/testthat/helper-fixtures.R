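# Shared fixtures and independent oracles.

# triple-loop evaluation of the topological overlap formula, kept free of
# matrix algebra so it can serve as an independent oracle
brute_force_tom <- function(a) {
  n <- nrow(a)
  w <- diag(n)
  k <- rowSums(a) - diag(a)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l_ij <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l_ij <- l_ij + a[i, u] * a[u, j]
      }
      w[i, j] <- (l_ij + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  w
}

# exhaustive hypergeometric upper tail P(X >= k) by direct pmf summation
hyper_tail_bruteforce <- function(k, K, N, n) {
  xs <- max(k, 0):min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# small random symmetric adjacency in [0,1] with zero diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# compact synthetic dataset for unit tests: 3 small planted modules plus
# background, full design, quick to generate
small_dataset <- function(seed = 1, effect_size = 4, divergence_tp = 35,
                          noise_sd = 0.5) {
  mods <- list(
    list(module_id = "gonadA", n_genes = 25L, archetype = "gonad_forming"),
    list(module_id = "testisA", n_genes = 25L, archetype = "testis_specific"),
    list(module_id = "ovaryA", n_genes = 25L, archetype = "ovary_specific")
  )
  mods <- lapply(mods, function(m) {
    m$effect_size <- effect_size
    m$divergence_tp <- divergence_tp
    m
  })
  simulate_expression(modules = mods, n_background = 75L,
                      noise_sd = noise_sd, seed = seed)
}
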