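# Fixtures are generated in code; seeds fixed so failures reproduce.

rand_mm <- function(n_sites = 20, n_d = 10, n_n = 10, seed = 42,
                    sd_d = 1, sd_n = 1) {
  set.seed(seed)
  vals <- cbind(matrix(rnorm(n_sites * n_d, sd = sd_d), n_sites),
                matrix(rnorm(n_sites * n_n, sd = sd_n), n_sites))
  methyl_matrix(vals, rep(c(1L, 0L), c(n_d, n_n)))
}

# Independent step-up BH oracle: explicit double loop over the definition
# adj_i = min over j with p_(j) >= p_(i) of m * p_(j) / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Ordinary pooled two-sample t p-value per site of a deviation matrix.
pooled_t_p <- function(z) {
  zd <- z$z_values[, z$labels == 1L, drop = FALSE]
  zn <- z$z_values[, z$labels == 0L, drop = FALSE]
  vapply(seq_len(nrow(zd)), function(i)
    t.test(zd[i, ], zn[i, ], var.equal = TRUE)$p.value, numeric(1))
}
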