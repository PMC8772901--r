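# Small in-code fixtures shared across test files.

# a tiny deterministic count matrix: 4 genes x 8 samples (2 reps/type)
toy_count_matrix <- function() {
  counts <- matrix(
    c(10, 12, 20, 22, 30, 28, 40, 44,
      0, 0, 0, 0, 0, 0, 0, 0,
      100, 90, 10, 12, 55, 60, 50, 52,
      5, 6, 5, 7, 6, 5, 7, 6),
    nrow = 4, byrow = TRUE
  )
  sample_ids <- c("PC_1", "PC_2", "PB_1", "PB_2",
                  "F1BC_1", "F1BC_2", "F1CB_1", "F1CB_2")
  dimnames(counts) <- list(paste0("g", 1:4), sample_ids)
  type_map <- setNames(rep(c("PC", "PB", "F1BC", "F1CB"), each = 2), sample_ids)
  lengths <- setNames(c(1000, 2000, 500, 1500), paste0("g", 1:4))
  count_matrix(counts, lengths, type_map)
}

# independent brute-force two-sided Mann-Whitney p over all group assignments
mwu_brute_force <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  p_le <- mean(us <= u_obs + eps)
  p_ge <- mean(us >= u_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

# independent conditional NB split-probability oracle for the exact test
nb_exact_oracle <- function(sum_a, n_a, sum_b, n_b, phi,
                            mean = (sum_a + sum_b) / (n_a + n_b)) {
  total <- sum_a + sum_b
  if (total == 0) return(1)
  k <- 0:total
  pk <- if (phi == 0) {
    dpois(k, n_a * mean) * dpois(total - k, n_b * mean)
  } else {
    dnbinom(k, size = n_a / phi, mu = n_a * mean) *
      dnbinom(total - k, size = n_b / phi, mu = n_b * mean)
  }
  pk <- pk / sum(pk)
  obs <- pk[sum_a + 1]
  min(1, sum(pk[pk <= obs * (1 + 1e-12)]))
}

# independent step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
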