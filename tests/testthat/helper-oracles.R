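# Brute-force oracles for the nonparametric tests, independent of the
# package implementation.

# exact two-sided Mann-Whitney p by enumerating all pooled-rank assignments
mwu_oracle <- function(a, b) {
  m <- length(a); n <- length(b)
  U_obs <- sum(outer(a, b, ">"))
  combos <- utils::combn(m + n, m)
  ranks <- seq_len(m + n)
  U_all <- apply(combos, 2, function(pos) sum(ranks[pos]) - m * (m + 1) / 2)
  p <- min(1, 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs)))
  list(U = U_obs, p_value = p)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(combinat_perms(v[-i]), function(p) c(v[i], p)))
  out
}

# Friedman statistic straight from the rank-sum formula, and exact p by
# looping over every combination of within-block orderings
friedman_oracle <- function(m) {
  k <- nrow(m); n <- ncol(m)
  R <- apply(m, 2, rank)
  stat <- 12 / (n * k * (k + 1)) * sum(rowSums(R)^2) - 3 * n * (k + 1)
  perm_rows <- matrix(unlist(combinat_perms(seq_len(k))), ncol = k,
                      byrow = TRUE)
  count <- 0L
  idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(perm_rows))), n)))
  for (r in seq_len(nrow(idx))) {
    Rp <- sapply(seq_len(n), function(j) perm_rows[idx[r, j], ])
    s <- 12 / (n * k * (k + 1)) * sum(rowSums(Rp)^2) - 3 * n * (k + 1)
    if (s >= stat - 1e-9) count <- count + 1L
  }
  list(statistic = stat, p_exact = count / nrow(idx))
}
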