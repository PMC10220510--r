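# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately re-derive each quantity from first
# principles rather than calling the code paths they test.

# Benjamini-Hochberg step-up written literally from its definition:
# order the p-values, compute m * p_(k) / k, and take the running minimum
# from the largest rank downward.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- m * p[ord] / seq_len(m)
  adj <- rev(cummin(rev(q)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exact two-sided rank-sum P value by enumerating every assignment of the
# pooled ranks to the first group (no ties assumed).
wilcox_exact_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact probability of each founder-count outcome under the weighted
# multinomial model, by enumerating ordered founder draws.
founder_outcome_probs <- function(abundance, c, B) {
  w <- abundance * c
  w <- w / sum(w)
  k <- length(w)
  draws <- expand.grid(rep(list(seq_len(k)), B))
  outcome <- apply(draws, 1L, function(idx) {
    paste(tabulate(idx, nbins = k), collapse = ",")
  })
  prob <- apply(draws, 1L, function(idx) prod(w[idx]))
  tapply(prob, outcome, sum)
}

# Frequency table of observed founder counts over repeated sampling.
founder_empirical_probs <- function(pop, B, n_draws) {
  ids <- pop$genotypes$id
  out <- replicate(n_draws, {
    f <- sample_founders(pop, B)
    counts <- f$genotypes$abundance[match(ids, f$genotypes$id)]
    counts[is.na(counts)] <- 0
    paste(counts, collapse = ",")
  })
  table(out) / n_draws
}

# all permutations of 1..m as a list of index vectors
combinat_permutations <- function(m) {
  if (m == 1L) {
    return(list(1L))
  }
  smaller <- combinat_permutations(m - 1L)
  out <- list()
  for (p in smaller) {
    for (pos in seq_len(m)) {
      out[[length(out) + 1L]] <- append(p, m, after = pos - 1L)
    }
  }
  out
}

# small trajectory table in the freq_c<k> dialect from a plain matrix
traj_table <- function(m, cycles = seq_len(ncol(m)), ids = NULL) {
  ids <- ids %||% paste0("mut", seq_len(nrow(m)))
  df <- tibble::tibble(mutation_id = ids)
  for (j in seq_along(cycles)) {
    df[[paste0("freq_c", cycles[j])]] <- m[, j]
  }
  df
}
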