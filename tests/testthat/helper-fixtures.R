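# Shared fixtures and independent brute-force oracles.

# random fully connected three-state fixture: six rates i.i.d. log-uniform
# on [1e-2, 1e2]
rand_three_state <- function(seed) {
  set.seed(seed)
  r <- exp(stats::runif(6, log(1e-2), log(1e2)))
  three_state(r[1], r[2], r[3], r[4], r[5], r[6])
}

# first `n` seeds whose fixture falls in the given regime
seeds_in_regime <- function(n, regime, from = 1L) {
  found <- integer(0); s <- from
  while (length(found) < n) {
    inv <- ts_invariants(rand_three_state(s))
    if (!inv$degenerate && ts_classify(inv) == regime) found <- c(found, s)
    s <- s + 1L
  }
  found
}

# ---- brute-force graph counting oracle (small n) -------------------------
# Enumerates labelled configurations explicitly and counts orbits under all
# vertex permutations by canonical (minimal) encoding.  Completely
# independent of the cycle-index route.

brute_graph_counts <- function(n, coloured = FALSE, connected_only = FALSE,
                               both_colours = FALSE) {
  pairs <- t(utils::combn(n, 2))
  ne <- nrow(pairs)
  nbit <- ne + if (coloured) n else 0L
  configs <- as.matrix(expand.grid(rep(list(0:1), nbit)))
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), , drop = FALSE]
  edge_index <- matrix(0L, n, n)
  for (e in seq_len(ne)) edge_index[pairs[e, 1], pairs[e, 2]] <-
      edge_index[pairs[e, 2], pairs[e, 1]] <- e
  if (connected_only) {
    keep <- apply(configs, 1, function(cf) {
      adj <- matrix(FALSE, n, n)
      for (e in seq_len(ne)) if (cf[e] == 1) {
        adj[pairs[e, 1], pairs[e, 2]] <- adj[pairs[e, 2], pairs[e, 1]] <- TRUE
      }
      seen <- c(TRUE, rep(FALSE, n - 1))
      repeat {
        new <- (as.vector(seen %*% adj) > 0) & !seen
        if (!any(new)) break
        seen <- seen | new
      }
      all(seen)
    })
    configs <- configs[keep, , drop = FALSE]
  }
  if (both_colours) {
    cols <- configs[, ne + seq_len(n), drop = FALSE]
    configs <- configs[rowSums(cols) > 0 & rowSums(cols) < n, , drop = FALSE]
  }
  if (nrow(configs) == 0L) return(0L)
  w <- 2^(seq_len(nbit) - 1)
  canon <- rep(Inf, nrow(configs))
  for (p in seq_len(nrow(perms))) {
    pr <- perms[p, ]
    edge_map <- vapply(seq_len(ne), function(e)
      edge_index[pr[pairs[e, 1]], pr[pairs[e, 2]]], integer(1))
    bit_map <- c(edge_map, if (coloured) ne + pr)
    # image config under the permutation: bit bit_map[i] = original bit i
    permuted <- configs
    permuted[, bit_map] <- configs
    enc <- as.vector(permuted %*% w)
    canon <- pmin(canon, enc)
  }
  length(unique(canon))
}

# independent partition counter (classic p(n, max) recursion)
count_partitions <- function(n, maxpart = n) {
  if (n == 0) return(1L)
  if (n < 0 || maxpart == 0) return(0L)
  count_partitions(n - maxpart, maxpart) + count_partitions(n, maxpart - 1L)
}

# analytic mixture cdf for comparison with empirical dwell distributions
mixture_cdf <- function(sj, t) {
  1 - as.vector(outer(t, sj$rates, function(tt, r) exp(-r * tt)) %*% sj$weights)
}

expect_model_close <- function(a, b, tol = 1e-9) {
  expect_equal(unname(a$Q), unname(b$Q), tolerance = tol)
}
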