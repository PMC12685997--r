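# Exact Polya enumeration of aggregated Markov model topologies.
#
# An aggregated Markov model with n states is, as a topology, a connected
# graph on n vertices whose vertices carry one of two colours (open/closed),
# with both colours present.  Two-colourings are counted via rooted graphs:
# adjacency to a (never materialized) root encodes the colour, i.e. the root
# adjacency bit of a vertex is represented as a loop.  The pipeline is
#   cycle index -> substitution (t_i -> 2 or 1+t^i) -> inverse Euler
#   transform (connected counts) -> M_n = CR_n - 2 c_n.
# All arithmetic is exact (see bigint.R).

MAX_ENUM_N <- 12L

#' Integer partitions
#'
#' All partitions of `n` as non-increasing vectors, in reverse-lexicographic
#' order (so `n` itself comes first and `rep(1, n)` last).  Partitions index
#' the conjugacy classes of the symmetric group, which is how the cycle
#' indices below are assembled.
#'
#' @param n positive integer.
#' @return list of integer vectors, each non-increasing and summing to `n`.
#' @examples
#' integer_partitions(3)  # [[3]], [[2,1]], [[1,1,1]]
#' @export
integer_partitions <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("n must be a positive integer")
  n <- as.integer(n)
  out <- list()
  rec <- function(rest, maxpart, acc) {
    if (rest == 0L) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (p in seq.int(min(maxpart, rest), 1L)) rec(rest - p, p, c(acc, p))
  }
  rec(n, n, integer(0))
  out
}

partition_class_size <- function(parts, n_fact) {
  # |conjugacy class| = n! / (prod_k k^{m_k} m_k!)
  tab <- table(parts)
  z <- prod(as.numeric(names(tab))^as.numeric(tab)) * prod(factorial(as.numeric(tab)))
  n_fact / z
}

new_cycle_index <- function(exps, weights, denom, n) {
  # exps: matrix, one row per monomial, column j = exponent of t_j
  # weights: integer-valued doubles (conjugacy-class sizes); denom = n!
  # graded lexicographic ordering: total degree first, then exponents
  deg <- as.vector(exps %*% seq_len(ncol(exps)))
  key <- do.call(paste, c(as.data.frame(format(exps, width = 3)), sep = ""))
  o <- order(-deg, key, method = "radix", decreasing = c(FALSE, TRUE))
  structure(list(exps = exps[o, , drop = FALSE], weights = weights[o],
                 denom = denom, n = n),
            class = "cycle_index")
}

#' @export
print.cycle_index <- function(x, ...) {
  terms <- vapply(seq_along(x$weights), function(i) {
    e <- x$exps[i, ]
    vars <- paste0("t", which(e > 0),
                   ifelse(e[e > 0] > 1, paste0("^", e[e > 0]), ""))
    mono <- paste(vars, collapse = " ")
    if (mono == "") mono <- "1"
    paste0(format(x$weights[i]), " ", mono)
  }, character(1))
  cat("Cycle index on ", x$n, " vertices (1/", format(x$denom), ") * (\n  ",
      paste(terms, collapse = " +\n  "), "\n)\n", sep = "")
  invisible(x)
}

edge_cycles_of_partition <- function(parts, rooted = FALSE) {
  # exponent vector of the induced permutation on 2-subsets of vertices
  # (plus, if rooted, one t_k slot per vertex k-cycle for the root-adjacency
  # bit, i.e. the loop encoding of the colour)
  maxlen <- max(1L, if (length(parts) > 1L) max(outer(parts, parts, function(a, b) a * b %/% mapply(gcd_int, a, b))) else parts)
  e <- integer(max(maxlen, max(parts)))
  for (k in parts) {
    if (k %% 2L == 1L) {
      e[k] <- e[k] + (k - 1L) %/% 2L
    } else {
      e[k] <- e[k] + k %/% 2L - 1L
      e[k %/% 2L] <- e[k %/% 2L] + 1L
    }
    if (rooted) e[k] <- e[k] + 1L
  }
  if (length(parts) > 1L) {
    for (i in seq_len(length(parts) - 1L)) {
      for (j in seq.int(i + 1L, length(parts))) {
        k <- parts[i]; l <- parts[j]
        g <- gcd_int(k, l)
        e[k * l %/% g] <- e[k * l %/% g] + g
      }
    }
  }
  e
}

gcd_int <- function(a, b) {
  while (b != 0L) { tmp <- a %% b; a <- b; b <- tmp }
  a
}

build_cycle_index <- function(n, rooted) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    stop("n must be a positive integer")
  if (n > MAX_ENUM_N)
    stop("exact enumeration is supported up to n = ", MAX_ENUM_N, " states")
  n <- as.integer(n)
  parts <- integer_partitions(n)
  n_fact <- factorial(n)
  evs <- lapply(parts, edge_cycles_of_partition, rooted = rooted)
  m <- max(vapply(evs, length, integer(1)))
  exps <- t(vapply(evs, function(e) c(e, integer(m - length(e))), integer(m)))
  weights <- vapply(parts, partition_class_size, numeric(1), n_fact = n_fact)
  new_cycle_index(exps, weights, n_fact, n)
}

#' Cycle index of the pair group
#'
#' Cycle index of the symmetric group on `n` vertices acting on the
#' 2-subsets of vertices (the edge slots of a graph); substituting
#' `t_i -> 1 + t^i` enumerates unlabelled graphs by edge count, and
#' `t_i -> 2` gives the total number of unlabelled graphs on `n` vertices.
#'
#' @param n vertex count (1..12).
#' @return object of class `cycle_index`; coefficients are class
#'   sizes over `n!`, summing to 1.
#' @examples
#' pair_group_cycle_index(3)  # (1/6)(t1^3 + 3 t1 t2 + 2 t3)
#' @export
pair_group_cycle_index <- function(n) build_cycle_index(n, rooted = FALSE)

#' Cycle index for rooted graphs (two-coloured vertices)
#'
#' As [pair_group_cycle_index()], but each vertex cycle of length k
#' contributes one extra `t_k` slot for the adjacency bit to a distinguished
#' root.  Filling or leaving each slot (`t_i -> 2`) counts graphs whose
#' vertices carry one of two colours; the root itself is never counted as a
#' vertex, matching the convention that `n` is the number of coloured
#' vertices.
#'
#' @inheritParams pair_group_cycle_index
#' @return object of class `cycle_index`.
#' @export
rooted_cycle_index <- function(n) build_cycle_index(n, rooted = TRUE)

#' Substitute into a cycle index
#'
#' Exact evaluation of a cycle index with each variable `t_i` replaced by a
#' number or a polynomial in `t`.  The two substitutions used in counting
#' are `t_i -> 2` (total configuration count) and `t_i -> 1 + t^i`
#' (enumeration by number of occupied slots, i.e. by edges).
#'
#' @param z a `cycle_index`.
#' @param images either a single number applied to every variable, a
#'   function of the cycle length `i` returning a number, or the string
#'   `"1+t^i"` for the edge-enumerating substitution.
#' @return for numeric images, the exact count (double, exact below 2^53,
#'   with the full decimal string in attribute `"exact"`); for the
#'   polynomial substitution, an object of class `edge_polynomial`.
#' @examples
#' ci_substitute(pair_group_cycle_index(3), 2)        # 4 graphs
#' ci_substitute(pair_group_cycle_index(3), "1+t^i")  # 1 + t + t^2 + t^3
#' @export
ci_substitute <- function(z, images) {
  stopifnot(inherits(z, "cycle_index"))
  nv <- ncol(z$exps)
  if (is.character(images)) {
    if (!identical(images, "1+t^i")) stop("unknown symbolic substitution: ", images)
    total <- bipoly_zero(1L)
    for (r in seq_along(z$weights)) {
      p <- list(bi(1))
      e <- z$exps[r, ]
      for (i in which(e > 0)) for (rep in seq_len(e[i])) p <- bipoly_mul_1plus(p, i)
      total <- bipoly_add(total, bipoly_mul_small(p, z$weights[r]))
    }
    coefs <- lapply(total, bi_div_exact, d = z$denom)
    new_edge_polynomial(coefs, z$n)
  } else {
    img <- if (is.function(images)) vapply(seq_len(nv), images, numeric(1))
           else rep(images, length.out = nv)
    if (any(img != floor(img)) || any(img < 0))
      stop("numeric images must be non-negative integers for exact substitution")
    total <- bi_zero()
    for (r in seq_along(z$weights)) {
      v <- bi(z$weights[r])
      e <- z$exps[r, ]
      for (i in which(e > 0)) for (rep in seq_len(e[i])) v <- bi_mul_small(v, img[i])
      total <- bi_add(total, v)
    }
    total <- bi_div_exact(total, z$denom)
    structure(as.double(total), exact = format(total))
  }
}

new_edge_polynomial <- function(coefs, n) {
  structure(list(coeff = coefs, n = n), class = "edge_polynomial")
}

#' @export
print.edge_polynomial <- function(x, ...) {
  terms <- vapply(seq_along(x$coeff), function(i) {
    c <- format(x$coeff[[i]])
    if (c == "0") return(NA_character_)
    deg <- i - 1L
    if (deg == 0L) c
    else paste0(if (c == "1") "" else paste0(c, " "),
                "t", if (deg > 1L) paste0("^", deg) else "")
  }, character(1))
  cat("Graphs on ", x$n, " vertices by edge count:\n  ",
      paste(terms[!is.na(terms)], collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' @export
as.double.edge_polynomial <- function(x, ...) vapply(x$coeff, as.double, numeric(1))

#' @export
as.character.edge_polynomial <- function(x, ...) vapply(x$coeff, format, character(1))

#' Moebius function
#'
#' `mobius(1) = 1`; for a product of r distinct primes, `(-1)^r`; 0 whenever
#' a squared prime divides `k`.  Used in the Moebius inversion step of the
#' inverse Euler transform.
#'
#' @param k positive integer (vectorized).
#' @return integer(s) in `{-1, 0, 1}`.
#' @export
mobius <- function(k) {
  if (any(k < 1) || any(k != floor(k))) stop("k must be a positive integer")
  vapply(as.integer(k), function(kk) {
    if (kk == 1L) return(1L)
    r <- 0L
    p <- 2L
    while (p * p <= kk) {
      if (kk %% p == 0L) {
        kk <- kk %/% p
        if (kk %% p == 0L) return(0L)
        r <- r + 1L
      }
      p <- p + 1L
    }
    if (kk > 1L) r <- r + 1L
    if (r %% 2L == 0L) 1L else -1L
  }, integer(1))
}

divisors <- function(k) which(k %% seq_len(k) == 0L)

series_to_bi <- function(g) {
  if (is.list(g)) lapply(g, as_bi) else lapply(g, bi)
}

#' Inverse Euler transform (connected counts from total counts)
#'
#' Given the series `g_k` counting all graphs with some property on k
#' vertices, recovers the series `c_k` counting the connected ones, through
#' the generating-series identity `1 + g(t) = exp(sum_k c(t^k)/k)`.
#' Internally `a_k = g_k - (1/k) sum_{i<k} i a_i g_{k-i}` is computed via the
#' integer recursion on `A_k = k a_k`, then Moebius inversion
#' `c_k = (1/k) sum_{d|k} mu(d) A_{k/d}` yields the connected counts.  A
#' non-integer `c_k` means the input was not a valid count series and raises
#' an error.
#'
#' @param g numeric vector of exact counts, `g[k]` = count at k vertices.
#' @return numeric vector `c` of connected counts (exact integers), with the
#'   scaled intermediate series `A_k = k a_k` in attribute `"A"`.
#' @examples
#' inverse_euler(c(1, 2, 4, 11, 34))  # 1 1 2 6 21 connected graphs
#' @export
inverse_euler <- function(g) {
  if (length(g) < 1L) stop("series must have at least one term")
  gb <- series_to_bi(g)
  N <- length(gb)
  A <- vector("list", N)
  for (k in seq_len(N)) {
    s <- bi_mul_small(gb[[k]], k)
    if (k > 1L) for (i in seq_len(k - 1L)) s <- bi_sub(s, bi_mul(A[[i]], gb[[k - i]]))
    A[[k]] <- s
  }
  cc <- vector("list", N)
  for (k in seq_len(N)) {
    s <- bi_zero()
    for (d in divisors(k)) {
      mu <- mobius(d)
      if (mu != 0L) s <- bi_add(s, bi_mul_small(A[[k %/% d]], mu))
    }
    dm <- bi_divmod_small(s, k)
    if (dm$r != 0)
      stop("inverse Euler transform produced a non-integer connected count at k = ",
           k, "; the input is not a consistent count series")
    if (bi_cmp(dm$q, 0) < 0)
      stop("inverse Euler transform produced a negative count at k = ", k)
    cc[[k]] <- dm$q
  }
  structure(vapply(cc, as.double, numeric(1)),
            A = vapply(A, as.double, numeric(1)))
}

#' Forward Euler transform (total counts from connected counts)
#'
#' Inverse of [inverse_euler()]: reconstructs the all-graphs series from the
#' connected series, used as a round-trip consistency check.
#'
#' @param cc numeric vector of connected counts.
#' @return numeric vector of total counts.
#' @export
euler_transform <- function(cc) {
  cb <- series_to_bi(cc)
  N <- length(cb)
  A <- vector("list", N)
  for (k in seq_len(N)) {
    s <- bi_zero()
    for (d in divisors(k)) s <- bi_add(s, bi_mul_small(cb[[d]], d))
    A[[k]] <- s
  }
  g <- vector("list", N)
  for (k in seq_len(N)) {
    s <- A[[k]]
    if (k > 1L) for (i in seq_len(k - 1L)) s <- bi_add(s, bi_mul(A[[i]], g[[k - i]]))
    g[[k]] <- bi_div_exact(s, k)
  }
  vapply(g, as.double, numeric(1))
}

#' Count the aggregated Markov model topologies on n states
#'
#' Number of connected graphs on `n` vertices with two vertex colours
#' (open/closed), both colours present: `M_n = CR_n - 2 c_n`, where `CR_n`
#' counts connected rooted graphs (= connected two-coloured graphs) and
#' `c_n` connected graphs, subtracting the two single-colour colourings of
#' every connected graph.
#'
#' @param n state count (1..12).
#' @return exact count as a double (all supported values are below 2^53).
#' @examples
#' count_aggregated_models(5)   # 312
#' @export
count_aggregated_models <- function(n) {
  tab <- model_count_table(n)
  tab$aggregated_markov_models[n]
}

#' Enumeration table of graphs and aggregated Markov models
#'
#' All five count columns for 1..`n_max` vertices: unlabelled graphs,
#' connected graphs, rooted graphs (two-coloured vertices, root not
#' counted), connected rooted graphs, and aggregated Markov models.
#'
#' @param n_max largest vertex count, between 1 and 12.
#' @return data.frame with columns `n`, `graphs`, `connected_graphs`,
#'   `rooted_graphs`, `connected_rooted_graphs`, `aggregated_markov_models`.
#'   Entries are exact integers stored as doubles.
#' @examples
#' model_count_table(5)
#' @export
model_count_table <- function(n_max) {
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 1 || n_max != floor(n_max))
    stop("n_max must be a positive integer")
  if (n_max > MAX_ENUM_N)
    stop("exact enumeration is supported up to n = ", MAX_ENUM_N, " states")
  graphs <- vapply(seq_len(n_max), function(n)
    ci_substitute(pair_group_cycle_index(n), 2), numeric(1))
  rooted <- vapply(seq_len(n_max), function(n)
    ci_substitute(rooted_cycle_index(n), 2), numeric(1))
  conn <- inverse_euler(graphs)
  conn_rooted <- inverse_euler(rooted)
  data.frame(n = seq_len(n_max),
             graphs = as.numeric(graphs),
             connected_graphs = as.numeric(conn),
             rooted_graphs = as.numeric(rooted),
             connected_rooted_graphs = as.numeric(conn_rooted),
             aggregated_markov_models = as.numeric(conn_rooted) - 2 * as.numeric(conn))
}
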