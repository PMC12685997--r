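# Stochastic dwell-time sequences.  The simulator is the package's
# empirical cross-check: equivalent models must generate statistically
# indistinguishable dwell sequences, and the analytic sojourn/bivariate
# machinery must match the simulated histograms.

#' Simulate a dwell-time sequence
#'
#' Exact continuous-time jump simulation (exponential holding times,
#' categorical successor choice), aggregated to the observable record:
#' consecutive sojourns in states of the same class merge into one dwell.
#' The sequence starts with an open dwell; the initial open state is drawn
#' from the open-class entry distribution, so dwells are stationary from
#' the first event.
#'
#' @param model a valid, irreducible `aggregated_model`.
#' @param n_events number of dwells to record (>= 1).
#' @param seed integer seed; sequences are reproducible in it.
#' @return object of class `dwell_sequence`: data.frame with columns
#'   `index`, `class` (`"open"`/`"closed"`, strictly alternating) and
#'   `duration`, with the seed in attribute `"seed"`.
#' @export
simulate_dwells <- function(model, n_events, seed) {
  assert_valid(model)
  if (n_events < 1) stop("n_events must be at least 1")
  is_open <- model$class_of == "open"
  with_seed(seed, {
    phiO <- entry_distribution(model, "open")
    start <- which(is_open)[sample.int(length(phiO), 1L, prob = phiO)]
    res <- sim_dwells_cpp(model$Q, is_open, start, as.integer(n_events))
    structure(data.frame(index = seq_len(n_events),
                         class = ifelse(res$open == 1L, "open", "closed"),
                         duration = res$duration),
              seed = seed, class = c("dwell_sequence", "data.frame"))
  })
}

#' @export
print.dwell_sequence <- function(x, ...) {
  cat("Dwell sequence:", nrow(x), "events (seed", attr(x, "seed"), ")\n")
  for (cl in c("open", "closed")) {
    d <- x$duration[x$class == cl]
    cat(sprintf("  %-6s n = %d, mean = %.6g\n", cl, length(d), mean(d)))
  }
  invisible(x)
}

#' Sample dwell pairs from a bivariate coefficient matrix
#'
#' Two-stage sampling of (first dwell, subsequent dwell) pairs: the
#' coefficient matrix defines a finite distribution over pairs of
#' exponential components; a pair of components is drawn, then the two
#' dwells.  Signed coefficient matrices are handled by rejection sampling
#' against the envelope mixture with coefficients `|A|/sum|A|`, which
#' dominates the target density; a signed matrix whose density is negative
#' somewhere is rejected as non-realizable.
#'
#' @param biv a `bivariate_dwell` (or a list with `open_rates`,
#'   `closed_rates`, `coeff_oc`).
#' @param n_pairs number of pairs.
#' @param seed integer seed.
#' @param which `"oc"` (open then closed, default) or `"co"`.
#' @return data.frame with columns `t1`, `t2`.
#' @export
mixture_sample <- function(biv, n_pairs, seed, which = c("oc", "co")) {
  which <- match.arg(which)
  A <- if (which == "oc") biv$coeff_oc else biv$coeff_co
  r1 <- if (which == "oc") biv$open_rates else biv$closed_rates
  r2 <- if (which == "oc") biv$closed_rates else biv$open_rates
  with_seed(seed, {
    if (all(A >= -1e-12)) {
      A <- pmax(A, 0)
      idx <- sample.int(length(A), n_pairs, replace = TRUE, prob = as.vector(A))
      i <- (idx - 1L) %% nrow(A) + 1L
      j <- (idx - 1L) %/% nrow(A) + 1L
      data.frame(t1 = stats::rexp(n_pairs, r1[i]), t2 = stats::rexp(n_pairs, r2[j]))
    } else {
      # rejection against the |A|-mixture envelope: the target density
      # f = sum_ij A_ij comp_ij is dominated by sum_ij |A|_ij comp_ij,
      # i.e. M times the proposal density with M = sum |A|
      f <- function(t1, t2) {
        E1 <- r1 * exp(-outer(r1, t1))           # n1 x N component densities
        E2 <- r2 * exp(-outer(r2, t2))           # n2 x N
        colSums((t(A) %*% E1) * E2)
      }
      Aabs <- abs(A); M <- sum(Aabs)
      out <- matrix(numeric(0), 0, 2)
      for (it in seq_len(1000L)) {
        need <- n_pairs - nrow(out)
        if (need <= 0L) break
        draw <- ceiling(need * M * 1.2) + 16L
        idx <- sample.int(length(Aabs), draw, replace = TRUE, prob = as.vector(Aabs))
        i <- (idx - 1L) %% nrow(A) + 1L
        j <- (idx - 1L) %/% nrow(A) + 1L
        t1 <- stats::rexp(draw, r1[i]); t2 <- stats::rexp(draw, r2[j])
        g <- f(t1, t2)
        if (any(g < -1e-10 * max(abs(g))))
          stop("signed coefficient matrix has negative density: not realizable")
        env <- colSums((t(Aabs) %*% (r1 * exp(-outer(r1, t1)))) *
                         (r2 * exp(-outer(r2, t2))))   # = M * proposal density
        accept <- stats::runif(draw) < pmax(g, 0) / env
        out <- rbind(out, cbind(t1, t2)[accept, , drop = FALSE])
      }
      if (nrow(out) < n_pairs) stop("rejection sampling failed to reach n_pairs")
      data.frame(t1 = out[seq_len(n_pairs), 1], t2 = out[seq_len(n_pairs), 2])
    }
  })
}

ks_stat <- function(a, b) {
  # two-sample ecdf sup-distance
  all_v <- sort(c(a, b))
  Fa <- stats::ecdf(a)(all_v); Fb <- stats::ecdf(b)(all_v)
  max(abs(Fa - Fb))
}

#' Compare two dwell sequences
#'
#' Two-sample ecdf sup-distances (open and closed dwells separately)
#' against the asymptotic critical value at significance `alpha`:
#' `c(alpha) sqrt((n+m)/(n m))` with `c(alpha) = sqrt(-log(alpha/2)/2)`.
#' `pass = TRUE` means the sequences are statistically indistinguishable at
#' that level in both classes.
#'
#' @param a,b `dwell_sequence`s (non-empty).
#' @param alpha significance level (default 0.01).
#' @return list with per-class `statistic`, `critical`, and overall `pass`.
#' @export
compare_dwells <- function(a, b, alpha = 0.01) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  c_alpha <- sqrt(-log(alpha / 2) / 2)
  out <- list()
  pass <- TRUE
  for (cl in c("open", "closed")) {
    da <- a$duration[a$class == cl]; db <- b$duration[b$class == cl]
    stat <- ks_stat(da, db)
    na <- as.numeric(length(da)); nb <- as.numeric(length(db))
    crit <- c_alpha * sqrt((na + nb) / (na * nb))
    out[[cl]] <- c(statistic = stat, critical = crit)
    pass <- pass && stat < crit
  }
  out$alpha <- alpha
  out$pass <- pass
  out
}

#' Write / read dwell sequences as CSV
#'
#' Columns `index,class,duration` with a mandatory header; durations in
#' model time units.
#'
#' @param dwells a `dwell_sequence` (or compatible data.frame).
#' @param path file path.
#' @return `path` / the `dwell_sequence`, invisibly for the writer.
#' @export
write_dwells <- function(dwells, path) {
  utils::write.csv(as.data.frame(dwells)[, c("index", "class", "duration")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dwells
#' @export
read_dwells <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(d), c("index", "class", "duration")))
    stop("dwell CSV must have columns index,class,duration")
  if (any(d$duration <= 0)) stop("durations must be positive")
  if (any(d$class[-1] == d$class[-nrow(d)])) stop("classes must alternate")
  structure(d, class = c("dwell_sequence", "data.frame"))
}
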