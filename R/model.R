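# Aggregated continuous-time Markov models: the channel's states are
# partitioned into an open and a closed class; only the class sequence and
# dwell durations are observable.  States are kept in the conventional
# block order: closed states first, then open states, so the generator is
#   Q = [ Q_CC  Q_CO ]
#       [ Q_OC  Q_OO ]

#' Construct an aggregated Markov model
#'
#' @param Q square matrix of transition rates (per unit time); off-diagonal
#'   entry `(i, j)` is the rate from state i to state j.  The diagonal is
#'   recomputed so that rows sum to zero.
#' @param classes character vector, one of `"open"`/`"closed"` per state,
#'   named by state if `Q` has dimnames.
#' @param states optional state labels; defaults to dimnames of `Q` or
#'   `S1..Sn`.
#' @return object of class `aggregated_model` with states reordered
#'   closed-first.
#' @examples
#' m <- aggregated_model(rbind(c(0, 1), c(2, 0)), c("closed", "open"))
#' @export
aggregated_model <- function(Q, classes, states = NULL) {
  Q <- as.matrix(Q)
  n <- nrow(Q)
  if (ncol(Q) != n) stop("Q must be square")
  if (is.null(states)) states <- rownames(Q)
  if (is.null(states)) states <- paste0("S", seq_len(n))
  if (length(states) != n) stop("length(states) must match nrow(Q)")
  classes <- as.character(classes)
  if (!is.null(names(classes))) classes <- classes[states]
  if (length(classes) != n || !all(classes %in% c("open", "closed")))
    stop("classes must give 'open' or 'closed' for every state")
  ord <- order(classes != "closed", seq_len(n))  # closed block first
  Q <- Q[ord, ord, drop = FALSE]
  states <- states[ord]
  classes <- classes[ord]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(states, states)
  structure(list(Q = Q, states = states, class_of = stats::setNames(classes, states)),
            class = "aggregated_model")
}

n_states <- function(model) length(model$states)
closed_states <- function(model) model$states[model$class_of == "closed"]
open_states <- function(model) model$states[model$class_of == "open"]

model_blocks <- function(model) {
  cs <- closed_states(model); os <- open_states(model)
  list(CC = model$Q[cs, cs, drop = FALSE],
       CO = model$Q[cs, os, drop = FALSE],
       OC = model$Q[os, cs, drop = FALSE],
       OO = model$Q[os, os, drop = FALSE])
}

#' @export
print.aggregated_model <- function(x, digits = 6, ...) {
  cat("Aggregated Markov model: ", length(closed_states(x)), " closed + ",
      length(open_states(x)), " open state(s)\n", sep = "")
  cat("States:", paste0(x$states, " (", substr(x$class_of, 1, 1), ")",
                        collapse = ", "), "\n")
  cat("Generator Q:\n")
  print(round(x$Q, digits))
  invisible(x)
}

strongly_connected <- function(adj) {
  # reachability from vertex 1 in adj and t(adj); TRUE iff irreducible
  reach <- function(A) {
    seen <- c(TRUE, rep(FALSE, nrow(A) - 1L))
    repeat {
      new <- (as.vector(seen %*% A) > 0) & !seen
      if (!any(new)) break
      seen <- seen | new
    }
    seen
  }
  all(reach(adj)) && all(reach(t(adj)))
}

#' Validate an aggregated Markov model
#'
#' Diagnostic check of the structural invariants: non-negative off-diagonal
#' rates, zero row sums, both classes present, and irreducibility of the
#' directed rate graph.  Never throws; returns all violations found.
#'
#' @param model an `aggregated_model`.
#' @param tol tolerance for row-sum checks.
#' @return list with `valid` (logical) and `problems` (character vector).
#' @export
validate_model <- function(model, tol = 1e-12) {
  problems <- character(0)
  Q <- model$Q
  off <- Q; diag(off) <- 0
  if (any(off < 0)) {
    bad <- which(off < 0, arr.ind = TRUE)
    problems <- c(problems, paste0("negative rate ", model$states[bad[, 1]],
                                   " -> ", model$states[bad[, 2]]))
  }
  rs <- rowSums(Q)
  if (any(abs(rs) > tol * pmax(1, abs(diag(Q)))))
    problems <- c(problems, paste0("row-sum violation at state ",
                                   model$states[abs(rs) > tol * pmax(1, abs(diag(Q)))]))
  if (length(closed_states(model)) == 0L || length(open_states(model)) == 0L)
    problems <- c(problems, "degenerate: single class (needs at least one open and one closed state)")
  if (!strongly_connected(off > 0))
    problems <- c(problems, "degenerate: rate graph is not irreducible")
  list(valid = length(problems) == 0L, problems = problems)
}

assert_valid <- function(model, tol = 1e-9) {
  v <- validate_model(model, tol = tol)
  if (!v$valid) stop("invalid aggregated model: ", paste(v$problems, collapse = "; "))
  invisible(model)
}

assert_algebraic <- function(model, tol = 1e-9) {
  # weaker contract for the spectral machinery: zero row sums, both classes,
  # connected nonzero pattern.  Negative rates are allowed here because
  # infeasible canonical forms and signed family members are still
  # well-defined algebraically and must support equivalence checks.
  Q <- model$Q
  if (max(abs(rowSums(Q))) > tol * max(1, max(abs(Q))))
    stop("generator does not have zero row sums")
  if (length(closed_states(model)) == 0L || length(open_states(model)) == 0L)
    stop("degenerate: single class")
  off <- Q; diag(off) <- 0
  if (!strongly_connected(abs(off) > 0))
    stop("rate graph is not irreducible")
  invisible(model)
}

#' Stationary distribution
#'
#' Unique probability vector `pi` with `pi %*% Q = 0`, for an irreducible
#' model.
#'
#' @param model an `aggregated_model`.
#' @return named numeric vector over states, summing to 1.
#' @export
stationary <- function(model) {
  off <- model$Q; diag(off) <- 0
  if (!strongly_connected(abs(off) > 0))
    stop("model is reducible; stationary distribution is not unique")
  n <- n_states(model)
  A <- rbind(t(model$Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(A, b)
  pi[abs(pi) < 1e-15] <- 0
  stats::setNames(pi / sum(pi), model$states)
}

undirected_cycle_basis <- function(adj) {
  # spanning tree + one fundamental cycle per chord; adj symmetric logical
  n <- nrow(adj)
  parent <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  parent[1] <- 0L; depth[1] <- 0L
  queue <- 1L
  tree <- matrix(FALSE, n, n)
  while (length(queue) > 0L) {
    v <- queue[1]; queue <- queue[-1]
    for (w in which(adj[v, ] & is.na(depth))) {
      parent[w] <- v; depth[w] <- depth[v] + 1L
      tree[v, w] <- tree[w, v] <- TRUE
      queue <- c(queue, w)
    }
  }
  cycles <- list()
  for (v in seq_len(n)) for (w in seq_len(n)) {
    if (w > v && adj[v, w] && !tree[v, w]) {
      # path v..w through tree
      pv <- v; pw <- w; up_v <- v; up_w <- w
      while (depth[pv] > depth[pw]) { pv <- parent[pv]; up_v <- c(up_v, pv) }
      while (depth[pw] > depth[pv]) { pw <- parent[pw]; up_w <- c(up_w, pw) }
      while (pv != pw) {
        pv <- parent[pv]; up_v <- c(up_v, pv)
        pw <- parent[pw]; up_w <- c(up_w, pw)
      }
      cycles[[length(cycles) + 1L]] <- c(up_v, rev(up_w[-length(up_w)]))
    }
  }
  cycles
}

#' Detailed balance (Kolmogorov criterion)
#'
#' A model satisfies detailed balance iff every edge is reversible
#' (`q_ij > 0` exactly when `q_ji > 0`) and the product of rates around
#' every cycle equals the product in the reverse direction; equivalently
#' `pi_i q_ij = pi_j q_ji` for all pairs.  The cycle condition is checked
#' on a fundamental cycle basis of the undirected rate graph.
#'
#' @param model an `aggregated_model`.
#' @param tol relative tolerance on cycle product ratios.
#' @return list with `holds`, `violated_cycles` (list of state-label
#'   vectors) and `max_violation` (largest relative product mismatch).
#' @export
detailed_balance <- function(model, tol = 1e-9) {
  off <- model$Q; diag(off) <- 0
  pos <- off > 0
  if (any(pos != t(pos))) {
    bad <- which(pos & !t(pos), arr.ind = TRUE)
    return(list(holds = FALSE,
                violated_cycles = lapply(seq_len(nrow(bad)), function(i)
                  model$states[c(bad[i, 1], bad[i, 2])]),
                max_violation = Inf,
                reason = "irreversible edge"))
  }
  cycles <- undirected_cycle_basis(pos | t(pos))
  violated <- list(); maxv <- 0
  for (cyc in cycles) {
    edges <- cbind(cyc, c(cyc[-1], cyc[1]))
    fwd <- prod(off[edges])
    bwd <- prod(off[edges[, c(2, 1), drop = FALSE]])
    v <- abs(fwd - bwd) / max(fwd, bwd, .Machine$double.xmin)
    maxv <- max(maxv, v)
    if (v > tol) violated[[length(violated) + 1L]] <- model$states[cyc]
  }
  list(holds = length(violated) == 0L, violated_cycles = violated,
       max_violation = maxv)
}

sorted_block_eigen <- function(B, what = "within-class block") {
  # eigen decomposition with decay rates (-eigenvalues) sorted descending;
  # errors on complex or defective blocks, which the mixture representation
  # of dwell densities assumes away
  ev <- eigen(B)
  scale <- max(abs(ev$values), 1e-300)
  if (any(abs(Im(ev$values)) > 1e-9 * scale))
    stop("complex eigenvalues in ", what,
         " (cannot occur under detailed balance); mixture representation unavailable")
  vals <- Re(ev$values)
  V <- Re(ev$vectors)
  if (abs(det(V)) < 1e-12 * prod(sqrt(colSums(V^2))))
    stop("non-diagonalizable ", what, "; mixture representation unavailable")
  rates <- -vals
  o <- order(-rates, seq_along(rates))
  list(rates = rates[o], V = V[, o, drop = FALSE])
}

entry_distribution <- function(model, cls) {
  # distribution of the state in which a class is entered, proportional to
  # the stationary probability flux into the class through the cross block
  pi <- stationary(model)
  bl <- model_blocks(model)
  phi <- if (cls == "closed") pi[open_states(model)] %*% bl$OC
         else pi[closed_states(model)] %*% bl$CO
  phi <- as.vector(phi)
  phi / sum(phi)
}

new_sojourn <- function(rates, weights, cls) {
  structure(list(rates = rates, weights = weights, class = cls),
            class = "sojourn_distribution")
}

#' @export
print.sojourn_distribution <- function(x, digits = 6, ...) {
  cat(x$class, "sojourn time: mixture of", length(x$rates), "exponential(s)\n")
  print(data.frame(rate = round(x$rates, digits), weight = round(x$weights, digits)))
  if (any(x$weights < 0)) cat("(signed mixture: some weights are negative)\n")
  invisible(x)
}

#' Density of a sojourn-time mixture
#'
#' @param sj a `sojourn_distribution`.
#' @param t non-negative times.
#' @return density values `sum_i w_i r_i exp(-r_i t)`.
#' @export
sojourn_density <- function(sj, t) {
  as.vector(outer(t, sj$rates, function(tt, r) r * exp(-r * tt)) %*% sj$weights)
}

check_realizable <- function(sj) {
  # a signed mixture must still be a density: check >= 0 on a geometric grid
  grid <- exp(seq(log(1e-3 / max(sj$rates)), log(10 / min(sj$rates)), length.out = 1000))
  d <- sojourn_density(sj, grid)
  if (any(d < -1e-10 * max(abs(d))))
    stop("signed mixture with negative density: not realizable as a sojourn distribution")
  invisible(sj)
}

#' Sojourn (dwell) time distribution of one class
#'
#' The dwell time in the open (closed) class is a possibly signed mixture of
#' exponentials whose rates are the negatives of the eigenvalues of the
#' within-class generator block, with weights obtained by projecting the
#' class-entry distribution onto the eigenbasis.
#'
#' @param model an `aggregated_model` (valid and irreducible).
#' @param cls `"open"` or `"closed"`.
#' @return a `sojourn_distribution` with decay rates sorted descending.
#' @export
sojourn <- function(model, cls = c("closed", "open")) {
  cls <- match.arg(cls)
  assert_algebraic(model)
  bl <- model_blocks(model)
  B <- if (cls == "closed") bl$CC else bl$OO
  cross <- if (cls == "closed") bl$CO else bl$OC
  eg <- sorted_block_eigen(B, paste0(cls, " block"))
  phi <- entry_distribution(model, cls)
  rexit <- rowSums(cross)                 # = -B %*% 1
  W <- solve(eg$V)
  amp <- as.vector(phi %*% eg$V) * as.vector(W %*% rexit)  # amplitude of e^{-r t}
  weights <- amp / eg$rates
  sj <- new_sojourn(eg$rates, weights, cls)
  check_realizable(sj)
  sj
}

#' Bivariate dwell distribution
#'
#' Joint density of a dwell time in one class and the immediately following
#' dwell in the other, `f(t1, t2) = sum_ij A[i,j] r_i e^{-r_i t1} s_j
#' e^{-s_j t2}`.  The pair of coefficient matrices (open-then-closed and
#' closed-then-open) characterizes the observable dynamics of the model
#' completely.
#'
#' @param model an `aggregated_model` with diagonalizable class blocks.
#' @return object of class `bivariate_dwell`: `open_rates`, `closed_rates`
#'   (descending), `coeff_oc` (`n_O x n_C`), `coeff_co` (`n_C x n_O`).
#' @export
bivariate <- function(model) {
  assert_algebraic(model)
  bl <- model_blocks(model)
  egO <- sorted_block_eigen(bl$OO, "open block")
  egC <- sorted_block_eigen(bl$CC, "closed block")
  WO <- solve(egO$V); WC <- solve(egC$V)
  phiO <- entry_distribution(model, "open")
  phiC <- entry_distribution(model, "closed")
  qCO1 <- rowSums(bl$CO)   # exit-rate vector of closed states
  qOC1 <- rowSums(bl$OC)
  # f_oc = phi_O e^{Q_OO t1} Q_OC e^{Q_CC t2} qCO1
  lead_O <- as.vector(phiO %*% egO$V)      # phi_O projected on eigencolumns
  lead_C <- as.vector(phiC %*% egC$V)
  mid_OC <- WO %*% bl$OC %*% egC$V
  mid_CO <- WC %*% bl$CO %*% egO$V
  tail_C <- as.vector(WC %*% qCO1)
  tail_O <- as.vector(WO %*% qOC1)
  coeff_oc <- (lead_O * mid_OC * rep(tail_C, each = length(lead_O))) /
    outer(egO$rates, egC$rates)
  coeff_co <- (lead_C * mid_CO * rep(tail_O, each = length(lead_C))) /
    outer(egC$rates, egO$rates)
  bv <- structure(list(open_rates = egO$rates, closed_rates = egC$rates,
                       coeff_oc = coeff_oc, coeff_co = coeff_co),
                  class = "bivariate_dwell")
  # marginalization consistency (both routes to each univariate weight)
  wo1 <- rowSums(coeff_oc); wo2 <- colSums(coeff_co)
  wc1 <- rowSums(coeff_co); wc2 <- colSums(coeff_oc)
  if (max(abs(wo1 - wo2), abs(wc1 - wc2)) > 1e-9)
    stop("internal error: bivariate marginalization constraints violated")
  bv
}

#' @export
print.bivariate_dwell <- function(x, digits = 6, ...) {
  cat("Bivariate dwell distribution\n open rates:  ",
      paste(signif(x$open_rates, digits), collapse = ", "),
      "\n closed rates:", paste(signif(x$closed_rates, digits), collapse = ", "), "\n")
  cat(" open-then-closed coefficients:\n")
  print(round(x$coeff_oc, digits))
  cat(" closed-then-open coefficients:\n")
  print(round(x$coeff_co, digits))
  invisible(x)
}

#' Identifiability parameter bound
#'
#' An aggregated Markov model with `n_O` open and `n_C` closed states can
#' carry at most `2 n_O n_C` identifiable parameters; a model with more
#' positive rates is necessarily non-identifiable.  Also reports the rank of
#' the open-to-closed cross block (the interconductance rank).
#'
#' @param model an `aggregated_model`.
#' @return list with `n_rates`, `bound`, `exceeds`, `interconductance_rank`.
#' @export
parameter_bound <- function(model) {
  off <- model$Q; diag(off) <- 0
  n_rates <- sum(off > 0)
  nO <- length(open_states(model)); nC <- length(closed_states(model))
  bound <- 2L * nO * nC
  bl <- model_blocks(model)
  rk <- qr(bl$OC, tol = 1e-10)$rank
  list(n_rates = n_rates, bound = bound, exceeds = n_rates > bound,
       interconductance_rank = rk)
}

#' Mean dwell time of a sojourn mixture
#'
#' @param sj a `sojourn_distribution`.
#' @return `sum_i w_i / r_i`.
#' @export
sojourn_mean <- function(sj) sum(sj$weights / sj$rates)
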