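# Complete analysis of the fully connected three-state model: two closed
# states C1, C2 and one open state O3.  Its observable dynamics is pinned
# down by four invariants:
#   lambda1 >= lambda2  decay rates of the closed-time mixture
#                       (eigen-decay-rates of the closed block),
#   lambda_O = q31+q32  open decay rate,
#   rho                 weight of the lambda1 component of the closed-time
#                       density (may fall outside [0,1]: signed mixture).
# Equivalent bookkeeping uses the elementary symmetric data of the closed
# block plus one coupling invariant:
#   Tc = lambda1 + lambda2 = q12 + q13 + q21 + q23
#   D  = lambda1 * lambda2 = q12 q23 + q13 q21 + q13 q23
#   C  = q13 q31 + q23 q32 = rho lambda1 lambda_O + (1-rho) lambda2 lambda_O
# (C/lambda_O is the closed-density value at t = 0; the auxiliary coupling
# invariant is S = rho (lambda1 - lambda2) lambda_O = C - lambda2 lambda_O.)
# Fixing (q13, q23) these equations are *linear* in (q12, q21) and in
# (q31, q32), which yields the continuous two-parameter equivalence family
# in closed form.

#' Construct the three-state model (C1, C2 closed; O3 open)
#'
#' @param q12,q13,q21,q23,q31,q32 non-negative rates; `qij` is the rate
#'   from state i to state j with states numbered C1 = 1, C2 = 2, O3 = 3.
#' @return an `aggregated_model`.
#' @export
three_state <- function(q12, q13, q21, q23, q31, q32) {
  r <- c(q12, q13, q21, q23, q31, q32)
  if (any(r < 0)) stop("rates must be non-negative")
  Q <- matrix(0, 3, 3, dimnames = list(c("C1", "C2", "O3"), c("C1", "C2", "O3")))
  Q["C1", "C2"] <- q12; Q["C1", "O3"] <- q13
  Q["C2", "C1"] <- q21; Q["C2", "O3"] <- q23
  Q["O3", "C1"] <- q31; Q["O3", "C2"] <- q32
  aggregated_model(Q, c(C1 = "closed", C2 = "closed", O3 = "open"))
}

ts_build <- function(rates) {
  # build the (possibly signed) three-state generator without the
  # non-negativity guard: infeasible reductions stay usable algebraically.
  # Solved family rates carry O(eps) roundoff; entries negligible against
  # the rate scale are snapped to exact zero so topology checks (edge
  # reversibility, cycle products) see the intended wiring.
  rates[abs(rates) < 1e-12 * max(abs(rates))] <- 0
  Q <- matrix(0, 3, 3, dimnames = list(c("C1", "C2", "O3"), c("C1", "C2", "O3")))
  Q["C1", "C2"] <- rates["q12"]; Q["C1", "O3"] <- rates["q13"]
  Q["C2", "C1"] <- rates["q21"]; Q["C2", "O3"] <- rates["q23"]
  Q["O3", "C1"] <- rates["q31"]; Q["O3", "C2"] <- rates["q32"]
  aggregated_model(Q, c(C1 = "closed", C2 = "closed", O3 = "open"))
}

ts_rates <- function(model) {
  if (n_states(model) != 3L || length(open_states(model)) != 1L)
    stop("not a three-state model with one open state")
  Q <- model$Q
  c(q12 = Q[1, 2], q13 = Q[1, 3], q21 = Q[2, 1], q23 = Q[2, 3],
    q31 = Q[3, 1], q32 = Q[3, 2])
}

#' Equivalence-class invariants of a three-state model
#'
#' @param model a three-state `aggregated_model` (two closed, one open).
#' @param tol relative tolerance below which the closed eigenvalues are
#'   treated as degenerate.
#' @return object of class `three_state_invariants` with fields `lambda1 >=
#'   lambda2` (closed decay rates), `lambda_O` (open decay rate), `rho`
#'   (weight of the `lambda1` closed component, possibly outside `[0,1]`),
#'   `S` (coupling invariant `rho (lambda1-lambda2) lambda_O`) and
#'   `degenerate` (TRUE when `lambda1 = lambda2`, where `rho` is undefined).
#' @export
ts_invariants <- function(model, tol = 1e-9) {
  q <- ts_rates(model)
  assert_algebraic(model)
  Tc <- q["q12"] + q["q13"] + q["q21"] + q["q23"]
  D <- q["q12"] * q["q23"] + q["q13"] * q["q21"] + q["q13"] * q["q23"]
  disc <- Tc^2 - 4 * D
  if (disc < -tol * Tc^2) stop("complex closed-block eigenvalues")
  disc <- max(disc, 0)
  lambda1 <- (Tc + sqrt(disc)) / 2
  lambda2 <- (Tc - sqrt(disc)) / 2
  lambda_O <- q["q31"] + q["q32"]
  degenerate <- (lambda1 - lambda2) <= tol * lambda1
  if (degenerate) {
    rho <- NA_real_; S <- NA_real_
  } else {
    sj <- sojourn(model, "closed")
    rho <- sj$weights[1]   # rates sorted descending: component 1 is lambda1
    S <- rho * (lambda1 - lambda2) * lambda_O
  }
  structure(list(lambda1 = unname(lambda1), lambda2 = unname(lambda2),
                 lambda_O = unname(lambda_O), rho = unname(rho),
                 S = unname(S), degenerate = degenerate),
            class = "three_state_invariants")
}

#' @export
print.three_state_invariants <- function(x, digits = 6, ...) {
  cat("Three-state invariants:\n")
  cat("  lambda1 =", signif(x$lambda1, digits),
      " lambda2 =", signif(x$lambda2, digits),
      " lambda_O =", signif(x$lambda_O, digits), "\n")
  if (x$degenerate) cat("  degenerate closed spectrum (rho undefined)\n")
  else cat("  rho =", signif(x$rho, digits),
           " (", ts_classify(x), ")\n", sep = "")
  invisible(x)
}

inv_TDC <- function(inv) {
  list(Tc = inv$lambda1 + inv$lambda2,
       D = inv$lambda1 * inv$lambda2,
       C = (inv$rho * inv$lambda1 + (1 - inv$rho) * inv$lambda2) * inv$lambda_O)
}

assert_nondegenerate <- function(inv) {
  if (inv$degenerate)
    stop("degenerate invariants (lambda1 = lambda2): rho is undefined and ",
         "the reductions are not applicable")
  invisible(inv)
}

#' Reduce to the star model C1-O3-C2
#'
#' The star (both closed states adjacent to the open state, no direct
#' closed-closed transition) is recovered directly from the invariants:
#' `q13 = lambda1`, `q23 = lambda2`, `q31 = rho lambda_O`,
#' `q32 = (1-rho) lambda_O`.  For `rho` outside `[0, 1]` one of the exit
#' rates is negative: the reduction exists algebraically but is not a
#' realizable model (`feasible = FALSE`).
#'
#' @param inv a `three_state_invariants` (non-degenerate).
#' @return list with `model` (a three-state `aggregated_model`, carrying
#'   signed rates when infeasible), `rates` (named vector of the six rates,
#'   possibly signed) and `feasible`.
#' @export
to_star <- function(inv) {
  assert_nondegenerate(inv)
  rates <- c(q12 = 0, q13 = inv$lambda1, q21 = 0, q23 = inv$lambda2,
             q31 = inv$rho * inv$lambda_O, q32 = (1 - inv$rho) * inv$lambda_O)
  feasible <- all(rates >= -1e-12)
  list(model = ts_build(rates), rates = rates, feasible = feasible)
}

#' Reduce to the chain model C1-C2-O3
#'
#' With detailed balance the chain has `q13 = q31 = 0` and its four rates
#' follow from the invariants: `q23 = C / lambda_O` (the closed-density
#' value at zero dwell time), `q12 = lambda1 lambda2 / q23`,
#' `q21 = lambda1 + lambda2 - q12 - q23`, `q32 = lambda_O`.  With
#' `detailed_balance = FALSE` the member of the `q13 = 0` family with
#' `q23 = lambda2` is returned (a documented convention fixing one point of
#' the one-parameter family that does not satisfy detailed balance).
#'
#' @param inv a `three_state_invariants` (non-degenerate).
#' @param detailed_balance return the detailed-balance chain (default) or
#'   the non-reversible `q13 = 0` family member.
#' @return as [to_star()].
#' @export
to_chain <- function(inv, detailed_balance = TRUE) {
  assert_nondegenerate(inv)
  tdc <- inv_TDC(inv)
  if (detailed_balance) {
    q23 <- tdc$C / inv$lambda_O          # = rho lambda1 + (1-rho) lambda2
    q12 <- tdc$D / q23
    q21 <- tdc$Tc - q12 - q23
    rates <- c(q12 = q12, q13 = 0, q21 = q21, q23 = q23, q31 = 0,
               q32 = inv$lambda_O)
  } else {
    rates <- family_rates(inv, q13 = 0, q23 = inv$lambda2)
  }
  feasible <- all(rates >= -1e-12)
  list(model = ts_build(rates), rates = rates, feasible = feasible)
}

family_rates <- function(inv, q13, q23) {
  # closed-form solution of the invariant equations for fixed (q13, q23)
  q13 <- unname(q13); q23 <- unname(q23)
  tdc <- inv_TDC(inv)
  if (abs(q13 - q23) <= 1e-12 * max(q13, q23, 1))
    stop("out of domain: q13 = q23 makes the family equations singular")
  A <- tdc$Tc - q13 - q23
  B <- tdc$D - q13 * q23
  q21 <- (B - A * q23) / (q13 - q23)
  q12 <- A - q21
  q31 <- (tdc$C - q23 * inv$lambda_O) / (q13 - q23)
  q32 <- inv$lambda_O - q31
  c(q12 = q12, q13 = q13, q21 = q21, q23 = q23, q31 = q31, q32 = q32)
}

#' Member of the continuous equivalence family
#'
#' The equivalence class of a (non-degenerate) three-state model is a
#' two-parameter family: choosing the closed-to-open rates `q13` and `q23`
#' freely, the remaining four rates are determined by the invariants.  The
#' returned rates always satisfy the invariant equations; the member is a
#' realizable model only when all six rates are non-negative (`feasible`).
#'
#' @param inv a `three_state_invariants` (non-degenerate).
#' @param q13,q23 free coordinates (non-negative, `q13 != q23`).
#' @return object of class `family_member`: `rates` (all six, possibly
#'   signed), `feasible`, and `model` (`NULL` when infeasible).
#' @export
family_member <- function(inv, q13, q23) {
  assert_nondegenerate(inv)
  if (q13 < 0 || q23 < 0) stop("q13 and q23 must be non-negative")
  rates <- family_rates(inv, q13, q23)
  feasible <- all(rates >= -1e-12)
  model <- ts_build(rates)
  if (feasible) {
    inv2 <- ts_invariants(model)
    err <- max(abs(c(inv2$lambda1 - inv$lambda1, inv2$lambda2 - inv$lambda2,
                     inv2$lambda_O - inv$lambda_O, inv2$rho - inv$rho)) /
               max(inv$lambda1, 1e-300))
    if (err > 1e-8)
      stop("internal error: family member does not reproduce the invariants (",
           signif(err, 3), ")")
  }
  structure(list(rates = rates, feasible = feasible, model = model,
                 q13 = q13, q23 = q23), class = "family_member")
}

#' @export
print.family_member <- function(x, digits = 6, ...) {
  cat("Equivalence-family member at (q13, q23) = (",
      signif(x$q13, digits), ", ", signif(x$q23, digits), ")",
      if (!x$feasible) "  [infeasible: negative rates]", "\n", sep = "")
  print(signif(x$rates, digits))
  invisible(x)
}

#' Feasible region of the equivalence family
#'
#' Evaluates [family_member()] on a rectangular grid of `(q13, q23)` values
#' and reports where all six rates are non-negative.
#'
#' @param inv a `three_state_invariants` (non-degenerate).
#' @param q13_grid,q23_grid numeric vectors of non-negative coordinates.
#' @return logical matrix, rows indexed by `q13_grid`, columns by
#'   `q23_grid`.
#' @export
feasible_region <- function(inv, q13_grid, q23_grid) {
  assert_nondegenerate(inv)
  mask <- matrix(FALSE, length(q13_grid), length(q23_grid),
                 dimnames = list(signif(q13_grid, 8), signif(q23_grid, 8)))
  for (i in seq_along(q13_grid)) for (j in seq_along(q23_grid)) {
    ok <- tryCatch(all(family_rates(inv, q13_grid[i], q23_grid[j]) >= -1e-12),
                   error = function(e) FALSE)
    mask[i, j] <- ok
  }
  mask
}

#' Classify the equivalence class of a three-state model
#'
#' `"reducible_mixture"` when the closed-time density is a proper mixture
#' (`rho` strictly inside `(0, 1)`): the class contains the star and the
#' detailed-balance chain, so an identifiable 4-rate representative exists.
#' `"irreducible_signed_mixture"` otherwise: the closed-time density is a
#' signed mixture (non-monotone), no acyclic representative with
#' non-negative rates exists, and detailed balance is unattainable in the
#' whole family.  Boundary values of `rho` (0 or 1) are reported as
#' `"degenerate_boundary"`.
#'
#' @param inv a `three_state_invariants` (non-degenerate).
#' @param tol boundary tolerance on `rho`.
#' @return character scalar.
#' @export
ts_classify <- function(inv, tol = 1e-10) {
  assert_nondegenerate(inv)
  if (abs(inv$rho) <= tol || abs(inv$rho - 1) <= tol) return("degenerate_boundary")
  if (inv$rho > 0 && inv$rho < 1) "reducible_mixture" else "irreducible_signed_mixture"
}

#' Detailed-balance curve of the equivalence family
#'
#' Within the two-parameter family, the detailed-balance condition
#' `q31 q12 q23 = q13 q32 q21` selects a curve in the `(q13, q23)` plane
#' running from the chain point `(rho lambda1 + (1-rho) lambda2, 0)` to the
#' star point `(lambda1, lambda2)` (both trees, hence trivially balanced).
#' The curve is traced by stepping `q13` uniformly between the endpoints and
#' root-finding `q23` at each step.
#'
#' @param inv a `three_state_invariants` with class `"reducible_mixture"`.
#' @param n_points number of members returned (including endpoints).
#' @return list of `family_member`s; for a signed-mixture class an empty
#'   list with attribute `"status"` explaining that detailed balance cannot
#'   be satisfied.
#' @export
detailed_balance_curve <- function(inv, n_points = 50) {
  assert_nondegenerate(inv)
  if (ts_classify(inv) != "reducible_mixture") {
    out <- list()
    attr(out, "status") <- "detailed balance cannot be fulfilled: closed-time density is a signed mixture"
    return(out)
  }
  db_residual <- function(q13, q23) {
    r <- family_rates(inv, q13, q23)
    r["q31"] * r["q12"] * r["q23"] - r["q13"] * r["q32"] * r["q21"]
  }
  q13_chain <- (inv$rho * inv$lambda1 + (1 - inv$rho) * inv$lambda2)
  q13_star <- inv$lambda1
  q13s <- seq(q13_chain, q13_star, length.out = n_points)
  members <- vector("list", n_points)
  members[[1]] <- family_member(inv, q13_chain, 0)
  members[[n_points]] <- family_member(inv, q13_star, inv$lambda2)
  for (k in seq.int(2L, n_points - 1L)) {
    q13 <- q13s[k]
    lo <- 1e-12 * inv$lambda2; hi <- inv$lambda2 * (1 - 1e-12)
    f_lo <- db_residual(q13, lo); f_hi <- db_residual(q13, hi)
    if (sign(f_lo) == sign(f_hi)) {
      # scan for a sign change, then bisect
      grid <- seq(lo, hi, length.out = 200)
      vals <- vapply(grid, function(q) db_residual(q13, q), numeric(1))
      idx <- which(diff(sign(vals)) != 0)
      if (!length(idx)) stop("no detailed-balance solution found at q13 = ", q13)
      lo <- grid[idx[1]]; hi <- grid[idx[1] + 1L]
    }
    root <- stats::uniroot(function(q) db_residual(q13, q), c(lo, hi),
                           tol = 1e-13 * inv$lambda2)$root
    members[[k]] <- family_member(inv, q13, root)
  }
  members
}
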