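# Block-wise similarity transformations and the Bauer-Kienker uncoupled
# (BKU) canonical form.  A transform S = blockdiag(S_C, S_O) with row sums
# one maps a generator Q to the equivalent generator S^{-1} Q S: the class
# partition, the within-class spectra and all observable dwell
# distributions are preserved, while individual rates change.

#' Block-wise similarity transform
#'
#' @param S_C invertible matrix on the closed coordinates, rows summing to 1.
#' @param S_O invertible matrix on the open coordinates, rows summing to 1.
#' @return object of class `block_transform`.
#' @export
block_transform <- function(S_C, S_O) {
  S_C <- as.matrix(S_C); S_O <- as.matrix(S_O)
  for (nm in c("S_C", "S_O")) {
    S <- if (nm == "S_C") S_C else S_O
    if (nrow(S) != ncol(S)) stop(nm, " must be square")
    if (max(abs(rowSums(S) - 1)) > 1e-9)
      stop(nm, " must have unit row sums so transformed generators keep zero row sums")
    if (abs(det(S)) < 1e-12) stop(nm, " is singular")
  }
  structure(list(S_C = S_C, S_O = S_O,
                 kappa = c(C = kappa(S_C, exact = FALSE), O = kappa(S_O, exact = FALSE))),
            class = "block_transform")
}

transform_matrix <- function(model, transform) {
  nC <- length(closed_states(model)); nO <- length(open_states(model))
  if (nrow(transform$S_C) != nC || nrow(transform$S_O) != nO)
    stop("transform block sizes do not match the model's class sizes")
  S <- matrix(0, nC + nO, nC + nO)
  S[seq_len(nC), seq_len(nC)] <- transform$S_C
  S[nC + seq_len(nO), nC + seq_len(nO)] <- transform$S_O
  S
}

#' Apply a block-wise similarity transform
#'
#' Returns the equivalent model `S^{-1} Q S` with the same class partition.
#'
#' @param model an `aggregated_model` (states in closed-first order).
#' @param transform a `block_transform`.
#' @return transformed `aggregated_model`.
#' @export
apply_transform <- function(model, transform) {
  S <- transform_matrix(model, transform)
  Qp <- solve(S, model$Q %*% S)
  if (max(abs(rowSums(Qp))) > 1e-8 * max(1, max(abs(Qp))))
    stop("transformed generator lost zero row sums; transform is not row-sum-one")
  m <- model
  dimnames(Qp) <- dimnames(model$Q)
  m$Q <- Qp
  m
}

#' Bauer-Kienker uncoupled (BKU) canonical form
#'
#' Block-diagonalizing similarity transform that makes both within-class
#' blocks diagonal, so that all transitions run between open and closed
#' states.  The BKU representative is parameter-identifiable (it has at most
#' `2 n_O n_C` free rates), but for some equivalence classes it carries
#' negative off-diagonal entries and is then flagged infeasible — the
#' equivalence-class algebra still holds, there is just no realizable model
#' of this shape.
#'
#' Eigenvalues are ordered by descending decay rate within each class
#' (ties broken by original index), which fixes the representative.
#'
#' @param model an `aggregated_model` with diagonalizable class blocks.
#' @param tol entries below `-tol` make the form infeasible; smaller
#'   negative residue is clamped to zero.
#' @return list of class `canonical_form`: `model` (the BKU generator),
#'   `feasible`, `transform` (the `block_transform` used), and
#'   `off_block_residue` (largest within-block off-diagonal left by the
#'   numerical diagonalization).
#' @export
bku_form <- function(model, tol = 1e-12) {
  assert_algebraic(model)
  bl <- model_blocks(model)
  mk_block <- function(B, what) {
    eg <- sorted_block_eigen(B, what)
    cs <- solve(eg$V, rep(1, nrow(eg$V)))   # column scaling for unit row sums
    if (any(abs(cs) < 1e-12))
      stop("cannot normalize ", what, " eigenvectors to row-sum one (zero scaling)")
    eg$V %*% diag(cs, nrow = length(cs))
  }
  S_C <- mk_block(bl$CC, "closed block")
  S_O <- mk_block(bl$OO, "open block")
  tr <- block_transform(S_C, S_O)
  out <- apply_transform(model, tr)
  nC <- length(closed_states(model)); nO <- length(open_states(model))
  within <- rbind(cbind(matrix(TRUE, nC, nC), matrix(FALSE, nC, nO)),
                  cbind(matrix(FALSE, nO, nC), matrix(TRUE, nO, nO)))
  offdiag_within <- within & !diag(TRUE, nC + nO)
  residue <- max(abs(out$Q[offdiag_within]))
  if (residue > 1e-10 * max(abs(out$Q)))
    stop("BKU diagonalization left a within-block residue of ", residue)
  Qp <- out$Q
  Qp[offdiag_within] <- 0
  off <- Qp; diag(off) <- 0
  feasible <- all(off >= -tol)
  off[off < 0 & off >= -tol] <- 0
  diag(off) <- 0
  Qp <- off; diag(Qp) <- -rowSums(off)
  dimnames(Qp) <- dimnames(model$Q)
  out$Q <- Qp
  structure(list(model = out, feasible = feasible, transform = tr,
                 off_block_residue = residue),
            class = "canonical_form")
}

#' @export
print.canonical_form <- function(x, ...) {
  cat("BKU canonical form (feasible: ", x$feasible, ")\n", sep = "")
  print(x$model)
  invisible(x)
}

#' Test equivalence of two aggregated models
#'
#' Two models are equivalent when they generate the same observable
#' dynamics.  Since the bivariate dwell distributions characterize the
#' dynamics completely, the test compares the sorted within-class spectra
#' and the bivariate coefficient matrices (already aligned by the spectral
#' sort) to a relative tolerance.
#'
#' @param m1,m2 `aggregated_model`s with the same class sizes.
#' @param tol relative tolerance (default `1e-9`).
#' @return logical; attribute `"detail"` carries the largest spectral and
#'   coefficient discrepancies.  When either model has deficient
#'   interconductance rank the result carries attribute
#'   `"rank_deficient" = TRUE` (coefficient comparison may then be coarser
#'   than the refined rank-based criterion).
#' @export
are_equivalent <- function(m1, m2, tol = 1e-9) {
  if (length(open_states(m1)) != length(open_states(m2)) ||
      length(closed_states(m1)) != length(closed_states(m2))) {
    out <- FALSE
    attr(out, "detail") <- "class sizes differ"
    return(out)
  }
  b1 <- bivariate(m1); b2 <- bivariate(m2)
  rel <- function(a, b) max(abs(a - b)) / max(abs(a), abs(b), 1e-300)
  d_spec <- max(rel(b1$open_rates, b2$open_rates),
                rel(b1$closed_rates, b2$closed_rates))
  d_coef <- max(max(abs(b1$coeff_oc - b2$coeff_oc)),
                max(abs(b1$coeff_co - b2$coeff_co)))
  out <- d_spec <= tol && d_coef <= tol
  attr(out, "detail") <- c(spectra = d_spec, coefficients = d_coef)
  pb1 <- parameter_bound(m1); pb2 <- parameter_bound(m2)
  full_rank <- min(length(open_states(m1)), length(closed_states(m1)))
  if (pb1$interconductance_rank < full_rank || pb2$interconductance_rank < full_rank)
    attr(out, "rank_deficient") <- TRUE
  out
}
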