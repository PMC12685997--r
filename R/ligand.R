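# Ligand-dependent star models and their equivalent chain forms.
#
# A star model C1-O3-C2 whose rates depend on the ligand concentration c
# (mass action k*c for a binding step, constant otherwise) transforms, at
# every c, into an equivalent chain C1-C2-O3.  The chain rates follow from
# the invariants of the star at that concentration:
#   q~32 = lambda_O(c) = q31 + q32
#   q~23 = (q13 q31 + q23 q32) / lambda_O
#   q~12 = q13 q23 / q~23
#   q~21 = q13 + q23 - q~12 - q~23
# These expressions are symmetric in the two closed components, so they
# remain well defined even where the closed eigenvalues cross (there the
# star/family picture degenerates but the chain does not: q~21 simply has
# a double root).

NAMED_SCHEMES <- c("two_activating", "one_activating", "activating_inhibitory")

#' Ligand-binding scheme for the star model
#'
#' Specifies, for each star rate (`q13`, `q23`, `q31`, `q32`), whether it is
#' a mass-action binding rate `k*c` or a concentration-independent constant
#' `k`.  Named schemes:
#' \describe{
#'   \item{two_activating}{`q13 = k13 c`, `q23 = k23 c`, `q31 = k31`,
#'     `q32 = k32` — two activating binding sites.}
#'   \item{one_activating}{`q13 = k13 c`, `q23 = k23`, `q31 = k31`,
#'     `q32 = k32` — one activating site, one ligand-independent opening.}
#'   \item{activating_inhibitory}{`q13 = k13 c`, `q23 = k23`, `q31 = k31`,
#'     `q32 = k32 c` — one activating and one inhibitory site.}
#' }
#'
#' @param scheme one of the named schemes, or `"custom"` with `kinds`.
#' @param k13,k23,k31,k32 positive rate constants.
#' @param kinds for `"custom"`: named character vector over
#'   `c("q13","q23","q31","q32")` with values `"mass_action"`/`"constant"`.
#' @return object of class `ligand_scheme`.
#' @export
ligand_scheme <- function(scheme = c(NAMED_SCHEMES, "custom"),
                          k13, k23, k31, k32, kinds = NULL) {
  scheme <- match.arg(scheme)
  k <- c(q13 = k13, q23 = k23, q31 = k31, q32 = k32)
  if (any(k <= 0)) stop("all rate constants must be positive")
  kinds <- switch(scheme,
    two_activating = c(q13 = "mass_action", q23 = "mass_action",
                       q31 = "constant", q32 = "constant"),
    one_activating = c(q13 = "mass_action", q23 = "constant",
                       q31 = "constant", q32 = "constant"),
    activating_inhibitory = c(q13 = "mass_action", q23 = "constant",
                              q31 = "constant", q32 = "mass_action"),
    custom = {
      if (is.null(kinds) || !setequal(names(kinds), names(k)) ||
          !all(kinds %in% c("mass_action", "constant")))
        stop("custom scheme needs kinds = named vector over q13,q23,q31,q32 ",
             "with values 'mass_action'/'constant'")
      kinds[names(k)]
    })
  structure(list(scheme = scheme, k = k, kinds = kinds), class = "ligand_scheme")
}

#' @export
print.ligand_scheme <- function(x, ...) {
  cat("Ligand scheme '", x$scheme, "':\n", sep = "")
  for (nm in names(x$k))
    cat("  ", nm, " = ", x$k[nm],
        if (x$kinds[nm] == "mass_action") " * c" else "", "\n", sep = "")
  invisible(x)
}

star_rates_at <- function(scheme, c) {
  k <- scheme$k
  ifelse(scheme$kinds == "mass_action", k * c, k)
}

#' Star model at a given concentration
#'
#' @param scheme a `ligand_scheme`.
#' @param c positive ligand concentration.
#' @return the star `aggregated_model` C1-O3-C2 at concentration `c`.
#' @export
star_model_at <- function(scheme, c) {
  if (c <= 0) stop("concentration must be positive")
  q <- star_rates_at(scheme, c)
  three_state(0, q["q13"], 0, q["q23"], q["q31"], q["q32"])
}

#' Equivalent chain rates at a given concentration
#'
#' Transforms the star model at concentration `c` into its equivalent chain
#' C1-C2-O3 and returns the four chain rates.  Any negative solved rate is
#' reported via the `feasible` attribute rather than silently clipped.
#'
#' @param scheme a `ligand_scheme`.
#' @param c positive concentration.
#' @return named vector `(q12, q21, q23, q32)` of chain rates, with
#'   attribute `"feasible"`.
#' @export
chain_rates_at <- function(scheme, c) {
  if (c <= 0) stop("concentration must be positive")
  q <- star_rates_at(scheme, c)
  lambda_O <- q["q31"] + q["q32"]
  q23c <- (q["q13"] * q["q31"] + q["q23"] * q["q32"]) / lambda_O
  q12c <- q["q13"] * q["q23"] / q23c
  q21c <- q["q13"] + q["q23"] - q12c - q23c
  out <- c(q12 = unname(q12c), q21 = unname(q21c), q23 = unname(q23c),
           q32 = unname(lambda_O))
  attr(out, "feasible") <- all(out >= -1e-12)
  out
}

#' Chain model at a given concentration
#'
#' @inheritParams chain_rates_at
#' @return the chain `aggregated_model` (rates from [chain_rates_at()]).
#' @export
chain_model_at <- function(scheme, c) {
  r <- chain_rates_at(scheme, c)
  if (!attr(r, "feasible")) stop("chain rates at c = ", c, " are negative")
  three_state(r["q12"], 0, r["q21"], r["q23"], 0, r["q32"])
}

RATE_FORM_KINDS <- c("constant", "mass_action", "mass_action_offset",
                     "michaelis_menten", "quadratic_over_linear")

fit_rate_form <- function(cs, vs, rel_tol = 1e-8) {
  # classify v(c) into the five-form library by exact interpolation on a few
  # support points followed by a residual check on the whole grid
  stopifnot(length(cs) >= 5L)
  relres <- function(pred) max(abs(pred - vs)) / max(abs(vs), 1e-300)
  # constant
  f <- list(kind = "constant", constants = c(k = vs[1]))
  if (relres(rep(vs[1], length(cs))) <= rel_tol) return(c(f, residual = relres(rep(vs[1], length(cs)))))
  # mass action: k c
  k <- vs[1] / cs[1]
  if (relres(k * cs) <= rel_tol)
    return(list(kind = "mass_action", constants = c(k = k), residual = relres(k * cs)))
  # mass action with offset: k c + K
  i2 <- length(cs)
  k <- (vs[i2] - vs[1]) / (cs[i2] - cs[1]); K <- vs[1] - k * cs[1]
  if (relres(k * cs + K) <= rel_tol)
    return(list(kind = "mass_action_offset", constants = c(k = k, K = K),
                residual = relres(k * cs + K)))
  # Michaelis-Menten: F c / (H + c); F c - H v = v c, linear in (F, H)
  idx <- c(1L, length(cs))
  Amat <- cbind(cs[idx], -vs[idx])
  sol <- tryCatch(solve(Amat, vs[idx] * cs[idx]), error = function(e) NULL)
  if (!is.null(sol)) {
    Fc <- sol[1]; H <- sol[2]
    pred <- Fc * cs / (H + cs)
    if (all(is.finite(pred)) && relres(pred) <= rel_tol)
      return(list(kind = "michaelis_menten", constants = c(F = Fc, H = H),
                  residual = relres(pred)))
  }
  # quadratic over linear: (a c^2 + b c + g) / (H + c), linear in (a,b,g,H)
  idx <- unique(round(seq(1, length(cs), length.out = 4)))
  if (length(idx) == 4L) {
    Amat <- cbind(cs[idx]^2, cs[idx], 1, -vs[idx])
    sol <- tryCatch(solve(Amat, vs[idx] * cs[idx]), error = function(e) NULL)
    if (!is.null(sol)) {
      a <- sol[1]; b <- sol[2]; g <- sol[3]; H <- sol[4]
      pred <- (a * cs^2 + b * cs + g) / (H + cs)
      if (all(is.finite(pred)) && relres(pred) <= rel_tol) {
        disc <- b^2 - 4 * a * g
        root <- if (abs(disc) <= 1e-6 * max(b^2, abs(4 * a * g))) -b / (2 * a) else NA_real_
        return(list(kind = "quadratic_over_linear",
                    constants = c(F = a, H = H, root = root),
                    residual = relres(pred)))
      }
    }
  }
  list(kind = "unclassified", constants = numeric(0),
       residual = NA_real_)
}

#' Classify the functional forms of the transformed chain rates
#'
#' Evaluates [chain_rates_at()] over a concentration grid and fits each of
#' the four chain rates to a small library of forms: constant `k`, mass
#' action `k c`, mass action with offset `k c + K`, Michaelis-Menten
#' `F c/(H + c)`, and quadratic-over-linear `F (c - r)^2/(H + c)`.  Fits
#' are by exact interpolation on support points with a full-grid residual
#' check; a rate matching none of the forms is reported `"unclassified"`
#' with its residuals, never forced.
#'
#' @param scheme a `ligand_scheme`.
#' @param c_grid at least 20 positive concentrations (default: 40 points
#'   log-spaced on `[1e-3, 1e3]`).
#' @return named list over `q12`, `q21`, `q23`, `q32`; each entry has
#'   `kind`, `constants` and `residual`.
#' @export
classify_forms <- function(scheme, c_grid = NULL) {
  if (is.null(c_grid)) c_grid <- exp(seq(log(1e-3), log(1e3), length.out = 40))
  if (length(c_grid) < 20L) stop("c_grid needs at least 20 points")
  c_grid <- sort(c_grid)
  vals <- vapply(c_grid, function(c) chain_rates_at(scheme, c), numeric(4))
  out <- lapply(seq_len(4), function(i) fit_rate_form(c_grid, vals[i, ]))
  names(out) <- rownames(vals)
  out
}

#' Report unexpected ligand dependencies in the transformed chain
#'
#' Under a sequential-binding reading of the chain C1-C2-O3, the forward
#' transitions (`q12`, `q23`) may carry ligand dependence (binding) but
#' should vanish at `c = 0`, while the backward transitions (`q21`, `q32`)
#' would ordinarily be ligand-independent (unbinding).  The report lists
#' every transformed rate whose fitted form breaks these expectations —
#' the signature that the chain was obtained by reparametrising a star
#' rather than built mechanistically.
#'
#' @param scheme a `ligand_scheme`.
#' @param c_grid as in [classify_forms()].
#' @return data.frame with columns `rate`, `kind`, `why`; zero rows when
#'   nothing is unexpected.
#' @export
unexpected_dependency_report <- function(scheme, c_grid = NULL) {
  forms <- classify_forms(scheme, c_grid)
  rows <- list()
  flag <- function(rate, kind, why)
    rows[[length(rows) + 1L]] <<- data.frame(rate = rate, kind = kind, why = why)
  for (rate in c("q21", "q32")) {
    kind <- forms[[rate]]$kind
    if (!(kind %in% c("constant", "unclassified")))
      flag(rate, kind, "backward (unbinding-like) transition acquires ligand dependence")
  }
  for (rate in c("q12", "q23")) {
    kind <- forms[[rate]]$kind
    if (kind == "mass_action_offset")
      flag(rate, kind, "binding-like transition has a nonzero ligand-independent offset")
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(rate = character(0), kind = character(0), why = character(0))
}
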