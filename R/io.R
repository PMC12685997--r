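# Model files and fixtures.
#
# Model JSON dialect (schema version 1):
#   { "version": 1,
#     "states":  ["C1", "C2", "O3"],
#     "classes": {"C1": "closed", "C2": "closed", "O3": "open"},
#     "rates":   {"C1->O3": 1.5, "O3->C1": 0.2, ...} }
# Absent rates are zero; the diagonal is never stored; rates must be
# strictly positive; unknown top-level fields are rejected.

MODEL_SCHEMA_VERSION <- 1L

#' Read an aggregated model from JSON
#'
#' @param path file path.
#' @return a validated `aggregated_model`; all schema violations are
#'   reported at once on failure.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  problems <- character(0)
  known <- c("version", "states", "classes", "rates")
  extra <- setdiff(names(obj), known)
  if (length(extra)) problems <- c(problems, paste0("unknown field: ", extra))
  if (is.null(obj$version)) problems <- c(problems, "missing schema version")
  else if (obj$version > MODEL_SCHEMA_VERSION)
    problems <- c(problems, paste0("schema version ", obj$version,
                                   " is newer than supported version ",
                                   MODEL_SCHEMA_VERSION))
  states <- as.character(obj$states)
  if (length(states) < 2L) problems <- c(problems, "need at least two states")
  if (anyDuplicated(states)) problems <- c(problems, "duplicate state labels")
  classes <- unlist(obj$classes)
  missing_cls <- setdiff(states, names(classes))
  if (length(missing_cls))
    problems <- c(problems, paste0("missing class label for state ", missing_cls))
  if (!all(classes %in% c("open", "closed")))
    problems <- c(problems, "classes must be 'open' or 'closed'")
  rates <- unlist(obj$rates)
  if (length(rates)) {
    bad_key <- !grepl("^[^>]+->[^>]+$", names(rates))
    if (any(bad_key)) problems <- c(problems, paste0("malformed rate key: ",
                                                     names(rates)[bad_key]))
    if (any(rates <= 0)) problems <- c(problems, paste0("non-positive rate ",
                                                        names(rates)[rates <= 0]))
  }
  if (length(problems)) stop("invalid model file ", path, ":\n  ",
                             paste(problems, collapse = "\n  "))
  n <- length(states)
  Q <- matrix(0, n, n, dimnames = list(states, states))
  for (key in names(rates)) {
    ft <- strsplit(key, "->", fixed = TRUE)[[1]]
    if (!all(ft %in% states)) stop("rate ", key, " references unknown state")
    if (ft[1] == ft[2]) stop("rate ", key, " is diagonal; diagonals are implied")
    Q[ft[1], ft[2]] <- rates[[key]]
  }
  aggregated_model(Q, classes[states], states)
}

#' Write an aggregated model to JSON
#'
#' Inverse of [read_model()]; rates are written in canonical (row-major,
#' state-order) key order so that write/read round trips are exact.
#'
#' @param model an `aggregated_model`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  off <- model$Q; diag(off) <- 0
  keys <- character(0); vals <- numeric(0)
  for (i in seq_along(model$states)) for (j in seq_along(model$states)) {
    if (off[i, j] > 0) {
      keys <- c(keys, paste0(model$states[i], "->", model$states[j]))
      vals <- c(vals, off[i, j])
    }
  }
  obj <- list(version = MODEL_SCHEMA_VERSION,
              states = model$states,
              classes = as.list(model$class_of),
              rates = stats::setNames(as.list(vals), keys))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

with_seed <- function(seed, code) {
  # run code under a fixed RNG state without disturbing the global stream
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Random model fixtures
#'
#' Reproducible random aggregated models for tests and demonstrations.
#' Rates are drawn i.i.d. log-uniform on `rate_range` (default
#' `[1e-2, 1e2]`, two decades either side of unit rate, the spread typical
#' of "fast" versus "slow" gating transitions).
#'
#' @param n_open,n_closed class sizes (each at least 1).
#' @param topology `"full"` (every ordered pair connected), `"star"`
#'   (every closed state connected to a single open hub; requires
#'   `n_open = 1`), `"chain"` (path through all closed then all open
#'   states), or `"random_connected"` (random spanning tree plus extra
#'   reversible edges).
#' @param seed integer seed; fixtures are deterministic in it.
#' @param rate_range positive length-2 vector of rate bounds.
#' @return an `aggregated_model` that passes [validate_model()].
#' @export
make_fixture <- function(n_open, n_closed, topology = c("full", "star", "chain", "random_connected"),
                         seed, rate_range = c(1e-2, 1e2)) {
  topology <- match.arg(topology)
  if (n_open < 1 || n_closed < 1) stop("need at least one state per class")
  if (topology == "star" && n_open != 1)
    stop("star topology requires a single open hub state")
  n <- n_open + n_closed
  states <- c(paste0("C", seq_len(n_closed)), paste0("O", n_closed + seq_len(n_open)))
  classes <- c(rep("closed", n_closed), rep("open", n_open))
  with_seed(seed, {
    rate <- function(k) exp(stats::runif(k, log(rate_range[1]), log(rate_range[2])))
    edges <- switch(topology,
      full = t(utils::combn(n, 2)),
      star = cbind(seq_len(n_closed), n),
      chain = cbind(seq_len(n - 1L), seq.int(2L, n)),
      random_connected = {
        # random spanning tree (random attachment), then extra edges
        e <- cbind(vapply(seq.int(2L, n), function(v) sample.int(v - 1L, 1L), integer(1)),
                   seq.int(2L, n))
        others <- t(utils::combn(n, 2))
        keep <- stats::runif(nrow(others)) < 0.3
        unique(rbind(e, others[keep, , drop = FALSE]))
      })
    Q <- matrix(0, n, n, dimnames = list(states, states))
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      Q[i, j] <- rate(1); Q[j, i] <- rate(1)
    }
    aggregated_model(Q, classes, states)
  })
}
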