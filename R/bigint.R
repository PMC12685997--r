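# Minimal exact big-integer arithmetic used by the enumeration module.
#
# Table-1 style counts reach ~1e10 and intermediate products in the inverse
# Euler transform and cycle-index substitutions exceed 2^53, so IEEE doubles
# cannot carry them exactly.  Numbers are stored sign/magnitude with limbs in
# base 1e7 (little-endian), so every intermediate product of a limb with a
# small multiplier stays below 2^53 and double arithmetic on limbs is exact.
#
# All functions are internal; only what the enumeration code needs is
# implemented: add, subtract, compare, full multiply, multiply/divide by a
# "small" integer (< ~9e8), and decimal conversion.

BI_BASE <- 1e7

# magnitude = numeric vector of limbs, little-endian, no trailing zeros;
# numeric(0) is zero.

mag_trim <- function(m) {
  n <- length(m)
  while (n > 0L && m[n] == 0) n <- n - 1L
  m[seq_len(n)]
}

mag_carry <- function(m) {
  # normalize limbs into [0, BI_BASE)
  repeat {
    c <- floor(m / BI_BASE)
    if (all(c == 0)) break
    m <- m - c * BI_BASE
    m <- c(m, 0)[seq_len(length(m) + 1L)]
    idx <- seq_along(c) + 1L
    m[idx] <- m[idx] + c
  }
  mag_trim(m)
}

mag_cmp <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  if (length(a) == 0L) return(0L)
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(if (a[i] > b[i]) 1L else -1L)
  }
  0L
}

mag_add <- function(a, b) {
  n <- max(length(a), length(b))
  x <- numeric(n)
  x[seq_along(a)] <- a
  x[seq_along(b)] <- x[seq_along(b)] + b
  mag_carry(x)
}

mag_sub <- function(a, b) {
  # requires a >= b
  n <- length(a)
  x <- a
  x[seq_along(b)] <- x[seq_along(b)] - b
  for (i in seq_len(n)) {
    if (x[i] < 0) {
      x[i] <- x[i] + BI_BASE
      x[i + 1L] <- x[i + 1L] - 1
    }
  }
  mag_trim(x)
}

mag_mul_small <- function(a, s) {
  # s a non-negative integer-valued double < ~9e8
  if (s == 0 || length(a) == 0L) return(numeric(0))
  x <- a * s
  # limb*s <= (1e7-1)*9e8 < 9e15 < 2^53: exact
  mag_carry(x)
}

mag_mul <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(numeric(0))
  res <- numeric(length(a) + length(b))
  for (j in seq_along(b)) {
    if (b[j] == 0) next
    part <- mag_mul_small(a, b[j])
    idx <- seq_along(part) + (j - 1L)
    res[idx] <- res[idx] + part
    res <- mag_carry(res)
    res <- c(res, numeric(length(a) + length(b) - length(res)))
  }
  mag_trim(res)
}

mag_divmod_small <- function(a, d) {
  # d a positive integer-valued double < ~9e8; returns list(q = mag, r = double)
  if (length(a) == 0L) return(list(q = numeric(0), r = 0))
  q <- numeric(length(a))
  r <- 0
  for (i in rev(seq_along(a))) {
    x <- r * BI_BASE + a[i]   # < 9e8*1e7 + 1e7 < 2^53: exact
    q[i] <- floor(x / d)
    r <- x - q[i] * d
  }
  list(q = mag_trim(q), r = r)
}

bi <- function(x) {
  # construct from an integer-valued double with |x| < 2^53
  stopifnot(is.numeric(x), length(x) == 1L, x == floor(x), abs(x) < 2^53)
  s <- sign(x)
  m <- numeric(0)
  x <- abs(x)
  while (x > 0) {
    m <- c(m, x %% BI_BASE)
    x <- floor(x / BI_BASE)
  }
  structure(list(s = s, m = m), class = "bigint")
}

bi_zero <- function() structure(list(s = 0, m = numeric(0)), class = "bigint")

is_bigint <- function(x) inherits(x, "bigint")

as_bi <- function(x) if (is_bigint(x)) x else bi(x)

bi_norm <- function(s, m) {
  if (length(m) == 0L) s <- 0
  structure(list(s = s, m = m), class = "bigint")
}

bi_add <- function(a, b) {
  a <- as_bi(a); b <- as_bi(b)
  if (a$s == 0) return(b)
  if (b$s == 0) return(a)
  if (a$s == b$s) return(bi_norm(a$s, mag_add(a$m, b$m)))
  cmp <- mag_cmp(a$m, b$m)
  if (cmp == 0L) return(bi_zero())
  if (cmp > 0L) bi_norm(a$s, mag_sub(a$m, b$m)) else bi_norm(b$s, mag_sub(b$m, a$m))
}

bi_neg <- function(a) bi_norm(-a$s, a$m)

bi_sub <- function(a, b) bi_add(as_bi(a), bi_neg(as_bi(b)))

bi_mul <- function(a, b) {
  a <- as_bi(a); b <- as_bi(b)
  if (a$s == 0 || b$s == 0) return(bi_zero())
  bi_norm(a$s * b$s, mag_mul(a$m, b$m))
}

bi_mul_small <- function(a, s) {
  a <- as_bi(a)
  stopifnot(s == floor(s), abs(s) < 9e8)
  if (s == 0 || a$s == 0) return(bi_zero())
  bi_norm(a$s * sign(s), mag_mul_small(a$m, abs(s)))
}

bi_divmod_small <- function(a, d) {
  # division with remainder by positive d < ~9e8; truncated toward zero
  a <- as_bi(a)
  stopifnot(d > 0, d == floor(d), d < 9e8)
  dm <- mag_divmod_small(a$m, d)
  list(q = bi_norm(a$s, dm$q), r = a$s * dm$r)
}

bi_div_exact <- function(a, d) {
  dm <- bi_divmod_small(a, d)
  if (dm$r != 0) stop("exact division failed: remainder ", dm$r, " dividing by ", d)
  dm$q
}

bi_cmp <- function(a, b) {
  a <- as_bi(a); b <- as_bi(b)
  if (a$s != b$s) return(sign(a$s - b$s))
  if (a$s == 0) return(0L)
  a$s * mag_cmp(a$m, b$m)
}

bi_is_zero <- function(a) as_bi(a)$s == 0

#' @export
format.bigint <- function(x, ...) {
  if (x$s == 0) return("0")
  digits <- vapply(rev(x$m), function(l) sprintf("%07d", l), character(1))
  digits[1] <- sub("^0+", "", digits[1])
  paste0(if (x$s < 0) "-" else "", paste(digits, collapse = ""))
}

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.bigint <- function(x, ...) format(x)

#' @export
as.double.bigint <- function(x, ...) {
  if (x$s == 0) return(0)
  x$s * sum(x$m * BI_BASE^(seq_along(x$m) - 1))
}

bi_from_string <- function(s) {
  s <- trimws(s)
  sg <- 1
  if (startsWith(s, "-")) { sg <- -1; s <- substring(s, 2L) }
  stopifnot(grepl("^[0-9]+$", s))
  m <- numeric(0)
  while (nchar(s) > 0L) {
    k <- max(1L, nchar(s) - 6L)
    m <- c(m, as.numeric(substring(s, k)))
    s <- substring(s, 1L, k - 1L)
  }
  bi_norm(if (all(m == 0)) 0 else sg, mag_trim(m))
}

# polynomial with bigint coefficients: plain list, index i = degree i-1
bipoly_zero <- function(len) replicate(len, bi_zero(), simplify = FALSE)

bipoly_trim <- function(p) {
  n <- length(p)
  while (n > 1L && bi_is_zero(p[[n]])) n <- n - 1L
  p[seq_len(n)]
}

bipoly_add <- function(p, q) {
  n <- max(length(p), length(q))
  out <- bipoly_zero(n)
  for (i in seq_along(p)) out[[i]] <- p[[i]]
  for (i in seq_along(q)) out[[i]] <- bi_add(out[[i]], q[[i]])
  out
}

# multiply polynomial by (1 + t^i): p + shift(p, i)
bipoly_mul_1plus <- function(p, i) {
  shifted <- c(bipoly_zero(i), p)
  bipoly_add(p, shifted)
}

bipoly_mul_small <- function(p, s) lapply(p, bi_mul_small, s = s)
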