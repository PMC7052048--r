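# Arbitrary-precision nonnegative integers.
#
# History counts overflow 2^64 already at moderate sizes, so every count in
# the package is carried as an exact big integer.  Internally a number is a
# little-endian double vector of limbs in base 1e7 (so limb products stay
# well inside the 2^53 exact-integer range of doubles).  The raw limb
# representation is used in the dynamic-programming inner loops; the
# exported `bigint` class is a thin wrapper for user-facing values.

BIG_BASE <- 1e7

## ---- raw limb operations (internal) ----

big_norm <- function(x) {
  repeat {
    q <- x %/% BIG_BASE
    if (!any(q != 0)) break
    x <- x - q * BIG_BASE
    x <- c(x, 0)
    idx <- seq_along(q) + 1L
    x[idx] <- x[idx] + q
  }
  n <- length(x)
  while (n > 1L && x[n] == 0) n <- n - 1L
  x[seq_len(n)]
}

big_zero <- function() 0
big_one <- function() 1

big_is_zero <- function(a) length(a) == 1L && a[1L] == 0

big_add <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la < lb) { a <- c(a, numeric(lb - la)) } else if (lb < la) b <- c(b, numeric(la - lb))
  big_norm(a + b)
}

big_sum <- function(lst) {
  acc <- 0
  for (x in lst) acc <- big_add(acc, x)
  acc
}

big_mul <- function(a, b) {
  if (big_is_zero(a) || big_is_zero(b)) return(0)
  la <- length(a); lb <- length(b)
  acc <- numeric(la + lb)
  ia <- seq_len(la)
  for (j in seq_len(lb)) {
    acc[ia + (j - 1L)] <- acc[ia + (j - 1L)] + a * b[j]
    # renormalize periodically so partial sums stay exactly representable
    if (j %% 64L == 0L) {
      acc <- big_norm(acc)
      if (length(acc) < la + lb) acc <- c(acc, numeric(la + lb - length(acc)))
    }
  }
  big_norm(acc)
}

big_mul_small <- function(a, s) {
  stopifnot(s >= 0, s < BIG_BASE)
  if (s == 0) return(0)
  big_norm(a * s)
}

# exact division by a small positive integer; errors if not divisible
# unless remainder_ok
big_div_small <- function(a, s, remainder_ok = FALSE) {
  stopifnot(s >= 1, s < BIG_BASE)
  n <- length(a)
  q <- numeric(n)
  rem <- 0
  for (i in rev(seq_len(n))) {
    cur <- rem * BIG_BASE + a[i]
    q[i] <- cur %/% s
    rem <- cur %% s
  }
  if (!remainder_ok && rem != 0) stop("non-exact division in big_div_small")
  big_norm(q)
}

big_cmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(if (la < lb) -1L else 1L)
  for (i in rev(seq_len(la))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

big_from_num <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x),
            x <= 2^53)
  big_norm(x)
}

big_from_string <- function(s) {
  s <- gsub("^\\s+|\\s+$", "", s)
  stopifnot(grepl("^[0-9]+$", s))
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  nd <- nchar(s)
  nlimb <- ceiling(nd / 7)
  limbs <- numeric(nlimb)
  for (i in seq_len(nlimb)) {
    to <- nd - (i - 1L) * 7L
    from <- max(1L, to - 6L)
    limbs[i] <- as.numeric(substr(s, from, to))
  }
  big_norm(limbs)
}

big_to_string <- function(a) {
  n <- length(a)
  if (n == 1L) return(sprintf("%.0f", a))
  paste0(sprintf("%.0f", a[n]),
         paste(sprintf("%07.0f", rev(a[-n])), collapse = ""))
}

# natural log of a positive big integer (-Inf for zero)
big_log <- function(a) {
  if (big_is_zero(a)) return(-Inf)
  n <- length(a)
  top <- min(n, 3L)
  idx <- (n - top + 1L):n
  mant <- sum(a[idx] * BIG_BASE^(seq_len(top) - 1L))
  log(mant) + (n - top) * log(BIG_BASE)
}

# a/b as a double (both positive)
big_ratio <- function(a, b) {
  if (big_is_zero(b)) stop("division by zero in big_ratio")
  exp(big_log(a) - big_log(b))
}

big_to_num <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1L))

## ---- exported bigint class ----

#' Arbitrary-precision nonnegative integers
#'
#' History counts grow like \eqn{\rho^{-n}} and overflow machine integers
#' almost immediately, so the package carries them as exact big integers of
#' class `bigint`.  The class supports `+`, `*`, comparison operators
#' (against other `bigint`s, whole doubles below 2^53, or decimal strings),
#' `as.character()` (exact decimal digits), `as.numeric()` (possibly
#' lossy), and printing.
#'
#' @param x a whole nonnegative number below 2^53, a decimal string, or a
#'   `bigint`.
#' @return `as.bigint()` returns a `bigint`.
#' @examples
#' as.bigint("35066384") * as.bigint(2)
#' as.bigint(10)^3 > as.bigint("999")
#' @export
as.bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  limbs <- if (is.character(x)) big_from_string(x) else big_from_num(x)
  new_bigint(limbs)
}

new_bigint <- function(limbs) structure(list(limbs = limbs), class = "bigint")

#' @export
as.character.bigint <- function(x, ...) big_to_string(x$limbs)

#' @export
as.double.bigint <- function(x, ...) big_to_num(x$limbs)

#' @export
format.bigint <- function(x, ...) big_to_string(x$limbs)

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", big_to_string(x$limbs), "\n", sep = "")
  invisible(x)
}

#' @export
log.bigint <- function(x, base = exp(1)) big_log(x$limbs) / log(base)

#' @export
Ops.bigint <- function(e1, e2) {
  if (nargs() == 1L) stop("unary ", .Generic, " not supported for bigint")
  a <- as.bigint(e1)$limbs
  b <- as.bigint(e2)$limbs
  switch(.Generic,
    "+" = new_bigint(big_add(a, b)),
    "*" = new_bigint(big_mul(a, b)),
    "==" = big_cmp(a, b) == 0L,
    "!=" = big_cmp(a, b) != 0L,
    "<" = big_cmp(a, b) < 0L,
    ">" = big_cmp(a, b) > 0L,
    "<=" = big_cmp(a, b) <= 0L,
    ">=" = big_cmp(a, b) >= 0L,
    "^" = {
      stopifnot(length(e2) == 1L, e2 >= 0)
      out <- 1; base <- a
      for (i in seq_len(e2)) out <- big_mul(out, base)
      new_bigint(out)
    },
    stop("operator ", .Generic, " not supported for bigint")
  )
}

#' Catalan numbers as exact big integers
#'
#' `big_catalan(m)` returns the m-th Catalan number
#' \eqn{C_m = \binom{2m}{m}/(m+1)} computed through the exact ratio
#' recurrence \eqn{C_m = C_{m-1} \cdot 2(2m-1)/(m+1)}.  The number of
#' duplication-loss histories over a single-species tree equals
#' \eqn{C_{n-1}} (ordered binary duplication trees with n extant leaves),
#' which makes this a convenient independent oracle.
#'
#' @param m nonnegative integer index.
#' @return a [bigint][as.bigint].
#' @examples
#' big_catalan(4) # 14
#' @export
big_catalan <- function(m) {
  stopifnot(m >= 0, m == floor(m))
  c_limbs <- 1
  if (m > 0) {
    for (i in seq_len(m)) {
      c_limbs <- big_mul_small(c_limbs, 2 * (2 * i - 1))
      c_limbs <- big_div_small(c_limbs, i + 1)
    }
  }
  new_bigint(c_limbs)
}
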