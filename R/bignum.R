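# Exact arbitrary-precision non-negative integers for model-space counts.
#
# Graph-configuration counts such as choose(120, 60) ~ 1e35 overflow doubles,
# and the closure identity sum_d C(D, d) = 2^D must hold exactly, so counting
# is done in exact integer arithmetic.  Representation: little-endian digit
# vector in base 1e7 stored as doubles (digit * small-factor products stay far
# below 2^53).  Only the operations the combinatorics needs are provided.

BIGBASE <- 1e7

big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  d <- numeric(0)
  repeat {
    d <- c(d, x %% BIGBASE)
    x <- x %/% BIGBASE
    if (x == 0) break
  }
  structure(list(d = d), class = "bnsynth_bigint")
}

big_trim <- function(d) {
  n <- length(d)
  while (n > 1L && d[n] == 0) n <- n - 1L
  d[seq_len(n)]
}

# multiply by a small non-negative integer (< ~2^26)
big_mul_small <- function(a, k) {
  stopifnot(k >= 0, k == floor(k), k < 2^26)
  d <- a$d * k
  carry <- 0
  for (i in seq_along(d)) {
    v <- d[i] + carry
    d[i] <- v %% BIGBASE
    carry <- v %/% BIGBASE
  }
  while (carry > 0) {
    d <- c(d, carry %% BIGBASE)
    carry <- carry %/% BIGBASE
  }
  structure(list(d = big_trim(d)), class = "bnsynth_bigint")
}

# exact division by a small positive integer; errors if not divisible
big_div_small <- function(a, k) {
  stopifnot(k >= 1, k == floor(k), k < 2^26)
  d <- a$d
  out <- numeric(length(d))
  rem <- 0
  for (i in rev(seq_along(d))) {
    v <- rem * BIGBASE + d[i]
    out[i] <- v %/% k
    rem <- v %% k
  }
  if (rem != 0) bn_stop("internal", "non-exact big-integer division")
  structure(list(d = big_trim(out)), class = "bnsynth_bigint")
}

big_add <- function(a, b) {
  n <- max(length(a$d), length(b$d))
  da <- c(a$d, numeric(n - length(a$d)))
  db <- c(b$d, numeric(n - length(b$d)))
  d <- da + db
  carry <- 0
  for (i in seq_len(n)) {
    v <- d[i] + carry
    d[i] <- v %% BIGBASE
    carry <- v %/% BIGBASE
  }
  if (carry > 0) d <- c(d, carry)
  structure(list(d = big_trim(d)), class = "bnsynth_bigint")
}

big_eq <- function(a, b) {
  identical(big_trim(a$d), big_trim(b$d))
}

big_pow2 <- function(e) {
  out <- big_from_num(1)
  full <- e %/% 20L                     # 2^20 < 2^26, safe small factor
  for (i in seq_len(full)) out <- big_mul_small(out, 2^20)
  r <- e %% 20L
  if (r > 0) out <- big_mul_small(out, 2^r)
  out
}

#' @export
format.bnsynth_bigint <- function(x, ...) {
  d <- rev(big_trim(x$d))
  paste0(d[1L], paste(sprintf("%07d", d[-1L]), collapse = ""))
}

#' @export
print.bnsynth_bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.bnsynth_bigint <- function(x, ...) format(x)

#' @export
as.double.bnsynth_bigint <- function(x, ...) {
  sum(x$d * BIGBASE^(seq_along(x$d) - 1))
}

#' @export
"==.bnsynth_bigint" <- function(e1, e2) {
  if (!inherits(e1, "bnsynth_bigint")) e1 <- big_from_num(e1)
  if (!inherits(e2, "bnsynth_bigint")) e2 <- big_from_num(e2)
  big_eq(e1, e2)
}
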