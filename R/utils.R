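# Shared low-level helpers: state indexing, big power-of-two decimals.
#
# One convention is used throughout the package: a tuple of bits is read as an
# unsigned binary number with the FIRST element most significant.  The same
# convention orders truth-table rows (argument 1 most significant), network
# states (v1 most significant) and colours (first parameter constant most
# significant).

# 0-based code of a bit vector, first bit most significant
bits_to_code <- function(bits) {
  n <- length(bits)
  if (n == 0L) return(0)
  sum(as.numeric(bits) * 2^((n - 1L):0L))
}

# bit vector (first most significant) of a 0-based code
code_to_bits <- function(code, n) {
  if (n == 0L) return(integer(0))
  as.integer(bitwAnd(code %/% 2^((n - 1L):0L), 1))
}

# matrix of all 2^n bit vectors, row r = code r-1
all_bit_rows <- function(n) {
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  codes <- 0:(2^n - 1L)
  m <- vapply(seq_len(n), function(j) bitwAnd(codes %/% 2^(n - j), 1L), integer(2^n))
  matrix(m, nrow = 2^n, ncol = n)
}

# bit j (1-based, most significant first) of every state code 0..2^n-1
state_bit_column <- function(n, j) {
  bitwAnd((0:(2^n - 1L)) %/% 2^(n - j), 1L) == 1L
}

# index (1-based) of the state obtained by flipping bit j of every state
flip_index <- function(n, j) {
  bitwXor(0:(2^n - 1L), 2^(n - j)) + 1L
}

is_identifier <- function(x) {
  grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
}

#' Exact decimal representation of a power of two
#'
#' Returns `2^exponent` as an exact decimal string for arbitrary non-negative
#' integer exponents.  Counts of influence-graph-consistent networks are always
#' powers of two, which makes exact arbitrary-precision arithmetic a matter of
#' repeated doubling of a digit vector.
#'
#' @param exponent non-negative integer
#' @return character scalar with the exact decimal digits
#' @examples
#' pow2_decimal(11)   # "2048"
#' pow2_decimal(100)
#' @export
pow2_decimal <- function(exponent) {
  stopifnot(length(exponent) == 1L, exponent >= 0, exponent == floor(exponent))
  digits <- c(1L)  # little-endian decimal digits
  e <- as.numeric(exponent)
  while (e > 0) {
    digits <- digits * 2L
    carry <- 0L
    for (i in seq_along(digits)) {
      v <- digits[i] + carry
      digits[i] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
    e <- e - 1
  }
  paste(rev(digits), collapse = "")
}

# big-count object: exact decimal string plus exponent metadata
big_count <- function(exponent) {
  structure(pow2_decimal(exponent), exponent = as.numeric(exponent), class = "bnsketch_count")
}

#' @export
print.bnsketch_count <- function(x, ...) {
  e <- attr(x, "exponent")
  cat(unclass(x), sprintf("(= 2^%g)\n", e))
  invisible(x)
}

#' @export
as.numeric.bnsketch_count <- function(x, ...) 2^attr(x, "exponent")

`%||%` <- function(a, b) if (is.null(a)) b else a
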