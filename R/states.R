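#' State indexing for binary network states
#'
#' An `N`-region network has `2^N` possible activity states, each a vector of
#' +1 (high oscillatory power) and -1 (low). States are indexed by an integer
#' `k` in `0:(2^N - 1)`: bit `i - 1` of `k` corresponds to region `i`
#' (column `i` of a state matrix), and a set bit means +1. All modules share
#' this convention.
#'
#' @param k Integer state index (vectorized), each in `0:(2^N - 1)`.
#' @param N Number of regions.
#' @return `state_vector()` returns a length-`N` vector in `{-1, +1}` (or a
#'   matrix with one row per index when `k` has length > 1);
#'   `state_index()` its inverse; `state_matrix()` the full `2^N x N`
#'   enumeration with row `k + 1` holding state `k`;
#'   `state_pattern()` a compact string such as `"-++-"`.
#' @examples
#' state_vector(5, 3)        # bits 0 and 2 set -> +1 -1 +1
#' state_index(c(1, -1, 1))  # 5
#' @export
state_vector <- function(k, N) {
  stopifnot(all(k >= 0), all(k < 2^N))
  out <- vapply(seq_len(N), function(i) {
    ifelse(bitwAnd(as.integer(k), bitwShiftL(1L, i - 1L)) > 0L, 1, -1)
  }, numeric(length(k)))
  if (length(k) == 1L) as.numeric(out) else matrix(out, nrow = length(k))
}

#' @param s Numeric vector (or matrix, one state per row) with entries +1/-1.
#' @rdname state_vector
#' @export
state_index <- function(s) {
  if (is.matrix(s)) {
    N <- ncol(s)
    as.integer((s > 0) %*% 2^(seq_len(N) - 1))
  } else {
    sum((s > 0) * 2^(seq_along(s) - 1))
  }
}

#' @rdname state_vector
#' @export
state_matrix <- function(N) {
  stopifnot(N >= 1, N <= 25)
  k <- 0:(2^N - 1)
  m <- vapply(seq_len(N), function(i) {
    ifelse(bitwAnd(k, bitwShiftL(1L, i - 1L)) > 0L, 1, -1)
  }, numeric(length(k)))
  matrix(m, nrow = length(k))
}

#' @rdname state_vector
#' @export
state_pattern <- function(k, N) {
  vapply(k, function(kk) {
    bits <- bitwAnd(bitwShiftR(as.integer(kk), seq_len(N) - 1L), 1L)
    paste(ifelse(bits > 0, "+", "-"), collapse = "")
  }, character(1))
}

#' Hamming-1 neighbours of a network state
#'
#' Two states are adjacent on the energy landscape when their binary activity
#' vectors differ in exactly one region (Hamming distance 1). The `N`
#' neighbours of state `k` are its single-bit flips, returned in ascending
#' bit (region) order.
#'
#' @inheritParams state_vector
#' @return Integer vector of `N` state indices.
#' @examples
#' adjacent_states(0, 3) # 1 2 4
#' @export
adjacent_states <- function(k, N) {
  stopifnot(length(k) == 1L, k >= 0, k < 2^N)
  bitwXor(as.integer(k), bitwShiftL(1L, seq_len(N) - 1L))
}

# 2^N x N integer matrix; row k+1 lists the neighbours of state k.
neighbour_matrix <- function(N) {
  k <- 0:(2^N - 1)
  vapply(seq_len(N), function(i) bitwXor(k, bitwShiftL(1L, i - 1L)),
         integer(length(k)))
}
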