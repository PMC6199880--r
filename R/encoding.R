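#' Bits needed for one target-index gene segment
#'
#' A gene segment must be able to represent any target class index in
#' `0..n2` (0 = unmapped), so the binary code length is the smallest `b`
#' with `2^b >= n2 + 1`, i.e. `ceiling(log2(n2 + 1))`.
#'
#' @param n2 number of target-ontology concepts (>= 1).
#' @return integer bit length.
#' @examples
#' segment_bit_length(3)     # 2
#' segment_bit_length(3304)  # 12
#' @export
segment_bit_length <- function(n2) {
  stopifnot(n2 >= 1)
  b <- 1L
  while (2^b < n2 + 1) b <- b + 1L
  b
}

#' Bits needed for the threshold gene segment
#'
#' The trailing segment encodes the alignment filtering threshold on a
#' grid of step `num_accuracy`; it must represent the `ceil(1 /
#' num_accuracy) + 1` grid values in `[0, 1]`.
#'
#' @param num_accuracy numerical accuracy in `(0, 1]`.
#' @return integer bit length.
#' @examples
#' threshold_bit_length(0.01)  # 7
#' threshold_bit_length(0.5)   # 2
#' @export
threshold_bit_length <- function(num_accuracy) {
  stopifnot(num_accuracy > 0, num_accuracy <= 1)
  u <- ceiling(1 / num_accuracy)
  b <- 1L
  while (2^b < u + 1) b <- b + 1L
  b
}

#' Encoding geometry for a matching problem
#'
#' @param n1,n2 concept counts of the source and target ontologies.
#' @param num_accuracy threshold grid step (default 0.01).
#' @return a list of class `ccoem_encoding` with the per-segment and
#'   total bit lengths.
#' @export
encoding_params <- function(n1, n2, num_accuracy = 0.01) {
  stopifnot(n1 >= 1, n2 >= 1)
  sb <- segment_bit_length(n2)
  tb <- threshold_bit_length(num_accuracy)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 num_accuracy = num_accuracy,
                 segment_bits = sb, threshold_bits = tb,
                 threshold_levels = as.integer(ceiling(1 / num_accuracy)),
                 length = as.integer(n1 * sb + tb)),
            class = "ccoem_encoding")
}

# big-endian bit groups -> integers, vectorized over rows
bits_to_ints <- function(bits, nbits) {
  mat <- matrix(bits, ncol = nbits, byrow = TRUE)
  pow <- 2^((nbits - 1L):0L)
  as.integer(mat %*% pow)
}

#' Decode a chromosome into an alignment vector and threshold
#'
#' The first `n1` big-endian segments decode to target indices; a decoded
#' value `d > n2` is folded back into range as `d mod (n2 + 1)` so every
#' bit pattern is valid (0 means unmapped).  The trailing segment decodes
#' to `d * num_accuracy` after the same fold against the grid size, capped
#' at 1.
#'
#' @param bits integer vector of 0/1 of length `enc$length`.
#' @param enc an [encoding_params()].
#' @return a list of class `ccoem_solution` with `mapping` (integers in
#'   `0..n2`, length `n1`) and `threshold` (in `[0, 1]`).
#' @export
decode_chromosome <- function(bits, enc) {
  if (length(bits) != enc$length)
    stop("chromosome length ", length(bits),
         " does not match encoding length ", enc$length)
  nseg <- enc$n1 * enc$segment_bits
  mapping <- bits_to_ints(bits[seq_len(nseg)], enc$segment_bits)
  mapping <- mapping %% (enc$n2 + 1L)
  td <- bits_to_ints(bits[(nseg + 1L):enc$length], enc$threshold_bits)
  td <- td %% (enc$threshold_levels + 1L)
  structure(list(mapping = mapping,
                 threshold = min(td * enc$num_accuracy, 1)),
            class = "ccoem_solution")
}

#' Sample a chromosome from a probability vector
#'
#' Bit `i` is set to 1 exactly when a fresh uniform draw on `[0, 1)` is
#' below `pv[i]`; with `pv[i] = 1` the bit is always 1 and with
#' `pv[i] = 0` always 0.  Draws come from the current R RNG stream, or
#' can be injected for worked examples.
#'
#' @param pv numeric probability vector with elements in `[0, 1]`.
#' @param draws optional uniform draws of the same length (defaults to
#'   `runif(length(pv))`).
#' @return integer vector of 0/1.
#' @examples
#' sample_chromosome(c(0.5, 0.9, 0.3, 0.8),
#'                   draws = c(0.6, 0.5, 0.8, 0.9))  # 0 1 0 0
#' @export
sample_chromosome <- function(pv, draws = stats::runif(length(pv))) {
  stopifnot(length(draws) == length(pv), all(pv >= 0), all(pv <= 1))
  as.integer(draws < pv)
}

#' Move a probability vector toward an elite chromosome
#'
#' Each element gains `rate` where the elite bit is 1 and loses `rate`
#' where it is 0, clamped to `[0, 1]`.
#'
#' @param pv numeric probability vector.
#' @param elite integer 0/1 vector of the same length.
#' @param rate update step in `(0, 1)`.
#' @return the updated probability vector.
#' @examples
#' update_pv(c(0.5, 0.9, 0.3, 0.8), c(0L, 1L, 0L, 0L), 0.1)
#' # 0.4 1.0 0.2 0.7
#' @export
update_pv <- function(pv, elite, rate) {
  if (length(pv) != length(elite))
    stop("probability vector and elite have different lengths")
  stopifnot(rate > 0, rate < 1)
  pmin(pmax(pv + rate * (2 * elite - 1), 0), 1)
}

#' Bit-flip mutation
#'
#' Flips each bit independently with probability `pm`.
#'
#' @param bits integer 0/1 vector.
#' @param pm per-bit flip probability in `[0, 1]`.
#' @return mutated 0/1 vector.
#' @export
mutate_chromosome <- function(bits, pm) {
  stopifnot(pm >= 0, pm <= 1)
  if (pm == 0) return(bits)
  flip <- stats::runif(length(bits)) < pm
  bits[flip] <- 1L - bits[flip]
  bits
}
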