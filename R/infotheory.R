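# ---------------------------------------------------------------------------
# Plug-in information theory on discrete vectors.  All quantities are in
# bits (log base 2): the representation-entropy magnitudes the evaluation
# module reports only make sense on that scale, and mutual information uses
# the same base for internal consistency.  Estimation is maximum-likelihood
# ("plug-in") with no smoothing or bias correction.
# ---------------------------------------------------------------------------

#' Joint contingency counts of two discrete vectors
#'
#' @param x,y equal-length vectors of discrete states.
#' @return A list with `states_x`, `states_y`, integer `counts`
#'   (states_x x states_y) and total `n`.
#' @export
joint_counts <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ",
                                   length(y))
  if (length(x) == 0) stop("empty vectors")
  ux <- sort(unique(x))
  uy <- sort(unique(y))
  ix <- match(x, ux)
  iy <- match(y, uy)
  counts <- matrix(tabulate((iy - 1L) * length(ux) + ix,
                            nbins = length(ux) * length(uy)),
                   nrow = length(ux), ncol = length(uy),
                   dimnames = list(as.character(ux), as.character(uy)))
  list(states_x = ux, states_y = uy, counts = counts, n = length(x))
}

entropy_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Shannon entropy of a discrete vector (bits)
#'
#' Plug-in estimate H(x) = -sum p log2 p over the observed states.
#' Zero iff the vector is constant.
#'
#' @param x non-empty vector of discrete states.
#' @return Entropy in bits, >= 0.
#' @examples
#' entropy_bits(c(-1, -1, 1, 1))  # 1 bit
#' @export
entropy_bits <- function(x) {
  if (length(x) == 0) stop("empty vector")
  entropy_from_counts(tabulate(match(x, unique(x))))
}

#' Mutual information between two discrete vectors (bits)
#'
#' Plug-in estimate I(x; y) = H(x) + H(y) - H(x, y).  Non-negative by
#' construction (tiny negative rounding is clamped at 0) and symmetric.
#'
#' @param x,y equal-length discrete vectors.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ",
                                   length(y))
  if (length(x) == 0) stop("empty vectors")
  ux <- unique(x); uy <- unique(y)
  ix <- match(x, ux); iy <- match(y, uy)
  nx <- length(ux); ny <- length(uy)
  joint <- tabulate((iy - 1L) * nx + ix, nbins = nx * ny)
  hx <- entropy_from_counts(tabulate(ix, nbins = nx))
  hy <- entropy_from_counts(tabulate(iy, nbins = ny))
  hxy <- entropy_from_counts(joint)
  max(0, hx + hy - hxy)
}

#' Normalized mutual information in [0, 1]
#'
#' I(x; y) / min(H(x), H(y)).  When either vector is constant the
#' normalizer is zero and the value is 0 by convention (a constant feature
#' carries no information).
#'
#' @param x,y equal-length discrete vectors.
#' @return NMI in [0, 1].
#' @export
normalized_mi <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ",
                                   length(y))
  hx <- entropy_bits(x)
  hy <- entropy_bits(y)
  m <- min(hx, hy)
  if (m == 0) return(0)
  min(1, mutual_information(x, y) / m)
}
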