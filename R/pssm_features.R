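#' PSSM semi-composition (SC)
#'
#' Column means of the substitution-probability matrix,
#' \eqn{SC_j = \frac{1}{L}\sum_i P_{ij}}: the evolutionary analogue of
#' amino-acid composition, computed from the profile rather than the
#' sequence.  For a row-stochastic PSSM the 20 values sum to one.
#'
#' @param pssm a \code{"pssm"} object.
#' @return named numeric vector of 20 values in [0,1].
#' @export
pssm_sc <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  out <- colMeans(pssm$probs)
  names(out) <- paste0("SC_", pssm$column_order)
  out
}

#' PSSM auto-covariance (AC)
#'
#' Lagged covariance of each PSSM column with itself,
#' \eqn{AC_{k,j} = \frac{1}{L-k}\sum_{i=1}^{L-k}
#' (P_{ij}-\bar P_j)(P_{i+k,j}-\bar P_j)}, for lags k = 1..DF, where
#' \eqn{\bar P_j} is the column mean.  Captures how a residue's
#' substitution preferences co-vary with its neighbours' along the chain.
#' Output is amino-acid-major, lag-minor: 20 x DF values.
#'
#' Sequences with L <= DF are refused rather than zero-padded: padded
#' coefficients would be indistinguishable from genuine zero covariance.
#'
#' @param pssm a \code{"pssm"} object with \code{length > distance_factor}.
#' @param distance_factor maximum lag DF (default 10).
#' @return named numeric vector of \code{20 * distance_factor} values.
#' @export
pssm_ac <- function(pssm, distance_factor = 10L) {
  stopifnot(inherits(pssm, "pssm"))
  DF <- as.integer(distance_factor)
  if (DF < 1L) stop("distance_factor must be >= 1")
  L <- pssm$length
  if (L <= DF) {
    stop("protein '", pssm$protein_id, "' has L = ", L,
         " <= distance_factor = ", DF,
         ": lower the distance factor or drop the protein ",
         "(auto-covariance is not zero-padded)")
  }
  centered <- sweep(pssm$probs, 2L, colMeans(pssm$probs))
  out <- numeric(20L * DF)
  for (j in seq_len(20L)) {
    x <- centered[, j]
    for (k in seq_len(DF)) {
      out[(j - 1L) * DF + k] <-
        sum(x[seq_len(L - k)] * x[seq_len(L - k) + k]) / (L - k)
    }
  }
  names(out) <- paste0("AC_", rep(pssm$column_order, each = DF),
                       "_lag", rep(seq_len(DF), 20L))
  out
}
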