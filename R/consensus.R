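#' Evolutionary consensus sequence of a PSSM
#'
#' Replaces each position of the query by the amino acid with the maximum
#' substitution probability in that PSSM row, i.e.
#' \eqn{I_i = \arg\max_j P_{ij}}.  Ties are broken by the lowest column
#' index, which makes the result deterministic across platforms.
#'
#' @param pssm a \code{"pssm"} object.
#' @return a length-one character vector of class
#'   \code{"consensus_sequence"} spelling the L consensus residues, with a
#'   \code{protein_id} attribute.
#' @export
consensus_sequence <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  idx <- max.col(pssm$probs, ties.method = "first")
  structure(paste(pssm$column_order[idx], collapse = ""),
            protein_id = pssm$protein_id,
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat("Consensus sequence for '", attr(x, "protein_id"), "' (L = ",
      nchar(x), ")\n", unclass(x), "\n", sep = "")
  invisible(x)
}

#' Map a consensus sequence through a normalized physicochemical scale
#'
#' The 20 scale values are normalized once per scale, then looked up per
#' residue, giving the per-position attribute values \eqn{R_i \in [0,1]}
#' that the segmented density and autocorrelation descriptors consume.
#'
#' Normalization methods: \code{"minmax"} (default) maps each scale value v
#' to (v - min)/(max - min) over the 20 values, guaranteeing the [0,1]
#' range; \code{"zscore_clipped"} standardizes the 20 values, clips at
#' plus/minus 3 standard deviations and rescales \code{(z + 3)/6} into
#' [0,1], which is less sensitive to a single extreme residue value.
#'
#' @param cons a \code{"consensus_sequence"} (or plain character string over
#'   the 20 canonical residues).
#' @param scale an \code{"attribute_scale"}.
#' @param normalization \code{"minmax"} or \code{"zscore_clipped"}.
#' @return an object of class \code{"attribute_sequence"}: a numeric vector
#'   of length L in [0,1] with \code{protein_id}, \code{attribute_id} and
#'   \code{normalization} attributes.
#' @export
attribute_sequence <- function(cons, scale,
                               normalization = c("minmax", "zscore_clipped")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(scale, "attribute_scale"))
  v <- as.numeric(scale)
  names(v) <- names(scale)
  norm <- switch(normalization,
                 minmax = (v - min(v)) / (max(v) - min(v)),
                 zscore_clipped = {
                   z <- (v - mean(v)) / stats::sd(v)
                   (pmax(pmin(z, 3), -3) + 3) / 6
                 })
  res <- strsplit(as.character(cons), "")[[1]]
  if (length(res) == 0L) stop("empty consensus sequence")
  unknown <- setdiff(res, AA_CANONICAL)
  if (length(unknown)) {
    stop("consensus sequence contains non-canonical residue(s): ",
         paste(unknown, collapse = ", "))
  }
  structure(as.numeric(norm[res]),
            protein_id = attr(cons, "protein_id"),
            attribute_id = attr(scale, "attribute_id"),
            normalization = normalization,
            class = "attribute_sequence")
}

#' @export
print.attribute_sequence <- function(x, ...) {
  cat("Attribute sequence '", attr(x, "attribute_id"), "' for '",
      attr(x, "protein_id"), "' (L = ", length(x), ", ",
      attr(x, "normalization"), "-normalized)\n", sep = "")
  print(as.numeric(x))
  invisible(x)
}
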