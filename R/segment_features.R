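#' Segmentation configuration for the physicochemical descriptors
#'
#' Collects the tunables of the overlapped segmented density (OSD) and
#' autocorrelation (OSA) descriptors.  Defaults follow the published
#' parameterization: OSD segments every 5\% of the length up to 75\%
#' (15 nested segments per side), OSA segments every 10\% up to 70\%
#' (7 per side), distance factor 10.  Because the deepest segments pass the
#' midpoint, left and right segments overlap mid-sequence.
#'
#' \code{boundary_mode} decides where a d\% segment ends:
#' \code{"length_fraction"} takes the first \code{max(1, floor(d/100 * L))}
#' residues; \code{"mass_fraction"} takes the smallest prefix whose
#' attribute-value sum reaches d\% of the total attribute mass.
#'
#' @param osd_step,osd_max OSD segmentation step and maximum, in percent.
#' @param osa_step,osa_max OSA segmentation step and maximum, in percent.
#' @param distance_factor maximum autocorrelation lag (DF).
#' @param boundary_mode \code{"length_fraction"} or \code{"mass_fraction"}.
#' @param osd_normalize divide each OSD segment sum by its segment length
#'   (off by default: the descriptors are raw prefix sums).
#' @return an object of class \code{"seg_config"}.
#' @export
seg_config <- function(osd_step = 5L, osd_max = 75L,
                       osa_step = 10L, osa_max = 70L,
                       distance_factor = 10L,
                       boundary_mode = c("length_fraction", "mass_fraction"),
                       osd_normalize = FALSE) {
  boundary_mode <- match.arg(boundary_mode)
  for (nm in c("osd_step", "osd_max", "osa_step", "osa_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v != round(v) || v <= 0) {
      stop("'", nm, "' must be a positive integer")
    }
  }
  if (osd_max %% osd_step != 0L) stop("osd_step must divide osd_max")
  if (osa_max %% osa_step != 0L) stop("osa_step must divide osa_max")
  if (osd_max >= 100L || osa_max >= 100L) {
    stop("segment maxima must stay below 100 percent")
  }
  if (distance_factor < 1L) stop("distance_factor must be >= 1")
  structure(list(osd_step = as.integer(osd_step),
                 osd_max = as.integer(osd_max),
                 osa_step = as.integer(osa_step),
                 osa_max = as.integer(osa_max),
                 distance_factor = as.integer(distance_factor),
                 boundary_mode = boundary_mode,
                 osd_normalize = isTRUE(osd_normalize)),
            class = "seg_config")
}

#' @export
print.seg_config <- function(x, ...) {
  cat("Segmentation config: OSD ", x$osd_step, "..", x$osd_max,
      "%, OSA ", x$osa_step, "..", x$osa_max, "%, DF = ",
      x$distance_factor, ", boundaries by ", x$boundary_mode,
      if (x$osd_normalize) ", length-normalized OSD" else "", "\n", sep = "")
  invisible(x)
}

#' Last index of a d-percent segment counted from one sequence end
#'
#' @param attr_seq numeric attribute values (an \code{"attribute_sequence"}
#'   or plain vector).
#' @param percent segment extent in percent, 0 < percent < 100.
#' @param side \code{"left"} or \code{"right"}.
#' @param mode boundary rule, see [seg_config()].
#' @return number of residues in the segment (at least 1, at most L).
#' @export
segment_boundary <- function(attr_seq, percent,
                             side = c("left", "right"),
                             mode = c("length_fraction", "mass_fraction")) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  if (percent <= 0 || percent >= 100) stop("percent must be in (0, 100)")
  v <- as.numeric(attr_seq)
  L <- length(v)
  if (mode == "length_fraction") {
    return(min(L, max(1L, floor(percent / 100 * L))))
  }
  if (side == "right") v <- rev(v)
  total <- sum(v)
  if (total <= 0) { # all-zero attribute mass: fall back to the length rule
    return(min(L, max(1L, floor(percent / 100 * L))))
  }
  min(L, max(1L, which(cumsum(v) >= percent / 100 * total)[1L]))
}

#' Global density of an attribute sequence
#'
#' The mean attribute value \eqn{D = \sum_i R_i / L} over the whole
#' sequence.
#'
#' @inheritParams segment_boundary
#' @return a single number in [0,1] for normalized inputs.
#' @export
global_density <- function(attr_seq) {
  v <- as.numeric(attr_seq)
  if (length(v) == 0L) stop("empty attribute sequence")
  sum(v) / length(v)
}

#' Overlapped segmented density features (OSD)
#'
#' Prefix attribute sums over nested segments from both sequence ends, plus
#' the global density.  At the default configuration the segments cover
#' 5\%, 10\%, ..., 75\% of the length from each side, giving
#' 1 + 15 + 15 = 31 features.  Output order: global, left ascending d,
#' right ascending d.
#'
#' @inheritParams segment_boundary
#' @param cfg a \code{"seg_config"}.
#' @return named numeric vector of \code{1 + 2 * osd_max/osd_step} values.
#' @export
osd_features <- function(attr_seq, cfg = seg_config()) {
  stopifnot(inherits(cfg, "seg_config"))
  v <- as.numeric(attr_seq)
  if (length(v) == 0L) stop("empty attribute sequence")
  ds <- seq(cfg$osd_step, cfg$osd_max, by = cfg$osd_step)
  side_sums <- function(x, side) {
    vapply(ds, function(d) {
      b <- segment_boundary(x, d, side = side, mode = cfg$boundary_mode)
      s <- sum(x[seq_len(b)])
      if (cfg$osd_normalize) s / b else s
    }, 0)
  }
  left <- side_sums(v, "left")
  right <- side_sums(rev(v), "left") # right side = left of the reversal
  out <- c(global_density(v), left, right)
  names(out) <- c("OSD_global",
                  paste0("OSD_left_d", ds), paste0("OSD_right_d", ds))
  out
}

#' Overlapped segmented autocorrelation features (OSA)
#'
#' Lagged products of attribute values within nested segments from both
#' ends, plus a whole-sequence block.  For a segment of D residues and lag
#' i, the coefficient is \eqn{\frac{1}{D-i}\sum_{j=1}^{D-i} R_j R_{j+i}};
#' lags that do not fit (D - i <= 0) contribute 0 so the vector length is
#' fixed even for very short proteins.  Right-side coefficients are
#' computed on the reversed sequence.  At the defaults (7 segments per
#' side, DF = 10) this yields 70 + 70 + 10 = 150 features, ordered left
#' (segment-major, lag-minor), right, then global.
#'
#' @inheritParams osd_features
#' @return named numeric vector of \code{15 * distance_factor} values at
#'   the default segment counts.
#' @export
osa_features <- function(attr_seq, cfg = seg_config()) {
  stopifnot(inherits(cfg, "seg_config"))
  v <- as.numeric(attr_seq)
  if (length(v) < 2L) stop("autocorrelation needs a sequence of length >= 2")
  DF <- cfg$distance_factor
  ds <- seq(cfg$osa_step, cfg$osa_max, by = cfg$osa_step)
  lag_block <- function(x, D) {
    vapply(seq_len(DF), function(i) {
      if (D - i <= 0L) return(0)
      sum(x[seq_len(D - i)] * x[seq_len(D - i) + i]) / (D - i)
    }, 0)
  }
  side_block <- function(x) {
    unlist(lapply(ds, function(d) {
      D <- segment_boundary(x, d, side = "left", mode = cfg$boundary_mode)
      lag_block(x, D)
    }))
  }
  left <- side_block(v)
  right <- side_block(rev(v))
  glob <- lag_block(v, length(v))
  out <- c(left, right, glob)
  names(out) <- c(paste0("OSA_left_d", rep(ds, each = DF), "_lag",
                         rep(seq_len(DF), length(ds))),
                  paste0("OSA_right_d", rep(ds, each = DF), "_lag",
                         rep(seq_len(DF), length(ds))),
                  paste0("OSA_global_lag", seq_len(DF)))
  out
}
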