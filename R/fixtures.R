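## Dirichlet sampler built on rgamma; rows with all-zero draws (possible at
## tiny shape parameters) fall back to uniform.
rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  rs <- rowSums(g)
  zero <- rs == 0
  if (any(zero)) {
    g[zero, ] <- 1
    rs[zero] <- k
  }
  g / rs
}

#' Generate a synthetic PSSM
#'
#' Rows are drawn from a Dirichlet distribution centred on
#' \code{base_composition} with sharpness \code{concentration}; large
#' concentrations make every row approach the base composition.  The
#' result passes all PSSM invariants (row-stochastic L x 20), so the rest
#' of the pipeline cannot tell it from a parsed PSI-BLAST profile.
#'
#' @param L sequence length.
#' @param base_composition point on the 20-simplex (defaults to uniform).
#' @param concentration Dirichlet concentration (> 0), default 20.
#' @param seed integer seed.
#' @param protein_id identifier for the generated protein.
#' @return an object of class \code{"pssm"}.
#' @export
synth_pssm <- function(L, base_composition = rep(1 / 20, 20),
                       concentration = 20, seed = 1L,
                       protein_id = "synthetic") {
  if (L < 1L) stop("L must be >= 1")
  if (length(base_composition) != 20L || any(base_composition < 0) ||
      abs(sum(base_composition) - 1) > 1e-8) {
    stop("base_composition must be a point on the 20-simplex")
  }
  if (concentration <= 0) stop("concentration must be > 0")
  probs <- with_seed(seed,
                     rdirichlet_rows(L, concentration * pmax(base_composition,
                                                             1e-8)))
  new_pssm(protein_id = protein_id, probs = probs,
           column_order = PSSM_COL_ORDER, prob_source = "synthetic")
}

#' Synthetic attribute scale
#'
#' Twenty distinct values drawn uniformly on (0, 1); non-degenerate by
#' construction.
#'
#' @param seed integer seed.
#' @param attribute_id identifier for the generated scale.
#' @return an \code{"attribute_scale"}.
#' @export
synth_attribute_scale <- function(seed = 1L, attribute_id = "synthetic") {
  vals <- with_seed(seed, stats::runif(20))
  while (anyDuplicated(vals)) { # runif ties have probability ~0; be safe
    vals <- vals + seq_along(vals) * 1e-12
  }
  new_attribute_scale(stats::setNames(vals, AA_CANONICAL), attribute_id)
}

#' Specification for a synthetic labelled PSSM corpus
#'
#' @param n_classes number of location classes.
#' @param samples_per_class scalar, or one count per class (to emulate the
#'   strong imbalance of real localization benchmarks).
#' @param length_range (min, max) protein length, inclusive.
#' @param class_signal magnitude of the class-specific composition bias
#'   (>= 0); 0 makes classes indistinguishable, 0.5 makes the full
#'   pipeline separate them.
#' @param concentration Dirichlet sharpness of PSSM rows.
#' @param n_multilocation number of proteins additionally annotated to a
#'   second, different location (duplicated into two samples).
#' @param seed integer seed.
#' @return an object of class \code{"fixture_spec"}.
#' @export
fixture_spec <- function(n_classes = 4L, samples_per_class = 50L,
                         length_range = c(50L, 200L), class_signal = 0.5,
                         concentration = 20, n_multilocation = 0L,
                         seed = 1L) {
  if (n_classes < 1L) stop("n_classes must be >= 1")
  if (length(samples_per_class) == 1L) {
    samples_per_class <- rep(samples_per_class, n_classes)
  }
  if (length(samples_per_class) != n_classes ||
      any(samples_per_class < 1L)) {
    stop("samples_per_class must be a positive scalar or one count per class")
  }
  if (length(length_range) != 2L || length_range[1L] > length_range[2L] ||
      length_range[1L] < 2L) {
    stop("length_range must be (min, max) with 2 <= min <= max")
  }
  if (class_signal < 0) stop("class_signal must be >= 0")
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 length_range = as.integer(length_range),
                 class_signal = class_signal,
                 concentration = concentration,
                 n_multilocation = as.integer(n_multilocation),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Imbalanced fixture preset mirroring an 8-location corpus
#'
#' Class sizes follow the shape of the Gram-negative benchmark's location
#' distribution, scaled down by \code{scale}, so per-location reporting of
#' tiny classes (down to a handful of samples) is exercised.
#'
#' @param scale divisor applied to the reference class sizes (minimum class
#'   size clamps at 2).
#' @param ... passed to [fixture_spec()].
#' @return a \code{"fixture_spec"}.
#' @export
fixture_spec_imbalanced <- function(scale = 10, ...) {
  ref <- c(557, 124, 410, 133, 32, 12, 8, 180)
  fixture_spec(n_classes = 8L,
               samples_per_class = pmax(2L, as.integer(round(ref / scale))),
               ...)
}

#' Generate a synthetic labelled PSSM corpus
#'
#' Class c's base composition is the uniform simplex point mixed with a
#' class-specific signature distribution (mass spread over 5 signature
#' amino acids): \code{base_c = (uniform + class_signal * sig_c) /
#' (1 + class_signal)}.  At \code{class_signal = 0} all classes share the
#' uniform composition and carry no signal; as the signal grows, the
#' composition bias feeds every feature block (SC directly, OSD/OSA via
#' the consensus sequence, AC via row variability).
#'
#' @param spec a \code{"fixture_spec"}.
#' @return a list with \code{samples} (a \code{"sample_table"}),
#'   \code{pssms} (named list of \code{"pssm"}, one per protein),
#'   \code{manifest} (a \code{"dataset_manifest"}) and
#'   \code{compositions} (class base compositions).
#' @export
synth_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  nc <- spec$n_classes
  class_labels <- sprintf("loc%02d", seq_len(nc))
  ## deterministic signature residues per class: a seeded 5-of-20 draw
  compositions <- lapply(seq_len(nc), function(c) {
    sig <- numeric(20)
    sig[with_seed(derive_seed(spec$seed, 777000L + c), sample.int(20L, 5L))] <-
      1 / 5
    (rep(1 / 20, 20) + spec$class_signal * sig) / (1 + spec$class_signal)
  })
  ids <- character(0)
  labels <- list()
  pssms <- list()
  idx <- 0L
  for (c in seq_len(nc)) {
    for (s in seq_len(spec$samples_per_class[c])) {
      idx <- idx + 1L
      id <- sprintf("P%05d", idx)
      L <- with_seed(derive_seed(spec$seed, idx),
                     sample(spec$length_range[1L]:spec$length_range[2L], 1L))
      pssms[[id]] <- synth_pssm(L, compositions[[c]],
                                concentration = spec$concentration,
                                seed = derive_seed(spec$seed, 100000L + idx),
                                protein_id = id)
      ids <- c(ids, id)
      labels[[idx]] <- class_labels[c]
    }
  }
  if (spec$n_multilocation > 0L && nc >= 2L) {
    extra <- with_seed(derive_seed(spec$seed, 900000L),
                       sample(seq_along(ids),
                              min(spec$n_multilocation, length(ids))))
    for (i in extra) {
      other <- setdiff(class_labels, labels[[i]])
      labels[[i]] <- c(labels[[i]],
                       other[derive_seed(spec$seed, i) %% length(other) + 1L])
    }
  }
  manifest <- new_manifest(ids, labels, label_universe = class_labels)
  list(samples = expand_manifest(manifest), pssms = pssms,
       manifest = manifest, compositions = compositions)
}

#' Write a fixture corpus to disk in the pipeline's external formats
#'
#' Materializes a synthetic dataset exactly as the I/O layer expects real
#' data: one ASCII PSSM file per protein (PSI-BLAST dialect), a manifest
#' TSV and an attribute-scale TSV, so end-to-end tests exercise the same
#' readers as production runs.
#'
#' @param dataset result of [synth_dataset()].
#' @param dir output directory (created if missing).
#' @param scale an \code{"attribute_scale"} to write alongside (default: a
#'   synthetic one).
#' @return \code{dir}, invisibly.
#' @export
write_fixture_corpus <- function(dataset, dir,
                                 scale = synth_attribute_scale()) {
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  for (p in dataset$pssms) {
    write_pssm_ascii(p, file.path(dir, "pssm", paste0(p$protein_id, ".pssm")))
  }
  write_manifest(dataset$manifest, file.path(dir, "manifest.tsv"))
  write_attribute_scale(scale, file.path(dir, "scale.tsv"))
  invisible(dir)
}
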