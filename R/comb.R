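#' Assemble the 401-feature combined descriptor of one protein
#'
#' Runs the full per-protein pipeline: consensus sequence from the PSSM,
#' attribute sequence through the given physicochemical scale, then the
#' four feature blocks concatenated in the fixed order
#' OSD (31) | OSA (150) | SC (20) | AC (200) — 401 features at the default
#' configuration, with block boundaries at indices 31, 181 and 201.
#'
#' @param pssm a \code{"pssm"} with \code{length > distance_factor}.
#' @param scale an \code{"attribute_scale"}.
#' @param cfg a \code{"seg_config"}.
#' @param normalization scale normalization, see [attribute_sequence()].
#' @return a named numeric vector (class \code{"comb_vector"}) with
#'   attributes \code{protein_id}, \code{attribute_id}, \code{blocks}
#'   (block lengths) and \code{metadata} (boundary mode, prob source,
#'   normalization, config hash).
#' @export
build_comb_vector <- function(pssm, scale, cfg = seg_config(),
                              normalization = "minmax") {
  stopifnot(inherits(pssm, "pssm"), inherits(scale, "attribute_scale"),
            inherits(cfg, "seg_config"))
  if (pssm$length <= cfg$distance_factor) {
    stop("protein '", pssm$protein_id, "' is too short (L = ", pssm$length,
         " <= DF = ", cfg$distance_factor, ") for auto-covariance features")
  }
  cons <- consensus_sequence(pssm)
  aseq <- attribute_sequence(cons, scale, normalization = normalization)
  osd <- osd_features(aseq, cfg)
  osa <- osa_features(aseq, cfg)
  sc <- pssm_sc(pssm)
  ac <- pssm_ac(pssm, distance_factor = cfg$distance_factor)
  out <- c(osd, osa, sc, ac)
  attr_id <- attr(scale, "attribute_id")
  names(out) <- paste(attr_id, names(out), sep = "_")
  structure(out,
            protein_id = pssm$protein_id,
            attribute_id = attr_id,
            blocks = c(OSD = length(osd), OSA = length(osa),
                       SC = length(sc), AC = length(ac)),
            metadata = comb_metadata(cfg, pssm$prob_source, normalization),
            class = "comb_vector")
}

comb_metadata <- function(cfg, prob_source, normalization) {
  settings <- c(unlist(cfg, use.names = TRUE),
                prob_source = prob_source, normalization = normalization)
  c(as.list(settings),
    config_hash = fnv1a32(paste(names(settings), settings,
                                sep = "=", collapse = ";")))
}

#' @export
print.comb_vector <- function(x, ...) {
  b <- attr(x, "blocks")
  cat("Combined feature vector for '", attr(x, "protein_id"), "' (",
      length(x), " features: ",
      paste(names(b), b, sep = "=", collapse = ", "), "), attribute '",
      attr(x, "attribute_id"), "'\n", sep = "")
  invisible(x)
}

#' Build the feature matrix of a sample table
#'
#' One row per (protein, location) sample; the duplicated samples of a
#' multi-location protein share identical feature values and differ only
#' in label.  Rows follow the sample-table order.
#'
#' @param pssms named list of \code{"pssm"} objects (names = protein ids),
#'   or an unnamed list (names taken from each PSSM's \code{protein_id}).
#' @param samples a \code{"sample_table"}.
#' @param scale an \code{"attribute_scale"}.
#' @param cfg a \code{"seg_config"}.
#' @param normalization scale normalization.
#' @return numeric matrix (samples x features) with feature names as
#'   column names, sample protein ids as row names and the sample table in
#'   attribute \code{"samples"}; metadata in attribute \code{"metadata"}.
#' @export
build_feature_matrix <- function(pssms, samples, scale, cfg = seg_config(),
                                 normalization = "minmax") {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1L)
  if (is.null(names(pssms))) {
    names(pssms) <- vapply(pssms, function(p) p$protein_id, "")
  }
  missing <- setdiff(unique(samples$protein_id), names(pssms))
  if (length(missing)) {
    stop("no PSSM for protein(s): ", paste(missing, collapse = ", "))
  }
  vecs <- lapply(pssms[unique(samples$protein_id)], build_comb_vector,
                 scale = scale, cfg = cfg, normalization = normalization)
  mat <- do.call(rbind, vecs)[match(samples$protein_id,
                                    unique(samples$protein_id)), ,
                              drop = FALSE]
  rownames(mat) <- samples$protein_id
  colnames(mat) <- names(vecs[[1L]])
  attr(mat, "samples") <- samples
  attr(mat, "metadata") <- attr(vecs[[1L]], "metadata")
  mat
}

#' Write / read a feature matrix as CSV
#'
#' The CSV carries provenance metadata (boundary mode, probability source,
#' normalization, config hash) as leading \code{#key=value} comment lines,
#' then a header row of feature names and one row per sample with the
#' protein id and label in the first two columns.  Rebuilding from the
#' same corpus and configuration yields a byte-identical file.
#'
#' @param mat matrix from [build_feature_matrix()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(mat, path) {
  samples <- attr(mat, "samples")
  meta <- attr(mat, "metadata")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(paste0("#", names(meta), "=", unlist(meta)), con)
  }
  writeLines(paste(c("protein_id", "label", colnames(mat)), collapse = ","),
             con)
  lab <- if (!is.null(samples)) samples$label else rep(NA, nrow(mat))
  body <- apply(format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                1L, paste, collapse = ",")
  writeLines(paste(rownames(mat), lab, body, sep = ","), con)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @return \code{read_feature_matrix}: the matrix with \code{"samples"} and
#'   \code{"metadata"} attributes restored.
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- startsWith(lines, "#")
  meta <- NULL
  if (any(is_meta)) {
    kv <- strsplit(sub("^#", "", lines[is_meta]), "=", fixed = TRUE)
    meta <- stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  }
  tab <- utils::read.csv(text = lines[!is_meta], check.names = FALSE,
                         stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(mat) <- tab$protein_id
  samples <- data.frame(protein_id = tab$protein_id, label = tab$label,
                        group = tab$protein_id, stringsAsFactors = FALSE)
  class(samples) <- c("sample_table", "data.frame")
  attr(mat, "samples") <- samples
  attr(mat, "metadata") <- meta
  mat
}
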