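#' Read protein sequences from a FASTA file
#'
#' Multi-record FASTA with wrapped sequence lines.  Sequences are uppercased;
#' the 20 canonical residues plus the ambiguity codes X/B/Z/U are accepted.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns \code{id} and \code{sequence}, one row
#'   per record.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("FASTA format error: '", path, "' contains no records")
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("FASTA format error in '", path, "': sequence data at line 1 ",
         "before any '>' header")
  }
  rec <- cumsum(is_header)
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- sub("\\s.*$", "", ids) # first token is the id
  seqs <- vapply(split(lines[!is_header], rec[!is_header]),
                 function(x) toupper(paste(x, collapse = "")), "")
  out <- character(max(rec))
  out[as.integer(names(seqs))] <- seqs
  if (any(!nzchar(out))) {
    stop("FASTA format error in '", path, "': record with empty sequence (",
         paste(ids[!nzchar(out)], collapse = ", "), ")")
  }
  if (anyDuplicated(ids)) {
    stop("FASTA format error in '", path, "': duplicated id '",
         ids[duplicated(ids)][1L], "'")
  }
  bad <- grepl(paste0("[^", paste(c(AA_CANONICAL, AA_AMBIGUOUS), collapse = ""),
                      "]"), out)
  if (any(bad)) {
    stop("FASTA format error in '", path, "': non-amino-acid characters in ",
         "record '", ids[bad][1L], "'")
  }
  data.frame(id = ids, sequence = out, stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records data.frame with columns \code{id} and \code{sequence}.
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the text matrix produced by \code{psiblast -out_ascii_pssm}: header
#' lines, then one row per residue carrying the 1-based position, the query
#' residue, 20 log-odds integers, 20 weighted-percentage integers and two
#' trailing information columns.
#'
#' Substitution probabilities are built from one of two sources.  With
#' \code{prob_source = "percentages"} (default) the weighted-percentage block
#' is divided by 100 and each row renormalized to sum to one (an all-zero row
#' becomes the uniform distribution).  With \code{"sigmoid_logodds"} the
#' logistic function \eqn{1/(1+e^{-s})} is applied to the log-odds block
#' before the same renormalization; this matches how several sequence
#' feature-extraction pipelines squash log-odds scores into probabilities.
#'
#' @param path path to an ASCII PSSM file.
#' @param prob_source \code{"percentages"} or \code{"sigmoid_logodds"}.
#' @return an object of class \code{"pssm"}: a list with \code{protein_id},
#'   \code{length}, \code{probs} (L x 20 row-stochastic matrix),
#'   \code{residues}, \code{column_order} and \code{prob_source}.
#' @export
parse_pssm <- function(path, prob_source = c("percentages", "sigmoid_logodds")) {
  prob_source <- match.arg(prob_source)
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  is_data <- vapply(fields, function(f) {
    length(f) >= 42L && grepl("^[0-9]+$", f[1L]) &&
      grepl("^[A-Z]$", f[2L])
  }, TRUE)
  ## column-order header: a line of exactly 40 single letters
  hdr <- which(vapply(fields, function(f) {
    length(f) == 40L && all(grepl("^[A-Z]$", f))
  }, TRUE))
  column_order <- if (length(hdr) >= 1L) fields[[hdr[1L]]][1:20] else
    PSSM_COL_ORDER
  rows <- fields[is_data]
  if (length(rows) == 0L) {
    stop("PSSM format error in '", path, "': no data rows (L = 0)")
  }
  bad <- which(lengths(rows) < 42L)
  if (length(bad)) {
    stop("PSSM format error in '", path, "': wrong column count at data row ",
         bad[1L])
  }
  logodds <- t(vapply(rows, function(f) as.numeric(f[3:22]), numeric(20)))
  perc <- t(vapply(rows, function(f) as.numeric(f[23:42]), numeric(20)))
  raw <- switch(prob_source,
                percentages = perc / 100,
                sigmoid_logodds = 1 / (1 + exp(-logodds)))
  residues <- paste(vapply(rows, `[`, "", 2L), collapse = "")
  new_pssm(protein_id = sub("\\.[^.]*$", "", basename(path)),
           probs = raw, residues = residues,
           column_order = column_order, prob_source = prob_source)
}

#' Construct a PSSM object from a probability-like matrix
#'
#' Rows are renormalized to sum to one; an all-zero row is replaced by the
#' uniform distribution over the 20 amino acids.
#'
#' @param protein_id identifier of the query protein.
#' @param probs L x 20 matrix of non-negative values.
#' @param residues query sequence (length-L string); defaults to the
#'   consensus implied by \code{probs}.
#' @param column_order character vector of the 20 column letters.
#' @param prob_source provenance tag for the probability representation.
#' @return an object of class \code{"pssm"}.
#' @export
new_pssm <- function(protein_id, probs, residues = NULL,
                     column_order = PSSM_COL_ORDER,
                     prob_source = "percentages") {
  probs <- as.matrix(probs)
  if (ncol(probs) != 20L) stop("PSSM must have exactly 20 columns")
  if (nrow(probs) == 0L) stop("PSSM format error: L = 0")
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop("PSSM probabilities must be finite and non-negative")
  }
  stopifnot(length(column_order) == 20L, !anyDuplicated(column_order))
  rs <- rowSums(probs)
  zero <- rs == 0
  if (any(zero)) {
    probs[zero, ] <- 1 / 20
    rs[zero] <- 1
  }
  probs <- probs / rs
  colnames(probs) <- column_order
  if (is.null(residues)) {
    residues <- paste(column_order[max.col(probs, ties.method = "first")],
                      collapse = "")
  }
  if (nchar(residues) != nrow(probs)) {
    stop("PSSM residues string length (", nchar(residues),
         ") does not match row count (", nrow(probs), ")")
  }
  structure(list(protein_id = protein_id, length = nrow(probs),
                 probs = probs, residues = residues,
                 column_order = column_order, prob_source = prob_source),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM for '", x$protein_id, "': L = ", x$length,
      ", prob_source = ", x$prob_source, "\n", sep = "")
  invisible(x)
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Emits the header, the 40-letter column line, one data row per residue
#' (position, residue, 20 log-odds integers, 20 percentage integers, two
#' trailing columns) so files can be re-read with [parse_pssm()].  Percentages
#' are rounded to integers, so a round trip reproduces probabilities to about
#' 0.005 per cell.
#'
#' @param pssm a \code{"pssm"} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pssm_ascii <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  perc <- round(pssm$probs * 100)
  ## synthetic log-odds against a uniform background, clamped like BLAST
  lo <- round(2 * log2(pmax(pssm$probs, 1e-4) / 0.05))
  lo <- pmax(pmin(lo, 13), -16)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts"),
             con)
  writeLines(paste0("           ",
                    paste(sprintf("%3s", rep(pssm$column_order, 2)),
                          collapse = "")), con)
  res <- strsplit(pssm$residues, "")[[1]]
  for (i in seq_len(pssm$length)) {
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%3d", lo[i, ]), collapse = " "),
                      "  ",
                      paste(sprintf("%4d", perc[i, ]), collapse = " "),
                      sprintf("  %4.2f %8.2f", 0, 0)), con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Read a physicochemical attribute scale
#'
#' Accepts either a two-column table (amino-acid letter, value; tab- or
#' whitespace-separated, \code{#} comments allowed) or an AAindex flat-file
#' entry (\code{H}/\code{I} records with two rows of ten values in the
#' standard layout: A R N D C Q E G H I on the first row and
#' L K M F P S T W Y V on the second).
#'
#' @param path path to the scale file.
#' @param attribute_id identifier recorded on the returned scale; for AAindex
#'   files with several entries, selects the accession to read (default: the
#'   first entry).
#' @return an object of class \code{"attribute_scale"}: a named numeric
#'   vector of 20 values ordered \code{ACDEFGHIKLMNPQRSTVWY} with an
#'   \code{attribute_id} attribute.
#' @export
read_attribute_scale <- function(path, attribute_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^H ", lines))) {
    return(parse_aaindex(lines, attribute_id))
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "[\t ]+")
  if (any(lengths(fields) < 2L)) {
    stop("attribute-scale format error in '", path,
         "': expected two columns (amino acid, value)")
  }
  aa <- toupper(vapply(fields, `[`, "", 1L))
  val <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (any(is.na(val))) {
    stop("attribute-scale format error in '", path, "': non-numeric value ",
         "for residue ", aa[is.na(val)][1L])
  }
  if (anyDuplicated(aa)) {
    stop("attribute-scale format error in '", path, "': residue '",
         aa[duplicated(aa)][1L], "' listed more than once")
  }
  missing <- setdiff(AA_CANONICAL, aa)
  if (length(missing)) {
    stop("attribute-scale format error in '", path, "': missing residue(s) ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(aa, AA_CANONICAL)
  if (length(extra)) {
    stop("attribute-scale format error in '", path,
         "': unknown residue(s) ", paste(extra, collapse = ", "))
  }
  new_attribute_scale(stats::setNames(val, aa)[AA_CANONICAL],
                      attribute_id %||%
                        sub("\\.[^.]*$", "", basename(path)))
}

## AAindex flat-file entry -> attribute_scale
parse_aaindex <- function(lines, attribute_id = NULL) {
  starts <- grep("^H ", lines)
  acc <- sub("^H\\s+", "", lines[starts])
  pick <- if (is.null(attribute_id)) 1L else match(attribute_id, acc)
  if (is.na(pick)) {
    stop("AAindex entry '", attribute_id, "' not found (available: ",
         paste(acc, collapse = ", "), ")")
  }
  end <- c(starts[-1L] - 1L, length(lines))[pick]
  block <- lines[starts[pick]:end]
  i_line <- grep("^I ", block)
  if (length(i_line) != 1L || length(block) < i_line + 2L) {
    stop("AAindex format error: missing or truncated I record for entry '",
         acc[pick], "'")
  }
  row1 <- as.numeric(strsplit(trimws(block[i_line + 1L]), "\\s+")[[1]])
  row2 <- as.numeric(strsplit(trimws(block[i_line + 2L]), "\\s+")[[1]])
  if (length(row1) != 10L || length(row2) != 10L || any(is.na(c(row1, row2)))) {
    stop("AAindex format error: expected 2 x 10 numeric values for entry '",
         acc[pick], "'")
  }
  order1 <- strsplit("ARNDCQEGHI", "")[[1]]
  order2 <- strsplit("LKMFPSTWYV", "")[[1]]
  vals <- stats::setNames(c(row1, row2), c(order1, order2))[AA_CANONICAL]
  new_attribute_scale(vals, acc[pick])
}

#' Construct an attribute scale from 20 per-residue values
#'
#' @param values named numeric vector covering the 20 canonical amino acids.
#' @param attribute_id identifier (e.g. an AAindex accession).
#' @return an object of class \code{"attribute_scale"}.
#' @export
new_attribute_scale <- function(values, attribute_id) {
  stopifnot(is.numeric(values), length(values) == 20L)
  if (is.null(names(values))) names(values) <- AA_CANONICAL
  if (!setequal(names(values), AA_CANONICAL)) {
    stop("attribute scale must name each of the 20 canonical amino acids")
  }
  values <- values[AA_CANONICAL]
  if (any(!is.finite(values))) stop("attribute scale has non-finite values")
  if (max(values) == min(values)) {
    stop("degenerate attribute scale: all 20 values identical")
  }
  structure(values, attribute_id = attribute_id, class = "attribute_scale")
}

#' @export
print.attribute_scale <- function(x, ...) {
  cat("Attribute scale '", attr(x, "attribute_id"), "'\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Write an attribute scale as a two-column TSV
#'
#' @param scale an \code{"attribute_scale"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_attribute_scale <- function(scale, path) {
  stopifnot(inherits(scale, "attribute_scale"))
  writeLines(c(paste0("# attribute: ", attr(scale, "attribute_id")),
               paste(names(scale), format(as.numeric(scale), digits = 15),
                     sep = "\t")),
             path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' Tab-separated \code{protein_id<TAB>label[;label]} with \code{#} comments.
#' A protein annotated to several subcellular locations lists them
#' semicolon-separated on one line.
#'
#' @param path path to a manifest TSV.
#' @return an object of class \code{"dataset_manifest"}: a list with
#'   \code{ids}, \code{labels} (list of character vectors, one per protein)
#'   and \code{label_universe}.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("manifest '", path, "' has no entries")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("manifest format error in '", path, "': line without a label field")
  }
  ids <- vapply(fields, `[`, "", 1L)
  labels <- lapply(fields, function(f) {
    strsplit(f[2L], ";", fixed = TRUE)[[1]]
  })
  new_manifest(ids, labels)
}

#' Construct a dataset manifest
#'
#' @param ids character vector of protein ids (unique).
#' @param labels list of character vectors, one non-empty set per protein.
#' @param label_universe optional ordered label list; defaults to labels in
#'   order of first appearance.
#' @return an object of class \code{"dataset_manifest"}.
#' @export
new_manifest <- function(ids, labels, label_universe = NULL) {
  stopifnot(length(ids) == length(labels))
  if (anyDuplicated(ids)) {
    stop("manifest has a duplicated protein id: '",
         ids[duplicated(ids)][1L], "'")
  }
  if (any(lengths(labels) == 0L)) {
    stop("every manifest entry needs at least one location label")
  }
  seen <- unique(unlist(labels))
  if (is.null(label_universe)) {
    label_universe <- seen
  } else if (!all(seen %in% label_universe)) {
    stop("label(s) outside the declared universe: ",
         paste(setdiff(seen, label_universe), collapse = ", "))
  }
  structure(list(ids = ids, labels = labels,
                 label_universe = label_universe),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("Dataset manifest: ", length(x$ids), " proteins, ",
      length(x$label_universe), " locations, ",
      sum(lengths(x$labels)), " samples after expansion\n", sep = "")
  invisible(x)
}

#' Write a dataset manifest as TSV
#'
#' @param manifest a \code{"dataset_manifest"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  writeLines(paste(manifest$ids,
                   vapply(manifest$labels, paste, "", collapse = ";"),
                   sep = "\t"),
             path)
  invisible(path)
}

#' Expand a manifest into one sample per (protein, location) pair
#'
#' A protein annotated to two locations contributes two samples that share a
#' group key, so downstream cross-validation can keep them in the same fold.
#' This is the counting scheme under which 515 single-location plus 4
#' dual-location proteins make 523 samples.
#'
#' @param manifest a \code{"dataset_manifest"}.
#' @return an object of class \code{"sample_table"}: a data.frame with
#'   columns \code{protein_id}, \code{label} and \code{group}.
#' @export
expand_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  n <- lengths(manifest$labels)
  out <- data.frame(protein_id = rep(manifest$ids, n),
                    label = unlist(manifest$labels),
                    group = rep(manifest$ids, n),
                    stringsAsFactors = FALSE)
  attr(out, "label_universe") <- manifest$label_universe
  class(out) <- c("sample_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
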