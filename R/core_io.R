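#' Read contigs from a FASTA file
#'
#' Loads a multi-record FASTA into a contig table. Header tokens may encode
#' the hybrid source and chromosome as `"id|source|chromosome"`; headers
#' without the extra tokens get `NA` labels. Sequences are upper-cased and
#' validated against the alphabet `{A, C, G, T, N}`.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id`, `source`, `chromosome`, `length`,
#'   `sequence` (one row per record).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">wav17|WAV17|HSA21", "ACGTACGT"), fa)
#' read_contigs(fa)
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) abort("no records")
  seqs <- toupper(as.character(recs))
  headers <- names(recs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf(
      "illegal character '%s' at offset %d in record '%s'",
      substr(seqs[i], bad[i], bad[i]), bad[i] - 1L, headers[i]
    ))
  }
  tok <- strsplit(sub(" .*$", "", headers), "|", fixed = TRUE)
  ids <- vapply(tok, `[`, "", 1)
  if (anyDuplicated(ids)) abort("duplicate contig ids in FASTA")
  if (any(!nzchar(ids))) abort("empty contig id in FASTA")
  tibble(
    id = ids,
    source = vapply(tok, function(x) x[2] %||% NA_character_, ""),
    chromosome = vapply(tok, function(x) x[3] %||% NA_character_, ""),
    length = unname(nchar(seqs)),
    sequence = unname(seqs)
  )
}

#' Write contigs to a FASTA file
#'
#' Inverse of [read_contigs()]: headers are re-assembled as
#' `id|source|chromosome` when labels are present, bare `id` otherwise.
#'
#' @param contigs a contig tibble with at least `id` and `sequence`.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path, width = 80) {
  contigs <- .as_cohort_full(contigs)
  hdr <- ifelse(
    is.na(contigs$source) & is.na(contigs$chromosome),
    contigs$id,
    paste(contigs$id, contigs$source, contigs$chromosome, sep = "|")
  )
  x <- Biostrings::BStringSet(setNames(contigs$sequence, hdr))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# like .as_cohort but keeps/creates source and chromosome columns
.as_cohort_full <- function(x) {
  x <- as_tibble(x)
  if (!"source" %in% names(x)) x$source <- NA_character_
  if (!"chromosome" %in% names(x)) x$chromosome <- NA_character_
  x
}

#' Annotation records
#'
#' Constructs a validated annotation table. Coordinates are 0-based
#' half-open throughout the package.
#'
#' @param contig_id,start,end,feature_class vectors of equal length;
#'   `feature_class` must be one of `satellite_block`,
#'   `inverted_repeat_arm`, `foreign_insert`, `rdna_stub`, `homology_block`,
#'   `indel_marker`.
#' @param attributes optional character vector of `key=value;key=value`
#'   strings (or `"."`).
#' @param contig_length optional contig length(s) used to validate `end`.
#' @return a tibble of annotation records.
#' @export
annotation_records <- function(contig_id, start, end, feature_class,
                               attributes = ".", contig_length = NULL) {
  classes <- c(
    "satellite_block", "inverted_repeat_arm", "foreign_insert",
    "rdna_stub", "homology_block", "indel_marker"
  )
  if (!all(feature_class %in% classes)) {
    abort(paste0(
      "unknown feature_class: ",
      paste(setdiff(feature_class, classes), collapse = ", ")
    ))
  }
  if (any(start < 0) || any(end <= start)) {
    abort("annotation intervals must satisfy 0 <= start < end")
  }
  if (!is.null(contig_length) && any(end > contig_length)) {
    abort("annotation end beyond contig length")
  }
  tibble(
    contig_id = contig_id, start = as.integer(start), end = as.integer(end),
    feature_class = feature_class,
    attributes = rep_len(attributes, length(contig_id))
  )
}

#' Write annotations as BED6+1
#'
#' Records are written 0-based half-open with the feature class in the BED
#' name column, score 0, strand from an `strand=` attribute when present
#' (else `+`), and the serialized attribute string in a seventh column.
#' Output is sorted by (contig_id, start).
#'
#' @param records an annotation tibble (see [annotation_records()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  records <- arrange(records, .data$contig_id, .data$start)
  attrs <- records$attributes %||% rep(".", nrow(records))
  strand <- ifelse(grepl("strand=-", attrs), "-", "+")
  df <- data.frame(
    chrom = records$contig_id, chromStart = records$start,
    chromEnd = records$end, name = records$feature_class,
    score = 0L, strand = strand, attributes = attrs
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#'
#' @param path a BED6+1 file.
#' @return an annotation tibble.
#' @export
read_annotations <- function(path) {
  if (file.size(path) == 0) {
    return(annotation_records(character(0), integer(0), integer(0), character(0))[0, ])
  }
  df <- readr::read_tsv(
    path,
    col_names = c(
      "contig_id", "start", "end", "feature_class", "score", "strand",
      "attributes"
    ),
    col_types = "ciicicc", progress = FALSE
  )
  tibble(
    contig_id = df$contig_id, start = df$start, end = df$end,
    feature_class = df$feature_class, attributes = df$attributes
  )
}

#' Write a labelled matrix as TSV
#'
#' First column holds row labels (header `label`), remaining columns are the
#' matrix columns. Presence matrices keep integer 0/1 (NA for missing);
#' distance matrices keep full-precision decimals.
#'
#' @param m a matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path.
#' @return a matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
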