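#' Read precursor sequences from an amino-acid FASTA file
#'
#' Multi-record FASTA via Biostrings. A description line containing the token
#' `partial` marks the record as an incomplete precursor.
#'
#' @param path FASTA file.
#' @return list of [precursor()] objects.
#' @export
read_precursor_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  if (!length(aas)) stop("no sequences in '", path, "'", call. = FALSE)
  headers <- names(aas)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate ids in '", path, "'", call. = FALSE)
  }
  partial <- grepl("\\bpartial\\b", headers, ignore.case = TRUE)
  mapply(precursor, ids, as.character(aas), partial,
         SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write precursors to FASTA
#'
#' @param precursors list of [precursor()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_precursor_fasta <- function(precursors, path) {
  seqs <- Biostrings::AAStringSet(vapply(precursors, `[[`, "", "aa_seq"))
  names(seqs) <- vapply(precursors, function(p) {
    paste0(p$id, if (p$is_partial) " partial" else "")
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a segment annotation table as TSV
#'
#' @param annotations list of `precursor_annotation` objects (or one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotations, path) {
  tab <- annotation_table(annotations)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export annotated segments as GFF3
#'
#' Renders signal peptide, repeat domains and linkers as GFF3 features on
#' protein coordinates (GFF3 is 1-based, closed; the package's 0-based
#' half-open coordinates are converted on the way out). Requires the
#' rtracklayer and GenomicRanges packages.
#'
#' @param annotations list of `precursor_annotation` objects (or one).
#' @param path output `.gff3` file.
#' @return `path`, invisibly.
#' @export
export_annotation_gff3 <- function(annotations, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    stop("GFF3 export needs the rtracklayer and GenomicRanges packages",
         call. = FALSE)
  }
  tab <- annotation_table(annotations)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$precursor_id,
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end),
    type = tab$segment_type)
  gr$source <- "irdkit"
  gr$inhibitor_class <- tab$class
  gr$cys_count <- tab$cys_count
  gr$scaffold_deviation <- tab$scaffold_deviation
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read / write MALDI peak lists
#'
#' Peak lists are plain text, one mass (Da) per line; `#` comments allowed.
#'
#' @param path file path.
#' @return for the reader, a numeric vector of masses sorted ascending.
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  x <- as.numeric(lines)
  if (anyNA(x) || any(x <= 0)) {
    stop("peak list '", path, "' must contain positive numbers only",
         call. = FALSE)
  }
  sort(x)
}

#' @rdname read_peaklist
#' @param peaks numeric vector of masses (Da).
#' @export
write_peaklist <- function(peaks, path) {
  stopifnot(is.numeric(peaks), all(peaks > 0))
  writeLines(format(sort(peaks), trim = TRUE), path)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm a `distance_matrix` from [pairwise_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  m <- dm$values
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste0(formatC(dm$labels[i], width = -10),
                      paste(sprintf("%.6f", m[i, ]), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
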