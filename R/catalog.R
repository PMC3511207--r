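#' Build IRD and signal-peptide catalogs from annotated precursors
#'
#' Deduplicates repeat-domain and signal-peptide sequences across a set of
#' annotations by exact amino-acid identity. Labels are opaque integers
#' assigned in first-occurrence order; single-residue variants therefore get
#' distinct labels, matching how unique domains are counted in this family.
#'
#' @param annotations non-empty list of `precursor_annotation` objects.
#' @return list with `ird_catalog` (class `ird_catalog`: named vectors
#'   `entries` label -> sequence, `class_of`, `deviation_of`), `sp_catalog`
#'   (named vector label -> 25-aa sequence), and `compositions` (list of
#'   `gene_composition`: `gene_id`, `sp_label`, `ird_labels`, `n_irds`,
#'   `is_partial`).
#' @export
build_catalog <- function(annotations) {
  if (!length(annotations)) {
    stop("annotation list must be non-empty", call. = FALSE)
  }
  ird_seqs <- character(0); ird_class <- character(0); ird_dev <- logical(0)
  sp_seqs <- character(0)
  compositions <- vector("list", length(annotations))
  for (k in seq_along(annotations)) {
    ann <- annotations[[k]]
    sp_label <- NA_integer_
    if (!is.null(ann$signal_peptide)) {
      hit <- match(ann$signal_peptide$aa_seq, sp_seqs)
      if (is.na(hit)) {
        sp_seqs <- c(sp_seqs, ann$signal_peptide$aa_seq)
        hit <- length(sp_seqs)
      }
      sp_label <- hit
    }
    labels <- integer(ann$n_irds)
    for (j in seq_along(ann$irds)) {
      ird <- ann$irds[[j]]
      hit <- match(ird$aa_seq, ird_seqs)
      if (is.na(hit)) {
        ird_seqs <- c(ird_seqs, ird$aa_seq)
        ird_class <- c(ird_class, ird$reactive_site$inhibitor_class)
        ird_dev <- c(ird_dev, ird$scaffold_deviation)
        hit <- length(ird_seqs)
      }
      labels[j] <- hit
    }
    compositions[[k]] <- structure(list(
      gene_id = ann$precursor_id, sp_label = sp_label,
      ird_labels = labels, n_irds = length(labels),
      is_partial = ann$is_partial
    ), class = "gene_composition")
  }
  lab <- as.character(seq_along(ird_seqs))
  list(
    ird_catalog = structure(list(
      entries = setNames(ird_seqs, lab),
      class_of = setNames(ird_class, lab),
      deviation_of = setNames(ird_dev, lab)
    ), class = "ird_catalog"),
    sp_catalog = setNames(sp_seqs, as.character(seq_along(sp_seqs))),
    compositions = compositions
  )
}

#' @export
print.ird_catalog <- function(x, ...) {
  cat(sprintf("<IRD catalog  %d unique domain(s): %d TI, %d CI, %d other; %d scaffold variant(s)>\n",
              length(x$entries), sum(x$class_of == "TI", na.rm = TRUE),
              sum(x$class_of == "CI", na.rm = TRUE),
              sum(!x$class_of %in% c("TI", "CI")),
              sum(x$deviation_of, na.rm = TRUE)))
  invisible(x)
}

#' @export
print.gene_composition <- function(x, ...) {
  cat(sprintf("<%s  SP-%s  IRDs: %s%s>\n", x$gene_id,
              ifelse(is.na(x$sp_label), "?", x$sp_label),
              paste(x$ird_labels, collapse = ","),
              if (x$is_partial) " (partial)" else ""))
  invisible(x)
}

#' Catalog-level summary statistics
#'
#' @param catalog an `ird_catalog`.
#' @param compositions list of `gene_composition` objects.
#' @return list with `n_genes`, `genes_by_n_irds` (named integer vector,
#'   names = number of domains), `n_unique_irds`, `class_counts` (TI / CI /
#'   UNCLASSIFIED among unique domains; `NA` when classes are unknown, as for
#'   a label-only catalog), `n_cys_variants`, `n_sp_variants`.
#' @export
catalog_summary <- function(catalog, compositions) {
  stopifnot(inherits(catalog, "ird_catalog"))
  known <- names(catalog$entries)
  used <- unlist(lapply(compositions, function(g) as.character(g$ird_labels)))
  missing <- setdiff(unique(used), known)
  if (length(missing)) {
    stop("composition references label(s) absent from catalog: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_by <- vapply(compositions, `[[`, 0L, "n_irds")
  genes_by <- if (length(n_by)) {
    tab <- table(factor(n_by, levels = sort(unique(n_by))))
    setNames(as.integer(tab), names(tab))
  } else integer(0)
  cls <- catalog$class_of
  class_counts <- if (all(is.na(cls))) {
    c(TI = NA_integer_, CI = NA_integer_, UNCLASSIFIED = NA_integer_)
  } else {
    c(TI = sum(cls == "TI", na.rm = TRUE),
      CI = sum(cls == "CI", na.rm = TRUE),
      UNCLASSIFIED = sum(cls == "UNCLASSIFIED", na.rm = TRUE))
  }
  sp <- vapply(compositions, `[[`, 0L, "sp_label")
  list(
    n_genes = length(compositions),
    genes_by_n_irds = genes_by,
    n_unique_irds = length(catalog$entries),
    class_counts = class_counts,
    n_cys_variants = if (all(is.na(catalog$deviation_of))) NA_integer_
                     else sum(catalog$deviation_of, na.rm = TRUE),
    n_sp_variants = length(unique(sp[!is.na(sp)]))
  )
}

#' Export / import a catalog
#'
#' TSV export writes one row per label; JSON round-trips the full catalog
#' (entries, classes, deviation flags).
#'
#' @param catalog an `ird_catalog`.
#' @param path output file.
#' @return `path` invisibly (writers); an `ird_catalog` (reader).
#' @export
write_catalog_tsv <- function(catalog, path) {
  stopifnot(inherits(catalog, "ird_catalog"))
  df <- data.frame(label = names(catalog$entries),
                   aa_seq = unname(catalog$entries),
                   class = unname(catalog$class_of),
                   scaffold_deviation = unname(catalog$deviation_of))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
write_catalog_json <- function(catalog, path) {
  stopifnot(inherits(catalog, "ird_catalog"))
  jsonlite::write_json(list(entries = as.list(catalog$entries),
                            class_of = as.list(catalog$class_of),
                            deviation_of = as.list(catalog$deviation_of)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_json <- function(path) {
  x <- jsonlite::read_json(path)
  lab <- names(x$entries)
  structure(list(
    entries = setNames(vapply(x$entries, as.character, ""), lab),
    class_of = setNames(vapply(x$class_of, as.character, ""), lab),
    deviation_of = setNames(vapply(x$deviation_of, isTRUE, NA), lab)
  ), class = "ird_catalog")
}

# A catalog holding labels only (no sequences), as when compositions come
# from a transcribed table rather than from annotated sequences.
label_only_catalog <- function(labels) {
  lab <- as.character(sort(unique(as.integer(labels))))
  structure(list(
    entries = setNames(rep(NA_character_, length(lab)), lab),
    class_of = setNames(rep(NA_character_, length(lab)), lab),
    deviation_of = setNames(rep(NA, length(lab)), lab)
  ), class = "ird_catalog")
}
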