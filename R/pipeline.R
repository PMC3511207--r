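#' End-to-end analysis report
#'
#' Runs the full pipeline on one input set: annotation of every precursor,
#' catalog construction, clone-library diversity statistics, and (when a
#' peak list is supplied) processed-peptide mass matching. The returned
#' object reproduces the headline tables of a clone-library induction study:
#' catalog summary, per-treatment class abundance, shared/unique expression
#' partition, domain frequency, and TI/CI bias.
#'
#' @param precursors list of [precursor()] objects, or a path to an
#'   amino-acid FASTA file.
#' @param clone_table a [clone_count_table()] over the same gene ids, or
#'   `NULL` to skip clone statistics.
#' @param peaks optional numeric vector of observed masses (Da), or a path
#'   to a peak-list file.
#' @param config an [annotation_config()].
#' @param max_flank flank residues for mass-candidate enumeration.
#' @param mass_tolerance peak-matching tolerance (Da).
#' @param seed seed recorded in the provenance block (the pipeline itself is
#'   deterministic).
#' @return object of class `ird_report`.
#' @export
ird_report <- function(precursors, clone_table = NULL, peaks = NULL,
                       config = annotation_config(), max_flank = 2L,
                       mass_tolerance = 3, seed = NA_integer_) {
  input_files <- character(0)
  if (is.character(precursors)) {
    input_files <- c(input_files, precursors)
    precursors <- read_precursor_fasta(precursors)
  }
  if (is.character(peaks)) {
    input_files <- c(input_files, peaks)
    peaks <- read_peaklist(peaks)
  }
  annotations <- annotate_set(precursors, config)
  cat_res <- build_catalog(annotations)
  summary <- catalog_summary(cat_res$ird_catalog, cat_res$compositions)

  diversity <- NULL
  if (!is.null(clone_table)) {
    induced <- setdiff(clone_table$treatments, "UL")
    diversity <- list(
      validation = validate_table(clone_table),
      class_abundance = setNames(lapply(clone_table$treatments, function(tr) {
        class_abundance(clone_table, cat_res$compositions, tr)
      }), clone_table$treatments),
      gene_frequency = gene_frequency(clone_table),
      partition = if (length(induced) >= 2L) {
        shared_unique_partition(clone_table, induced)
      },
      ird_frequency = ird_frequency(clone_table, cat_res$compositions,
                                    cat_res$ird_catalog),
      class_specificity = class_specificity_summary(
        clone_table, cat_res$compositions, cat_res$ird_catalog))
  }

  massmatch <- NULL
  if (!is.null(peaks)) {
    candidates <- do.call(rbind, lapply(annotations, enumerate_candidates,
                                        max_flank = max_flank))
    massmatch <- list(candidates = candidates,
                      assignments = match_peaks(peaks, candidates,
                                                tolerance = mass_tolerance))
  }

  structure(list(
    annotations = annotations, catalog = cat_res$ird_catalog,
    sp_catalog = cat_res$sp_catalog, compositions = cat_res$compositions,
    summary = summary, diversity = diversity, massmatch = massmatch,
    provenance = list(
      tool = "irdkit",
      version = as.character(utils::packageVersion("irdkit")),
      seed = seed,
      input_md5 = if (length(input_files)) tools::md5sum(input_files),
      sp_length = config$sp_length,
      tolerance = config$tolerance,
      max_flank = max_flank,
      mass_tolerance = mass_tolerance)
  ), class = "ird_report")
}

#' @export
print.ird_report <- function(x, ...) {
  s <- x$summary
  cat("== precursor annotation report ==\n")
  cat(sprintf("genes: %d   unique IRDs: %d   SP variants: %d\n",
              s$n_genes, s$n_unique_irds, s$n_sp_variants))
  cat("genes by IRD number: ",
      paste(sprintf("%s-IRD: %d", names(s$genes_by_n_irds),
                    s$genes_by_n_irds), collapse = "  "), "\n")
  if (!all(is.na(s$class_counts))) {
    cat(sprintf("unique IRD classes: %d TI / %d CI / %d other\n",
                s$class_counts[["TI"]], s$class_counts[["CI"]],
                s$class_counts[["UNCLASSIFIED"]]))
  }
  if (!is.null(x$diversity)) {
    cat("\nclass abundance (% of sequenced clones):\n")
    for (tr in names(x$diversity$class_abundance)) {
      ca <- x$diversity$class_abundance[[tr]]
      cat(sprintf("  %-5s %s\n", tr,
                  paste(sprintf("%d-IRD: %d%%", ca$n_irds, ca$percent),
                        collapse = "  ")))
    }
  }
  if (!is.null(x$massmatch)) {
    matched <- sum(!is.na(x$massmatch$assignments$candidate))
    cat(sprintf("\npeaks matched: %d / %d (tolerance %.1f Da)\n",
                matched, nrow(x$massmatch$assignments),
                x$provenance$mass_tolerance))
  }
  invisible(x)
}
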