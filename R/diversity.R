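# round half-up: 0.5 always rounds away from zero toward +Inf
round_half_up <- function(x) floor(x + 0.5)

#' Clone-count table
#'
#' Genes-by-treatments matrix of sequenced-clone counts, with the expected
#' sequencing depth per treatment (how many clones were sequenced from that
#' library, e.g. 60 per induced treatment and 25 for uninduced leaves).
#'
#' @param counts non-negative integer matrix, genes in rows (rownames
#'   required), treatments in columns (colnames required).
#' @param expected_totals named vector of expected clone totals per
#'   treatment, or `NULL`.
#' @return object of class `clone_count_table`.
#' @export
clone_count_table <- function(counts, expected_totals = NULL) {
  stopifnot(is.matrix(counts))
  if ((nrow(counts) && is.null(rownames(counts))) ||
      (ncol(counts) && is.null(colnames(counts)))) {
    stop("counts must carry gene rownames and treatment colnames",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("clone counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (!is.null(expected_totals)) {
    if (is.null(names(expected_totals)) ||
        !all(colnames(counts) %in% names(expected_totals))) {
      stop("expected_totals must be named for every treatment column",
           call. = FALSE)
    }
    expected_totals <- expected_totals[colnames(counts)]
  }
  structure(list(counts = counts,
                 treatments = colnames(counts) %||% character(0),
                 expected_totals = expected_totals),
            class = "clone_count_table")
}

#' @export
print.clone_count_table <- function(x, ...) {
  cat(sprintf("<clone-count table  %d gene(s) x %d treatment(s)>\n",
              nrow(x$counts), ncol(x$counts)))
  print(utils::head(x$counts, 6L))
  if (nrow(x$counts) > 6L) cat("...\n")
  invisible(x)
}

# resolve the percentage / frequency denominator for one treatment
column_denominator <- function(table, treatment,
                               denominator = c("expected", "observed")) {
  denominator <- match.arg(denominator)
  obs <- sum(table$counts[, treatment])
  if (denominator == "expected" && !is.null(table$expected_totals) &&
      !is.na(table$expected_totals[treatment])) {
    unname(table$expected_totals[treatment])
  } else {
    obs
  }
}

#' Validate column totals of a clone-count table
#'
#' Compares each treatment column sum with its expected sequencing depth.
#' A mismatch (clones lost to failed reads etc.) is flagged, never raised as
#' an error; negative or non-integer counts are rejected at construction.
#'
#' @param table a [clone_count_table()].
#' @return data.frame with `treatment`, `total`, `expected`, `matches`.
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "clone_count_table"))
  if (!ncol(table$counts)) {
    return(data.frame(treatment = character(0), total = integer(0),
                      expected = integer(0), matches = logical(0)))
  }
  totals <- colSums(table$counts)
  expected <- if (is.null(table$expected_totals)) {
    rep(NA_integer_, length(totals))
  } else as.integer(table$expected_totals)
  data.frame(treatment = table$treatments, total = as.integer(totals),
             expected = expected,
             matches = !is.na(expected) & totals == expected,
             row.names = NULL)
}

#' Clone abundance by number of repeat domains
#'
#' For one treatment, sums clone counts of all genes that carry the same
#' number of IRDs and converts them to percentages of the sequencing depth,
#' rounded half-up to integers (the convention under which 23 of 60 clones
#' prints as 38%).
#'
#' @param table a [clone_count_table()].
#' @param compositions list of `gene_composition` covering every gene in the
#'   table.
#' @param treatment treatment column name.
#' @param denominator `"expected"` (the treatment's sequencing depth, the
#'   default when depths are recorded) or `"observed"` (the column sum).
#' @return data.frame of class `class_abundance` with `n_irds`, `count`,
#'   `percent`, plus attributes `treatment` and `denominator`.
#' @export
class_abundance <- function(table, compositions, treatment,
                            denominator = c("expected", "observed")) {
  stopifnot(inherits(table, "clone_count_table"))
  treatment <- match.arg(treatment, table$treatments)
  nby <- composition_n_irds(compositions, rownames(table$counts))
  denom <- column_denominator(table, treatment, denominator)
  if (denom == 0) stop("no clones in treatment '", treatment, "'",
                       call. = FALSE)
  cls <- sort(unique(nby))
  cnt <- vapply(cls, function(k) {
    sum(table$counts[nby == k, treatment])
  }, 0L)
  out <- data.frame(n_irds = cls, count = cnt,
                    percent = round_half_up(100 * cnt / denom))
  attr(out, "treatment") <- treatment
  attr(out, "denominator") <- denom
  class(out) <- c("class_abundance", "data.frame")
  out
}

# named vector gene -> n_irds, erroring on genes without a composition
composition_n_irds <- function(compositions, genes) {
  ids <- vapply(compositions, `[[`, "", "gene_id")
  hit <- match(genes, ids)
  if (anyNA(hit)) {
    stop("no composition for gene(s): ",
         paste(genes[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  setNames(vapply(compositions[hit], `[[`, 0L, "n_irds"), genes)
}

#' Per-gene clone frequencies
#'
#' Frequency of occurrence of each gene among the clones sequenced from each
#' treatment. Genes with zero count in a treatment are absent from the
#' result for that treatment.
#'
#' @inheritParams class_abundance
#' @return data.frame with `gene`, `treatment`, `count`, `fraction`.
#' @export
gene_frequency <- function(table, denominator = c("expected", "observed")) {
  stopifnot(inherits(table, "clone_count_table"))
  out <- do.call(rbind, lapply(table$treatments, function(tr) {
    denom <- column_denominator(table, tr, denominator)
    if (denom == 0) stop("no clones in treatment '", tr, "'", call. = FALSE)
    cnt <- table$counts[, tr]
    present <- cnt > 0L
    data.frame(gene = rownames(table$counts)[present], treatment = tr,
               count = cnt[present], fraction = cnt[present] / denom,
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Shared / unique expression partition across induced treatments
#'
#' Venn-style partition of expressed genes (clone count > 0) over the
#' selected treatments: every expressed gene lands in exactly one region,
#' keyed by the set of treatments it is expressed in.
#'
#' @param table a [clone_count_table()].
#' @param treatments at least two treatment column names; defaults to the
#'   three induced treatments.
#' @return list of class `venn_partition`: `regions` (named list of gene
#'   vectors, names like `"AI"` or `"AI&W+W"`) and `treatments`.
#' @export
shared_unique_partition <- function(table,
                                    treatments = c("AI", "W+W", "W+OS")) {
  stopifnot(inherits(table, "clone_count_table"))
  treatments <- match.arg(treatments, table$treatments, several.ok = TRUE)
  if (length(treatments) < 2L) {
    stop("need at least two treatments to partition", call. = FALSE)
  }
  pres <- table$counts[, treatments, drop = FALSE] > 0L
  key <- apply(pres, 1L, function(p) paste(treatments[p], collapse = "&"))
  expressed <- key[nzchar(key)]
  # regions in subset order: singletons, pairs, ..., full intersection
  subsets <- unlist(lapply(seq_along(treatments), function(k) {
    combn(treatments, k, paste, collapse = "&", simplify = FALSE)
  }))
  regions <- setNames(lapply(subsets, function(s) {
    names(expressed)[expressed == s]
  }), subsets)
  structure(list(regions = regions, treatments = treatments),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<expression partition over", paste(x$treatments, collapse = ", "),
      ">\n")
  for (nm in names(x$regions)) {
    cat(sprintf("  %-20s %d gene(s)\n", nm, length(x$regions[[nm]])))
  }
  invisible(x)
}

#' Per-IRD occurrence counts by treatment
#'
#' Occurrence of domain label L in treatment T is the clone count of each
#' gene times the multiplicity of L in that gene's composition, summed over
#' genes (a domain occurring twice in one clone counts twice).
#'
#' @inheritParams class_abundance
#' @param catalog an `ird_catalog`; every composition label must exist in it.
#' @return integer matrix, labels x treatments.
#' @export
ird_frequency <- function(table, compositions, catalog) {
  stopifnot(inherits(table, "clone_count_table"),
            inherits(catalog, "ird_catalog"))
  ids <- vapply(compositions, `[[`, "", "gene_id")
  hit <- match(rownames(table$counts), ids)
  if (anyNA(hit)) {
    stop("no composition for gene(s): ",
         paste(rownames(table$counts)[is.na(hit)], collapse = ", "),
         call. = FALSE)
  }
  labels <- names(catalog$entries)
  used <- unique(unlist(lapply(compositions,
                               function(g) as.character(g$ird_labels))))
  missing <- setdiff(used, labels)
  if (length(missing)) {
    stop("composition references label(s) absent from catalog: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # multiplicity matrix: label x gene
  mult <- vapply(compositions[hit], function(g) {
    tabulate(match(as.character(g$ird_labels), labels),
             nbins = length(labels))
  }, integer(length(labels)))
  out <- mult %*% table$counts
  dimnames(out) <- list(labels, table$treatments)
  out
}

#' Clone-weighted TI / CI composition per treatment
#'
#' For each treatment, the fraction of domain occurrences (clone-weighted,
#' with multiplicity) whose catalog class is TI, CI, or neither.
#'
#' @inheritParams ird_frequency
#' @return data.frame with `treatment`, `ti_fraction`, `ci_fraction`,
#'   `other_fraction`; fractions are `NaN` for treatments with zero
#'   occurrences.
#' @export
class_specificity_summary <- function(table, compositions, catalog) {
  freq <- ird_frequency(table, compositions, catalog)
  cls <- catalog$class_of[rownames(freq)]
  per_class <- function(code) colSums(freq[which(cls == code), , drop = FALSE])
  total <- colSums(freq)
  data.frame(treatment = colnames(freq),
             ti_fraction = per_class("TI") / total,
             ci_fraction = per_class("CI") / total,
             other_fraction = 1 - (per_class("TI") + per_class("CI")) / total,
             row.names = NULL)
}
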