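#' The packaged CanPI clone-library table
#'
#' Loads the transcribed gene table of 47 Capsicum annuum Pin-II PI genes:
#' per-gene signal-peptide label, ordered IRD labels (a `p` marker denotes a
#' partial trailing domain, which counts toward the domain number but has no
#' label), a novelty flag, and sequenced-clone counts for uninduced leaves
#' (UL, 25 clones sequenced) and three induction treatments (AI = aphid
#' infestation, W+W = wounding plus water, W+OS = wounding plus insect oral
#' secretions; 60 clones sequenced each).
#'
#' @param path CSV file in the fixture dialect (columns `gene`, `sp`,
#'   `ird1`..`ird4`, `partial`, `novel`, `count_UL`, `count_AI`, `count_WW`,
#'   `count_WOS`); defaults to the packaged table.
#' @return list with `compositions` (list of `gene_composition`, each with an
#'   extra `novel` flag), `counts` (a [clone_count_table()]), `catalog` (a
#'   label-only `ird_catalog` over the labels used), and `novel` (named
#'   logical vector per gene).
#' @examples
#' t1 <- canpi_clone_library()
#' catalog_summary(t1$catalog, t1$compositions)$n_unique_irds  # 28
#' @export
canpi_clone_library <- function(path = system.file("extdata", "canpi_clone_library.csv",
                                            package = "irdkit")) {
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("gene", "sp", paste0("ird", 1:4), "partial", "novel",
            "count_UL", "count_AI", "count_WW", "count_WOS")
  if (!all(need %in% names(raw))) {
    stop("malformed fixture CSV: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  compositions <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    cells <- unlist(raw[i, paste0("ird", 1:4)], use.names = FALSE)
    cells <- cells[nzchar(cells)]
    labels <- suppressWarnings(as.integer(cells[cells != "p"]))
    if (anyNA(labels)) {
      stop("malformed IRD label in fixture row for ", raw$gene[i],
           call. = FALSE)
    }
    compositions[[i]] <- structure(list(
      gene_id = raw$gene[i],
      sp_label = if (nzchar(raw$sp[i])) as.integer(raw$sp[i]) else NA_integer_,
      ird_labels = labels,
      n_irds = length(cells),            # a trailing "p" marker counts
      is_partial = as.logical(raw$partial[i]),
      novel = as.logical(raw$novel[i])
    ), class = "gene_composition")
  }
  counts <- as.matrix(vapply(
    c("count_UL", "count_AI", "count_WW", "count_WOS"),
    function(cn) as.integer(raw[[cn]]), integer(nrow(raw))))
  dimnames(counts) <- list(raw$gene, c("UL", "AI", "W+W", "W+OS"))
  tab <- clone_count_table(counts,
                           expected_totals = c("UL" = 25, "AI" = 60,
                                               "W+W" = 60, "W+OS" = 60))
  labels <- unlist(lapply(compositions, `[[`, "ird_labels"))
  list(compositions = compositions, counts = tab,
       catalog = label_only_catalog(labels),
       novel = setNames(vapply(compositions, `[[`, NA, "novel"), raw$gene))
}
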