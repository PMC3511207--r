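#' Enumerate processed single-domain peptide candidates
#'
#' Endogenous proteases release single-IRD peptides by cleaving within the
#' linkers; the exact cleavage offsets vary, so each annotated domain yields
#' the bare domain plus every extension of 0..`max_flank` residues borrowed
#' from the adjacent linkers (bounded by the residues actually available).
#' Duplicate sequences are removed.
#'
#' @param annotation a `precursor_annotation`.
#' @param max_flank maximum residues borrowed on each side (default 0).
#' @param n_disulfides_rule disulfide count for the oxidized mass: all
#'   scaffold cysteines paired, `floor(n_cys / 2)`.
#' @param monoisotopic compute monoisotopic instead of average masses.
#' @return data.frame of class `peptide_candidates`: `gene_id`, `ird_index`,
#'   `flank_left`, `flank_right`, `aa_seq`, `mass_reduced`, `mass_oxidized`.
#' @export
enumerate_candidates <- function(annotation, max_flank = 0L,
                                 monoisotopic = FALSE) {
  stopifnot(inherits(annotation, "precursor_annotation"))
  max_flank <- as.integer(max_flank)
  rows <- list()
  for (j in seq_along(annotation$irds)) {
    ird <- annotation$irds[[j]]
    left_start <- annotation$linkers$start[annotation$linkers$end == ird$start]
    left_avail <- if (length(left_start)) {
      min(max_flank, ird$start - left_start[1L])
    } else 0L
    right_end <- annotation$linkers$end[annotation$linkers$start == ird$end]
    right_avail <- if (length(right_end)) {
      min(max_flank, right_end[1L] - ird$end)
    } else 0L
    for (fl in 0:left_avail) {
      for (fr in 0:right_avail) {
        seq <- substr(annotation$aa_seq, ird$start + 1L - fl, ird$end + fr)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = annotation$precursor_id, ird_index = j,
          flank_left = fl, flank_right = fr, aa_seq = seq)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(gene_id = character(0), ird_index = integer(0),
                      flank_left = integer(0), flank_right = integer(0),
                      aa_seq = character(0), mass_reduced = numeric(0),
                      mass_oxidized = numeric(0))
    class(out) <- c("peptide_candidates", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$aa_seq), , drop = FALSE]
  n_ss <- vapply(strsplit(out$aa_seq, "", fixed = TRUE),
                 function(r) sum(r == "C") %/% 2L, 0L)
  out$mass_reduced <- mapply(average_mass, out$aa_seq, 0L,
                             MoreArgs = list(monoisotopic = monoisotopic))
  out$mass_oxidized <- mapply(average_mass, out$aa_seq, n_ss,
                              MoreArgs = list(monoisotopic = monoisotopic))
  rownames(out) <- NULL
  class(out) <- c("peptide_candidates", "data.frame")
  out
}

#' Assign MALDI peaks to peptide candidates
#'
#' Each peak is assigned to the candidate with the smallest absolute mass
#' difference within the tolerance; ties go to the smaller candidate mass.
#' Peaks are treated as neutral masses by default; set
#' `proton_adjust = TRUE` to interpret them as singly protonated \[M+H\]+
#' (subtracting 1.007 Da before matching). The oxidized (all-disulfides-
#' formed) candidate mass is used unless `reduced = TRUE`.
#'
#' @param peaks numeric vector of observed masses (Da).
#' @param candidates a `peptide_candidates` data.frame from
#'   [enumerate_candidates()] (or several row-bound together).
#' @param tolerance maximum |delta| in Da (default 3).
#' @param reduced match against reduced instead of oxidized masses.
#' @param proton_adjust treat peaks as \[M+H\]+ rather than neutral.
#' @return data.frame of class `peak_assignment`: `peak`, `candidate`
#'   (row index into `candidates`, `NA` if unmatched), `gene_id`, `aa_seq`,
#'   `candidate_mass`, `delta`.
#' @export
match_peaks <- function(peaks, candidates, tolerance = 3,
                        reduced = FALSE, proton_adjust = FALSE) {
  stopifnot(is.numeric(peaks), all(peaks > 0), tolerance > 0)
  peaks <- sort(peaks)
  masses <- if (reduced) candidates$mass_reduced else candidates$mass_oxidized
  if (!length(masses)) {
    warning("empty candidate list: all peaks unmatched", call. = FALSE)
  }
  neutral <- if (proton_adjust) peaks - MASS_PROTON else peaks
  idx <- vapply(neutral, function(m) {
    if (!length(masses)) return(NA_integer_)
    delta <- abs(masses - m)
    ok <- which(delta <= tolerance)
    if (!length(ok)) return(NA_integer_)
    ok[order(delta[ok], masses[ok])][1L]   # min |delta|, tie: smaller mass
  }, NA_integer_)
  out <- data.frame(
    peak = peaks, candidate = idx,
    gene_id = ifelse(is.na(idx), NA_character_, candidates$gene_id[idx]),
    aa_seq = ifelse(is.na(idx), NA_character_, candidates$aa_seq[idx]),
    candidate_mass = ifelse(is.na(idx), NA_real_, masses[idx]))
  out$delta <- out$candidate_mass - neutral
  class(out) <- c("peak_assignment", "data.frame")
  out
}
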