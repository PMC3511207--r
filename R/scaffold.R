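#' Canonical cysteine scaffold template of a Pin-II repeat domain
#'
#' Every inhibitory repeat domain carries eight conserved cysteines; the
#' reactive-site pentapeptide C-\[P/T\]-P1-X-C spans the second and third of
#' them. The template fixes the scaffold geometry used both to grow domain
#' boundaries during annotation and to build synthetic domains: 0-based
#' cysteine offsets within a canonical 50-residue repeat, the reactive-site
#' offset, the fixed N-terminal head before the first cysteine and C-terminal
#' tail after the last one, and the spacing tolerance.
#'
#' @param cys_offsets 0-based offsets of the 8 cysteines in the canonical
#'   repeat.
#' @param tail residues after the last cysteine.
#' @param tolerance maximum allowed deviation (residues) of each inter-
#'   cysteine gap from the template before the scaffold is called deviant.
#' @return a list of class `ird_template` with elements `cys_offsets`,
#'   `gaps`, `rs_offset`, `head`, `tail`, `base_length`, `tolerance`.
#' @export
ird_template <- function(cys_offsets = c(3L, 7L, 11L, 20L, 25L, 33L, 39L, 44L),
                         tail = 5L, tolerance = 2L) {
  cys_offsets <- as.integer(cys_offsets)
  if (length(cys_offsets) != 8L || is.unsorted(cys_offsets, strictly = TRUE)) {
    stop("cys_offsets must be 8 strictly increasing offsets", call. = FALSE)
  }
  if (cys_offsets[3L] - cys_offsets[2L] != 4L) {
    stop("cysteines 2 and 3 must be 4 residues apart ",
         "(they bracket the reactive-site pentapeptide)", call. = FALSE)
  }
  structure(list(
    cys_offsets = cys_offsets,
    gaps        = diff(cys_offsets),
    rs_offset   = cys_offsets[2L],
    head        = cys_offsets[1L],
    tail        = as.integer(tail),
    base_length = cys_offsets[8L] + as.integer(tail) + 1L,
    tolerance   = as.integer(tolerance)
  ), class = "ird_template")
}

#' Cysteine profile of a repeat-domain sequence
#'
#' Counts and locates all cysteines and flags scaffold deviation: `TRUE`
#' when the count differs from 8 or when any successive inter-cysteine gap
#' deviates from the template spacing by more than the tolerance.
#'
#' @param aa_seq amino-acid string (one repeat domain).
#' @param template an [ird_template()].
#' @param tolerance spacing tolerance; defaults to the template's.
#' @return list with `cys_count`, `cys_positions` (0-based) and
#'   `scaffold_deviation`.
#' @export
cysteine_profile <- function(aa_seq, template = ird_template(),
                             tolerance = template$tolerance) {
  check_aa(aa_seq, what = "sequence")
  res <- strsplit(aa_seq, "", fixed = TRUE)[[1L]]
  pos <- which(res == "C") - 1L
  n <- length(pos)
  deviation <- n != 8L ||
    any(abs(diff(pos) - template$gaps) > tolerance)
  list(cys_count = n, cys_positions = pos, scaffold_deviation = deviation)
}
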