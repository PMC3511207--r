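#' Classify a reactive-site pentapeptide by its P1 residue
#'
#' The reactive site of a Pin-II inhibitory repeat domain is a pentapeptide
#' C-\[P/T\]-P1-X-C whose central (third) residue, P1, determines protease
#' specificity: Lys or Arg at P1 gives a trypsin-inhibitory (TI) site, Leu or
#' Pro a chymotrypsin-inhibitory (CI) site; any other residue is left
#' `UNCLASSIFIED`.
#'
#' @param pentapeptide 5-residue string whose first and fifth residues are
#'   cysteine.
#' @return an object of class `reactive_site`: a list with `pentapeptide`,
#'   `p1_residue` and `inhibitor_class` (`"TI"`, `"CI"` or `"UNCLASSIFIED"`).
#' @examples
#' classify_reactive_site("CPRNC")  # TI
#' classify_reactive_site("CTLNC")  # CI
#' @export
classify_reactive_site <- function(pentapeptide) {
  check_aa(pentapeptide, allow_x = TRUE, what = "pentapeptide")
  if (nchar(pentapeptide) != 5L) {
    stop("reactive-site motif '", pentapeptide,
         "' must be exactly 5 residues", call. = FALSE)
  }
  res <- strsplit(pentapeptide, "", fixed = TRUE)[[1L]]
  if (res[1L] != "C" || res[5L] != "C") {
    stop("reactive-site motif '", pentapeptide,
         "' must start and end with cysteine", call. = FALSE)
  }
  p1 <- res[3L]
  cls <- if (p1 %in% c("K", "R")) "TI"
         else if (p1 %in% c("L", "P")) "CI"
         else "UNCLASSIFIED"
  structure(list(pentapeptide = pentapeptide, p1_residue = p1,
                 inhibitor_class = cls),
            class = "reactive_site")
}

#' @export
print.reactive_site <- function(x, ...) {
  cat(sprintf("<reactive site %s  P1=%s  class=%s>\n",
              x$pentapeptide, x$p1_residue, x$inhibitor_class))
  invisible(x)
}

# All (possibly overlapping) occurrences of the reactive-site motif
# C-[P/T]-X-X-C. X (unknown) never matches C nor contributes a P1 class.
rs_motif_positions <- function(aa_seq) {
  m <- gregexpr("(?=C[PT]..C)", aa_seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Locate reactive-site motifs in a sequence
#'
#' Scans left to right for non-overlapping matches of the pentapeptide
#' pattern C-\[P/T\]-X-X-C and classifies each match by its P1 residue.
#'
#' @param aa_seq amino-acid string.
#' @return data.frame with 0-based `position`, `pentapeptide`, `p1_residue`
#'   and `inhibitor_class`; zero rows when no motif is present.
#' @examples
#' find_reactive_sites("AAACPRNCAAA")
#' @export
find_reactive_sites <- function(aa_seq) {
  check_aa(aa_seq, what = "sequence")
  pos <- rs_motif_positions(aa_seq)
  keep <- integer(0)
  last_end <- -1L
  for (p in pos) {                     # greedy left-to-right, no overlap
    if (p > last_end) {
      keep <- c(keep, p)
      last_end <- p + 4L
    }
  }
  if (!length(keep)) {
    return(data.frame(position = integer(0), pentapeptide = character(0),
                      p1_residue = character(0),
                      inhibitor_class = character(0)))
  }
  penta <- substring(aa_seq, keep + 1L, keep + 5L)
  sites <- lapply(penta, classify_reactive_site)
  data.frame(position = keep,
             pentapeptide = penta,
             p1_residue = vapply(sites, `[[`, "", "p1_residue"),
             inhibitor_class = vapply(sites, `[[`, "", "inhibitor_class"))
}
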