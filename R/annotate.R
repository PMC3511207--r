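#' Precursor sequence object
#'
#' A lightweight container for one Pin-II precursor amino-acid sequence.
#'
#' @param id unique text identifier.
#' @param aa_seq amino-acid string (20 standard one-letter codes plus `X`).
#' @param is_partial is the sequence an incomplete (truncated) precursor?
#' @return object of class `precursor_sequence`.
#' @export
precursor <- function(id, aa_seq, is_partial = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  check_aa(aa_seq, what = paste0("precursor '", id, "'"))
  structure(list(id = id, aa_seq = aa_seq, is_partial = isTRUE(is_partial)),
            class = "precursor_sequence")
}

#' @export
print.precursor_sequence <- function(x, ...) {
  cat(sprintf("<precursor %s  %d aa%s>\n", x$id, nchar(x$aa_seq),
              if (x$is_partial) "  (partial)" else ""))
  invisible(x)
}

#' Annotation parameters
#'
#' @param sp_length signal-peptide length in residues (the family's ER signal
#'   peptide is 25 residues).
#' @param template cysteine-scaffold template, see [ird_template()].
#' @param tolerance spacing tolerance (residues) for calling scaffold
#'   deviation; the internal scaffold walk uses `tolerance + 2` so that point
#'   substitutions near a cysteine cannot derail domain detection.
#' @return list of class `annotation_config`.
#' @export
annotation_config <- function(sp_length = 25L, template = ird_template(),
                              tolerance = template$tolerance) {
  structure(list(sp_length = as.integer(sp_length), template = template,
                 tolerance = as.integer(tolerance)),
            class = "annotation_config")
}

#' Extract the N-terminal signal peptide
#'
#' Returns the fixed-length N-terminal signal peptide and the coordinates of
#' the remaining mature region. A precursor shorter than `sp_length` is an
#' error unless flagged partial, in which case the signal peptide is reported
#' absent and the whole sequence is treated as mature region.
#'
#' @param prec a [precursor()].
#' @param sp_length signal-peptide length (default 25).
#' @return list with `signal_peptide` (string or `NA`), `sp_start`, `sp_end`,
#'   `mature_start`, `mature_end` (0-based, half-open).
#' @export
extract_signal_peptide <- function(prec, sp_length = 25L) {
  stopifnot(inherits(prec, "precursor_sequence"))
  n <- nchar(prec$aa_seq)
  sp_length <- as.integer(sp_length)
  if (n <= sp_length) {
    if (!prec$is_partial) {
      stop("precursor '", prec$id, "' (", n, " aa) is not longer than ",
           "sp_length = ", sp_length, call. = FALSE)
    }
    return(list(signal_peptide = NA_character_, sp_start = NA_integer_,
                sp_end = NA_integer_, mature_start = 0L, mature_end = n))
  }
  list(signal_peptide = substr(prec$aa_seq, 1L, sp_length),
       sp_start = 0L, sp_end = sp_length,
       mature_start = sp_length, mature_end = n)
}

# Walk the 8-cysteine scaffold right of an anchor (= cysteine 2, the first
# residue of the reactive-site pentapeptide). Returns found cysteine
# positions, or a partial walk when the template runs off the sequence end.
scaffold_walk <- function(cpos, anchor, seq_len, template, walk_tol) {
  gaps <- template$gaps
  found <- c(NA_integer_, anchor, anchor + 4L)   # c2, c3 fixed by the motif
  # cysteine 1, left of the anchor
  exp1 <- anchor - gaps[1L]
  cand <- cpos[abs(cpos - exp1) <= walk_tol & cpos < anchor]
  if (!length(cand)) return(NULL)
  found[1L] <- cand[order(abs(cand - exp1), cand)][1L]
  # cysteines 4..8, successively right of the last found
  for (k in 4:8) {
    exp_k <- found[k - 1L] + gaps[k - 1L]
    cand <- cpos[abs(cpos - exp_k) <= walk_tol & cpos > found[k - 1L]]
    if (!length(cand)) {
      if (exp_k + walk_tol > seq_len - 1L) {     # template runs off the end
        return(list(cys = found[1:(k - 1L)], partial = TRUE))
      }
      return(NULL)
    }
    found[k] <- cand[order(abs(cand - exp_k), cand)][1L]
  }
  list(cys = found, partial = FALSE)
}

#' Annotate a precursor into signal peptide, repeat domains and linkers
#'
#' Segments a Pin-II precursor: the signal peptide is the fixed 25-residue
#' N-terminal prefix; every reactive-site motif in the mature region seeds a
#' candidate domain that is grown over the 8-cysteine scaffold template;
#' candidates failing to complete the scaffold are discarded, overlaps are
#' resolved greedily left to right, and a terminal repeat running off the
#' sequence end is kept and flagged partial. Domain boundaries are template
#' constants around the scaffold (`head` residues before the first cysteine,
#' `tail` after the last); all remaining residues become linkers, so the
#' segments concatenate back to the input exactly.
#'
#' @param prec a [precursor()].
#' @param config an [annotation_config()].
#' @return object of class `precursor_annotation`: list with `precursor_id`,
#'   `aa_seq`, `signal_peptide` (list `aa_seq`,`start`,`end`, or `NULL` for a
#'   partial precursor shorter than the signal peptide), `irds` (list of
#'   `ird_record`), `linkers` (data.frame `start`,`end`,`aa_seq`), `n_irds`,
#'   and `warnings`.
#' @examples
#' cfg <- synth_config(seed = 1, n_genes = 1)
#' sim <- generate_precursors(generate_ird_pool(cfg), cfg)
#' annotate_precursor(sim$precursors[[1]])
#' @export
annotate_precursor <- function(prec, config = annotation_config()) {
  stopifnot(inherits(prec, "precursor_sequence"))
  tpl <- config$template
  walk_tol <- config$tolerance + 2L
  sp <- extract_signal_peptide(prec, config$sp_length)
  seq_len <- nchar(prec$aa_seq)
  res <- strsplit(prec$aa_seq, "", fixed = TRUE)[[1L]]
  cpos <- which(res == "C") - 1L
  warnings <- character(0)

  anchors <- rs_motif_positions(prec$aa_seq)
  anchors <- anchors[anchors >= sp$mature_start]
  irds <- list()
  claim_end <- sp$mature_start
  for (a in anchors) {
    if (a - tpl$gaps[1L] - tpl$head < claim_end) next  # inside claimed span
    walk <- scaffold_walk(cpos, a, seq_len, tpl, walk_tol)
    if (is.null(walk)) next
    start <- walk$cys[1L] - tpl$head
    if (start < claim_end) next
    if (walk$partial) {
      end <- seq_len
      partial <- TRUE
    } else {
      end <- walk$cys[8L] + tpl$tail + 1L
      partial <- end > seq_len
      if (partial) end <- seq_len
    }
    seg <- substr(prec$aa_seq, start + 1L, end)
    prof <- cysteine_profile(seg, tpl, config$tolerance)
    irds[[length(irds) + 1L]] <- structure(list(
      start = start, end = end, aa_seq = seg,
      cys_positions = prof$cys_positions, cys_count = prof$cys_count,
      reactive_site = classify_reactive_site(
        substr(prec$aa_seq, a + 1L, a + 5L)),
      scaffold_deviation = prof$scaffold_deviation,
      is_partial = partial
    ), class = "ird_record")
    claim_end <- end
  }

  if (!length(irds)) {
    warnings <- c(warnings, paste0(
      "no repeat domain detected in precursor '", prec$id, "'"))
  }

  # everything not in the signal peptide or a domain becomes a linker
  starts <- vapply(irds, `[[`, 0L, "start")
  ends <- vapply(irds, `[[`, 0L, "end")
  gap_from <- c(if (!is.na(sp$sp_end)) sp$sp_end else 0L, ends)
  gap_to <- c(starts, seq_len)
  keep <- gap_to > gap_from
  linkers <- data.frame(start = gap_from[keep], end = gap_to[keep],
                        aa_seq = substring(prec$aa_seq, gap_from[keep] + 1L,
                                           gap_to[keep]))

  structure(list(
    precursor_id = prec$id, aa_seq = prec$aa_seq,
    is_partial = prec$is_partial,
    signal_peptide = if (is.na(sp$sp_end)) NULL else
      list(aa_seq = sp$signal_peptide, start = sp$sp_start, end = sp$sp_end),
    irds = irds, linkers = linkers, n_irds = length(irds),
    warnings = warnings
  ), class = "precursor_annotation")
}

#' Annotate a set of precursors
#'
#' @param precursors list of [precursor()] objects (or an `AAStringSet` as
#'   returned by [read_precursor_fasta()] after conversion).
#' @param config an [annotation_config()].
#' @return named list of `precursor_annotation` objects.
#' @export
annotate_set <- function(precursors, config = annotation_config()) {
  ids <- vapply(precursors, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate precursor ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  setNames(lapply(precursors, annotate_precursor, config = config), ids)
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cls <- vapply(x$irds, function(i) i$reactive_site$inhibitor_class, "")
  cat(sprintf("<annotation %s  %d aa  SP=%s  %d IRD(s)%s>\n",
              x$precursor_id, nchar(x$aa_seq),
              if (is.null(x$signal_peptide)) "absent" else "25aa",
              x$n_irds,
              if (x$n_irds) paste0(" [", paste(cls, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Segment table of one or many annotations
#'
#' @param x a `precursor_annotation` or list of them.
#' @param ... unused.
#' @return data.frame with columns `precursor_id`, `segment_type`, `start`,
#'   `end`, `class`, `cys_count`, `scaffold_deviation`, `is_partial`
#'   (0-based, half-open coordinates).
#' @export
as.data.frame.precursor_annotation <- function(x, ...) {
  rows <- list()
  add <- function(type, start, end, class = NA, cys = NA, dev = NA,
                  partial = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      precursor_id = x$precursor_id, segment_type = type,
      start = start, end = end, class = class, cys_count = cys,
      scaffold_deviation = dev, is_partial = partial)
  }
  if (!is.null(x$signal_peptide)) {
    add("signal_peptide", x$signal_peptide$start, x$signal_peptide$end)
  }
  for (i in x$irds) {
    add("ird", i$start, i$end, i$reactive_site$inhibitor_class,
        i$cys_count, i$scaffold_deviation, i$is_partial)
  }
  if (nrow(x$linkers)) {
    for (k in seq_len(nrow(x$linkers))) {
      add("linker", x$linkers$start[k], x$linkers$end[k])
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' @rdname as.data.frame.precursor_annotation
#' @param annotations list of `precursor_annotation` objects.
#' @export
annotation_table <- function(annotations) {
  if (inherits(annotations, "precursor_annotation")) {
    annotations <- list(annotations)
  }
  out <- do.call(rbind, lapply(annotations, as.data.frame))
  rownames(out) <- NULL
  out
}
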