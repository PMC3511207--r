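# 19-letter background alphabet: scaffold cysteines are placed explicitly,
# so random positions never introduce extra cysteines.
AA_BG <- setdiff(AA20, "C")

TI_MOTIFS <- c("CPRNC", "CPKNC", "CPRYC", "CPRDC")
CI_MOTIFS <- c("CTLNC", "CTPNC")

# run `expr` under a deterministic seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Configuration of the synthetic precursor generator
#'
#' The defaults mirror the study conditions of the clone-library analysis:
#' a pool of 28 unique ~50-residue repeat domains, 21 of them trypsin-
#' inhibitory (`ti_fraction = 21/28`); 47 genes with 1-4 domains in the
#' observed 3/15/20/9 architecture ratio; ten 25-residue signal-peptide
#' variants; 25 sequenced clones for uninduced leaves and 60 per induced
#' treatment.
#'
#' @param seed integer; the single seed governing all stochastic draws
#'   (each generator stage derives its own stream from it).
#' @param n_unique_irds size of the unique-domain pool.
#' @param ti_fraction fraction of pool domains with TI reactive sites.
#' @param ird_length canonical domain length (residues).
#' @param length_jitter total length jitter (residues); split over the two
#'   long inter-cysteine loops, at most `tolerance` per loop.
#' @param cys_template scaffold geometry, see [ird_template()].
#' @param n_genes number of genes to simulate.
#' @param architecture named probabilities of 1-4 domains per gene.
#' @param sp_pool_size number of distinct signal peptides.
#' @param sp_length signal-peptide length.
#' @param linker_length integer range (min, max) of linker lengths.
#' @param mutation_rate per-residue substitution probability applied to each
#'   domain instance outside the cysteine scaffold and reactive site; 0
#'   keeps every gene an exact mosaic of pool domains.
#' @param treatments named vector of clone totals per treatment.
#' @param gene_proportions optional genes-by-treatments matrix of true clone
#'   proportions (columns sum to 1); drawn from a Dirichlet-type skewed
#'   distribution when `NULL`.
#' @param peak_sigma Gaussian mass noise (Da) on synthetic peaks.
#' @param n_peaks number of peaks per synthetic peak list.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_unique_irds = 28L,
                         ti_fraction = 21 / 28,
                         ird_length = 50L,
                         length_jitter = 4L,
                         cys_template = ird_template(),
                         n_genes = 47L,
                         architecture = c(`1` = 3, `2` = 15, `3` = 20,
                                          `4` = 9) / 47,
                         sp_pool_size = 10L,
                         sp_length = 25L,
                         linker_length = c(5L, 8L),
                         mutation_rate = 0,
                         treatments = c("UL" = 25L, "AI" = 60L,
                                        "W+W" = 60L, "W+OS" = 60L),
                         gene_proportions = NULL,
                         peak_sigma = 1,
                         n_peaks = 8L) {
  stopifnot(ti_fraction >= 0, ti_fraction <= 1,
            abs(sum(architecture) - 1) < 1e-8,
            all(treatments > 0), mutation_rate >= 0, mutation_rate <= 1)
  if (ird_length != cys_template$base_length) {
    stop("ird_length ", ird_length, " incompatible with the cysteine ",
         "template (base length ", cys_template$base_length, ")",
         call. = FALSE)
  }
  if (!is.null(gene_proportions)) {
    stopifnot(is.matrix(gene_proportions),
              ncol(gene_proportions) == length(treatments),
              all(gene_proportions >= 0),
              all(abs(colSums(gene_proportions) - 1) < 1e-8))
  }
  structure(as.list(environment()), class = "synth_config")
}

# one random domain: scaffold cysteines per template (with loop jitter),
# reactive-site motif across cysteines 2-3, background elsewhere
random_ird <- function(motif, template, jitter, tolerance) {
  per_loop <- min(tolerance, jitter %/% 2L)
  jit <- seq.int(-per_loop, per_loop)
  d1 <- jit[sample.int(length(jit), 1L)]
  d2 <- jit[sample.int(length(jit), 1L)]
  offs <- template$cys_offsets
  offs[4:8] <- offs[4:8] + d1          # stretch loop between cys 3 and 4
  offs[6:8] <- offs[6:8] + d2          # and between cys 5 and 6
  len <- offs[8L] + template$tail + 1L
  res <- sample(AA_BG, len, replace = TRUE)
  res[offs + 1L] <- "C"
  res[(offs[2L] + 1L):(offs[2L] + 5L)] <- strsplit(motif, "")[[1L]]
  # cysteines 1 and 2 are also 4 apart: keep P/T out of the position after
  # cysteine 1 so the reactive-site motif is unique within the domain
  if (res[offs[1L] + 2L] %in% c("P", "T")) {
    res[offs[1L] + 2L] <- sample(setdiff(AA_BG, c("P", "T")), 1L)
  }
  paste(res, collapse = "")
}

#' Generate the labeled pool of unique repeat domains
#'
#' Reactive-site motifs are drawn from the family's observed sets
#' (TI: CPRNC, CPKNC, CPRYC, CPRDC; CI: CTLNC, CTPNC) respecting
#' `ti_fraction`; the first `round(ti_fraction * n)` labels are TI.
#'
#' @param config a [synth_config()].
#' @return list with `sequences` (named by integer label), `classes`,
#'   `motifs`.
#' @export
generate_ird_pool <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- config$n_unique_irds
    n_ti <- round(config$ti_fraction * n)
    classes <- c(rep("TI", n_ti), rep("CI", n - n_ti))
    motifs <- character(n)
    motifs[classes == "TI"] <- sample(TI_MOTIFS, n_ti, replace = TRUE)
    motifs[classes == "CI"] <- sample(CI_MOTIFS, n - n_ti, replace = TRUE)
    seqs <- vapply(motifs, random_ird, "", template = config$cys_template,
                   jitter = config$length_jitter,
                   tolerance = config$cys_template$tolerance)
    labels <- as.character(seq_len(n))
    list(sequences = setNames(unname(seqs), labels),
         classes = setNames(classes, labels),
         motifs = setNames(unname(motifs), labels))
  })
}

# position-weighted substitution outside the cysteine scaffold and reactive
# site: variation concentrates near the reactive-site loop and the
# C-terminal end
mutate_ird <- function(aa_seq, rate, template) {
  if (rate <= 0) return(aa_seq)
  res <- strsplit(aa_seq, "", fixed = TRUE)[[1L]]
  n <- length(res)
  protected <- res == "C"
  rs <- seq.int(template$rs_offset + 1L, template$rs_offset + 5L)
  protected[rs[rs <= n]] <- TRUE
  w <- rep(1, n)
  loop <- seq.int(max(1L, template$rs_offset - 2L),
                  min(n, template$rs_offset + 8L))
  w[loop] <- 2
  w[seq.int(max(1L, n - 9L), n)] <- 2
  p <- pmin(1, rate * w / mean(w))
  hit <- which(runif(n) < p & !protected)
  if (length(hit)) {
    res[hit] <- vapply(res[hit], function(r) sample(setdiff(AA_BG, r), 1L),
                       "")
  }
  paste(res, collapse = "")
}

#' Generate synthetic precursors with ground truth
#'
#' Each gene is `SP(25) + [linker + IRD] x k + terminal linker`, with `k`
#' drawn from the architecture distribution, domains drawn uniformly from
#' the pool, and linkers of random length from the configured range (no
#' cysteines, so the domain scaffolds stay unambiguous).
#'
#' @param pool result of [generate_ird_pool()].
#' @param config a [synth_config()].
#' @return list with `precursors` (list of [precursor()]), `sp_pool`
#'   (named vector of signal peptides), and `ground_truth`: per gene a list
#'   with `gene_id`, `sp_label`, `ird_labels`, `classes`, `k`, and a
#'   `segments` data.frame (`type`, `start`, `end`, `label`; 0-based
#'   half-open).
#' @export
generate_precursors <- function(pool, config) {
  stopifnot(inherits(config, "synth_config"), length(pool$sequences) > 0)
  with_seed(config$seed + 1L, {
    sp_pool <- setNames(vapply(seq_len(config$sp_pool_size), function(i) {
      paste(c("M", sample(AA_BG, config$sp_length - 1L, replace = TRUE)),
            collapse = "")
    }, ""), as.character(seq_len(config$sp_pool_size)))
    arch_k <- as.integer(names(config$architecture))
    ks <- arch_k[sample.int(length(arch_k), config$n_genes, replace = TRUE,
                            prob = config$architecture)]
    ll_range <- seq.int(config$linker_length[1L], config$linker_length[2L])
    draw_linker <- function() {
      ll <- ll_range[sample.int(length(ll_range), 1L)]
      paste(sample(AA_BG, ll, replace = TRUE), collapse = "")
    }
    precursors <- vector("list", config$n_genes)
    truth <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      id <- sprintf("SYN-%d", g)
      k <- ks[g]
      sp_label <- sample(names(sp_pool), 1L)
      ird_labels <- sample(names(pool$sequences), k, replace = TRUE)
      segs <- data.frame(type = "signal_peptide", start = 0L,
                         end = nchar(sp_pool[[sp_label]]),
                         label = sp_label)
      parts <- sp_pool[[sp_label]]
      pos <- nchar(parts)
      for (j in seq_len(k)) {
        linker <- draw_linker()
        segs <- rbind(segs, data.frame(type = "linker", start = pos,
                                       end = pos + nchar(linker),
                                       label = NA))
        pos <- pos + nchar(linker)
        ird <- mutate_ird(pool$sequences[[ird_labels[j]]],
                          config$mutation_rate, config$cys_template)
        segs <- rbind(segs, data.frame(type = "ird", start = pos,
                                       end = pos + nchar(ird),
                                       label = ird_labels[j]))
        pos <- pos + nchar(ird)
        parts <- c(parts, linker, ird)
      }
      linker <- draw_linker()
      segs <- rbind(segs, data.frame(type = "linker", start = pos,
                                     end = pos + nchar(linker), label = NA))
      parts <- c(parts, linker)
      precursors[[g]] <- precursor(id, paste(parts, collapse = ""))
      truth[[g]] <- list(gene_id = id, sp_label = sp_label,
                         ird_labels = ird_labels,
                         classes = unname(pool$classes[ird_labels]),
                         k = k, segments = segs)
    }
    list(precursors = setNames(precursors, vapply(truth, `[[`, "", "gene_id")),
         sp_pool = sp_pool,
         ground_truth = setNames(truth, vapply(truth, `[[`, "", "gene_id")))
  })
}

#' Generate a multinomial clone-count table with ground-truth proportions
#'
#' Clone counts per treatment column are drawn multinomially with the
#' configured totals from per-treatment gene-proportion vectors.
#'
#' @param config a [synth_config()].
#' @return list with `table` (a [clone_count_table()]) and `proportions`
#'   (genes-by-treatments matrix of true proportions).
#' @export
generate_clone_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed + 2L, {
    genes <- sprintf("SYN-%d", seq_len(config$n_genes))
    props <- config$gene_proportions
    if (is.null(props)) {
      props <- vapply(config$treatments, function(total) {
        x <- rgamma(config$n_genes, shape = 0.8)   # skewed clone libraries
        x / sum(x)
      }, numeric(config$n_genes))
    }
    dimnames(props) <- list(genes, names(config$treatments))
    counts <- vapply(names(config$treatments), function(tr) {
      as.integer(rmultinom(1L, config$treatments[[tr]], props[, tr]))
    }, integer(config$n_genes))
    dimnames(counts) <- dimnames(props)
    list(table = clone_count_table(counts,
                                   expected_totals = config$treatments),
         proportions = props)
  })
}

#' Generate a synthetic MALDI peak list with ground truth
#'
#' Samples processed single-domain peptides (the true domain instances of
#' the simulated genes, no flank extension), computes their oxidized average
#' masses, and adds Gaussian noise.
#'
#' @param sim result of [generate_precursors()].
#' @param config a [synth_config()].
#' @return list with `peaks` (sorted numeric vector), and `ground_truth`
#'   data.frame (`peak`, `gene_id`, `label`, `aa_seq`, `true_mass`).
#' @export
generate_peaklist <- function(sim, config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed + 3L, {
    cand <- do.call(rbind, lapply(sim$ground_truth, function(gt) {
      irds <- gt$segments[gt$segments$type == "ird", , drop = FALSE]
      seqs <- substring(sim$precursors[[gt$gene_id]]$aa_seq,
                        irds$start + 1L, irds$end)
      data.frame(gene_id = gt$gene_id, label = irds$label, aa_seq = seqs)
    }))
    cand <- cand[!duplicated(cand$aa_seq), , drop = FALSE]
    pick <- cand[sample(nrow(cand), min(config$n_peaks, nrow(cand))), ,
                 drop = FALSE]
    pick$true_mass <- vapply(pick$aa_seq, function(s) {
      n_ss <- sum(strsplit(s, "")[[1L]] == "C") %/% 2L
      average_mass(s, n_ss)
    }, 0)
    pick$peak <- pick$true_mass + rnorm(nrow(pick), 0, config$peak_sigma)
    ord <- order(pick$peak)
    pick <- pick[ord, c("peak", "gene_id", "label", "aa_seq", "true_mass")]
    rownames(pick) <- NULL
    list(peaks = pick$peak, ground_truth = pick)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_ird_pool()],
#' [generate_precursors()], [generate_clone_table()] and
#' [generate_peaklist()] under one configuration.
#'
#' @param config a [synth_config()].
#' @return list with `pool`, `sim` (precursors + ground truth), `clones`,
#'   `peaklist`, `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  pool <- generate_ird_pool(config)
  sim <- generate_precursors(pool, config)
  clones <- generate_clone_table(config)
  peaklist <- generate_peaklist(sim, config)
  list(pool = pool, sim = sim, clones = clones, peaklist = peaklist,
       config = config)
}

#' Export a synthetic dataset's ground truth as JSON
#'
#' @param dataset result of [generate_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(dataset, path) {
  jsonlite::write_json(list(
    seed = dataset$config$seed,
    pool = list(sequences = as.list(dataset$pool$sequences),
                classes = as.list(dataset$pool$classes)),
    genes = lapply(dataset$sim$ground_truth, function(gt) {
      gt$segments$label <- as.character(gt$segments$label)
      gt
    }),
    proportions = as.data.frame(dataset$clones$proportions),
    peaks = dataset$peaklist$ground_truth
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
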