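# Independent oracles used across the suite. Each recomputes a quantity by a
# different route than the package implementation.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(len, alphabet = AA_LETTERS) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- mass oracle: residue elemental compositions x IUPAC atomic weights ----
# counts of C, H, N, O, S per residue (amino acid minus water)
RESIDUE_FORMULA <- rbind(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
ATOMIC_WEIGHT <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

oracle_average_mass <- function(aa_seq, n_disulfides = 0) {
  res <- strsplit(aa_seq, "", fixed = TRUE)[[1L]]
  atoms <- colSums(RESIDUE_FORMULA[res, , drop = FALSE])
  atoms <- atoms + c(0, 2, 0, 1, 0)            # one water for the termini
  atoms[2] <- atoms[2] - 2 * n_disulfides      # each S-S bond loses 2 H
  sum(atoms * ATOMIC_WEIGHT)
}

# --- alignment oracle: exhaustive enumeration over all global alignments ---
# Returns min edit cost, and among min-cost alignments the min length.
# Feasible for strings up to ~6 residues.
oracle_align <- function(a, b) {
  ra <- strsplit(a, "")[[1L]]; rb <- strsplit(b, "")[[1L]]
  best <- c(Inf, Inf)
  recurse <- function(i, j, cost, len) {
    if (i > length(ra) && j > length(rb)) {
      if (cost < best[1L] || (cost == best[1L] && len < best[2L])) {
        best <<- c(cost, len)
      }
      return(invisible())
    }
    if (i <= length(ra) && j <= length(rb)) {
      recurse(i + 1L, j + 1L, cost + (ra[i] != rb[j]), len + 1L)
    }
    if (i <= length(ra)) recurse(i + 1L, j, cost + 1L, len + 1L)
    if (j <= length(rb)) recurse(i, j + 1L, cost + 1L, len + 1L)
  }
  recurse(1L, 1L, 0L, 0L)
  best
}

oracle_p_distance <- function(a, b) {
  st <- oracle_align(a, b)
  st[1L] / st[2L]
}

# --- UPGMA oracle: naive agglomeration recomputing every cluster distance --
# from scratch as the mean over all cross leaf pairs of the input matrix.
# Returns the cophenetic distance matrix (leaves join at their merge
# distance). Same tie rule as specified: lexicographically smallest sorted
# pair of cluster representative (minimum) labels.
oracle_upgma_cophenetic <- function(m) {
  labels <- rownames(m)
  clusters <- as.list(labels)
  coph <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1L):length(clusters)) {
        d <- mean(m[clusters[[i]], clusters[[j]]])
        pr <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        better <- is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           (pr[1L] < best$pr[1L] ||
            (pr[1L] == best$pr[1L] && pr[2L] < best$pr[2L])))
        if (better) best <- list(i = i, j = j, d = d, pr = pr)
      }
    }
    for (x in clusters[[best$i]]) {
      for (y in clusters[[best$j]]) {
        coph[x, y] <- coph[y, x] <- best$d
      }
    }
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}

random_distance_matrix <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- round(runif(n * (n - 1) / 2, 0.01, 1), 3)
  m <- m + t(m)
  dimnames(m) <- list(LETTERS[1:n], LETTERS[1:n])
  m
}

# cophenetic matrix of an irdkit upgma tree, rows/cols ordered by label
tree_cophenetic <- function(tree) {
  co <- ape::cophenetic.phylo(tree$phylo)
  co[order(rownames(co)), order(colnames(co))]
}
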