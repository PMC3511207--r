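#' p-distance between two amino-acid sequences
#'
#' Globally aligns the sequences under edit-distance costs (match 0,
#' mismatch 1, gap 1) and returns the fraction of differing alignment
#' columns. Among co-optimal alignments the shortest one is used
#' (substitutions preferred over indel pairs), so the statistic is
#' deterministic.
#'
#' @param a,b non-empty amino-acid strings.
#' @return distance in `[0, 1]`.
#' @examples
#' p_distance("AAAA", "AAAT")  # 0.25
#' p_distance("AAAA", "AAA")   # 0.25: one gap column over length 4
#' @export
p_distance <- function(a, b) {
  check_aa(a, what = "sequence a")
  check_aa(b, what = "sequence b")
  st <- .align_stats(a, b)
  st[1L] / st[2L]
}

#' Pairwise p-distance matrix
#'
#' @param seqs named character vector (or named list) of at least two
#'   sequences; names must be unique.
#' @return object of class `distance_matrix`: `labels`, symmetric `values`
#'   with zero diagonal, and `mean_distance`, the mean off-diagonal distance
#'   (the set's "average variance" when expressed as a percentage).
#' @export
pairwise_matrix <- function(seqs) {
  seqs <- unlist(seqs)
  if (length(seqs) < 2L) stop("need at least two sequences", call. = FALSE)
  labels <- names(seqs)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    stop("sequences must carry unique non-empty names", call. = FALSE)
  }
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- p_distance(seqs[[i]], seqs[[j]])
    }
  }
  structure(list(labels = labels, values = m,
                 mean_distance = mean(m[upper.tri(m)])),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance matrix  %d sequence(s)  mean off-diagonal %.4f>\n",
              length(x$labels), x$mean_distance))
  invisible(x)
}

#' UPGMA dendrogram from a distance matrix
#'
#' Standard unweighted pair-group agglomeration with arithmetic-mean
#' (Lance-Williams) updates. When several pairs are tied at the minimum
#' distance, the pair whose sorted leaf-representative labels are
#' lexicographically smallest is merged, so the result is independent of
#' input order. Node heights are half the merge distance (ultrametric).
#'
#' @param dm a `distance_matrix` from [pairwise_matrix()], or a plain
#'   symmetric numeric matrix with dimnames.
#' @return object of class `upgma_tree`: `phylo` (an ape tree with branch
#'   lengths), `newick` (serialization), `heights` (merge heights, leaves to
#'   root), `labels`.
#' @export
upgma <- function(dm) {
  if (inherits(dm, "distance_matrix")) {
    m <- dm$values
  } else if (is.matrix(dm)) {
    m <- dm
  } else stop("dm must be a distance_matrix or matrix", call. = FALSE)
  n <- nrow(m)
  if (n < 2L) stop("need at least two leaves", call. = FALSE)
  if (is.null(rownames(m))) {
    dimnames(m) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  }
  if (!isTRUE(all.equal(m, t(m))) || any(diag(m) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  labels <- rownames(m)
  rep_ <- labels                      # smallest leaf label per cluster
  size <- rep(1L, n)
  height <- rep(0, n)
  frag <- labels                      # newick fragment per cluster
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        i <- active[ii]; j <- active[jj]
        d <- m[i, j]
        pr <- sort(c(rep_[i], rep_[j]))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (pr[1L] < best$pr[1L] ||
              (pr[1L] == best$pr[1L] && pr[2L] < best$pr[2L])))) {
          best <- list(i = i, j = j, d = d, pr = pr)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    heights <- c(heights, h)
    kids <- order(c(rep_[i], rep_[j]))
    ch_frag <- c(frag[i], frag[j])[kids]
    ch_h <- c(height[i], height[j])[kids]
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)",
                        ch_frag[1L], h - ch_h[1L],
                        ch_frag[2L], h - ch_h[2L])
    # arithmetic-mean update of distances to the merged cluster
    for (k in setdiff(active, c(i, j))) {
      m[i, k] <- m[k, i] <-
        (size[i] * m[i, k] + size[j] * m[j, k]) / (size[i] + size[j])
    }
    frag[i] <- new_frag
    height[i] <- h
    rep_[i] <- min(rep_[i], rep_[j])
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  newick <- paste0(frag[active], ";")
  structure(list(phylo = ape::read.tree(text = newick),
                 newick = newick, heights = heights, labels = labels),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<UPGMA tree  %d leaves  root height %.4f>\n",
              length(x$labels), max(x$heights)))
  invisible(x)
}

#' @export
plot.upgma_tree <- function(x, ...) {
  plot(x$phylo, ...)
  invisible(x)
}

#' Write a tree in Newick format
#'
#' @param tree an `upgma_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "upgma_tree"))
  writeLines(tree$newick, path)
  invisible(path)
}
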