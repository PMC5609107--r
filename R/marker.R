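#' Kimura 2-parameter distance between two aligned sequences
#'
#' Columns where either sequence carries a gap (`-`) or `N` are excluded,
#' then `P` = transition proportion (A<->G, C<->T), `Q` = transversion
#' proportion, and `d = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]`. The distance
#' is undefined (saturated marker) when `1 - 2P - Q <= 0` or `1 - 2Q <= 0`.
#' For set-wide complete deletion (every column with a gap/N anywhere removed
#' before any pair is measured, as in published marker trees) use
#' [k2p_matrix()].
#'
#' @param a,b aligned sequences of equal length over `A,C,G,T,-,N`.
#' @return list with `P`, `Q`, `d`, `sites_used`.
#' @export
k2p_pair <- function(a, b) {
  gs_assert(nchar(a) == nchar(b), "aligned sequences must have equal length")
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  gs_assert(sum(ok) > 0, "no usable sites after gap/N exclusion")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  diff <- x != y
  purine <- c("A", "G")
  transitions <- diff & ((x %in% purine) == (y %in% purine))
  P <- sum(transitions) / n
  Q <- sum(diff & !transitions) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop(sprintf("saturated marker pair: 1-2P-Q = %.4g, 1-2Q = %.4g", w1, w2),
         call. = FALSE)
  }
  list(P = P, Q = Q, d = -0.5 * log(w1 * sqrt(w2)), sites_used = n)
}

#' K2P distance matrix with set-wide complete deletion
#'
#' Complete deletion is applied once across the whole alignment: any column
#' containing a gap or `N` in any sequence is removed for every pair
#' (matching the convention of published marker-gene trees), then pairwise
#' K2P distances are computed on the retained columns.
#'
#' @param seqs named character vector of aligned sequences (equal lengths).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
k2p_matrix <- function(seqs) {
  gs_assert(length(seqs) >= 2, "need >= 2 sequences")
  gs_assert(!is.null(names(seqs)), "sequences must be named")
  lens <- nchar(seqs)
  gs_assert(length(unique(lens)) == 1, "aligned sequences must share one length")
  rows <- lapply(seqs, function(s) strsplit(toupper(s), "")[[1]])
  m <- do.call(rbind, rows)
  good_col <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  gs_assert(any(good_col), "complete deletion removed every column")
  m <- m[, good_col, drop = FALSE]
  clean <- apply(m, 1, paste, collapse = "")
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- k2p_pair(clean[i], clean[j])$d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]; negative branch lengths
#' (a known NJ artifact on non-additive input) are clamped to zero with a
#' warning. The distance-based stand-in for likelihood marker trees.
#'
#' @param dist_matrix square symmetric matrix, zero diagonal, n >= 3.
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(dist_matrix) {
  gs_assert(is.matrix(dist_matrix) && nrow(dist_matrix) == ncol(dist_matrix),
            "distance matrix must be square")
  gs_assert(nrow(dist_matrix) >= 3, "neighbor joining needs >= 3 taxa")
  gs_assert(max(abs(dist_matrix - t(dist_matrix))) <= 1e-9,
            "distance matrix must be symmetric")
  gs_assert(all(diag(dist_matrix) == 0), "diagonal must be zero")
  ord <- order(rownames(dist_matrix))
  tree <- ape::nj(as.dist(dist_matrix[ord, ord]))
  if (any(tree$edge.length < 0)) {
    warning(sprintf("clamped %d negative NJ branch length(s) to 0",
                    sum(tree$edge.length < 0)))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}
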