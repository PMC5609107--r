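#' ANI configuration
#'
#' Fragment-based average nucleotide identity in the Goris style: the query
#' genome is cut into consecutive non-overlapping `frag_len` pieces (default
#' 1,020 bp); a piece contributes iff its best alignment against the subject
#' reaches `min_identity` percent identity and covers at least `min_frag_cov`
#' percent of the piece. ANI of the pair is the mean over both directions.
#' The clustering cutoff defaults to 94 percent, the threshold used to call
#' genospecies clusters in the source study.
#'
#' @param frag_len fragment length (bp).
#' @param min_identity retention threshold on percent identity.
#' @param min_frag_cov retention threshold on fragment coverage (percent).
#' @param cutoff clustering cutoff (percent), in `(0, 100]`.
#' @return an `ani_config` list.
#' @export
ani_config <- function(frag_len = 1020L, min_identity = 70, min_frag_cov = 70,
                       cutoff = 94) {
  gs_assert(cutoff > 0 && cutoff <= 100, "cutoff must be in (0, 100]")
  gs_assert(frag_len >= 100, "frag_len unreasonably small")
  structure(list(frag_len = as.integer(frag_len), min_identity = min_identity,
                 min_frag_cov = min_frag_cov, cutoff = cutoff),
            class = "ani_config")
}

#' @noRd
ani_fragments <- function(genome, frag_len) {
  unlist(lapply(genome$contigs, function(ctg) {
    L <- nchar(ctg)
    if (L < frag_len) return(character(0))
    starts <- seq(1L, L - frag_len + 1L, by = frag_len)
    substring(ctg, starts, starts + frag_len - 1L)
  }), use.names = FALSE)
}

#' One-directional ANI (mean identity of retained fragments)
#' @noRd
ani_one_direction <- function(A, B, config, params) {
  frags <- ani_fragments(A, config$frag_len)
  gs_assert(length(frags) > 0, "genome %s shorter than frag_len=%d",
            A$strain_id, config$frag_len)
  hits <- query_vs_set(frags, B$contigs, params, type = "dna")
  keep <- !is.na(hits$subject) &
    hits$identity >= config$min_identity &
    hits$q_cov >= config$min_frag_cov
  if (!any(keep)) return(NA_real_)
  mean(hits$identity[keep])
}

#' Pairwise average nucleotide identity
#'
#' `(ANI(A->B) + ANI(B->A)) / 2`; identical genomes give 100. When no
#' fragment passes the identity/coverage retention filters in either
#' direction (unrelated genomes) the value is missing (`NA`), which is
#' reported distinctly from a low ANI.
#'
#' @param A,B [genome_record()]s, both at least `frag_len` long.
#' @param config an [ani_config()].
#' @param params an [align_params()].
#' @return percent ANI, or `NA_real_` when undefined.
#' @export
ani_pair <- function(A, B, config = ani_config(), params = align_params()) {
  ab <- ani_one_direction(A, B, config, params)
  ba <- ani_one_direction(B, A, config, params)
  if (is.na(ab) && is.na(ba)) return(NA_real_)
  mean(c(ab, ba), na.rm = TRUE)
}

#' All-vs-all ANI matrix
#'
#' Symmetric by construction (both directions averaged), diagonal exactly
#' 100; undefined pairs are `NA`.
#'
#' @param cohort named list of [genome_record()]s.
#' @param config an [ani_config()].
#' @param params an [align_params()].
#' @return square numeric matrix with strain dimnames.
#' @export
ani_matrix <- function(cohort, config = ani_config(), params = align_params()) {
  ids <- vapply(cohort, `[[`, character(1), "strain_id")
  gs_assert(length(ids) >= 2, "cohort must contain >= 2 genomes")
  gs_assert(!anyDuplicated(ids), "duplicate strain ids")
  n <- length(ids)
  M <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- ani_pair(cohort[[i]], cohort[[j]], config, params)
      M[i, j] <- M[j, i] <- v
    }
  }
  M
}

#' Single-linkage genospecies clustering at an ANI cutoff
#'
#' Connected components of the graph whose edges join strains with
#' `ANI >= cutoff` (missing values never form edges). Components of size one
#' are singleton strains. Clusters are labeled `A, B, C, ...` by decreasing
#' size, ties broken by the lexicographically smallest member. The published
#' matrix is printed with small asymmetries, so near-symmetric input (within
#' `tol`) is accepted and symmetrized by the mean.
#'
#' @param m square ANI (or similarity) percent matrix with matching dimnames.
#' @param cutoff percent threshold in `(0, 100]`.
#' @param method `"single"` (connected components; default) or `"complete"`
#'   (every within-cluster pair must reach the cutoff, greedy agglomeration).
#' @param tol asymmetry tolerance (percent).
#' @return object of class `cluster_assignment`: list with `clusters` (named
#'   list of strain-id vectors, size >= 2), `singletons`, `cutoff`, `method`.
#' @export
single_linkage_clusters <- function(m, cutoff = 94, method = c("single", "complete"),
                                    tol = 0.5) {
  method <- match.arg(method)
  gs_assert(is.matrix(m) && nrow(m) == ncol(m), "matrix must be square")
  gs_assert(identical(rownames(m), colnames(m)), "row/col labels must coincide")
  gs_assert(cutoff > 0 && cutoff <= 100, "cutoff must be in (0, 100]")
  asym <- max(abs(m - t(m)), na.rm = TRUE)
  gs_assert(asym <= tol, "matrix asymmetric beyond tol=%g (max %.3g)", tol, asym)
  m <- (m + t(m)) / 2
  ids <- rownames(m)
  n <- length(ids)
  adj <- !is.na(m) & m >= cutoff
  diag(adj) <- FALSE

  if (method == "single") {
    comp <- components_of(adj)
  } else {
    # greedy complete linkage on the thresholded graph: repeatedly merge the
    # pair of groups whose worst cross-pair still meets the cutoff
    comp <- seq_len(n)
    repeat {
      merged <- FALSE
      for (a in sort(unique(comp))) {
        for (b in sort(unique(comp))) {
          if (b <= a) next
          ia <- which(comp == a); ib <- which(comp == b)
          if (all(adj[ia, ib, drop = FALSE])) {
            comp[ib] <- a; merged <- TRUE; break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }

  groups <- split(ids, comp)
  sizes <- lengths(groups)
  clusters <- groups[sizes >= 2]
  singles <- sort(unlist(groups[sizes == 1], use.names = FALSE))
  if (length(clusters)) {
    clusters <- lapply(clusters, sort)
    ord <- order(-lengths(clusters),
                 vapply(clusters, `[`, character(1), 1))
    clusters <- clusters[ord]
    names(clusters) <- LETTERS[seq_along(clusters)]
  } else {
    clusters <- setNames(list(), character(0))
  }
  structure(list(clusters = clusters, singletons = as.character(singles),
                 cutoff = cutoff, method = method),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> cutoff %.4g%%, %d cluster(s), %d singleton(s)\n",
              x$cutoff, length(x$clusters), length(x$singletons)))
  for (nm in names(x$clusters)) {
    cat(sprintf("  %s (%d): %s\n", nm, length(x$clusters[[nm]]),
                paste(x$clusters[[nm]], collapse = ", ")))
  }
  if (length(x$singletons))
    cat("  singletons:", paste(x$singletons, collapse = ", "), "\n")
  invisible(x)
}

#' Strain -> cluster label vector ("singleton" for unclustered strains)
#' @param assignment a `cluster_assignment`.
#' @return named character vector.
#' @export
cluster_labels <- function(assignment) {
  lab <- setNames(rep("singleton", length(assignment$singletons)),
                  assignment$singletons)
  for (nm in names(assignment$clusters)) {
    lab[assignment$clusters[[nm]]] <- nm
  }
  lab
}

#' Connected components of a logical adjacency matrix (union-find)
#' @noRd
components_of <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (adj[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}
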