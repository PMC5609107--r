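#' Genome fragmentation scheme
#'
#' Sliding-window fragmentation used by the phylogenomic similarity stage:
#' windows of `frag_len` bp advanced by `step` bp (defaults 200/100, the
#' published settings). A trailing window shorter than `min_tail` is dropped.
#' Fragments never span contig boundaries.
#'
#' @param frag_len window length (bp).
#' @param step step size (bp), `0 < step <= frag_len`.
#' @param min_tail minimum length of a trailing fragment.
#' @return a `fragmentation_scheme` list.
#' @export
fragmentation_scheme <- function(frag_len = 200L, step = 100L, min_tail = 100L) {
  gs_assert(step > 0 && step <= frag_len, "require 0 < step <= frag_len")
  structure(list(frag_len = as.integer(frag_len), step = as.integer(step),
                 min_tail = as.integer(min_tail)),
            class = "fragmentation_scheme")
}

#' Fragment a genome into overlapping windows
#'
#' Per contig of length `L >= frag_len` the fragment count is
#' `floor((L - frag_len)/step) + 1`, plus one trailing fragment when at least
#' `min_tail` bp remain beyond the last window's end (only possible when
#' `min_tail < step`). A whole contig shorter than `frag_len` but at least
#' `min_tail` bp yields a single fragment.
#'
#' @param genome a [genome_record()].
#' @param scheme a [fragmentation_scheme()].
#' @return character vector of fragments (ordered along each contig).
#' @export
fragment_genome <- function(genome, scheme = fragmentation_scheme()) {
  gs_assert(inherits(genome, "genome_record"), "expected a genome_record")
  out <- lapply(genome$contigs, function(ctg) {
    L <- nchar(ctg)
    if (L < scheme$min_tail) return(character(0))
    if (L < scheme$frag_len) return(ctg)
    n_full <- (L - scheme$frag_len) %/% scheme$step + 1L
    starts <- (seq_len(n_full) - 1L) * scheme$step + 1L
    frags <- substring(ctg, starts, starts + scheme$frag_len - 1L)
    last_end <- starts[n_full] + scheme$frag_len - 1L
    if (last_end < L && (L - last_end) >= scheme$min_tail) {
      frags <- c(frags, substring(ctg, last_end + 1L, L))
    }
    frags
  })
  unlist(out, use.names = FALSE)
}

#' Fragmented pairwise genome similarity (percent)
#'
#' Gegenees-style score-normalized similarity: genome A is fragmented, each
#' fragment's best local-alignment score against genome B (0 when nothing
#' aligns) is summed and normalized by the fragments' self-scores, so
#' `sim(A, A) = 100` exactly and non-homologous content drags the value far
#' below the ANI scale:
#' `sim(A,B) = 100 * sum_f best(f, B) / sum_f best(f, A)`.
#'
#' @param A,B [genome_record()]s.
#' @param scheme a [fragmentation_scheme()].
#' @param params an [align_params()].
#' @return percent similarity (scalar, asymmetric in its arguments).
#' @export
pair_similarity <- function(A, B, scheme = fragmentation_scheme(),
                            params = align_params()) {
  frags <- fragment_genome(A, scheme)
  gs_assert(length(frags) > 0, "genome %s yields no fragments", A$strain_id)
  # self-score of an N-free fragment is match * length; recompute exactly
  self <- frag_self_scores(frags, params)
  gs_assert(sum(self) > 0, "degenerate genome %s: zero self-score", A$strain_id)
  if (identical(A$strain_id, B$strain_id)) return(100)
  hits <- query_vs_set(frags, B$contigs, params, type = "dna")
  100 * sum(hits$score) / sum(self)
}

#' @noRd
frag_self_scores <- function(frags, params) {
  n_acgt <- nchar(frags) - vapply(frags, function(f)
    sum(strsplit(f, "")[[1]] == "N"), numeric(1), USE.NAMES = FALSE)
  params$match * n_acgt
}

#' All-vs-all fragmented similarity matrix
#'
#' Computes `sim(A, B)` for every ordered pair (the matrix is asymmetric, as
#' in Gegenees heatmaps; the diagonal is exactly 100). The companion
#' symmetric distance `D = 100 - (sim(A,B) + sim(B,A))/2` can be exported for
#' SplitsTree with [export_nexus_distances()].
#'
#' @param cohort named list of [genome_record()]s.
#' @param scheme a [fragmentation_scheme()].
#' @param params an [align_params()].
#' @return list with `similarity` (asymmetric percent matrix) and `distance`
#'   (symmetric `100 - mean similarity` matrix).
#' @export
similarity_matrix <- function(cohort, scheme = fragmentation_scheme(),
                              params = align_params()) {
  ids <- vapply(cohort, `[[`, character(1), "strain_id")
  gs_assert(length(ids) >= 2, "cohort must contain >= 2 genomes")
  gs_assert(!anyDuplicated(ids), "duplicate strain ids")
  n <- length(ids)
  S <- matrix(100, n, n, dimnames = list(ids, ids))
  frag_cache <- lapply(cohort, fragment_genome, scheme = scheme)
  self_cache <- lapply(frag_cache, frag_self_scores, params = params)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      hits <- query_vs_set(frag_cache[[i]], cohort[[j]]$contigs, params, "dna")
      S[i, j] <- 100 * sum(hits$score) / sum(self_cache[[i]])
    }
  }
  D <- 100 - (S + t(S)) / 2
  diag(D) <- 0
  list(similarity = S, distance = D)
}
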