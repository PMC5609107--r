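#' Alignment engine parameters
#'
#' A single parameter bundle shared by every alignment-backed stage
#' (fragmented similarity, ANI, wgMLST allele calling, protein orthology).
#' The engine is k-mer seed-and-extend: shared words vote for diagonals, the
#' best candidates are aligned with an affine-gap (Gotoh) local DP — full DP
#' when both sequences are at most `exact_threshold` long, banded DP of
#' half-width `band` around the seeded diagonal otherwise. The banded score is
#' never above the full Smith-Waterman optimum. The published study used BLAST
#' engines whose word sizes and penalties are unstated, so all engine
#' parameters here are explicit configuration.
#'
#' @param kmer_size seed word length (default 11 nt; use 4 for proteins).
#' @param match,mismatch,gap_open,gap_extend scoring; a gap of length L costs
#'   `gap_open + (L-1)*gap_extend`.
#' @param exact_threshold inputs no longer than this are aligned with the full
#'   local DP (exact optimum).
#' @param band half-width of the banded DP used for long subjects.
#' @param max_candidates seeded candidates aligned per query/strand.
#' @param min_seed_votes minimum shared k-mers on a diagonal bucket before a
#'   candidate is aligned (chance single-word matches are skipped unless
#'   nothing better seeded).
#' @return an `align_params` list.
#' @export
align_params <- function(kmer_size = 11L, match = 1L, mismatch = -1L,
                         gap_open = -2L, gap_extend = -1L,
                         exact_threshold = 600L, band = 16L,
                         max_candidates = 4L, min_seed_votes = 2L) {
  gs_assert(kmer_size >= 2, "kmer_size must be >= 2")
  gs_assert(exact_threshold >= kmer_size, "exact_threshold must be >= kmer_size")
  gs_assert(match > 0 && mismatch < 0 && gap_open < 0 && gap_extend < 0,
            "scoring must have positive match and negative penalties")
  structure(list(kmer_size = as.integer(kmer_size), match = as.integer(match),
                 mismatch = as.integer(mismatch), gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 exact_threshold = as.integer(exact_threshold),
                 band = as.integer(band),
                 max_candidates = as.integer(max_candidates),
                 min_seed_votes = as.integer(min_seed_votes)),
            class = "align_params")
}

#' Protein-mode defaults (shorter seed word)
#' @rdname align_params
#' @export
align_params_protein <- function(kmer_size = 4L, ...) {
  align_params(kmer_size = kmer_size, ...)
}

#' Build a k-mer position index for one sequence
#'
#' Maps every k-mer to its 0-based start positions; k-mers containing `N` are
#' omitted. Reference implementation used in tests; the batch aligner builds
#' its index in C++.
#'
#' @param sequence character scalar.
#' @param k word length.
#' @return named list: k-mer -> integer vector of 0-based positions.
#' @export
build_kmer_index <- function(sequence, k) {
  n <- nchar(sequence)
  gs_assert(k <= n, "k (%d) exceeds sequence length (%d)", k, n)
  starts <- seq_len(n - k + 1)
  words <- substring(sequence, starts, starts + k - 1)
  keep <- !grepl("N", words, fixed = TRUE)
  split(starts[keep] - 1L, words[keep])
}

#' Batch best-hit alignment of queries against a subject set (internal)
#'
#' @param queries,subjects character vectors.
#' @param params an `align_params`.
#' @param type `"dna"` (both strands searched) or `"protein"`.
#' @return data.frame, one row per query: `subject` index (NA when no hit),
#'   `score`, `identity` (percent of alignment columns identical, gaps in the
#'   denominator), `aln_len`, `q_cov`/`s_cov` (percent of query/subject length
#'   spanned by the alignment), coordinates, `strand`.
#' @keywords internal
query_vs_set <- function(queries, subjects, params = align_params(),
                         type = c("dna", "protein")) {
  type <- match.arg(type)
  protein <- type == "protein"
  hits <- cpp_query_vs_set(as.character(queries), as.character(subjects),
                           params$kmer_size, protein, !protein,
                           params$match, params$mismatch, params$gap_open,
                           params$gap_extend, params$exact_threshold,
                           params$band, params$max_candidates,
                           params$min_seed_votes)
  hits$identity <- ifelse(hits$aln_len > 0, 100 * hits$n_ident / hits$aln_len, NA_real_)
  qlen <- nchar(as.character(queries))
  slen <- nchar(as.character(subjects))
  hits$q_cov <- ifelse(is.na(hits$subject), NA_real_,
                       100 * (hits$q_end - hits$q_start + 1) / qlen[hits$query])
  hits$s_cov <- ifelse(is.na(hits$subject), NA_real_,
                       100 * (hits$s_end - hits$s_start + 1) / slen[hits$subject])
  hits
}

#' Best local alignment of a query/subject pair
#'
#' When both sequences are at most `exact_threshold` long the result is the
#' exact affine-gap Smith-Waterman optimum; otherwise the seed-and-extend
#' path is used and the reported score is a lower bound on the optimum. For
#' DNA both strands are searched and the better one reported (plus strand on
#' ties). Returns `NULL` when no positive-scoring alignment exists.
#'
#' @param query,subject character scalars.
#' @param params an `align_params`.
#' @param type `"dna"` or `"protein"`.
#' @return list with `score`, `identity`, `aln_len`, `q_cov`, `s_cov`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `strand`; or `NULL`.
#' @export
local_align <- function(query, subject, params = align_params(),
                        type = c("dna", "protein")) {
  type <- match.arg(type)
  gs_assert(nchar(query) > 0 && nchar(subject) > 0, "empty sequence")
  protein <- type == "protein"
  exact <- nchar(query) <= params$exact_threshold &&
    nchar(subject) <= params$exact_threshold
  if (exact) {
    pick <- NULL
    strands <- if (protein) list(c(1, query)) else
      list(c(1, query), c(-1, revcomp_chr(query)))
    for (st in strands) {
      r <- cpp_sw_full(st[2], subject, protein, params$match, params$mismatch,
                       params$gap_open, params$gap_extend)
      if (!r$valid) next
      if (is.null(pick) || r$score > pick$score) {
        pick <- r
        pick$strand <- as.integer(st[1])
      }
    }
    if (is.null(pick)) return(NULL)
    list(score = pick$score,
         identity = 100 * pick$n_ident / pick$aln_len,
         aln_len = pick$aln_len,
         q_cov = 100 * (pick$q_end - pick$q_start + 1) / nchar(query),
         s_cov = 100 * (pick$s_end - pick$s_start + 1) / nchar(subject),
         q_start = pick$q_start, q_end = pick$q_end,
         s_start = pick$s_start, s_end = pick$s_end, strand = pick$strand)
  } else {
    h <- query_vs_set(query, subject, params, type)
    if (is.na(h$subject[1])) return(NULL)
    as.list(h[1, c("score", "identity", "aln_len", "q_cov", "s_cov",
                   "q_start", "q_end", "s_start", "s_end", "strand")])
  }
}

#' Best hit of a query over a named collection of subjects
#'
#' Maximal alignment score over subjects; ties broken by lexicographic
#' subject name. Returns `NULL` when nothing aligns.
#'
#' @param query character scalar.
#' @param subjects named character vector of subject sequences.
#' @param params an `align_params`.
#' @param type `"dna"` or `"protein"`.
#' @return the winning hit as in [local_align()] plus `subject_id`.
#' @export
best_hit <- function(query, subjects, params = align_params(),
                     type = c("dna", "protein")) {
  type <- match.arg(type)
  gs_assert(length(subjects) >= 1, "need at least one subject")
  gs_assert(!is.null(names(subjects)), "subjects must be named")
  ord <- order(names(subjects))
  subjects <- subjects[ord]
  best <- NULL
  for (i in seq_along(subjects)) {
    h <- local_align(query, subjects[[i]], params, type)
    if (is.null(h)) next
    if (is.null(best) || h$score > best$score) {
      best <- h
      best$subject_id <- names(subjects)[i]
    }
  }
  best
}
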