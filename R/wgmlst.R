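#' Build a pan-locus allele database from per-strain gene sets
#'
#' Greedy single-pass clustering of nucleotide genes into loci: genes are
#' visited in decreasing length order (ties by gene id); a gene joins the
#' first existing locus whose representative it matches at `min_identity`
#' percent identity and `min_coverage` percent mutual coverage, otherwise it
#' founds a new locus. Distinct sequences within a locus are registered as
#' alleles, numbered 1-based in order of first observation. Thresholds
#' default to the published BLASTn filters (90% identity / 80% coverage).
#'
#' @param cds_sets named list (per strain) of named nucleotide gene vectors.
#' @param min_identity,min_coverage locus membership thresholds (percent).
#' @param params an [align_params()].
#' @return object of class `locus_db`: list with `representatives` (named
#'   vector, `locus_###`), `alleles` (per locus, character vector of distinct
#'   allele sequences), and the thresholds.
#' @export
build_locus_db <- function(cds_sets, min_identity = 90, min_coverage = 80,
                           params = align_params()) {
  gs_assert(length(cds_sets) >= 1 && any(lengths(cds_sets) > 0),
            "need at least one strain with at least one gene")
  genes <- unlist(unname(cds_sets))
  gs_assert(!is.null(names(genes)), "genes must be named")
  ord <- order(-nchar(genes), names(genes))
  genes <- genes[ord]

  reps <- character(0)
  alleles <- list()
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    joined <- FALSE
    if (length(reps) > 0) {
      h <- query_vs_set(g, reps, params, type = "dna")
      if (!is.na(h$subject[1]) &&
          h$identity[1] >= min_identity &&
          min(h$q_cov[1], h$s_cov[1]) >= min_coverage) {
        li <- h$subject[1]
        if (!(g %in% alleles[[li]])) alleles[[li]] <- c(alleles[[li]], g)
        joined <- TRUE
      }
    }
    if (!joined) {
      reps <- c(reps, g)
      alleles[[length(reps)]] <- g
    }
  }
  names(reps) <- sprintf("locus_%04d", seq_along(reps))
  names(alleles) <- names(reps)
  structure(list(representatives = reps, alleles = alleles,
                 min_identity = min_identity, min_coverage = min_coverage),
            class = "locus_db")
}

#' @export
print.locus_db <- function(x, ...) {
  cat(sprintf("<locus_db> %d loci, %d alleles (filters: %g%% id / %g%% cov)\n",
              length(x$representatives), sum(lengths(x$alleles)),
              x$min_identity, x$min_coverage))
  invisible(x)
}

#' Call a strain's allele profile against a locus database
#'
#' Per locus the representative is aligned against the strain's genes; the
#' locus is called iff the best hit reaches `min_identity` percent identity
#' and covers at least `min_coverage` percent of the locus representative.
#' An exact sequence match to a registered allele reuses its number; a novel
#' qualifying sequence mints the next number (the registry is updated in
#' place semantics by returning the extended db). No qualifying hit leaves
#' the locus `NA` (missing).
#'
#' @param genome_cds named nucleotide gene vector for one strain.
#' @param db a [build_locus_db()] result.
#' @param strain_id label stored on the profile.
#' @param params an [align_params()].
#' @return list with `profile` (named integer vector over all loci, `NA` =
#'   missing), `strain_id`, and `db` (allele registry possibly extended).
#' @export
call_alleles <- function(genome_cds, db, strain_id = "strain",
                         params = align_params()) {
  gs_assert(inherits(db, "locus_db") && length(db$representatives) > 0,
            "empty locus database")
  loci <- names(db$representatives)
  calls <- setNames(rep(NA_integer_, length(loci)), loci)
  if (length(genome_cds) > 0) {
    hits <- query_vs_set(db$representatives, genome_cds, params, type = "dna")
    for (i in seq_along(loci)) {
      h <- hits[i, ]
      if (is.na(h$subject) || h$identity < db$min_identity ||
          h$q_cov < db$min_coverage) next
      seqv <- as.character(genome_cds[[h$subject]])
      reg <- db$alleles[[i]]
      k <- match(seqv, reg)
      if (is.na(k)) {
        db$alleles[[i]] <- c(reg, seqv)
        k <- length(reg) + 1L
      }
      calls[i] <- k
    }
  }
  list(profile = calls, strain_id = strain_id, db = db)
}

#' Allele profiles for a whole cohort
#'
#' Builds the locus database from the cohort's gene sets and calls every
#' strain against it, threading the growing allele registry through the
#' calls so identical novel variants in different strains share a number.
#'
#' @param cds_sets named list (per strain) of named nucleotide gene vectors.
#' @param min_identity,min_coverage see [build_locus_db()].
#' @param params an [align_params()].
#' @return list with `profiles` (strains x loci integer matrix, `NA` =
#'   missing) and `db`.
#' @export
wgmlst_profiles <- function(cds_sets, min_identity = 90, min_coverage = 80,
                            params = align_params()) {
  db <- build_locus_db(cds_sets, min_identity, min_coverage, params)
  strains <- names(cds_sets)
  prof <- matrix(NA_integer_, length(strains), length(db$representatives),
                 dimnames = list(strains, names(db$representatives)))
  for (s in strains) {
    res <- call_alleles(cds_sets[[s]], db, s, params)
    db <- res$db
    prof[s, ] <- res$profile
  }
  list(profiles = prof, db = db)
}

#' Distance between two allele profiles
#'
#' Fraction of differing allele numbers among loci called in both profiles;
#' loci missing in either are excluded (assembly-driven absence), unless
#' `missing_as_diff = TRUE`, in which case a locus called in exactly one
#' profile counts as a difference.
#'
#' @param p,q integer allele vectors over the same locus set (`NA` = missing).
#' @param missing_as_diff count one-sided missing loci as differences.
#' @return distance in `[0, 1]`; `NA` (with a warning) when no locus is
#'   shared.
#' @export
profile_distance <- function(p, q, missing_as_diff = FALSE) {
  gs_assert(length(p) == length(q) && identical(names(p), names(q)),
            "profiles must share one locus set")
  both <- !is.na(p) & !is.na(q)
  diffs <- sum(p[both] != q[both])
  denom <- sum(both)
  if (missing_as_diff) {
    one_sided <- xor(is.na(p), is.na(q))
    diffs <- diffs + sum(one_sided)
    denom <- denom + sum(one_sided)
  }
  if (denom == 0) {
    warning("no shared called loci; distance undefined")
    return(NA_real_)
  }
  diffs / denom
}

#' Profile distance matrix for a cohort
#' @param profiles strains x loci integer matrix (from [wgmlst_profiles()]).
#' @inheritParams profile_distance
#' @return symmetric distance matrix (zero diagonal).
#' @export
profile_distance_matrix <- function(profiles, missing_as_diff = FALSE) {
  n <- nrow(profiles)
  D <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- profile_distance(profiles[i, ], profiles[j, ],
                                             missing_as_diff)
    }
  }
  D
}

#' UPGMA dendrogram from a distance matrix
#'
#' Unweighted pair-group method with arithmetic mean, via
#' `hclust(method = "average")`; the result is ultrametric (equal root-to-leaf
#' path lengths). Returned as an `ape::phylo` tree whose cophenetic distances
#' reproduce the merge heights.
#'
#' @param dist_matrix square symmetric non-negative matrix, zero diagonal.
#' @return rooted `phylo` tree with branch lengths.
#' @export
upgma <- function(dist_matrix) {
  gs_assert(is.matrix(dist_matrix) && nrow(dist_matrix) == ncol(dist_matrix),
            "distance matrix must be square")
  gs_assert(max(abs(dist_matrix - t(dist_matrix))) <= 1e-9,
            "distance matrix must be symmetric")
  gs_assert(all(dist_matrix >= 0) && all(diag(dist_matrix) == 0),
            "distances must be non-negative with a zero diagonal")
  ord <- order(rownames(dist_matrix))
  dist_matrix <- dist_matrix[ord, ord]
  hc <- hclust(as.dist(dist_matrix), method = "average")
  ape::as.phylo(hc)
}
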