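#' Protein similarity graph for ortholog-family inference
#'
#' All-vs-all best-hit comparison of per-strain protein sets (the stand-in
#' for the published all-vs-all BLASTp at e-value 1e-6, whose statistics are
#' not reproducible here; the gate is re-expressed as identity and coverage
#' thresholds). For each gene and each other strain the best local hit is
#' computed; a directed score `identity * min(q_cov, s_cov)/100` is retained
#' iff identity >= `min_identity` and `min(q_cov, s_cov)` >= `min_coverage`.
#' The undirected edge weight is the mean of the directed scores.
#'
#' @param protein_sets named list (per strain) of named amino-acid vectors;
#'   a strain with zero proteins is retained with a warning.
#' @param params an [align_params()] (protein defaults).
#' @param min_identity,min_coverage edge gate (percent).
#' @return object of class `similarity_graph`: `nodes` data.frame
#'   (`node`, `strain_id`, `gene_id`) and `edges` data.frame
#'   (`from`, `to`, `weight`), plus `strains`.
#' @export
build_graph <- function(protein_sets, params = align_params_protein(),
                        min_identity = 40, min_coverage = 50) {
  gs_assert(length(protein_sets) >= 2, "need >= 2 strains")
  empty <- names(protein_sets)[lengths(protein_sets) == 0]
  if (length(empty)) {
    warning("strains with no proteins retained with zero genes: ",
            paste(empty, collapse = ", "))
  }
  nodes <- do.call(rbind, lapply(names(protein_sets), function(s) {
    ps <- protein_sets[[s]]
    if (length(ps) == 0) return(NULL)
    data.frame(strain_id = s, gene_id = names(ps), seq = as.character(ps),
               stringsAsFactors = FALSE)
  }))
  gs_assert(!is.null(nodes) && nrow(nodes) > 0, "no proteins in cohort")
  nodes$node <- seq_len(nrow(nodes))

  strains <- names(protein_sets)
  idx_of <- split(nodes$node, nodes$strain_id)
  directed <- list()
  for (sa in strains) {
    for (sb in strains) {
      if (sa == sb) next
      ia <- idx_of[[sa]]; ib <- idx_of[[sb]]
      if (is.null(ia) || is.null(ib)) next
      hits <- query_vs_set(nodes$seq[ia], nodes$seq[ib], params, "protein")
      cov <- pmin(hits$q_cov, hits$s_cov)
      keep <- !is.na(hits$subject) & hits$identity >= min_identity &
        cov >= min_coverage
      if (!any(keep)) next
      directed[[paste(sa, sb)]] <- data.frame(
        from = ia[hits$query[keep]], to = ib[hits$subject[keep]],
        w = hits$identity[keep] * cov[keep] / 100, stringsAsFactors = FALSE)
    }
  }
  if (length(directed)) {
    dd <- do.call(rbind, unname(directed))
    key <- paste(pmin(dd$from, dd$to), pmax(dd$from, dd$to))
    agg <- tapply(dd$w, key, mean)
    pieces <- strsplit(names(agg), " ", fixed = TRUE)
    edges <- data.frame(
      from = as.integer(vapply(pieces, `[`, character(1), 1)),
      to = as.integer(vapply(pieces, `[`, character(1), 2)),
      weight = as.numeric(agg), stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(0), to = integer(0), weight = numeric(0))
  }
  structure(list(nodes = nodes[, c("node", "strain_id", "gene_id", "seq")],
                 edges = edges, strains = strains),
            class = "similarity_graph")
}

#' Markov clustering (MCL) of a similarity graph into gene families
#'
#' Classic MCL on the column-stochastic transition matrix: self-loops are
#' added (weight = the node's maximum incident edge weight, 1 for isolated
#' nodes), columns normalized, then expansion (matrix squaring) alternates
#' with inflation (elementwise power `inflation`, column renormalization)
#' and pruning of entries below `prune` until the matrix change drops below
#' `tol`. Families are the connected components of the converged matrix's
#' nonzero pattern; isolated nodes form their own family. Deterministic.
#'
#' @param graph a [build_graph()] result.
#' @param inflation inflation exponent (> 1; default 1.5).
#' @param max_iter iteration cap (error with diagnostics on non-convergence).
#' @param tol convergence threshold on the max absolute entry change.
#' @param prune entries below this are dropped after each inflation.
#' @return object of class `gene_family_set`: `membership` data.frame
#'   (`family_id`, `strain_id`, `gene_id`), `presence` (strains x families
#'   logical matrix over all cohort strains), `n_iter`.
#' @export
mcl <- function(graph, inflation = 1.5, max_iter = 100L, tol = 1e-5,
                prune = 1e-6) {
  gs_assert(inherits(graph, "similarity_graph"), "expected a similarity_graph")
  gs_assert(inflation > 1, "inflation must be > 1")
  n <- nrow(graph$nodes)
  e <- graph$edges
  loop_w <- rep(1, n)
  if (nrow(e) > 0) {
    mx <- tapply(c(e$weight, e$weight), c(e$from, e$to), max)
    loop_w[as.integer(names(mx))] <- as.numeric(mx)
  }
  M <- Matrix::sparseMatrix(
    i = c(e$from, e$to, seq_len(n)),
    j = c(e$to, e$from, seq_len(n)),
    x = c(e$weight, e$weight, loop_w), dims = c(n, n))
  normalize_cols <- function(A) {
    cs <- Matrix::colSums(A)
    A %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalize_cols(M)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M                      # expansion
    M2 <- as(M2, "CsparseMatrix")
    M2@x <- M2@x^inflation             # inflation
    M2 <- normalize_cols(M2)
    M2 <- Matrix::drop0(M2 * (abs(M2) >= prune))
    M2 <- normalize_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("MCL did not converge in %d iterations (last delta %.3g, %d nodes, %d edges)",
                 max_iter, delta, n, nrow(e)), call. = FALSE)
  }
  # families = components of the converged nonzero pattern
  T3 <- Matrix::summary(as(M, "TsparseMatrix"))
  comp <- components_from_edges(n, T3$i, T3$j)
  fam_index <- match(comp, sort(unique(comp)))
  fam_ids <- sprintf("fam_%04d", fam_index)
  membership <- data.frame(family_id = fam_ids,
                           strain_id = graph$nodes$strain_id,
                           gene_id = graph$nodes$gene_id,
                           stringsAsFactors = FALSE)
  structure(list(membership = membership,
                 presence = presence_matrix(membership, graph$strains),
                 n_iter = it),
            class = "gene_family_set")
}

#' @noRd
components_from_edges <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    ri <- find(from[k]); rj <- find(to[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Genomes x families presence/absence matrix
#'
#' @param membership data.frame with `family_id`, `strain_id` (one row per gene).
#' @param strains cohort strain ids (rows; strains absent from `membership`
#'   get all-FALSE rows).
#' @return logical matrix, strains x families.
#' @export
presence_matrix <- function(membership, strains = sort(unique(membership$strain_id))) {
  fams <- sort(unique(membership$family_id))
  P <- matrix(FALSE, length(strains), length(fams),
              dimnames = list(strains, fams))
  P[cbind(match(membership$strain_id, strains),
          match(membership$family_id, fams))] <- TRUE
  P
}

#' Partition gene families into pangenome subsets
#'
#' Core = families present in every genome; singleton families = present in
#' exactly one genome; shell = the remainder. Singletons are additionally
#' counted as genes (a singleton family may hold several genes of one
#' strain), and per-genome unique gene counts are reported.
#'
#' @param families a [mcl()] result (or any `gene_family_set`).
#' @param n_genomes number of genomes defining "core" (default: rows of the
#'   presence matrix).
#' @return object of class `pangenome_subsets`: list with `pangenome_size`,
#'   `core`, `shell`, `singleton_families`, `singleton_genes`,
#'   `per_genome_unique` (named vector of singleton gene counts).
#' @export
subsets <- function(families, n_genomes = nrow(families$presence)) {
  gs_assert(inherits(families, "gene_family_set"), "expected a gene_family_set")
  P <- families$presence
  gs_assert(ncol(P) > 0, "no families")
  counts <- colSums(P)
  core_f <- colnames(P)[counts == n_genomes]
  single_f <- colnames(P)[counts == 1]
  mem <- families$membership
  single_mem <- mem[mem$family_id %in% single_f, , drop = FALSE]
  per_unique <- setNames(integer(nrow(P)), rownames(P))
  if (nrow(single_mem)) {
    tb <- table(single_mem$strain_id)
    per_unique[names(tb)] <- as.integer(tb)
  }
  structure(list(pangenome_size = ncol(P),
                 core = length(core_f),
                 shell = ncol(P) - length(core_f) - length(single_f),
                 singleton_families = length(single_f),
                 singleton_genes = nrow(single_mem),
                 core_families = core_f,
                 per_genome_unique = per_unique),
            class = "pangenome_subsets")
}

#' @export
print.pangenome_subsets <- function(x, ...) {
  cat(sprintf(paste0("<pangenome_subsets> pangenome %d families: core %d, ",
                     "shell %d, singleton %d (%d genes)\n"),
              x$pangenome_size, x$core, x$shell, x$singleton_families,
              x$singleton_genes))
  invisible(x)
}
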