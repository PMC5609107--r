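#' Configuration for the synthetic genome-cohort generator
#'
#' The generator emits a bacterial cohort with known genospecies structure:
#' a root gene pool of core ORFs, per-lineage (cluster or singleton-strain)
#' accessory ORFs, strain-private ORFs, and nucleotide divergence applied on
#' two levels - between lineage ancestors and within clusters - so that the
#' expected pairwise identity of homologous sequence is `100*(1-d_within)`
#' inside a cluster and `100*(1-d_between)` across clusters. Defaults mirror
#' the published cohort's architecture (3 clusters of 5/4/4 strains plus 4
#' unclustered strains; intra-cluster ANI ~98%, inter-cluster ~87%) at desk
#' scale (tens of kilobases per genome rather than megabases).
#'
#' Substitutions are drawn independently per site (no multiple-hit modeling,
#' adequate for d <= 0.15) with transition:transversion odds `kappa:2`.
#' Genes are kept as intact ORFs: the first and last codons are never mutated
#' and internal stop codons arising from mutation are repaired at the third
#' codon position, so every emitted protein translates cleanly.
#'
#' @param n_clusters number of genospecies clusters.
#' @param genomes_per_cluster integer vector (recycled to `n_clusters`).
#' @param n_singletons strains belonging to no cluster.
#' @param core_genes ORFs shared by the whole cohort.
#' @param cluster_accessory lineage-specific ORFs per cluster/singleton.
#' @param private_genes Poisson mean of strain-private ORFs.
#' @param gene_len_mean,gene_len_sd gene length distribution (bp; rounded to a
#'   codon multiple, minimum 90 bp).
#' @param intergenic_len mean spacer length between genes (bp, Poisson).
#' @param d_within,d_between per-site substitution probabilities for
#'   within-cluster and between-cluster pairs (`0 <= d_within < d_between <= 0.3`).
#' @param kappa transition/transversion odds parameter (transition chosen with
#'   odds `kappa : 2`).
#' @param gene_loss_prob per-gene per-strain loss probability.
#' @param contigs_per_genome split each genome into this many contigs
#'   (emulates draft assemblies; 1 = closed genome).
#' @param seed integer seed fixing all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_clusters = 3L, genomes_per_cluster = c(5L, 4L, 4L),
                       n_singletons = 4L, core_genes = 60L,
                       cluster_accessory = 20L, private_genes = 8,
                       gene_len_mean = 330, gene_len_sd = 60,
                       intergenic_len = 60, d_within = 0.02, d_between = 0.13,
                       kappa = 2, gene_loss_prob = 0.02,
                       contigs_per_genome = 1L, seed = 1L) {
  genomes_per_cluster <- rep_len(as.integer(genomes_per_cluster), n_clusters)
  gs_assert(d_within >= 0 && d_within < d_between && d_between <= 0.3,
            "require 0 <= d_within < d_between <= 0.3")
  gs_assert(core_genes >= 1, "need at least one core gene")
  gs_assert(all(c(n_clusters, n_singletons, cluster_accessory) >= 0),
            "counts must be non-negative")
  structure(list(n_clusters = as.integer(n_clusters),
                 genomes_per_cluster = genomes_per_cluster,
                 n_singletons = as.integer(n_singletons),
                 core_genes = as.integer(core_genes),
                 cluster_accessory = as.integer(cluster_accessory),
                 private_genes = private_genes,
                 gene_len_mean = gene_len_mean, gene_len_sd = gene_len_sd,
                 intergenic_len = intergenic_len,
                 d_within = d_within, d_between = d_between, kappa = kappa,
                 gene_loss_prob = gene_loss_prob,
                 contigs_per_genome = as.integer(contigs_per_genome),
                 seed = as.integer(seed)),
            class = "sim_config")
}

SENSE_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

#' Random ORF: ATG start, random sense codons, single terminal stop
#' @noRd
random_orf <- function(len_bp) {
  n_codons <- max(30L, round(len_bp / 3))
  body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

#' @noRd
random_spacer <- function(mean_len) {
  n <- max(1L, rpois(1, mean_len))
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a sequence under a two-parameter substitution model
#'
#' Each site is substituted independently with probability `d`; a substituting
#' site takes the transition with odds `kappa : 2` against the two
#' transversions (each transversion equally likely). `N` sites are left
#' untouched; length is preserved. Uses the session RNG (seed it for
#' reproducibility).
#'
#' @param sequence character scalar over `A,C,G,T,N`.
#' @param d per-site substitution probability in `[0, 0.75]`.
#' @param kappa transition/transversion odds parameter.
#' @param protect_orf keep the first/last codon intact and repair internal
#'   stop codons (third-position edit), preserving ORF structure.
#' @return mutated sequence.
#' @export
mutate_seq <- function(sequence, d, kappa = 2, protect_orf = FALSE) {
  gs_assert(d >= 0 && d <= 0.75, "d must be in [0, 0.75]")
  if (d == 0) return(sequence)
  x <- strsplit(sequence, "")[[1]]
  n <- length(x)
  eligible <- x %in% c("A", "C", "G", "T")
  if (protect_orf && n >= 6) eligible[c(1:3, (n - 2):n)] <- FALSE
  hit <- which(eligible & runif(n) < d)
  if (length(hit)) {
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    tv_map <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
    is_ts <- runif(length(hit)) < kappa / (kappa + 2)
    x[hit] <- ifelse(is_ts, ts_map[x[hit]],
                     vapply(x[hit], function(b) sample(tv_map[[b]], 1), character(1)))
  }
  out <- paste(x, collapse = "")
  if (protect_orf) out <- repair_internal_stops(out)
  out
}

#' Deterministically repair internal stop codons (third-position edit)
#' @noRd
repair_internal_stops <- function(orf) {
  n <- nchar(orf)
  if (n < 9 || n %% 3 != 0) return(orf)
  x <- strsplit(orf, "")[[1]]
  fix <- c(TAA = "T", TAG = "T", TGA = "T") # TAA->TAT, TAG->TAT, TGA->TGT
  for (c0 in seq(4, n - 5, by = 3)) {
    codon <- paste(x[c0:(c0 + 2)], collapse = "")
    if (codon %in% names(fix)) x[c0 + 2] <- fix[[codon]]
  }
  paste(x, collapse = "")
}

#' Simulate the root ancestor: core gene pool and genome layout
#'
#' Core genes are random-codon ORFs (ATG start, terminal stop only); the
#' layout interleaves them with random intergenic spacers. Deterministic for
#' a fixed `config$seed`.
#'
#' @param config a `sim_config`.
#' @return list with `genes` (named ORF vector, family ids `core_###`) and
#'   `spacers` (length `core_genes + 1`).
#' @export
simulate_ancestor <- function(config) {
  gs_assert(inherits(config, "sim_config"), "expected a sim_config")
  set.seed(config$seed)
  lens <- pmax(90, round(rnorm(config$core_genes, config$gene_len_mean,
                               config$gene_len_sd) / 3) * 3)
  genes <- vapply(lens, random_orf, character(1))
  names(genes) <- sprintf("core_%03d", seq_len(config$core_genes))
  spacers <- vapply(rep(config$intergenic_len, config$core_genes + 1),
                    random_spacer, character(1))
  list(genes = genes, spacers = spacers)
}

#' Simulate a genome cohort with known genospecies structure
#'
#' Lineage ancestors (one per cluster plus one per singleton strain) are
#' derived from the root by mutating every gene and spacer at rate
#' `(d_between - d_within)/2` and appending lineage-specific accessory ORFs;
#' strains are derived from their lineage ancestor at rate `d_within/2`, with
#' per-gene loss and fresh private ORFs. The expected homologous-site
#' divergence is thus `d_within` within clusters and `d_between` between
#' lineages. Proteins are standard-code translations of the retained ORFs.
#'
#' @param config a `sim_config`.
#' @return list with
#'   `genomes` (named list of [genome_record()]),
#'   `genes` (per strain, named nucleotide ORF vector; names are gene ids),
#'   `proteins` (per strain, named amino-acid vector),
#'   `truth` (list: `clusters` strain->cluster label (`"singleton"` for
#'   unclustered strains), `inventory` data.frame of strain/gene/family,
#'   `families` all family ids, `core_families`, `expected_identity` matrix),
#'   and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  gs_assert(inherits(config, "sim_config"), "expected a sim_config")
  root <- simulate_ancestor(config) # seeds the RNG with config$seed
  d_lin <- (config$d_between - config$d_within) / 2
  d_str <- config$d_within / 2

  lineages <- c(sprintf("cl%d", seq_len(config$n_clusters)),
                if (config$n_singletons > 0) sprintf("sg%d", seq_len(config$n_singletons)))
  n_per <- c(config$genomes_per_cluster, rep(1L, config$n_singletons))
  is_cluster <- c(rep(TRUE, config$n_clusters), rep(FALSE, config$n_singletons))

  genomes <- list(); genes_by_strain <- list(); proteins <- list()
  inv <- list(); cluster_of <- character(0)
  all_families <- names(root$genes)

  for (li in seq_along(lineages)) {
    lin <- lineages[li]
    lin_genes <- vapply(root$genes, mutate_seq, character(1),
                        d = d_lin, kappa = config$kappa, protect_orf = TRUE)
    lin_spacers <- vapply(root$spacers, mutate_seq, character(1),
                          d = d_lin, kappa = config$kappa)
    if (config$cluster_accessory > 0) {
      acc_lens <- pmax(90, round(rnorm(config$cluster_accessory,
                                       config$gene_len_mean,
                                       config$gene_len_sd) / 3) * 3)
      acc <- vapply(acc_lens, random_orf, character(1))
      names(acc) <- sprintf("acc_%s_%03d", lin, seq_len(config$cluster_accessory))
      acc_spacers <- vapply(rep(config$intergenic_len, length(acc)),
                            random_spacer, character(1))
      lin_genes <- c(lin_genes, acc)
      lin_spacers <- c(lin_spacers, acc_spacers)
      all_families <- c(all_families, names(acc))
    }
    for (si in seq_len(n_per[li])) {
      strain <- if (is_cluster[li]) sprintf("%s_s%02d", lin, si) else
        sprintf("%s_solo", lin)
      st_genes <- vapply(lin_genes, mutate_seq, character(1),
                         d = d_str, kappa = config$kappa, protect_orf = TRUE)
      st_spacers <- vapply(lin_spacers, mutate_seq, character(1),
                           d = d_str, kappa = config$kappa)
      keep <- runif(length(st_genes)) >= config$gene_loss_prob
      st_genes <- st_genes[keep]
      n_priv <- rpois(1, config$private_genes)
      if (n_priv > 0) {
        priv_lens <- pmax(90, round(rnorm(n_priv, config$gene_len_mean,
                                          config$gene_len_sd) / 3) * 3)
        priv <- vapply(priv_lens, random_orf, character(1))
        names(priv) <- sprintf("prv_%s_%03d", strain, seq_len(n_priv))
        st_genes <- c(st_genes, priv)
        all_families <- c(all_families, names(priv))
      }
      gs_assert(length(st_genes) > 0, "config yielded an empty genome for %s", strain)
      lead <- st_spacers[seq_along(lin_genes)][keep] # spacer i precedes gene i
      if (n_priv > 0) {
        lead <- c(lead, vapply(rep(config$intergenic_len, n_priv),
                               random_spacer, character(1)))
      }
      genome_seq <- paste0(paste0(lead, st_genes, collapse = ""),
                           st_spacers[length(st_spacers)])
      contigs <- split_contigs(genome_seq, config$contigs_per_genome)
      gene_ids <- sprintf("%s|%s", strain, names(st_genes))
      gseq <- setNames(as.character(st_genes), gene_ids)
      genomes[[strain]] <- genome_record(strain, contigs)
      genes_by_strain[[strain]] <- gseq
      proteins[[strain]] <- translate_orfs(gseq)
      inv[[strain]] <- data.frame(strain_id = strain, gene_id = gene_ids,
                                  family_id = names(st_genes),
                                  stringsAsFactors = FALSE)
      cluster_of[strain] <- if (is_cluster[li]) LETTERS[li] else "singleton"
    }
  }

  strains <- names(genomes)
  dmat <- matrix(0, length(strains), length(strains),
                 dimnames = list(strains, strains))
  for (a in strains) for (b in strains) {
    if (a == b) next
    same <- cluster_of[a] != "singleton" && cluster_of[a] == cluster_of[b]
    dmat[a, b] <- if (same) config$d_within else config$d_between
  }
  truth <- list(clusters = cluster_of,
                inventory = do.call(rbind, unname(inv)),
                families = unique(all_families),
                core_families = names(root$genes),
                expected_identity = 100 * (1 - dmat))
  list(genomes = genomes, genes = genes_by_strain, proteins = proteins,
       truth = truth, config = config)
}

#' @noRd
split_contigs <- function(seq, n) {
  if (n <= 1) return(seq)
  L <- nchar(seq)
  n <- min(n, L)
  bounds <- floor(seq(0, L, length.out = n + 1))
  substring(seq, bounds[-length(bounds)] + 1, bounds[-1])
}

#' Translate ORFs with the standard genetic code (terminal stop removed)
#' @noRd
translate_orfs <- function(orfs) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(orfs), if.fuzzy.codon = "solve"))
  setNames(sub("\\*$", "", aa), names(orfs))
}

#' Write a simulated cohort to disk
#'
#' Emits per-strain genome FASTA (`genomes/`), gene and protein FASTA
#' (`genes/`, `proteins/`), `truth.tsv` (strain, cluster, gene, family) and
#' `simconfig.json`.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  for (d in file.path(dir, c("genomes", "genes", "proteins")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (strain in names(sim$genomes)) {
    write_fasta(sim$genomes[[strain]]$contigs,
                file.path(dir, "genomes", paste0(strain, ".fna")))
    write_fasta(sim$genes[[strain]],
                file.path(dir, "genes", paste0(strain, ".ffn")))
    write_fasta(sim$proteins[[strain]],
                file.path(dir, "proteins", paste0(strain, ".faa")))
  }
  tt <- sim$truth$inventory
  tt$cluster <- sim$truth$clusters[tt$strain_id]
  write.table(tt, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, file.path(dir, "simconfig.json"), auto_unbox = TRUE)
  invisible(dir)
}
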