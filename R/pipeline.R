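#' End-to-end pipeline configuration
#'
#' Bundles every stage's configuration with a single seed and an output
#' directory. Defaults match the published analysis wherever the paper states
#' a value (200/100 bp fragmentation, 94% ANI cutoff, 90%/80% wgMLST filters,
#' MCL inflation 1.5); everything else is explicit configuration. The config
#' round-trips losslessly through JSON ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param mode `"simulate"` (generate the cohort) or `"genomes-dir"` (read
#'   FASTA genomes, plus optional `genes/` and `proteins/` sibling dirs for
#'   the gene-based stages).
#' @param genomes_dir input directory for `mode = "genomes-dir"`.
#' @param sim a [sim_config()] (simulate mode).
#' @param scheme a [fragmentation_scheme()].
#' @param ani an [ani_config()].
#' @param align an [align_params()] for nucleotide stages.
#' @param align_aa an [align_params()] for protein stages.
#' @param wgmlst_identity,wgmlst_coverage wgMLST filters (percent).
#' @param pan_identity,pan_coverage protein-graph edge gate (percent).
#' @param inflation MCL inflation.
#' @param n_perms permutations for development curves.
#' @param alpha_margin support margin on alpha.
#' @param run_fragsim include the fragmented-similarity stage (the slowest).
#' @param seed master seed; stage seeds are derived as `seed*1009 + 97*stage`.
#' @param verbose log stage progress to stderr.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("simulate", "genomes-dir"),
                            genomes_dir = NULL, sim = sim_config(),
                            scheme = fragmentation_scheme(),
                            ani = ani_config(), align = align_params(),
                            align_aa = align_params_protein(),
                            wgmlst_identity = 90, wgmlst_coverage = 80,
                            pan_identity = 40, pan_coverage = 50,
                            inflation = 1.5, n_perms = 100L,
                            alpha_margin = 0.02, run_fragsim = TRUE,
                            seed = 1L, verbose = TRUE) {
  mode <- match.arg(mode)
  if (mode == "genomes-dir") {
    gs_assert(!is.null(genomes_dir), "genomes-dir mode needs genomes_dir")
  }
  structure(list(mode = mode, genomes_dir = genomes_dir, sim = sim,
                 scheme = scheme, ani = ani, align = align,
                 align_aa = align_aa,
                 wgmlst_identity = wgmlst_identity,
                 wgmlst_coverage = wgmlst_coverage,
                 pan_identity = pan_identity, pan_coverage = pan_coverage,
                 inflation = inflation, n_perms = as.integer(n_perms),
                 alpha_margin = alpha_margin,
                 run_fragsim = isTRUE(run_fragsim),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config(
    mode = x$mode, genomes_dir = x$genomes_dir,
    sim = do.call(sim_config, x$sim[names(x$sim) != "class"]),
    scheme = do.call(fragmentation_scheme, as.list(x$scheme)),
    ani = do.call(ani_config, as.list(x$ani)),
    align = do.call(align_params, as.list(x$align)),
    align_aa = do.call(align_params, as.list(x$align_aa)),
    wgmlst_identity = x$wgmlst_identity, wgmlst_coverage = x$wgmlst_coverage,
    pan_identity = x$pan_identity, pan_coverage = x$pan_coverage,
    inflation = x$inflation, n_perms = x$n_perms,
    alpha_margin = x$alpha_margin, run_fragsim = x$run_fragsim,
    seed = x$seed, verbose = x$verbose)
  cfg
}

#' @noRd
stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[genospecies] ", fmt), ...))
}

#' Run the full genospecies-delineation pipeline
#'
#' Simulates (or ingests) a cohort and runs cohort statistics, fragmented
#' similarity, ANI + single-linkage clustering, wgMLST profiling with a UPGMA
#' dendrogram, protein-graph pangenomics with MCL, permutation development
#' curves with Heap's and decay fits, and the combined ANI + alpha species
#' verdicts. Stage artifacts (TSV/JSON/newick/nexus) are written under
#' `out_dir` with an md5 manifest; an identical config and seed reproduces
#' byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return the genospecies report (list), invisibly also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("gsrun")) {
  gs_assert(inherits(config, "pipeline_config"), "expected a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  report <- list(seed = config$seed)
  artifacts <- character(0)
  emit <- function(writer, file) {
    path <- file.path(out_dir, file)
    writer(path)
    artifacts <<- c(artifacts, path)
    path
  }

  # --- cohort -----------------------------------------------------------
  truth <- NULL; genes <- NULL; proteins <- NULL
  if (config$mode == "simulate") {
    stage_log(config$verbose, "simulating cohort (seed %d)", config$seed)
    simcfg <- config$sim
    simcfg$seed <- derive_seed(config$seed, 1L)
    sim <- simulate_cohort(simcfg)
    write_cohort(sim, file.path(out_dir, "cohort"))
    genomes <- sim$genomes
    genes <- sim$genes; proteins <- sim$proteins; truth <- sim$truth
  } else {
    stage_log(config$verbose, "reading genomes from %s", config$genomes_dir)
    genomes <- read_cohort(config$genomes_dir)
    genes_dir <- file.path(dirname(config$genomes_dir), "genes")
    prot_dir <- file.path(dirname(config$genomes_dir), "proteins")
    if (dir.exists(genes_dir)) {
      genes <- lapply(read_cohort_files(genes_dir), identity)
    }
    if (dir.exists(prot_dir)) {
      proteins <- lapply(list.files(prot_dir, pattern = "\\.fa(a|sta)?$",
                                    full.names = TRUE),
                         read_fasta, type = "protein")
      names(proteins) <- sub("\\.fa(a|sta)?$", "",
                             basename(list.files(prot_dir,
                                                 pattern = "\\.fa(a|sta)?$")))
    }
  }
  gs_assert(length(genomes) >= 2, "cohort must contain >= 2 genomes")

  stats <- cohort_summary_genomes(genomes)
  report$cohort <- stats
  emit(function(p) write.table(stats$per_strain, p, sep = "\t", quote = FALSE,
                               row.names = FALSE), "cohort_stats.tsv")

  # --- fragmented similarity -------------------------------------------
  if (config$run_fragsim) {
    stage_log(config$verbose, "fragmented similarity (%d genomes)", length(genomes))
    fs <- similarity_matrix(genomes, config$scheme, config$align)
    emit(function(p) write_matrix_tsv(fs$similarity, p), "fragsim_similarity.tsv")
    emit(function(p) export_nexus_distances(fs$distance, p), "fragsim_distance.nex")
    report$fragsim <- list(similarity = fs$similarity, distance = fs$distance)
  }

  # --- ANI + clustering -------------------------------------------------
  stage_log(config$verbose, "ANI matrix")
  ani <- ani_matrix(genomes, config$ani, config$align)
  emit(function(p) write_matrix_tsv(ani, p), "ani.tsv")
  assignment <- single_linkage_clusters(ani, config$ani$cutoff)
  emit(function(p) jsonlite::write_json(
    list(clusters = assignment$clusters, singletons = assignment$singletons,
         cutoff = assignment$cutoff), p, auto_unbox = TRUE, digits = NA),
    "clusters.json")
  report$ani <- ani
  report$clusters <- assignment

  # --- wgMLST -----------------------------------------------------------
  if (!is.null(genes)) {
    stage_log(config$verbose, "wgMLST profiling (%d strains)", length(genes))
    wg <- wgmlst_profiles(genes, config$wgmlst_identity, config$wgmlst_coverage,
                          config$align)
    prof_chr <- wg$profiles
    emit(function(p) {
      df <- data.frame(strain_id = rownames(prof_chr), prof_chr,
                       check.names = FALSE)
      df[is.na(df)] <- "-"
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, "wgmlst_profiles.tsv")
    D <- profile_distance_matrix(wg$profiles)
    emit(function(p) write_matrix_tsv(D, p), "wgmlst_distance.tsv")
    tree <- upgma(D)
    emit(function(p) ape::write.tree(tree, p), "wgmlst_upgma.nwk")
    report$wgmlst <- list(n_loci = ncol(wg$profiles), distance = D, tree = tree)
  }

  # --- pangenome --------------------------------------------------------
  if (!is.null(proteins)) {
    stage_log(config$verbose, "pangenome graph + MCL")
    graph <- build_graph(proteins, config$align_aa, config$pan_identity,
                         config$pan_coverage)
    fams <- mcl(graph, config$inflation)
    emit(function(p) write.table(fams$membership, p, sep = "\t", quote = FALSE,
                                 row.names = FALSE), "families.tsv")
    emit(function(p) write_matrix_tsv(fams$presence + 0, p), "presence.tsv")
    global_subs <- subsets(fams)
    per_cluster_subs <- lapply(report$clusters$clusters, function(members) {
      subP <- fams$presence[members, , drop = FALSE]
      subP <- subP[, colSums(subP) > 0, drop = FALSE]
      mem <- fams$membership[fams$membership$strain_id %in% members, ]
      sub_f <- structure(list(membership = mem, presence = subP),
                         class = "gene_family_set")
      subsets(sub_f)
    })
    emit(function(p) jsonlite::write_json(
      list(global = unclass_subsets(global_subs),
           per_cluster = lapply(per_cluster_subs, unclass_subsets)),
      p, auto_unbox = TRUE, digits = NA), "subsets.json")
    report$pangenome <- list(families = fams, global = global_subs,
                             per_cluster = per_cluster_subs)

    # --- heaps + support ------------------------------------------------
    stage_log(config$verbose, "development curves and species support")
    curves <- lapply(c(pangenome = "pangenome", core = "core",
                       new_genes = "new_genes"), function(st) {
      permute_accumulate(fams$presence, st, config$n_perms,
                         derive_seed(config$seed, 2L))
    })
    emit(function(p) {
      rows <- do.call(rbind, lapply(names(curves), function(st) {
        cv <- curves[[st]]
        data.frame(statistic = st,
                   N = rep(cv$N, each = nrow(cv$samples)),
                   perm = rep(seq_len(nrow(cv$samples)), times = length(cv$N)),
                   value = as.vector(cv$samples))
      }))
      write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, "curves.tsv")
    heaps_fit_g <- fit_heaps(curves$pangenome)
    decay_core <- fit_decay(curves$core)
    decay_new <- fit_decay(curves$new_genes)
    support <- species_support(report$clusters, ani, fams$presence,
                               config$n_perms, derive_seed(config$seed, 3L),
                               config$ani$cutoff, config$alpha_margin)
    emit(function(p) jsonlite::write_json(
      list(heaps_global = unclass(heaps_fit_g),
           decay_core = unclass(decay_core),
           decay_new_genes = unclass(decay_new),
           support = support_as_list(support)),
      p, auto_unbox = TRUE, digits = NA), "fits.json")
    report$heaps <- list(curves = curves, heaps_global = heaps_fit_g,
                         decay_core = decay_core, decay_new = decay_new)
    report$support <- support
  }

  if (!is.null(truth)) report$truth <- truth

  # --- report + manifest ------------------------------------------------
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("genospecies")),
    seed = config$seed,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  emit(function(p) jsonlite::write_json(
    report_as_list(report), p, auto_unbox = TRUE, digits = NA), "report.json")
  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stage_log(config$verbose, "done in %.1f s -> %s",
            report$provenance$elapsed_sec, out_dir)
  invisible(report)
}

#' @noRd
unclass_subsets <- function(s) {
  s <- unclass(s)
  s$core_families <- NULL
  s$per_genome_unique <- as.list(s$per_genome_unique)
  s
}

#' @noRd
support_as_list <- function(s) {
  list(global = list(alpha = s$global$alpha,
                     core_fraction = s$global$core_fraction),
       clusters = lapply(s$clusters, function(cl) {
         list(n_genomes = cl$n_genomes, alpha = cl$alpha,
              min_intra_ani = cl$min_intra_ani,
              core_fraction = cl$core_fraction,
              verdict = cl$verdict, reasons = cl$reasons)
       }),
       margin = s$margin, ani_cutoff = s$ani_cutoff)
}

#' @noRd
report_as_list <- function(report) {
  out <- list(seed = report$seed,
              cohort = list(per_strain = report$cohort$per_strain,
                            aggregate = report$cohort$aggregate),
              provenance = report$provenance)
  if (!is.null(report$clusters)) {
    out$clusters <- list(clusters = report$clusters$clusters,
                         singletons = report$clusters$singletons,
                         cutoff = report$clusters$cutoff)
  }
  if (!is.null(report$ani)) out$ani_matrix <- as.data.frame(report$ani)
  if (!is.null(report$pangenome)) {
    out$pangenome <- list(global = unclass_subsets(report$pangenome$global),
                          per_cluster = lapply(report$pangenome$per_cluster,
                                               unclass_subsets))
  }
  if (!is.null(report$heaps)) {
    out$fits <- list(heaps_global = unclass(report$heaps$heaps_global),
                     decay_core = unclass(report$heaps$decay_core),
                     decay_new_genes = unclass(report$heaps$decay_new))
  }
  if (!is.null(report$support)) out$support <- support_as_list(report$support)
  if (!is.null(report$truth)) {
    out$truth <- list(clusters = as.list(report$truth$clusters))
  }
  out
}

#' @noRd
read_cohort_files <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta|ffn|fna)$",
                           full.names = TRUE))
  out <- lapply(files, read_fasta, type = "dna")
  names(out) <- sub("\\.(fa|fasta|ffn|fna)$", "", basename(files))
  out
}

#' Demo analysis on the packaged published tables
#'
#' Runs the stages computable from the printed fixtures alone: cohort
#' summary of the genome-feature table, single-linkage clustering of the
#' published ANI matrix at the 94% cutoff, and cluster-wise CDS means.
#'
#' @param cutoff ANI cutoff (percent).
#' @return list with `summary` (cohort aggregates), `assignment`
#'   (cluster assignment), `cluster_cds_means`, `ani_extrema`.
#' @export
fixtures_demo <- function(cutoff = 94) {
  t1 <- load_table1()
  t2 <- load_table2_ani()
  summ <- cohort_summary(data.frame(strain_id = t1$strain_id,
                                    length = t1$genome_length,
                                    gc = t1$gc_content,
                                    n_contigs = t1$sequences,
                                    n_cds = t1$patric_cds))
  assignment <- single_linkage_clusters(t2, cutoff)
  cds <- setNames(t1$patric_cds, t1$strain_id)
  cds_means <- vapply(assignment$clusters, function(members) {
    round_half_up(mean(cds[members]), 2)
  }, numeric(1))
  off <- t2[row(t2) != col(t2)]
  list(summary = summ, assignment = assignment,
       cluster_cds_means = cds_means,
       ani_extrema = c(min = min(off), max = max(off)))
}
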