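test_that("simulate_ancestor emits intact ORFs, deterministically", {
  cfg <- sim_config(core_genes = 10L, gene_len_mean = 300, seed = 5L)
  anc <- simulate_ancestor(cfg)
  expect_length(anc$genes, 10)
  expect_true(all(startsWith(anc$genes, "ATG")))
  expect_true(all(substring(anc$genes, nchar(anc$genes) - 2) %in%
                    c("TAA", "TAG", "TGA")))
  expect_true(all(nchar(anc$genes) %% 3 == 0))
  anc2 <- simulate_ancestor(cfg)
  expect_identical(anc, anc2)
})

test_that("mutate_seq hits the target rate and respects kappa", {
  expect_identical(mutate_seq("ACGTACGT", 0), "ACGTACGT")

  set.seed(2)
  s <- random_dna(20000)
  m <- mutate_seq(s, 0.05, kappa = 2)
  expect_equal(nchar(m), nchar(s))
  frac <- hamming_frac(s, m)
  sd3 <- 3 * sqrt(0.05 * 0.95 / 20000)
  expect_lt(abs(frac - 0.05), sd3)

  # kappa -> Inf limit: every difference is a transition
  m2 <- mutate_seq(s, 0.05, kappa = 1e9)
  x <- strsplit(s, "")[[1]]; y <- strsplit(m2, "")[[1]]
  d <- x != y
  pair <- paste0(pmin(x[d], y[d]), pmax(x[d], y[d]))
  expect_true(all(pair %in% c("AG", "CT")))
})

test_that("cohort divergence matches the stated within/between design", {
  sim <- simulate_cohort(small_sim_config(seed = 4, gene_loss_prob = 0))
  inv <- sim$truth$inventory
  core_fams <- sim$truth$core_families[1:10]
  pick <- function(strain, fam) {
    gid <- inv$gene_id[inv$strain_id == strain & inv$family_id == fam]
    as.character(sim$genes[[strain]][gid])
  }
  pair_div <- function(s1, s2) {
    mean(vapply(core_fams, function(f) hamming_frac(pick(s1, f), pick(s2, f)),
                numeric(1)))
  }
  within <- pair_div("cl1_s01", "cl1_s02")
  between <- pair_div("cl1_s01", "cl2_s01")
  solo <- pair_div("cl1_s01", "sg1_solo")
  # raw Hamming divergence: d_within and d_between, minus a small
  # double-hit collision term (substitutions are resampled independently)
  expect_lt(abs(within - 0.02), 0.005)
  expect_lt(abs(between - 0.13), 0.01)
  expect_lt(abs(solo - 0.13), 0.01)
})

test_that("loss-free, private-free cohorts are all-core; seeds reproduce bytes", {
  cfg <- small_sim_config(seed = 9, gene_loss_prob = 0, private_genes = 0,
                          cluster_accessory = 0L)
  sim <- simulate_cohort(cfg)
  invs <- split(sim$truth$inventory$family_id, sim$truth$inventory$strain_id)
  base <- sort(invs[[1]])
  for (iv in invs) expect_identical(sort(iv), base)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("emitted proteins translate without internal stops and start with M", {
  sim <- simulate_cohort(small_sim_config(seed = 12))
  for (s in names(sim$proteins)) {
    aa <- sim$proteins[[s]]
    expect_false(any(grepl("*", aa, fixed = TRUE)), info = s)
    expect_true(all(startsWith(aa, "M")), info = s)
  }
  # protein length = nt/3 - 1 (terminal stop removed)
  g1 <- sim$genes[[1]]; p1 <- sim$proteins[[1]]
  expect_identical(unname(nchar(p1)), unname(nchar(g1) %/% 3L - 1L))
})

test_that("genome length is the exact sum of its gene and spacer parts", {
  cfg <- small_sim_config(seed = 15, gene_loss_prob = 0, private_genes = 0)
  sim <- simulate_cohort(cfg)
  for (s in names(sim$genomes)[1:2]) {
    glen <- sum(nchar(sim$genomes[[s]]$contigs))
    genes_len <- sum(nchar(sim$genes[[s]]))
    expect_gt(glen, genes_len) # spacers present
    # every gene occurs verbatim in the genome
    genome <- paste(sim$genomes[[s]]$contigs, collapse = "")
    for (g in sim$genes[[s]][1:5]) expect_true(grepl(g, genome, fixed = TRUE))
  }
})

test_that("contig splitting emulates draft assemblies without losing sequence", {
  cfg <- small_sim_config(seed = 18, contigs_per_genome = 5L)
  sim <- simulate_cohort(cfg)
  expect_true(all(vapply(sim$genomes, function(g) length(g$contigs),
                         integer(1)) == 5L))
  cfg1 <- small_sim_config(seed = 18, contigs_per_genome = 1L)
  sim1 <- simulate_cohort(cfg1)
  expect_identical(paste(sim$genomes[[1]]$contigs, collapse = ""),
                   sim1$genomes[[1]]$contigs[[1]])
})
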