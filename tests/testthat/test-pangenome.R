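test_that("similarity graph: perfect matches, no chance edges, permutation-stable", {
  set.seed(90)
  prot <- setNames(vapply(rep(120, 6), random_protein, character(1)),
                   sprintf("p%d", 1:6))
  g <- build_graph(list(s1 = prot, s2 = prot))
  expect_equal(nrow(g$edges), 6)
  expect_true(all(abs(g$edges$weight - 100) < 1e-9))

  rand <- list(s1 = setNames(vapply(rep(100, 4), random_protein, character(1)),
                             paste0("a", 1:4)),
               s2 = setNames(vapply(rep(100, 4), random_protein, character(1)),
                             paste0("b", 1:4)))
  g2 <- build_graph(rand)
  expect_equal(nrow(g2$edges), 0)

  # edge count invariant under strain-order permutation
  g3 <- build_graph(list(s2 = prot, s1 = prot))
  expect_equal(nrow(g3$edges), nrow(g$edges))

  expect_warning(build_graph(list(s1 = prot, s2 = character(0))), "no proteins")
})

test_that("MCL on disconnected cliques returns the connected components", {
  # two 4-cliques, no bridging edge
  nodes <- data.frame(node = 1:8,
                      strain_id = rep(c("s1", "s2"), 4),
                      gene_id = paste0("g", 1:8),
                      seq = "", stringsAsFactors = FALSE)
  cl <- function(members) {
    t(combn(members, 2))
  }
  e <- rbind(cl(1:4), cl(5:8))
  graph <- structure(list(nodes = nodes,
                          edges = data.frame(from = e[, 1], to = e[, 2],
                                             weight = 100),
                          strains = c("s1", "s2")),
                     class = "similarity_graph")
  fam <- mcl(graph)
  expect_equal(length(unique(fam$membership$family_id)), 2)
  expect_length(unique(fam$membership$family_id[1:4]), 1)
  expect_length(unique(fam$membership$family_id[5:8]), 1)

  # a single weak bridge (1 vs 100) still yields 2 families at inflation 1.5
  graph$edges <- rbind(graph$edges, data.frame(from = 4, to = 5, weight = 1))
  fam2 <- mcl(graph, inflation = 1.5)
  expect_equal(length(unique(fam2$membership$family_id)), 2)

  # isolated node is its own family
  solo <- structure(list(nodes = nodes[1, ],
                         edges = data.frame(from = integer(0), to = integer(0),
                                            weight = numeric(0)),
                         strains = "s1"),
                    class = "similarity_graph")
  fam3 <- mcl(solo)
  expect_equal(nrow(fam3$membership), 1)
})

test_that("families partition genes and family count is monotone in inflation", {
  sim <- simulate_cohort(small_sim_config(seed = 41))
  graph <- build_graph(sim$proteins)
  fam <- mcl(graph)
  expect_equal(nrow(fam$membership), nrow(graph$nodes))
  expect_false(anyDuplicated(fam$membership$gene_id) > 0)

  counts <- vapply(c(1.2, 1.5, 2, 4), function(infl) {
    length(unique(mcl(graph, inflation = infl)$membership$family_id))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("pangenome subsets: trivial cases and truth recovery", {
  # 2 identical genomes: all families core, no singletons
  mem <- data.frame(family_id = rep(c("f1", "f2"), 2),
                    strain_id = rep(c("s1", "s2"), each = 2),
                    gene_id = paste0("g", 1:4))
  fam <- structure(list(membership = mem, presence = presence_matrix(mem)),
                   class = "gene_family_set")
  ss <- subsets(fam)
  expect_equal(ss$core, 2)
  expect_equal(ss$singleton_families, 0)
  expect_equal(ss$pangenome_size, 2)
  expect_equal(ss$core + ss$shell + ss$singleton_families, ss$pangenome_size)

  # 3 genomes sharing nothing: pangenome = sum of counts, core 0
  mem2 <- data.frame(family_id = paste0("f", 1:6),
                     strain_id = rep(c("s1", "s2", "s3"), each = 2),
                     gene_id = paste0("g", 1:6))
  fam2 <- structure(list(membership = mem2, presence = presence_matrix(mem2)),
                    class = "gene_family_set")
  ss2 <- subsets(fam2)
  expect_equal(ss2$pangenome_size, 6)
  expect_equal(ss2$core, 0)
  expect_equal(ss2$singleton_families, 6)
  expect_equal(ss2$per_genome_unique, c(s1 = 2L, s2 = 2L, s3 = 2L))

  # loss-free simulated cohort: core family count within 2% of truth
  sim <- simulate_cohort(small_sim_config(seed = 43, gene_loss_prob = 0))
  fam3 <- mcl(build_graph(sim$proteins))
  ss3 <- subsets(fam3)
  truth_core <- length(sim$truth$core_families)
  expect_lte(abs(ss3$core - truth_core) / truth_core, 0.02)
  # merging in a copy of an existing genome never decreases the core
  prot_plus <- c(sim$proteins,
                 list(clone = setNames(sim$proteins[[1]],
                                       sub("^[^|]*", "clone",
                                           names(sim$proteins[[1]])))))
  ss4 <- subsets(mcl(build_graph(prot_plus)))
  expect_gte(ss4$core, ss3$core)
})
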