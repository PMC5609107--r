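test_that("locus database construction: founding, joining, determinism", {
  set.seed(70)
  g <- paste0("ATG", random_dna(297))
  db <- build_locus_db(list(s1 = c(x = g), s2 = c(y = g), s3 = c(z = g)))
  expect_length(db$representatives, 1)
  expect_length(db$alleles[[1]], 1)

  # two unrelated genes (~25% chance identity) found two loci
  db2 <- build_locus_db(list(s1 = c(x = random_dna(300)),
                             s2 = c(y = random_dna(300))))
  expect_length(db2$representatives, 2)

  expect_error(build_locus_db(list(s1 = character(0))), "at least one")
})

test_that("locus count tracks the truth family count on a simulated cohort", {
  # divergence kept below the 90% identity filter so homologs join one locus
  # (at the default d_between = 0.13 cross-cluster homologs legitimately
  # split into per-lineage loci, which is the filter working as specified)
  sim <- simulate_cohort(small_sim_config(seed = 31, gene_loss_prob = 0,
                                          d_within = 0.002, d_between = 0.05))
  db <- build_locus_db(sim$genes)
  truth_n <- length(unique(sim$truth$inventory$family_id))
  expect_lte(abs(length(db$representatives) - truth_n) / truth_n, 0.02)
})

test_that("allele calling: thresholds, registry reuse, missing loci", {
  set.seed(75)
  reps <- setNames(vapply(rep(300, 5), function(n) paste0("ATG", random_dna(n - 3)),
                          character(1)), sprintf("g%d", 1:5))
  db <- build_locus_db(list(ref = reps))
  expect_length(db$representatives, 5)

  # exact representatives -> every locus called as allele 1
  res <- call_alleles(reps, db, "ref")
  expect_true(all(res$profile == 1))

  # a gene at ~82% identity to its locus stays below the 90% filter -> missing
  far <- reps
  far[[1]] <- local({
    x <- strsplit(reps[[1]], "")[[1]]
    k <- sample(seq_along(x), 54)
    x[k] <- vapply(x[k], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1))
    paste(x, collapse = "")
  })
  res2 <- call_alleles(far, db, "far")
  expect_true(is.na(res2$profile[1]))
  expect_true(all(!is.na(res2$profile[-1])))

  # the same novel variant in two strains gets one allele number
  variant <- reps
  v <- strsplit(reps[[2]], "")[[1]]
  v[10] <- setdiff(c("A", "C", "G", "T"), v[10])[1]
  variant[[2]] <- paste(v, collapse = "")
  r1 <- call_alleles(variant, db, "s1")
  r2 <- call_alleles(variant, r1$db, "s2")
  expect_identical(r1$profile[2], r2$profile[2])
  expect_gt(r1$profile[2], 1)
})

test_that("self-call on a loss-free cohort leaves no locus missing", {
  # all-core, low-divergence cohort: every strain carries a homolog of every
  # locus above the 90%/80% filters, so nothing can be missing, and
  # within-cluster strains still share most alleles while cross-cluster
  # alleles essentially always differ
  sim <- simulate_cohort(small_sim_config(seed = 35, gene_loss_prob = 0,
                                          cluster_accessory = 0L,
                                          private_genes = 0,
                                          d_within = 0.002, d_between = 0.05))
  wg <- wgmlst_profiles(sim$genes)
  expect_false(anyNA(wg$profiles))
  # profiles separate clusters
  D <- profile_distance_matrix(wg$profiles)
  lab <- sim$truth$clusters[rownames(D)]
  ids <- rownames(D)
  within <- c(); between <- c()
  for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    same <- lab[i] != "singleton" && lab[i] == lab[j]
    if (same) within <- c(within, D[i, j]) else between <- c(between, D[i, j])
  }
  expect_gt(min(between), max(within))
  expect_lt(max(within), 0.9)
})

test_that("profile distance arithmetic and pseudo-metric properties", {
  p <- setNames(c(1L, 2L, 1L, NA, 3L), paste0("l", 1:5))
  expect_equal(profile_distance(p, p), 0)

  q <- p; q[c(1, 2)] <- c(5L, 6L)
  expect_equal(profile_distance(p, q), 2 / 4)

  # 10 shared loci, 4 differing -> 0.4
  a <- setNames(rep(1L, 10), paste0("l", 1:10))
  b <- a; b[1:4] <- 2L
  expect_equal(profile_distance(a, b), 0.4)

  # missing handling
  c1 <- a; c1[1] <- NA
  expect_equal(profile_distance(a, c1), 0)
  expect_equal(profile_distance(a, c1, missing_as_diff = TRUE), 1 / 10)
  expect_warning(
    expect_true(is.na(profile_distance(setNames(NA_integer_, "l1"),
                                       setNames(1L, "l1")))),
    "undefined")
  expect_error(profile_distance(a, setNames(rep(1L, 10), paste0("m", 1:10))),
               "locus set")

  # pseudo-metric on sampled full profiles
  set.seed(80)
  profs <- replicate(6, setNames(sample(1:3, 12, TRUE), paste0("l", 1:12)),
                     simplify = FALSE)
  for (k in 1:10) {
    tri <- sample(6, 3)
    dxy <- profile_distance(profs[[tri[1]]], profs[[tri[2]]])
    dyz <- profile_distance(profs[[tri[2]]], profs[[tri[3]]])
    dxz <- profile_distance(profs[[tri[1]]], profs[[tri[3]]])
    expect_equal(dxy, profile_distance(profs[[tri[2]]], profs[[tri[1]]]))
    expect_lte(dxz, dxy + dyz + 1e-12)
  }
})

test_that("UPGMA reproduces the hand-computed merges and is ultrametric", {
  ids <- c("A", "B", "C")
  D <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3, dimnames = list(ids, ids))
  tr <- upgma(D)
  cp <- ape::cophenetic.phylo(tr)
  # ((A:1,B:1):3,C:4)
  expect_equal(cp["A", "B"], 2)
  expect_equal(cp["A", "C"], 8)
  expect_equal(cp["B", "C"], 8)
  depths <- ape::node.depth.edgelength(tr)
  leaf_depths <- depths[seq_along(tr$tip.label)]
  expect_lt(diff(range(leaf_depths)), 1e-9)
  expect_equal(max(leaf_depths), 4)

  # 2 taxa at distance 6 -> (A:3,B:3)
  D2 <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- upgma(D2)
  expect_equal(sort(tr2$edge.length), c(3, 3))

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2,
                            dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("UPGMA reconstructs a random ultrametric matrix exactly", {
  set.seed(85)
  for (rep in 1:3) {
    pts <- matrix(rnorm(8 * 4), 8)
    rownames(pts) <- sprintf("t%02d", 1:8)
    hc <- hclust(dist(pts), method = "average")
    UM <- as.matrix(ape::cophenetic.phylo(ape::as.phylo(hc))) # ultrametric
    tr <- upgma(UM)
    got <- as.matrix(ape::cophenetic.phylo(tr))[rownames(UM), colnames(UM)]
    expect_equal(got, UM, tolerance = 1e-9)
    depths <- ape::node.depth.edgelength(tr)
    expect_lt(diff(range(depths[seq_along(tr$tip.label)])), 1e-9)
  }
})
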