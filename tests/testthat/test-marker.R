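test_that("K2P pair: identity, constructed proportions, saturation", {
  s <- "ACGTACGTAC"
  r <- k2p_pair(s, s)
  expect_equal(r$P, 0)
  expect_equal(r$Q, 0)
  expect_equal(r$d, 0)

  # exactly 100 transitions and 50 transversions over 1000 sites:
  # d = -1/2 ln(0.75 * sqrt(0.9)), evaluated independently
  set.seed(110)
  a <- strsplit(random_dna(1000), "")[[1]]
  b <- a
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", C = "A", G = "T", T = "G")
  pos <- sample(1000, 150)
  b[pos[1:100]] <- ts_map[a[pos[1:100]]]
  b[pos[101:150]] <- tv_map[a[pos[101:150]]]
  r2 <- k2p_pair(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(r2$P, 0.1)
  expect_equal(r2$Q, 0.05)
  expect_equal(r2$d, -0.5 * log(0.75 * sqrt(0.9)), tolerance = 1e-12)
  expect_equal(r2$d, 0.1701812, tolerance = 1e-5)

  # P = 0.5, Q = 0: log-domain boundary
  a3 <- rep(c("A", "C"), 500)
  b3 <- a3; b3[seq(1, 1000, 2)] <- "G" # all A -> G transitions: P = 0.5
  expect_error(k2p_pair(paste(a3, collapse = ""), paste(b3, collapse = "")),
               "saturated")
})

test_that("K2P agrees with independent recounts and the small-distance limit", {
  set.seed(115)
  for (i in 1:20) {
    a <- random_dna(400)
    b <- mutate_seq(a, runif(1, 0.01, 0.2), kappa = 2)
    got <- k2p_pair(a, b)
    want <- k2p_counts_oracle(a, b)
    expect_equal(got$P, want$P)
    expect_equal(got$Q, want$Q)
    expect_equal(got$sites_used, want$n)
  }

  # first-order limit: d ~ P + Q at tiny distances
  a <- strsplit(random_dna(10000), "")[[1]]
  b <- a
  b[1:10] <- c(G = "A", A = "G", C = "T", T = "C")[a[1:10]]   # transitions
  b[11:20] <- c(A = "C", C = "A", G = "T", T = "G")[a[11:20]] # transversions
  r <- k2p_pair(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_lt(abs(r$d - (r$P + r$Q)) / (r$P + r$Q), 0.01)

  # monotone in P at fixed Q
  dd <- vapply(c(50, 100, 150), function(nts) {
    bb <- a
    bb[1:nts] <- c(G = "A", A = "G", C = "T", T = "C")[a[1:nts]]
    k2p_pair(paste(a, collapse = ""), paste(bb, collapse = ""))$d
  }, numeric(1))
  expect_true(all(diff(dd) > 0))
})

test_that("k2p_matrix applies set-wide complete deletion and matches ape", {
  seqs <- c(x = "ACGTAC-TAC",
            y = "ACGTACGTAC",
            z = "ACNTACGTAT")
  # columns 3 (N), 7 (-) removed everywhere; identical over kept columns
  # except x/y vs z at the final column
  D <- k2p_matrix(seqs)
  expect_equal(D["x", "y"], 0)
  expect_gt(D["x", "z"], 0)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))

  set.seed(120)
  base <- random_dna(300)
  seqs2 <- vapply(1:4, function(i) {
    s <- strsplit(mutate_seq(base, 0.08, kappa = 2), "")[[1]]
    s[sample(300, 8)] <- "-"
    paste(s, collapse = "")
  }, character(1))
  names(seqs2) <- paste0("t", 1:4)
  mat <- do.call(rbind, strsplit(seqs2, ""))
  rownames(mat) <- names(seqs2)
  got <- k2p_matrix(seqs2)
  bin <- ape::as.DNAbin(mat)
  want <- as.matrix(ape::dist.dna(bin, model = "K80",
                                  pairwise.deletion = FALSE))
  expect_equal(got, want[rownames(got), colnames(got)], tolerance = 1e-9)

  expect_error(k2p_matrix(c(a = "----", b = "ACGT")), "every column")
})

test_that("NJ recovers additive trees exactly", {
  # ((A:1,B:2):1,(C:3,D:4)) path metric
  ids <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(ids, ids))
  tr <- nj_tree(D)
  got <- as.matrix(ape::cophenetic.phylo(tr))[ids, ids]
  expect_equal(got, D, tolerance = 1e-9)

  # 3-taxon closed form: a = (dAB + dAC - dBC)/2, etc.
  ids3 <- c("A", "B", "C")
  D3 <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
               dimnames = list(ids3, ids3))
  tr3 <- nj_tree(D3)
  lens <- setNames(tr3$edge.length[match(seq_along(ids3),
                                         tr3$edge[, 2])],
                   tr3$tip.label)
  expect_equal(unname(lens["A"]), (5 + 9 - 8) / 2)
  expect_equal(unname(lens["B"]), (5 + 8 - 9) / 2)
  expect_equal(unname(lens["C"]), (9 + 8 - 5) / 2)

  expect_error(nj_tree(D3[1:2, 1:2]), ">= 3 taxa")
})

test_that("NJ on ultrametric input matches the UPGMA topology", {
  set.seed(125)
  pts <- matrix(rnorm(6 * 3), 6)
  rownames(pts) <- paste0("t", 1:6)
  hc <- hclust(dist(pts), method = "average")
  UM <- as.matrix(ape::cophenetic.phylo(ape::as.phylo(hc)))
  t_upgma <- upgma(UM)
  t_nj <- nj_tree(UM)
  expect_equal(ape::dist.topo(ape::unroot(t_upgma), t_nj),
               structure(0, names = "PH85"), ignore_attr = TRUE)
})
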