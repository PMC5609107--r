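test_that("development curves: trivial, exhaustive and deterministic cases", {
  # 2 identical genomes: flat pangenome, zero new genes at N=2
  P <- matrix(TRUE, 2, 5, dimnames = list(c("a", "b"), paste0("f", 1:5)))
  cv <- permute_accumulate(P, "pangenome")
  expect_true(all(cv$samples == 5))
  nv <- permute_accumulate(P, "new_genes")
  expect_true(all(nv$samples[, 2] == 0))

  # disjoint families of sizes 2, 3, 4: exhaustive over 3! orders
  mem <- data.frame(family_id = paste0("f", 1:9),
                    strain_id = rep(c("a", "b", "c"), times = c(2, 3, 4)),
                    gene_id = paste0("g", 1:9))
  P2 <- presence_matrix(mem)
  cv2 <- permute_accumulate(P2, "pangenome", n_perms = 100)
  expect_true(cv2$exhaustive)
  expect_equal(nrow(cv2$samples), 6)
  expect_equal(cv2$mean[1], 3)       # (2+3+4)/3
  expect_equal(cv2$mean[3], 9)
  expect_equal(cv2$median[1], 3)

  # same seed -> identical samples (sampled regime)
  P3 <- matrix(runif(7 * 30) > 0.5, 7,
               dimnames = list(paste0("s", 1:7), paste0("f", 1:30)))
  c1 <- permute_accumulate(P3, "pangenome", n_perms = 20, seed = 5)
  c2 <- permute_accumulate(P3, "pangenome", n_perms = 20, seed = 5)
  expect_identical(c1$samples, c2$samples)
})

test_that("curve monotonicity and conservation of discovery", {
  set.seed(95)
  P <- matrix(runif(6 * 40) > 0.4, 6,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:40)))
  P <- P[, colSums(P) > 0]
  pan <- permute_accumulate(P, "pangenome", n_perms = 50, seed = 2)
  core <- permute_accumulate(P, "core", n_perms = 50, seed = 2)
  expect_true(all(diff(pan$median) >= 0))
  expect_true(all(diff(core$median) <= 0))

  # exhaustive: sum over N of mean new genes = mean pangenome at N = G
  P4 <- P[1:4, , drop = FALSE]
  P4 <- P4[, colSums(P4) > 0]
  newc <- permute_accumulate(P4, "new_genes", n_perms = 1000)
  panc <- permute_accumulate(P4, "pangenome", n_perms = 1000)
  expect_true(newc$exhaustive)
  expect_equal(sum(newc$mean), panc$mean[4])
})

test_that("fit_heaps recovers exact power laws and classifies openness", {
  G <- 10
  curve <- structure(list(statistic = "pangenome", N = 1:G,
                          samples = matrix(1000 * (1:G)^0.4, 1),
                          median = 1000 * (1:G)^0.4,
                          mean = 1000 * (1:G)^0.4,
                          n_perms = 1, exhaustive = TRUE, seed = 1L),
                     class = "development_curve")
  fit <- fit_heaps(curve)
  expect_equal(fit$gamma, 0.4, tolerance = 1e-9)
  expect_equal(fit$alpha, 0.6, tolerance = 1e-9)
  expect_equal(fit$alpha + fit$gamma, 1)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$k, 1000, tolerance = 1e-6)
  expect_true(fit$open)

  # constant curve: gamma 0, alpha 1, open at the boundary
  cc <- curve; cc$median <- rep(500, G); cc$mean <- cc$median
  fitc <- fit_heaps(cc)
  expect_equal(fitc$gamma, 0)
  expect_equal(fitc$alpha, 1)
  expect_true(fitc$open)

  # shrinking "pangenome" (gamma < 0) classifies closed
  dec <- curve; dec$median <- 1000 * (1:G)^-0.2; dec$mean <- dec$median
  expect_false(fit_heaps(dec)$open)

  expect_error(fit_heaps(structure(list(statistic = "core"),
                                   class = "development_curve")), "pangenome")
})

test_that("fit_decay recovers exact exponentials and handles constants", {
  x <- 1:12
  y <- 200 * exp(-x / 3) + 1400
  curve <- structure(list(statistic = "core", N = x,
                          samples = matrix(y, 1), median = y, mean = y,
                          n_perms = 1, exhaustive = TRUE, seed = 1L),
                     class = "development_curve")
  fit <- fit_decay(curve)
  expect_lt(abs(fit$tg_theta - 1400), 1)
  expect_lt(abs(fit$t - 3), 0.05)
  expect_lt(abs(fit$k - 200) / 200, 0.01)

  cc <- curve; cc$mean <- rep(1500, 12)
  fitc <- fit_decay(cc)
  expect_equal(fitc$tg_theta, 1500)
  expect_lt(abs(fitc$k), 1e-6)

  # recovery within 1% on a noiseless new-genes-style curve
  y2 <- 900 * exp(-x / 1.7) + 60
  c2 <- curve; c2$statistic <- "new_genes"; c2$mean <- y2
  f2 <- fit_decay(c2)
  expect_lt(abs(f2$tg_theta - 60) / 60, 0.01)
  expect_lt(abs(f2$t - 1.7) / 1.7, 0.01)
})

test_that("species support applies the alpha margin and ANI rules", {
  # clones arbitrarily split into two "clusters": alpha contrast is absent
  set.seed(99)
  fams <- paste0("f", 1:40)
  P <- matrix(TRUE, 6, 40, dimnames = list(paste0("s", 1:6), fams))
  ani <- matrix(99, 6, 6, dimnames = list(rownames(P), rownames(P)))
  diag(ani) <- 100
  fake <- structure(list(
    clusters = list(A = c("s1", "s2", "s3"), B = c("s4", "s5", "s6")),
    singletons = character(0), cutoff = 94, method = "single"),
    class = "cluster_assignment")
  sup <- species_support(fake, ani, P, n_perms = 50, seed = 1)
  for (cl in sup$clusters) {
    expect_identical(cl$verdict, "not-supported")
    expect_true(any(grepl("alpha", cl$reasons)))
  }

  # a cluster with one pair below the cutoff fails with an ANI reason
  set.seed(100)
  P2 <- matrix(runif(6 * 40) > 0.3, 6, dimnames = dimnames(P))
  ani2 <- ani
  ani2["s1", "s2"] <- ani2["s2", "s1"] <- 90
  sup2 <- species_support(fake, ani2, P2, n_perms = 50, seed = 1)
  expect_identical(sup2$clusters$A$verdict, "not-supported")
  expect_true(any(grepl("ANI", sup2$clusters$A$reasons)))

  # clusters under 3 genomes are insufficient
  fake2 <- fake; fake2$clusters$A <- c("s1", "s2")
  sup3 <- species_support(fake2, ani, P, n_perms = 20, seed = 1)
  expect_identical(sup3$clusters$A$verdict, "insufficient")
})
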