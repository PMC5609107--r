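# Independent oracles and tiny fixture builders shared across the suite.
# Everything here is deliberately naive/brute-force so it stays independent
# of the package's own implementations.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), n,
               replace = TRUE), collapse = "")
}

# Full affine-gap local alignment score by straightforward dynamic
# programming (Gotoh recurrences, O(nm) loops, no traceback).
sw_score_oracle <- function(q, s, match = 1, mismatch = -1, go = -2, ge = -1) {
  qq <- strsplit(q, "")[[1]]
  ss <- strsplit(s, "")[[1]]
  n <- length(qq); m <- length(ss)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + go, E[i, j - 1] + ge)
      F[i, j] <- max(H[i - 1, j] + go, F[i - 1, j] + ge)
      sc <- if (qq[i - 1] == ss[j - 1] && qq[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

revcomp_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# Hamming difference fraction between equal-length strings
hamming_frac <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  mean(x != y)
}

# Adjusted Rand index from two label vectors (standard contingency formula)
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Small, fast simulator configuration for module-level tests; any field can
# be overridden through ...
small_sim_config <- function(seed = 1L, ...) {
  args <- list(n_clusters = 2L, genomes_per_cluster = 3L, n_singletons = 1L,
               core_genes = 25L, cluster_accessory = 8L, private_genes = 3,
               gene_len_mean = 300, gene_len_sd = 45, intergenic_len = 40,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# K2P transition/transversion recount with an independent site classifier
k2p_counts_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  pair <- paste0(pmin(x, y), pmax(x, y))
  list(P = mean(pair %in% c("AG", "CT")),
       Q = mean(!(pair %in% c("AG", "CT")) & x != y),
       n = length(x))
}
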