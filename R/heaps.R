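#' Permutation-based pangenome development curves
#'
#' For seeded permutations of the genome order and every prefix length `N`,
#' computes one of: `pangenome` (families present in at least one of the
#' first `N` genomes), `core` (families present in all of them) or
#' `new_genes` (families first contributed by genome `N`). When `G!` does not
#' exceed `n_perms` the permutations are enumerated exhaustively instead of
#' sampled.
#'
#' @param presence genomes x families logical matrix.
#' @param statistic `"pangenome"`, `"core"` or `"new_genes"`.
#' @param n_perms number of permutations (>= 1).
#' @param seed RNG seed for the sampled case.
#' @return object of class `development_curve`: list with `statistic`, `N`
#'   (1..G), `samples` (permutations x G matrix), `median`, `mean`,
#'   `n_perms` (actually used), `exhaustive`, `seed`.
#' @export
permute_accumulate <- function(presence, statistic = c("pangenome", "core", "new_genes"),
                               n_perms = 100L, seed = 1L) {
  statistic <- match.arg(statistic)
  gs_assert(is.matrix(presence) && nrow(presence) >= 2,
            "presence matrix needs >= 2 genomes")
  gs_assert(n_perms >= 1, "n_perms must be >= 1")
  P <- presence != 0
  G <- nrow(P)
  exhaustive <- factorial(G) <= n_perms
  if (exhaustive) {
    perms <- all_permutations(G)
  } else {
    set.seed(seed)
    perms <- t(vapply(seq_len(n_perms), function(i) sample.int(G), integer(G)))
  }
  samples <- t(apply(perms, 1, function(ord) {
    seen <- rep(FALSE, ncol(P))
    inall <- rep(TRUE, ncol(P))
    out <- numeric(G)
    for (k in seq_len(G)) {
      row <- P[ord[k], ]
      newf <- sum(row & !seen)
      seen <- seen | row
      inall <- inall & row
      out[k] <- switch(statistic,
                       pangenome = sum(seen),
                       core = sum(inall),
                       new_genes = newf)
    }
    out
  }))
  structure(list(statistic = statistic, N = seq_len(G), samples = samples,
                 median = apply(samples, 2, median),
                 mean = colMeans(samples),
                 n_perms = nrow(perms), exhaustive = exhaustive,
                 seed = as.integer(seed)),
            class = "development_curve")
}

#' @noRd
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Heap's-law fit of a pangenome development curve
#'
#' Ordinary least squares of `log(median)` on `log(N)` (the power law
#' `n = k * N^gamma` on log-log axes); `alpha = 1 - gamma`. An alpha of at
#' most 1 classifies the pangenome as open (each added genome still
#' contributes new families); alpha > 1 as closed. Medians are used for
#' robustness to permutation outliers.
#'
#' @param curve a `development_curve` with statistic `"pangenome"`.
#' @param include_n1 include the `N = 1` point (flag because its treatment in
#'   published fits is unstated).
#' @return object of class `heaps_fit`: list with `k`, `gamma`, `alpha`
#'   (= 1 - gamma exactly), `r2`, `open` (alpha <= 1), `n_points`.
#' @export
fit_heaps <- function(curve, include_n1 = TRUE) {
  gs_assert(inherits(curve, "development_curve") && curve$statistic == "pangenome",
            "expected a pangenome development_curve")
  N <- curve$N
  y <- curve$median
  if (!include_n1) { y <- y[N >= 2]; N <- N[N >= 2] }
  gs_assert(length(unique(N)) >= 3, "need >= 3 distinct N")
  gs_assert(all(y > 0), "non-positive medians; cannot fit log-log")
  lx <- log(N); ly <- log(y)
  if (stats::var(ly) < 1e-24) {
    fit <- list(k = exp(mean(ly)), gamma = 0, r2 = 1)
  } else {
    m <- lm(ly ~ lx)
    sst <- sum((ly - mean(ly))^2)
    r2 <- 1 - sum(residuals(m)^2) / sst # avoids summary.lm's perfect-fit warning
    fit <- list(k = exp(unname(coef(m)[1])), gamma = unname(coef(m)[2]),
                r2 = r2)
  }
  structure(list(k = fit$k, gamma = fit$gamma, alpha = 1 - fit$gamma,
                 r2 = fit$r2, open = (1 - fit$gamma) <= 1,
                 n_points = length(N)),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("<heaps_fit> n = %.4g * N^%.4f; alpha = %.4f (%s), r2 = %.4f\n",
              x$k, x$gamma, x$alpha, if (x$open) "open" else "closed", x$r2))
  invisible(x)
}

#' Exponential-decay fit of a core-genome or new-gene curve
#'
#' Least-squares fit of the per-`N` means to `n(x) = k * exp(-x/t) + tg_theta`
#' (the convergence value `tg_theta` is the extrapolated core size or
#' per-genome novel gene rate). Multi-start nonlinear least squares over
#' `t in {1, 2, 5, 10}` with `k0 = n(1) - n(G)`, `tg0 = n(G)`; bounds
#' `t > 0`, `tg_theta >= 0`; best residual sum of squares wins. A constant
#' curve short-circuits to `k = 0`, `tg_theta = mean`.
#'
#' @param curve a `development_curve` with statistic `"core"` or `"new_genes"`.
#' @return object of class `decay_fit`: list with `k`, `t`, `tg_theta`, `rss`.
#' @export
fit_decay <- function(curve) {
  gs_assert(inherits(curve, "development_curve") &&
              curve$statistic %in% c("core", "new_genes"),
            "expected a core or new_genes development_curve")
  x <- curve$N
  y <- curve$mean
  gs_assert(length(unique(x)) >= 4, "need >= 4 distinct N")
  if (stats::sd(y) < 1e-9) {
    return(structure(list(k = 0, t = 1, tg_theta = mean(y), rss = 0),
                     class = "decay_fit"))
  }
  k0 <- y[1] - y[length(y)]
  tg0 <- max(0, y[length(y)])
  best <- NULL
  diags <- character(0)
  for (t0 in c(1, 2, 5, 10)) {
    fit <- tryCatch(
      nls(y ~ k * exp(-x / t) + tg, data = data.frame(x = x, y = y),
          start = list(k = k0, t = t0, tg = tg0),
          algorithm = "port",
          lower = c(k = -Inf, t = 1e-6, tg = 0),
          control = list(maxiter = 500, warnOnly = FALSE)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diags <- c(diags, sprintf("t0=%g: %s", t0, conditionMessage(fit)))
      next
    }
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- coef(fit)
      best <- list(k = unname(cf["k"]), t = unname(cf["t"]),
                   tg_theta = unname(cf["tg"]), rss = rss)
    }
  }
  if (is.null(best)) {
    stop("decay fit failed at all starts:\n  ", paste(diags, collapse = "\n  "),
         call. = FALSE)
  }
  structure(best, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> n = %.4g * exp(-x/%.3g) + %.4g (rss %.3g)\n",
              x$k, x$t, x$tg_theta, x$rss))
  invisible(x)
}

#' Combined ANI + alpha genospecies support decision
#'
#' The study's proposal for in-silico species classification: a cluster is
#' supported as a genospecies when (i) every intra-cluster ANI is at or above
#' the species cutoff, and (ii) its pangenome is markedly more closed than
#' the whole cohort's - the cluster's Heap's alpha exceeds the global alpha
#' by at least `margin` (a high intra-cluster alpha marks a clonal,
#' species-like group). The core-genome fraction contrast (cluster core /
#' cluster pangenome vs global) is reported as corroborating evidence.
#' Clusters with fewer than 3 genomes are reported as `"insufficient"`.
#'
#' @param assignment a [single_linkage_clusters()] result.
#' @param ani ANI percent matrix covering all clustered strains.
#' @param presence genomes x families logical matrix.
#' @param n_perms permutations per development curve.
#' @param seed RNG seed (per-cluster seeds are derived deterministically).
#' @param ani_cutoff species ANI threshold (default: the assignment's cutoff).
#' @param margin minimum alpha excess over the global alpha.
#' @param include_n1 passed to [fit_heaps()].
#' @return object of class `species_support`: `global` (alpha, fit, core
#'   fraction), `clusters` (per label: `alpha`, `min_intra_ani`,
#'   `core_fraction`, `verdict`, `reasons`, `n_genomes`), plus parameters.
#' @export
species_support <- function(assignment, ani, presence, n_perms = 100L,
                            seed = 1L, ani_cutoff = assignment$cutoff,
                            margin = 0.02, include_n1 = TRUE) {
  gs_assert(inherits(assignment, "cluster_assignment"),
            "expected a cluster_assignment")
  all_members <- unlist(assignment$clusters, use.names = FALSE)
  gs_assert(all(all_members %in% rownames(presence)),
            "cluster members missing from presence matrix")
  gs_assert(all(all_members %in% rownames(ani)),
            "cluster members missing from ANI matrix")

  g_curve <- permute_accumulate(presence, "pangenome", n_perms,
                                derive_seed(seed, 0L))
  g_fit <- fit_heaps(g_curve, include_n1)
  g_core_frac <- core_fraction(presence)

  clusters <- list()
  for (ci in seq_along(assignment$clusters)) {
    nm <- names(assignment$clusters)[ci]
    members <- assignment$clusters[[nm]]
    sub_ani <- ani[members, members, drop = FALSE]
    min_ani <- min(sub_ani[upper.tri(sub_ani)])
    entry <- list(n_genomes = length(members), min_intra_ani = min_ani)
    if (length(members) < 3) {
      entry$verdict <- "insufficient"
      entry$reasons <- "fewer than 3 genomes"
      entry$alpha <- NA_real_
      entry$core_fraction <- core_fraction(presence[members, , drop = FALSE])
    } else {
      subP <- presence[members, , drop = FALSE]
      subP <- subP[, colSums(subP) > 0, drop = FALSE]
      c_curve <- permute_accumulate(subP, "pangenome", n_perms,
                                    derive_seed(seed, ci))
      c_fit <- fit_heaps(c_curve, include_n1)
      entry$alpha <- c_fit$alpha
      entry$fit <- c_fit
      entry$core_fraction <- core_fraction(subP)
      reasons <- character(0)
      if (!(c_fit$alpha > g_fit$alpha + margin - 1e-12)) {
        reasons <- c(reasons, sprintf(
          "alpha: cluster %.3f does not exceed global %.3f by margin %.3g",
          c_fit$alpha, g_fit$alpha, margin))
      }
      if (min_ani < ani_cutoff) {
        reasons <- c(reasons, sprintf("ANI: min intra-cluster %.2f < cutoff %.4g",
                                      min_ani, ani_cutoff))
      }
      entry$verdict <- if (length(reasons) == 0) "supported" else "not-supported"
      entry$reasons <- reasons
    }
    clusters[[nm]] <- entry
  }
  structure(list(global = list(alpha = g_fit$alpha, fit = g_fit,
                               core_fraction = g_core_frac),
                 clusters = clusters, margin = margin, ani_cutoff = ani_cutoff,
                 n_perms = n_perms, seed = as.integer(seed)),
            class = "species_support")
}

#' Core families as a fraction of the pangenome (over given genomes)
#' @noRd
core_fraction <- function(presence) {
  present <- colSums(presence != 0)
  sum(present == nrow(presence)) / sum(present > 0)
}

#' @export
print.species_support <- function(x, ...) {
  cat(sprintf("<species_support> global alpha %.3f, core fraction %.1f%% (cutoff %.4g%%)\n",
              x$global$alpha, 100 * x$global$core_fraction, x$ani_cutoff))
  for (nm in names(x$clusters)) {
    cl <- x$clusters[[nm]]
    cat(sprintf("  %s (n=%d): alpha %s, min ANI %.2f, core %.1f%% -> %s\n",
                nm, cl$n_genomes,
                if (is.na(cl$alpha)) "NA" else sprintf("%.3f", cl$alpha),
                cl$min_intra_ani, 100 * cl$core_fraction, cl$verdict))
    for (r in cl$reasons) cat("      - ", r, "\n", sep = "")
  }
  invisible(x)
}
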