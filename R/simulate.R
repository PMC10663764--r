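# Synthetic block-structured dissimilarity matrices and the validation
# experiments: sensitivity sweeps, sampling convergence, null calibration,
# partition selection, and the asymptotic size survey.

#' Generate a block-structured dissimilarity matrix
#'
#' Fills each diagonal (within) block with iid draws from its within
#' distribution and each off-diagonal (between) block with iid draws from its
#' between distribution. No symmetry is imposed: entry (alpha, beta) and
#' (beta, alpha) are independent draws, and the diagonal is filled like any
#' other within entry, so the output is a generic nonmetric dissimilarity
#' matrix. Blocks are filled in ascending (j, j') order so a seed fully
#' determines the matrix.
#'
#' @param sizes integer vector of group sizes (all >= 1, g >= 2 groups).
#' @param within a [dist_spec()], or a list of g specs (one per group).
#' @param between a [dist_spec()], or a g x g list-matrix of specs for the
#'   ordered between blocks (diagonal entries ignored).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return list with `dissim` (an [nma_dissim]) and `partition` (an
#'   [nma_partition] with group-major labels `g1`, `g2`, ...).
#' @examples
#' sim <- generate_block_matrix(c(10, 20, 30), dist_spec("uniform", 0, 1),
#'                              dist_spec("uniform", 2, 4), seed = 1)
#' @export
generate_block_matrix <- function(sizes, within, between, seed = NULL) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 2L) stop2("need at least 2 groups")
  if (any(sizes < 1L)) stop2("all group sizes must be >= 1")
  g <- length(sizes)
  if (inherits(within, "nma_dist")) within <- rep(list(within), g)
  if (length(within) != g) stop2("`within` must be one spec or one per group")
  between_of <- if (inherits(between, "nma_dist")) {
    function(j, jp) between
  } else if (is.function(between)) {
    between
  } else {
    if (!is.matrix(between) || any(dim(between) != g)) {
      stop2("`between` must be one spec, a g x g list-matrix, or a function(j, jp)")
    }
    function(j, jp) between[[j, jp]]
  }

  N <- sum(sizes)
  values <- matrix(NA_real_, N, N)
  offsets <- cumsum(c(0L, sizes))
  idx <- lapply(seq_len(g), function(j) (offsets[j] + 1L):offsets[j + 1L])
  with_seed(seed, {
    for (j in seq_len(g)) {
      for (jp in seq_len(g)) {
        spec <- if (j == jp) within[[j]] else between_of(j, jp)
        values[idx[[j]], idx[[jp]]] <- sample_distribution(spec, sizes[j] * sizes[jp])
      }
    }
  })
  # zero-padded so lexicographic level order matches the block layout
  labels <- rep(sprintf(paste0("g%0", nchar(g), "d"), seq_len(g)), sizes)
  list(dissim = nma_dissim(values),
       partition = nma_partition(labels))
}

# which ordered between blocks a sweep scenario perturbs
affected_pairs <- function(scenario, g) {
  pairs <- switch(scenario,
    "one-pair" = list(c(1, 2), c(2, 1)),
    "two-pairs" = list(c(1, 2), c(2, 1), c(1, 3), c(3, 1)),
    "all" = {
      out <- list()
      for (j in seq_len(g)) for (jp in seq_len(g)) {
        if (j != jp) out[[length(out) + 1L]] <- c(j, jp)
      }
      out
    },
    stop2("unknown scenario: ", scenario))
  bad <- vapply(pairs, function(p) p[1] == p[2] || any(p > g), logical(1))
  if (any(bad)) stop2("affected blocks must be off-diagonal blocks within 1..g")
  pairs
}

#' Sensitivity sweep over a location or dispersion offset
#'
#' Measures how the p-value responds as the between-block distribution drifts
#' away from the within-block one. At sweep step i the affected between
#' blocks are drawn from `uniform(a + psi*i, b + psi*i)` (`kind = "mean"`,
#' location shift at constant width) or `uniform(a - psi*i, b + psi*i)`
#' (`kind = "sd"`, symmetric widening at constant mean), with (a, b) the base
#' between distribution. Unaffected between blocks keep the base
#' distribution. Matrices are regenerated per step and replicate with
#' sub-seeds shared across `kind` and `scenario`, so curves from different
#' sweeps are paired draw-for-draw.
#'
#' @param sizes group sizes; default the 3-group 10/20/30 regime.
#' @param psi per-step offset increment (same units as the dissimilarities).
#' @param steps number of sweep steps (>= 1); step i uses offset `psi * i`.
#' @param scenario which between blocks are perturbed: `"one-pair"` (groups 1
#'   and 2), `"two-pairs"` (1-2 and 1-3), or `"all"`.
#' @param kind `"mean"` (location shift) or `"sd"` (widening).
#' @param replicates matrices simulated per step.
#' @param n_samplings proportional samplings per test.
#' @param within,between_base base uniform specs for within and between
#'   blocks.
#' @param seed base seed; per-(step, replicate) sub-seeds are derived from it.
#' @return data.frame with columns `kind`, `scenario`, `step`, `offset`,
#'   `replicate`, `mean_p`, `mean_f`.
#' @export
sensitivity_sweep <- function(sizes = c(10, 20, 30), psi = 0.1, steps = 10,
                              scenario = c("all", "one-pair", "two-pairs"),
                              kind = c("mean", "sd"),
                              replicates = 50, n_samplings = 25,
                              within = dist_spec("uniform", 0, 1),
                              between_base = dist_spec("uniform", 0, 1),
                              seed = NULL) {
  scenario <- match.arg(scenario)
  kind <- match.arg(kind)
  stopifnot(steps >= 1, replicates >= 1)
  if (between_base$family != "uniform") {
    stop2("the sweep construction is defined for a uniform base distribution")
  }
  g <- length(sizes)
  pairs <- affected_pairs(scenario, g)
  a <- between_base$par[1]; b <- between_base$par[2]
  base_seed <- if (is.null(seed)) sample.int(.Machine$integer.max, 1L) else as.integer(seed)

  rows <- vector("list", steps * replicates)
  ri <- 0L
  for (i in seq_len(steps)) {
    off <- psi * i
    shifted <- if (kind == "mean") {
      dist_spec("uniform", a + off, b + off)
    } else {
      dist_spec("uniform", a - off, b + off)
    }
    between_fun <- function(j, jp) {
      if (any(vapply(pairs, function(p) p[1] == j && p[2] == jp, logical(1)))) {
        shifted
      } else {
        between_base
      }
    }
    for (r in seq_len(replicates)) {
      # sub-seed depends on the replicate only: steps (and the mean/sd sweep
      # kinds) share common random numbers, so each replicate's matrices form
      # a coupled sequence along the sweep and curves are paired draw-for-draw
      sub_seed <- (base_seed + 7919L * r) %% .Machine$integer.max
      sim <- generate_block_matrix(sizes, within, between_fun, seed = sub_seed)
      fit <- nm_anova(sim$dissim, sim$partition, n_samplings = n_samplings,
                      seed = sub_seed + 1L)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(kind = kind, scenario = scenario, step = i,
                               offset = off, replicate = r,
                               mean_p = fit$mean_p, mean_f = fit$mean_f)
    }
  }
  do.call(rbind, rows)
}

#' Convergence of the mean p-value in the number of samplings
#'
#' Runs the test once with `max_samplings` replicates on a fixed matrix and
#' reports the cumulative mean of the per-replicate p-values on a log-spaced
#' grid, together with the cumulative mean F.
#'
#' @inheritParams nm_anova
#' @param max_samplings largest number of samplings on the curve.
#' @param grid evaluation points (defaults to ~60 log-spaced values).
#' @return data.frame with columns `n_samplings`, `cum_mean_p`, `cum_mean_f`.
#' @export
convergence_curve <- function(x, partition, max_samplings = 1e5, grid = NULL,
                              seed = NULL, ...) {
  max_samplings <- as.integer(max_samplings)
  if (is.null(grid)) {
    grid <- unique(round(10^seq(0, log10(max_samplings), length.out = 60)))
  }
  grid <- sort(unique(pmin(as.integer(grid), max_samplings)))
  fit <- nm_anova(x, partition, n_samplings = max_samplings, seed = seed, ...)
  cum_p <- cumsum(fit$p_values) / seq_along(fit$p_values)
  cum_f <- cumsum(fit$f_values) / seq_along(fit$f_values)
  data.frame(n_samplings = grid, cum_mean_p = cum_p[grid], cum_mean_f = cum_f[grid])
}

#' Null calibration of the p-value
#'
#' Simulates `n_matrices` independent matrices whose within and between
#' entries share one distribution (so the null hypothesis holds), tests each,
#' and compares the p-value sample against Uniform(0, 1) with a two-sided
#' Kolmogorov-Smirnov test.
#'
#' @param sizes group sizes; default 3 groups of 10.
#' @param spec the common entry distribution (a [dist_spec()]).
#' @param n_matrices number of simulated matrices (>= 2).
#' @param n_samplings samplings per test; the calibration default is 1 so each
#'   matrix contributes one draw from the p-value null distribution.
#' @param seed RNG seed.
#' @return list with `p_values`, `mean_p`, `ks_statistic`, `ks_p`.
#' @export
null_calibration <- function(sizes = c(10, 10, 10),
                             spec = dist_spec("normal", 0, 1),
                             n_matrices = 2000, n_samplings = 1, seed = NULL) {
  n_matrices <- as.integer(n_matrices)
  if (n_matrices < 2L) stop2("sample too small: need n_matrices >= 2 for a KS test")
  p <- numeric(n_matrices)
  with_seed(seed, {
    for (m in seq_len(n_matrices)) {
      sim <- generate_block_matrix(sizes, spec, spec)
      p[m] <- nm_anova(sim$dissim, sim$partition, n_samplings = n_samplings)$mean_p
    }
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  list(p_values = p, mean_p = mean(p),
       ks_statistic = unname(ks$statistic), ks_p = ks$p.value)
}

#' Rank candidate partitions by their mean p-value
#'
#' Tests each candidate partition of the same objects with a shared seed and
#' returns them ranked by ascending mean p, the most distinct partitioning
#' first. Candidates are matched to the matrix by object id (or position), so
#' the ranking is invariant to object order.
#'
#' @inheritParams nm_anova
#' @param partitions named list of candidate partitions (vectors of labels or
#'   [nma_partition] objects) over the same objects.
#' @return data.frame with columns `partition`, `g`, `mean_p`, `mean_f`,
#'   ranked by `mean_p`; the per-candidate fits are attached as attribute
#'   `"fits"`.
#' @export
partition_search <- function(x, partitions, n_samplings = 100, seed = NULL,
                             ...) {
  if (length(partitions) < 2L) stop2("need at least 2 candidate partitions")
  if (is.null(names(partitions))) {
    names(partitions) <- paste0("candidate", seq_along(partitions))
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  fits <- lapply(partitions, function(p) {
    nm_anova(x, p, n_samplings = n_samplings, seed = seed, ...)
  })
  out <- data.frame(
    partition = names(partitions),
    g = vapply(fits, function(f) as.integer(f$blocks$g), integer(1)),
    mean_p = vapply(fits, `[[`, numeric(1), "mean_p"),
    mean_f = vapply(fits, `[[`, numeric(1), "mean_f"),
    row.names = NULL
  )
  out <- out[order(out$mean_p), , drop = FALSE]
  attr(out, "fits") <- fits
  out
}

#' Asymptotic size survey under random distribution pairs
#'
#' For each matrix size, repeatedly draws a random within distribution and an
#' independent random between distribution (families and integer parameters
#' randomized as in [random_dist_spec()]), assigns the objects to g groups at
#' random, and records the test p-value. Degenerate draws (constant matrices,
#' e.g. an extreme Zipf exponent) are recorded as `NA`.
#'
#' @param ns vector of matrix sizes to survey.
#' @param g number of groups.
#' @param replicates draws per size.
#' @param families candidate families; defaults to the builtin set.
#' @param range integer parameter randomization range.
#' @param n_samplings samplings per test.
#' @param seed RNG seed.
#' @return data.frame with columns `n`, `replicate`, `within_family`,
#'   `between_family`, `p`.
#' @export
grid_experiment <- function(ns = c(30, 60, 120), g = 3, replicates = 100,
                            families = builtin_families(),
                            range = c(1, 400), n_samplings = 1, seed = NULL) {
  rows <- vector("list", length(ns) * replicates)
  ri <- 0L
  with_seed(seed, {
    for (n in ns) {
      for (r in seq_len(replicates)) {
        within <- random_dist_spec(families, range)
        between <- random_dist_spec(families, range)
        repeat {                       # random grouping with no empty group
          labels <- sample.int(g, n, replace = TRUE)
          if (length(unique(labels)) == g) break
        }
        sizes <- as.integer(table(labels))
        sim <- generate_block_matrix(sizes, within, between)
        p <- tryCatch(
          nm_anova(sim$dissim, sim$partition, n_samplings = n_samplings)$mean_p,
          error = function(e) NA_real_)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(n = n, replicate = r,
                                 within_family = within$family,
                                 between_family = between$family, p = p)
      }
    }
  })
  do.call(rbind, rows)
}
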