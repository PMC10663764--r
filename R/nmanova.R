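# The test contrasts every ordered between-block mean against a proportionally
# sampled within-block reference mean, standardizes each contrast by its CLT
# standard deviation, and refers the resulting ratio to an F distribution.

# Internal: precompute, for every ordered pair (j, j'), the donor pool of
# within entries (groups other than j and j'), the proportional sample size s,
# and the CLT standardizer. Shared by proportional_sample_means() and
# nm_anova()'s replicate loop.
prep_sampling <- function(summary, fallback_pool, replacement_policy) {
  g <- summary$g
  pairs <- which(row(diag(g)) != col(diag(g)))      # linear indices, col-major
  # ascending (j, j') order: j outer, j' inner
  ordered <- expand.grid(jp = seq_len(g), j = seq_len(g))[, c("j", "jp")]
  ordered <- ordered[ordered$j != ordered$jp, , drop = FALSE]
  ordered <- ordered[order(ordered$j, ordered$jp), , drop = FALSE]

  all_within <- unlist(summary$within_values, use.names = FALSE)
  ratio <- summary$Ndiag / summary$Noff
  out <- vector("list", nrow(ordered))
  fallback_used <- FALSE
  for (k in seq_len(nrow(ordered))) {
    j <- ordered$j[k]; jp <- ordered$jp[k]
    pool <- unlist(summary$within_values[-c(j, jp)], use.names = FALSE)
    if (length(pool) == 0L) {
      if (fallback_pool == "error") {
        stop2("empty exclusion pool (g = ", g, "): no within entries outside ",
              "groups ", j, " and ", jp,
              "; use fallback_pool = \"all-within\"")
      }
      pool <- all_within
      fallback_used <- TRUE
    }
    m_between <- summary$between_counts[j, jp]
    s <- round_half_up(m_between * ratio)
    s <- max(1, s)
    if (replacement_policy == "without-capped") s <- min(s, length(pool))
    out[[k]] <- list(j = j, jp = jp, pool = pool, s = as.integer(s),
                     between_mean = summary$between_means[j, jp],
                     sd_factor = sqrt(1 / m_between +
                                        summary$Noff / (m_between * summary$Ndiag)))
  }
  list(pairs = out, fallback_used = fallback_used)
}

draw_prop_mean <- function(pair, replacement_policy) {
  pool <- pair$pool; s <- pair$s; np <- length(pool)
  if (s <= np) {
    mean(pool[sample.int(np, s)])
  } else {
    # "without-then-with": exhaust the pool, then top up with replacement
    extra <- pool[sample.int(np, s - np, replace = TRUE)]
    (sum(pool) + sum(extra)) / s
  }
}

#' Proportional-sampling reference means
#'
#' For each ordered pair of groups (j, j'), draws the proportional reference
#' mean: the mean of a random sample of within-block entries taken from groups
#' other than j and j'. The exclusion keeps the reference (approximately)
#' independent of the between-block mean it is contrasted with. The sample
#' size is `round(m_jj' * Ndiag / Noff)` (half away from zero, floored at 1),
#' where `m_jj'` is the observed entry count of the between block, so that the
#' reference mean has the variance assumed by the test's standardizer.
#'
#' With g = 2 the exclusion pool is empty; `fallback_pool = "all-within"`
#' (default) then samples from all within entries (with a warning that the
#' independence of numerator and denominator is weakened),
#' `fallback_pool = "error"` refuses.
#'
#' @inheritParams block_summary
#' @param summary a precomputed [block_summary] (computed if `NULL`).
#' @param n_samplings ignored here (one draw per pair); present for symmetry.
#' @param seed RNG seed; `NULL` uses (and advances) the current RNG stream.
#' @param fallback_pool `"all-within"` or `"error"`; behaviour when the
#'   exclusion pool is empty (always the case for g = 2).
#' @param replacement_policy `"without-capped"` (default: sample without
#'   replacement, cap the sample size at the pool size) or
#'   `"without-then-with"` (exhaust the pool, top up with replacement).
#' @return g x g numeric matrix of reference means (`NA` on the diagonal).
#' @export
proportional_sample_means <- function(x, partition, summary = NULL,
                                      seed = NULL,
                                      fallback_pool = c("all-within", "error"),
                                      replacement_policy = c("without-capped",
                                                             "without-then-with"),
                                      include_diagonal = TRUE,
                                      n_samplings = 1L) {
  fallback_pool <- match.arg(fallback_pool)
  replacement_policy <- match.arg(replacement_policy)
  if (is.null(summary)) summary <- block_summary(x, partition, include_diagonal)
  prep <- prep_sampling(summary, fallback_pool, replacement_policy)
  if (prep$fallback_used) {
    warning("empty exclusion pool (g = 2): proportional samples drawn from ",
            "all within entries; numerator/denominator independence is weakened",
            call. = FALSE)
  }
  g <- summary$g
  out <- matrix(NA_real_, g, g, dimnames = dimnames(summary$between_means))
  with_seed(seed, {
    for (pair in prep$pairs) {
      out[pair$j, pair$jp] <- draw_prop_mean(pair, replacement_policy)
    }
  })
  out
}

#' Sums of squared normalized means
#'
#' The two building blocks of the test statistic. The within term sums, over
#' groups, the squared deviations of the within-block means from the overall
#' within mean, each weighted by the square root of the block's observed entry
#' count (equal to nj with complete data and the diagonal included). The
#' between term sums, over ordered group pairs, the squared contrast between
#' the between-block mean and its proportional reference mean, standardized by
#' `sqrt(1/m + Noff/(m * Ndiag))` with `m` the block's observed count -- the
#' standard deviation of the contrast under a common entry variance of one.
#'
#' @param summary a [block_summary].
#' @param prop_means g x g matrix of proportional reference means, as returned
#'   by [proportional_sample_means()].
#' @return named numeric vector `c(snm_within, snm_between)`.
#' @export
snm_statistics <- function(summary, prop_means) {
  stopifnot(inherits(summary, "nma_blocks"))
  w <- sqrt(summary$within_counts)
  snm_within <- sum((w * (summary$within_means - summary$overall_within_mean))^2)
  g <- summary$g
  snm_between <- 0
  for (j in seq_len(g)) {
    for (jp in seq_len(g)) {
      if (j == jp) next
      m <- summary$between_counts[j, jp]
      sd_factor <- sqrt(1 / m + summary$Noff / (m * summary$Ndiag))
      z <- (summary$between_means[j, jp] - prop_means[j, jp]) / sd_factor
      snm_between <- snm_between + z^2
    }
  }
  c(snm_within = snm_within, snm_between = snm_between)
}

#' F statistic and p-value
#'
#' `F = (snm_between / g) / snm_within`, referred to the upper tail of the F
#' distribution with `df1 = g^2 - g` and `df2 = g - 1` degrees of freedom.
#' This equals the mean-square form `(snm_between/(g(g-1))) / (snm_within/(g-1))`.
#'
#' @param snm_between,snm_within nonnegative statistics from [snm_statistics()].
#' @param g number of groups (>= 2).
#' @return list with `f`, `df1`, `df2`, `p`, and `degenerate` (`TRUE` when
#'   `snm_within` is zero while `snm_between` is positive, giving `F = Inf`,
#'   `p = 0`).
#' @examples
#' f_and_p(157 / 3, 2, g = 3)
#' @export
f_and_p <- function(snm_between, snm_within, g) {
  stopifnot(g >= 2, snm_between >= 0, snm_within >= 0)
  df1 <- g * g - g
  df2 <- g - 1
  if (snm_within == 0) {
    if (snm_between == 0) stop2("degenerate constant input: both statistics are zero")
    return(list(f = Inf, df1 = df1, df2 = df2, p = 0, degenerate = TRUE))
  }
  f <- (snm_between / g) / snm_within
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Nonmetric analysis of variance
#'
#' Tests whether a partitioning of objects into g groups is supported by their
#' pairwise dissimilarities. The dissimilarities may be asymmetric, have a
#' nonzero diagonal, and contain missing entries. Because the reference means
#' are sampled, the test is replicated `n_samplings` times on the fixed block
#' decomposition; the headline p-value is the mean of the per-replicate
#' p-values, which converges as the number of samplings grows.
#'
#' @inheritParams proportional_sample_means
#' @param n_samplings number of proportional-sampling replicates (>= 1).
#' @return object of class `nmanova`: list with per-replicate `f_values` and
#'   `p_values`, the summaries `mean_p` (headline), `sd_p`, `mean_f`,
#'   `p_of_mean_f`, degrees of freedom `df1`/`df2`, `snm_within` (shared
#'   across replicates), `degenerate`, `fallback_used`, the `blocks` summary
#'   and bookkeeping (`n_samplings`, `seed`, `sample_sizes`).
#' @examples
#' d <- matrix(c(1, 5, 6, 4, 2, 7, 8, 9, 3), 3, byrow = TRUE)
#' nm_anova(d, c(1, 2, 3), n_samplings = 10)
#' @export
nm_anova <- function(x, partition, n_samplings = 10000L, seed = NULL,
                     include_diagonal = TRUE,
                     fallback_pool = c("all-within", "error"),
                     replacement_policy = c("without-capped",
                                            "without-then-with")) {
  fallback_pool <- match.arg(fallback_pool)
  replacement_policy <- match.arg(replacement_policy)
  n_samplings <- as.integer(n_samplings)
  if (is.na(n_samplings) || n_samplings < 1L) stop2("`n_samplings` must be >= 1")

  summary <- block_summary(x, partition, include_diagonal)
  prep <- prep_sampling(summary, fallback_pool, replacement_policy)
  if (prep$fallback_used) {
    warning("empty exclusion pool (g = 2): proportional samples drawn from ",
            "all within entries; numerator/denominator independence is weakened",
            call. = FALSE)
  }
  g <- summary$g
  df1 <- g * g - g
  df2 <- g - 1

  w <- sqrt(summary$within_counts)
  snm_within <- sum((w * (summary$within_means - summary$overall_within_mean))^2)

  # per-pair constants for the replicate loop
  bm <- vapply(prep$pairs, `[[`, numeric(1), "between_mean")
  inv_var <- vapply(prep$pairs, function(p) p$sd_factor^-2, numeric(1))

  f_values <- numeric(n_samplings)
  with_seed(seed, {
    for (r in seq_len(n_samplings)) {
      snmb <- 0
      for (k in seq_along(prep$pairs)) {
        m <- draw_prop_mean(prep$pairs[[k]], replacement_policy)
        snmb <- snmb + (bm[k] - m)^2 * inv_var[k]
      }
      f_values[r] <- snmb
    }
  })
  degenerate <- FALSE
  if (snm_within == 0) {
    if (all(f_values == 0)) stop2("degenerate constant input: both statistics are zero")
    degenerate <- TRUE
    f_values <- ifelse(f_values == 0, 0, Inf)
    p_values <- ifelse(is.infinite(f_values), 0, 1)
  } else {
    f_values <- (f_values / g) / snm_within
    p_values <- stats::pf(f_values, df1, df2, lower.tail = FALSE)
  }
  mean_f <- mean(f_values)

  structure(list(
    f_values = f_values,
    p_values = p_values,
    mean_p = mean(p_values),
    sd_p = stats::sd(p_values),
    mean_f = mean_f,
    p_of_mean_f = stats::pf(mean_f, df1, df2, lower.tail = FALSE),
    df1 = df1, df2 = df2,
    snm_within = snm_within,
    degenerate = degenerate,
    fallback_used = prep$fallback_used,
    n_samplings = n_samplings,
    seed = seed,
    sample_sizes = vapply(prep$pairs, `[[`, integer(1), "s"),
    blocks = summary
  ), class = "nmanova")
}

#' @export
print.nmanova <- function(x, digits = 4, ...) {
  b <- x$blocks
  cat("Nonmetric analysis of variance\n")
  cat(sprintf("  %d objects in %d groups (%s)\n",
              sum(b$sizes), b$g,
              paste(names(b$sizes), b$sizes, sep = "=", collapse = ", ")))
  cat(sprintf("  Ndiag = %d, Noff = %d, samplings = %d\n",
              b$Ndiag, b$Noff, x$n_samplings))
  if (x$fallback_used) {
    cat("  note: g = 2 fallback pool (all within entries) was used\n")
  }
  if (x$degenerate) {
    cat("  note: degenerate input (snm_within = 0); F = Inf, p = 0\n")
  }
  cat(sprintf("  F = %s on (%d, %d) df\n",
              format(x$mean_f, digits = digits), x$df1, x$df2))
  cat(sprintf("  p = %s (mean over samplings; sd = %s)\n",
              format(x$mean_p, digits = digits),
              format(x$sd_p, digits = digits)))
  invisible(x)
}
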