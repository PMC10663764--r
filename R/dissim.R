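#' Construct a dissimilarity matrix object
#'
#' Wraps a square numeric matrix of pairwise dissimilarities. No metric axiom
#' is assumed or enforced: the matrix may be asymmetric (quasimetric inputs
#' such as directional scores), carry a nonzero diagonal (metametric inputs
#' such as self-looped network nodes), contain zero off-diagonal entries
#' (pseudometric inputs), and have missing entries coded as `NA` (e.g. absent
#' edges in a network edge list). Observed entries must be finite.
#'
#' @param values square numeric matrix; `NA` marks a missing (unobserved)
#'   entry. A `data.frame` is coerced.
#' @param ids character vector of object identifiers, one per row/column.
#'   Defaults to the matrix dimnames, or `o1..oN` when unnamed.
#' @return An object of class `nma_dissim`: a list with elements `values`
#'   (the matrix, with ids as dimnames) and `ids`.
#' @examples
#' d <- nma_dissim(matrix(c(1, 5, 6, 4, 2, 7, 8, 9, 3), 3, byrow = TRUE))
#' d
#' @export
nma_dissim <- function(values, ids = NULL) {
  if (inherits(values, "nma_dissim")) return(values)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (inherits(values, "dist")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop2("`values` must be a numeric matrix")
  }
  if (nrow(values) != ncol(values)) {
    stop2("dissimilarity matrix must be square, got ",
          nrow(values), "x", ncol(values))
  }
  if (nrow(values) < 2L) stop2("need at least 2 objects")
  if (any(is.infinite(values)) || any(is.nan(values))) {
    stop2("observed dissimilarities must be finite (use NA for missing)")
  }
  if (is.null(ids)) {
    ids <- rownames(values) %||% colnames(values) %||%
      paste0("o", seq_len(nrow(values)))
  }
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) stop2("`ids` length must match matrix size")
  if (anyDuplicated(ids)) stop2("duplicate object ids: ",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids), class = "nma_dissim")
}

#' @export
print.nma_dissim <- function(x, ...) {
  n <- length(x$ids)
  miss <- sum(is.na(x$values))
  cat(sprintf("Dissimilarity matrix: %d objects", n))
  if (miss > 0L) cat(sprintf(", %d/%d entries missing", miss, n * n))
  sym <- isTRUE(all.equal(x$values, t(x$values)))
  cat(if (sym) " (symmetric)" else " (asymmetric)", "\n", sep = "")
  if (n <= 8L) print(x$values) else utils::str(x$values)
  invisible(x)
}

#' Construct a partition of objects into groups
#'
#' @param labels vector of group labels, one per object. A factor keeps its
#'   level order; otherwise levels are sorted, so the partition (and every
#'   downstream seeded computation) does not depend on the input order of the
#'   objects.
#' @param ids object identifiers; defaults to `names(labels)` when present.
#' @return An object of class `nma_partition`: list with `labels` (factor),
#'   `ids`, `g` (number of groups) and `sizes` (per-group counts).
#' @examples
#' nma_partition(c(a = "x", b = "x", c = "y"))
#' @export
nma_partition <- function(labels, ids = NULL) {
  if (inherits(labels, "nma_partition")) return(labels)
  if (is.null(ids)) ids <- names(labels)
  if (!is.factor(labels)) {
    labels <- factor(labels)
  } else {
    labels <- droplevels(labels)
  }
  if (anyNA(labels)) stop2("group labels must not be missing")
  if (!is.null(ids)) {
    ids <- as.character(ids)
    if (length(ids) != length(labels)) stop2("`ids` length must match labels")
    if (anyDuplicated(ids)) stop2("duplicate object ids in partition: ",
                                  paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  g <- nlevels(labels)
  if (g < 2L) stop2("partition must have g >= 2 groups, got ", g)
  sizes <- as.integer(table(labels))
  names(sizes) <- levels(labels)
  structure(list(labels = labels, ids = ids, g = g, sizes = sizes),
            class = "nma_partition")
}

#' @export
print.nma_partition <- function(x, ...) {
  cat(sprintf("Partition: %d objects in %d groups (%s)\n",
              length(x$labels), x$g,
              paste(names(x$sizes), x$sizes, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Validate and canonically order a dissimilarity matrix and partition
#'
#' Checks that the matrix and partition describe the same object set and
#' reorders both into the canonical group-major order (groups in level order,
#' input order within each group). All downstream computation, including the
#' seeded proportional sampling, operates on this canonical order, so results
#' do not depend on the input ordering of objects.
#'
#' When both carry ids, objects are matched by id; otherwise they are matched
#' by position (lengths must agree).
#'
#' @param x a [nma_dissim] or square numeric matrix.
#' @param partition a [nma_partition], or a vector of group labels (named by
#'   object id, or positional).
#' @return list with elements `dissim` and `partition`, reordered.
#' @export
validate_inputs <- function(x, partition) {
  x <- nma_dissim(x)
  partition <- nma_partition(partition)
  n <- length(x$ids)
  if (length(partition$labels) != n) {
    stop2("partition labels ", length(partition$labels),
          " objects but matrix has ", n)
  }
  if (!is.null(partition$ids)) {
    unknown <- setdiff(partition$ids, x$ids)
    if (length(unknown)) stop2("label for unknown object: ",
                               paste(unknown, collapse = ", "))
    unlabeled <- setdiff(x$ids, partition$ids)
    if (length(unlabeled)) stop2("unlabeled object: ",
                                 paste(unlabeled, collapse = ", "))
    partition$labels <- partition$labels[match(x$ids, partition$ids)]
    partition$ids <- x$ids
  } else {
    partition$ids <- x$ids
  }
  ord <- order(as.integer(partition$labels))   # stable: input order in group
  values <- x$values[ord, ord, drop = FALSE]
  part <- nma_partition(partition$labels[ord], ids = partition$ids[ord])
  list(dissim = nma_dissim(values), partition = part)
}

#' Block decomposition of a dissimilarity matrix under a partition
#'
#' Splits the matrix into its g within (diagonal) blocks and g^2 - g ordered
#' between (off-diagonal) blocks and computes the observed-entry counts and
#' mean dissimilarity of each block, the total within/between counts
#' `Ndiag`/`Noff`, and the overall within mean. Means are taken over observed
#' entries only; missing entries are excluded from counts and means.
#'
#' With `include_diagonal = TRUE` (default) the self-dissimilarities enter the
#' within blocks, so with complete data `Ndiag = sum(nj^2)`; this is the
#' metametric-friendly convention implied by the within weights of the test
#' statistic. With `include_diagonal = FALSE` the diagonal is dropped
#' (`Ndiag = sum(nj*(nj-1))` with complete data), for metric-style inputs
#' whose structural zeros would dilute the within means.
#'
#' @inheritParams validate_inputs
#' @param include_diagonal logical; count self-dissimilarities in the within
#'   blocks.
#' @return object of class `nma_blocks`: list with `within_means`,
#'   `within_counts` (length g), `between_means`, `between_counts` (g x g,
#'   `NA` on the diagonal), `Ndiag`, `Noff`, `overall_within_mean`, `g`,
#'   `sizes`, `within_values` (per-group observed within entries, used by the
#'   proportional sampler) and `include_diagonal`.
#' @examples
#' d <- matrix(c(1, 5, 6, 4, 2, 7, 8, 9, 3), 3, byrow = TRUE)
#' block_summary(d, c(1, 2, 3))
#' @export
block_summary <- function(x, partition, include_diagonal = TRUE) {
  v <- validate_inputs(x, partition)
  values <- v$dissim$values
  part <- v$partition
  g <- part$g
  idx <- split(seq_along(part$labels), part$labels)

  within_values <- vector("list", g)
  names(within_values) <- levels(part$labels)
  for (j in seq_len(g)) {
    blk <- values[idx[[j]], idx[[j]], drop = FALSE]
    if (!include_diagonal) diag(blk) <- NA
    # sorted, so seeded sampling from these pools is invariant to the input
    # order of the objects
    within_values[[j]] <- sort(blk[!is.na(blk)])
  }
  within_counts <- lengths(within_values)
  if (any(within_counts == 0L)) {
    stop2("empty block: within block of group ",
          paste(levels(part$labels)[within_counts == 0L], collapse = ", "),
          " has no observed entries")
  }
  within_means <- vapply(within_values, mean, numeric(1))

  between_means <- matrix(NA_real_, g, g,
                          dimnames = list(levels(part$labels), levels(part$labels)))
  between_counts <- matrix(NA_real_, g, g,
                           dimnames = dimnames(between_means))
  for (j in seq_len(g)) {
    for (jp in seq_len(g)) {
      if (j == jp) next
      blk <- values[idx[[j]], idx[[jp]], drop = FALSE]
      obs <- blk[!is.na(blk)]
      if (length(obs) == 0L) {
        stop2("empty block: between block (",
              levels(part$labels)[j], ",", levels(part$labels)[jp],
              ") has no observed entries")
      }
      between_counts[j, jp] <- length(obs)
      between_means[j, jp] <- mean(obs)
    }
  }

  Ndiag <- sum(within_counts)
  Noff <- sum(between_counts, na.rm = TRUE)
  overall_within_mean <- sum(within_means * within_counts) / Ndiag

  structure(list(
    within_means = within_means,
    within_counts = within_counts,
    between_means = between_means,
    between_counts = between_counts,
    Ndiag = Ndiag,
    Noff = Noff,
    overall_within_mean = overall_within_mean,
    g = g,
    sizes = part$sizes,
    within_values = within_values,
    include_diagonal = include_diagonal
  ), class = "nma_blocks")
}

#' @export
print.nma_blocks <- function(x, ...) {
  cat(sprintf("Block summary: %d groups (%s), Ndiag = %d, Noff = %d\n",
              x$g, paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "),
              x$Ndiag, x$Noff))
  cat(sprintf("overall within mean = %.6g\n", x$overall_within_mean))
  cat("within means:\n"); print(x$within_means)
  cat("between means:\n"); print(x$between_means)
  invisible(x)
}
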