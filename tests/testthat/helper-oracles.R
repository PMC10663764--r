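# Independent oracles used to freeze expected values. These deliberately use
# explicit loops / closed forms, not the package's code paths.

worked_matrix <- function() {
  matrix(c(1, 5, 6,
           4, 2, 7,
           8, 9, 3), nrow = 3, byrow = TRUE,
         dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
}

# brute-force block means/counts by explicit double loop over entries
oracle_blocks <- function(values, labels, include_diagonal = TRUE) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  g <- length(groups)
  sums <- matrix(0, g, g, dimnames = list(groups, groups))
  counts <- matrix(0, g, g, dimnames = list(groups, groups))
  n <- nrow(values)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b && !include_diagonal) next
      if (is.na(values[a, b])) next
      j <- labels[a]; jp <- labels[b]
      sums[j, jp] <- sums[j, jp] + values[a, b]
      counts[j, jp] <- counts[j, jp] + 1
    }
  }
  means <- sums / counts
  Ndiag <- sum(diag(counts))
  list(means = means, counts = counts,
       Ndiag = Ndiag, Noff = sum(counts) - Ndiag,
       delta_w = sum(diag(sums)) / Ndiag)
}

# closed-form upper tail of F(6, 2): CDF is I_u(3, 1) = u^3 with
# u = 6x / (6x + 2)
oracle_p_f62 <- function(f) {
  u <- 6 * f / (6 * f + 2)
  1 - u^3
}

# random test matrix with optional missingness; guaranteed non-empty blocks
random_case <- function(n, g, missing_frac = 0) {
  values <- matrix(rnorm(n * n), n, n)
  labels <- c(seq_len(g), sample.int(g, n - g, replace = TRUE))
  if (missing_frac > 0) {
    drop <- sample.int(n * n, round(missing_frac * n * n))
    values[drop] <- NA
    diag(values)[] <- rnorm(n)   # keep within blocks non-empty
    # restore one entry in any between block emptied by the drop
    for (j in seq_len(g)) {
      for (jp in seq_len(g)) {
        if (j == jp) next
        rows <- which(labels == j); cols <- which(labels == jp)
        if (all(is.na(values[rows, cols]))) {
          values[rows[1], cols[1]] <- rnorm(1)
        }
      }
    }
  }
  list(values = values, labels = paste0("grp", labels))
}
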