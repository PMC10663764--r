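# Constructors that turn raw feature data into nonmetric dissimilarity
# matrices: inverted alignment similarity scores (semimetric), directional
# correlation dissimilarity of sensitivity profiles (quasimetric), and
# Kullback-Leibler divergence between count profiles (asymmetric, zero
# diagonal).

#' Invert a similarity-score matrix into dissimilarities
#'
#' A higher alignment score (e.g. a BLAST bit score) marks more similar
#' objects, so inverted scores serve as dissimilarities. Asymmetry of the
#' score matrix is preserved.
#'
#' @param scores square numeric similarity matrix (may be asymmetric; `NA`
#'   marks missing).
#' @param mode `"reciprocal"` (default): `delta = 1/s`, requiring positive
#'   scores; or `"max-minus"`: `delta = max(s) - s`, usable with zero or
#'   negative scores.
#' @return an [nma_dissim].
#' @examples
#' invert_bit_scores(matrix(c(100, 40, 25, 90), 2, byrow = TRUE))
#' @export
invert_bit_scores <- function(scores, mode = c("reciprocal", "max-minus")) {
  mode <- match.arg(mode)
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (!is.matrix(scores) || !is.numeric(scores)) stop2("`scores` must be a numeric matrix")
  if (nrow(scores) != ncol(scores)) stop2("score matrix must be square")
  obs <- scores[!is.na(scores)]
  values <- if (mode == "reciprocal") {
    if (any(obs <= 0)) stop2("reciprocal inversion requires positive scores; ",
                             "use mode = \"max-minus\"")
    1 / scores
  } else {
    max(obs) - scores
  }
  nma_dissim(values, ids = rownames(scores))
}

#' Correlation dissimilarity between directional sensitivity profiles
#'
#' `delta[a, b] = 1 - cor(x_a, y_b)`, where `x_a` is object a's profile in
#' the baseline role and `y_b` is object b's profile in the response role.
#' With two distinct roles (e.g. a drug combination scored with itself as
#' baseline vs. as added agent) the matrix is asymmetric; anti-correlated
#' profiles reach the maximal dissimilarity of 2. Passing one table for both
#' roles gives the usual symmetric correlation dissimilarity. Observations
#' missing in either profile are dropped pairwise.
#'
#' @param baseline objects x features numeric matrix (profiles in the baseline
#'   role; rows are objects).
#' @param response objects x features numeric matrix for the response role;
#'   defaults to `baseline`.
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @return an [nma_dissim] with zero diagonal when both roles coincide.
#' @export
correlation_dissimilarity <- function(baseline, response = baseline,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.data.frame(baseline)) baseline <- as.matrix(baseline)
  if (is.data.frame(response)) response <- as.matrix(response)
  stopifnot(is.matrix(baseline), is.matrix(response))
  if (nrow(baseline) != nrow(response) || ncol(baseline) != ncol(response)) {
    stop2("`baseline` and `response` must have identical dimensions")
  }
  n <- nrow(baseline)
  values <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      xa <- baseline[a, ]; yb <- response[b, ]
      keep <- !is.na(xa) & !is.na(yb)
      if (sum(keep) < 3L) {
        stop2("objects ", a, " and ", b, " share fewer than 3 paired observations")
      }
      if (stats::sd(xa[keep]) == 0 || stats::sd(yb[keep]) == 0) {
        stop2("undefined correlation: zero-variance profile for object ",
              if (stats::sd(xa[keep]) == 0) a else b)
      }
      values[a, b] <- 1 - stats::cor(xa[keep], yb[keep], method = method)
    }
  }
  nma_dissim(values, ids = rownames(baseline))
}

#' Kullback-Leibler divergence matrix between count profiles
#'
#' Each object's feature vector is shifted by a pseudocount and normalized to
#' a discrete probability vector p; the dissimilarity is the divergence
#' `KL(p_a || p_b) = sum_k p_a(k) log(p_a(k) / p_b(k))` in nats. KL is
#' asymmetric with a zero diagonal and nonnegative (Gibbs' inequality). The
#' `"js"` variant returns the Jensen-Shannon divergence, the symmetrized and
#' smoothed version bounded by log(2), for use with methods that require
#' symmetric input.
#'
#' @param counts objects x features nonnegative matrix (e.g. expression
#'   counts; rows are objects).
#' @param pseudocount positive value added to every count before
#'   normalization, so zero counts stay comparable.
#' @param variant `"kl"` (default) or `"js"`.
#' @return an [nma_dissim].
#' @examples
#' kl_divergence_matrix(rbind(a = c(5, 5), b = c(9, 1)), pseudocount = 0)
#' @export
kl_divergence_matrix <- function(counts, pseudocount = 1e-8,
                                 variant = c("kl", "js")) {
  variant <- match.arg(variant)
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (anyNA(counts) || any(counts < 0)) stop2("`counts` must be nonnegative and complete")
  if (pseudocount < 0) stop2("`pseudocount` must be >= 0")
  shifted <- counts + pseudocount
  totals <- rowSums(shifted)
  if (any(totals == 0)) {
    stop2("all-zero count row with pseudocount = 0: rows ",
          paste(which(totals == 0), collapse = ", "))
  }
  p <- shifted / totals
  n <- nrow(p)
  kl <- function(pa, pb) {
    nz <- pa > 0
    sum(pa[nz] * log(pa[nz] / pb[nz]))
  }
  values <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      values[a, b] <- if (variant == "kl") {
        kl(p[a, ], p[b, ])
      } else {
        m <- (p[a, ] + p[b, ]) / 2
        0.5 * kl(p[a, ], m) + 0.5 * kl(p[b, ], m)
      }
    }
  }
  if (any(is.infinite(values))) {
    stop2("infinite divergence: a profile places zero mass where another does ",
          "not; use a positive pseudocount")
  }
  nma_dissim(values, ids = rownames(counts))
}
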