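# Readers and writers. Wide format: a square table with object ids as the
# header row and first column. Long format: (source_id, target_id, value)
# triples, doubling as a network edge list -- unlisted ordered pairs are
# missing, not zero, since zero dissimilarity is a meaningful pseudometric
# value.

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a dissimilarity matrix from a file
#'
#' @param path path to a TSV (default) or CSV file (separator inferred from
#'   the extension unless given).
#' @param format `"wide"`: square table, first row and first column hold the
#'   object ids; `"long"`: three columns (source_id, target_id, value).
#'   Empty cells and `NA` are missing; in long format, unlisted ordered pairs
#'   are missing.
#' @param sep field separator; overrides the extension-based inference.
#' @return an [nma_dissim].
#' @export
read_dissim <- function(path, format = c("wide", "long"), sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  sep <- sep %||% infer_sep(path)
  if (format == "wide") {
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop2("non-numeric value cell in ", path)
    if (nrow(m) != ncol(m)) stop2("wide matrix must be square, got ",
                                  nrow(m), "x", ncol(m))
    if (!identical(rownames(m), colnames(m))) {
      stop2("row ids and column ids disagree in ", path)
    }
    nma_dissim(m)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
    if (ncol(tab) < 3L) stop2("long format needs columns (source_id, target_id, value)")
    src <- as.character(tab[[1]]); tgt <- as.character(tab[[2]])
    val <- tab[[3]]
    if (!is.numeric(val)) stop2("non-numeric value cell in ", path)
    key <- paste(src, tgt, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop2("duplicate pair: (", sub("\r", ", ", d), ") listed more than once")
    }
    ids <- unique(c(src, tgt))
    m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(match(src, ids), match(tgt, ids))] <- val
    nma_dissim(m)
  }
}

#' Read group labels from a two-column file
#'
#' @param path path to a TSV/CSV file with columns (object_id, group_label).
#'   Group labels are mapped to groups in order of first appearance.
#' @param sep field separator; inferred from the extension by default.
#' @return an [nma_partition].
#' @export
read_groups <- function(path, sep = NULL) {
  if (!file.exists(path)) stop2("file not found: ", path)
  sep <- sep %||% infer_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop2("labels file needs columns (object_id, group_label)")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop2("duplicate id in labels file: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  labels <- as.character(tab[[2]])
  # groups numbered in order of first appearance in the file
  nma_partition(factor(labels, levels = unique(labels)), ids = ids)
}

#' Write a test result to disk
#'
#' `"json"` serializes every numeric field of the result at full precision;
#' `"tsv"` writes the per-replicate table (replicate, F, p) with full-precision
#' values.
#'
#' @param result an `nmanova` object.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_nma_result <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "nmanova"))
  if (format == "json") {
    fields <- list(
      f_values = result$f_values,
      p_values = result$p_values,
      mean_p = result$mean_p,
      sd_p = result$sd_p,
      mean_f = result$mean_f,
      p_of_mean_f = result$p_of_mean_f,
      df1 = result$df1, df2 = result$df2,
      snm_within = result$snm_within,
      degenerate = result$degenerate,
      fallback_used = result$fallback_used,
      n_samplings = result$n_samplings,
      g = result$blocks$g,
      sizes = as.integer(result$blocks$sizes),
      Ndiag = result$blocks$Ndiag,
      Noff = result$blocks$Noff
    )
    # digits = I(17): 17 significant digits reproduce doubles bit-exactly
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    tab <- data.frame(replicate = seq_along(result$f_values),
                      F = sprintf("%.17g", result$f_values),
                      p = sprintf("%.17g", result$p_values))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON result written by [write_nma_result()]
#'
#' @param path path to the JSON file.
#' @return list of result fields.
#' @export
read_nma_result <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
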