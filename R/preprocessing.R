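#' Read a phosphosite-by-time quantitative matrix
#'
#' The expected layout is the common exported form of SILAC-style time-course
#' quantitation: a header row, first column phosphosite identifiers
#' (gene symbol + residue, e.g. `"BAD;S136"`), remaining columns one per time
#' point in temporal order.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param sep field separator; `"\t"` or `","`.
#'
#' @return A numeric matrix with site identifiers as row names and time-point
#'   labels as column names.
#' @export
read_temporal_matrix <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (ncol(tab) < 3L) .stopf("matrix must have >= 2 time-point columns")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    .stopf("duplicated site identifier(s): %s",
           paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) .stopf("matrix contains missing values; impute or filter upstream")
  rownames(m) <- ids
  m
}

#' Write a temporal matrix to TSV
#'
#' @param m numeric matrix with site identifiers as row names.
#' @param path output path.
#' @param id_column header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_temporal_matrix <- function(m, path, id_column = "site") {
  tab <- data.frame(rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[1] <- id_column
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter phosphosites by fold change against a reference time point
#'
#' Keeps sites whose phosphorylation level changes at least `threshold`-fold
#' at some time point relative to the reference (typically the first, i.e.
#' unstimulated, time point), in either direction. On the ratio scale a site
#' is kept when `value/reference >= threshold` or `reference/value >=
#' threshold` at any non-reference time point; on the log2 scale the
#' criterion is `|value - reference| >= log2(threshold)`.
#'
#' @param m numeric site-by-time matrix.
#' @param threshold fold-change threshold (>= 1). The conventional cutoff for
#'   time-course phosphoproteomics is 2.
#' @param reference_index column index of the reference time point. Default 1.
#' @param scale `"ratio"` for positive abundance ratios, `"log2"` for log2
#'   ratios.
#'
#' @return The filtered matrix (possibly with zero rows). With `threshold = 1`
#'   every site is kept.
#' @export
fold_change_filter <- function(m, threshold = 2, reference_index = 1L,
                               scale = c("ratio", "log2")) {
  scale <- match.arg(scale)
  if (threshold < 1) .stopf("threshold must be >= 1")
  if (reference_index < 1L || reference_index > ncol(m)) {
    .stopf("reference_index out of range")
  }
  ref <- m[, reference_index]
  rest <- m[, -reference_index, drop = FALSE]
  if (scale == "ratio") {
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      .stopf("non-positive ratio for site '%s'; use scale = \"log2\" for log data",
             rownames(m)[bad[1, 1]])
    }
    fc <- pmax(rest / ref, ref / rest)
  } else {
    fc <- 2^abs(rest - ref)
  }
  keep <- apply(fc, 1L, max) >= threshold
  m[keep, , drop = FALSE]
}

#' Standardize each temporal profile to mean 0, SD 1
#'
#' Row-wise z-scoring (population standard deviation) removes per-site
#' magnitude so that Euclidean clustering compares profile shapes. Constant
#' rows carry no temporal shape and are dropped with a warning.
#'
#' @param m numeric site-by-time matrix.
#' @return The standardized matrix. Idempotent and rank-preserving within
#'   rows.
#' @export
standardize_rows <- function(m) {
  s <- .row_pop_sd(m)
  flat <- s == 0 | !is.finite(s)
  if (any(flat)) {
    .warnf("dropping %d constant profile(s) with no temporal shape (e.g. '%s')",
           sum(flat), rownames(m)[which(flat)[1]])
    m <- m[!flat, , drop = FALSE]
  }
  .zscore_rows(m)
}
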