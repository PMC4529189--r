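# Position-specific scoring matrices for kinase recognition motifs.
# Sequences are fixed-width amino-acid windows centered on the phosphosite
# (PhosphoSitePlus-style +/-7 windows of width 15, but any width works).

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Build a position-specific scoring matrix from substrate windows
#'
#' The PSSM entry for amino acid `a` at window position `j` is the empirical
#' frequency of `a` at `j` over the `N` training windows:
#' `P[a, j] = (1/N) * sum_i I(x[i, j] == a)`. Placeholder characters (the
#' unknown residue `X` and the edge-padding `_`) are excluded from the count
#' and the position renormalized over the remaining residues; a position with
#' no valid residue at all becomes a uniform column with a warning.
#'
#' @param sequences character vector of equal-width amino-acid windows.
#' @param pseudocount added to every (residue, position) count before
#'   normalization; 0 (default) gives the plain frequency matrix.
#'
#' @return An object of class `"pssm"`: a `width x 20` probability matrix
#'   (positions as rows, the 20 amino acids as columns; each row sums to 1)
#'   with attributes `n_sequences` and `width`.
#' @examples
#' build_pssm(c("AK", "AR"))
#' @export
build_pssm <- function(sequences, pseudocount = 0) {
  if (length(sequences) < 1L) .stopf("need at least one sequence")
  sequences <- toupper(sequences)
  w <- unique(nchar(sequences))
  if (length(w) != 1L) {
    .stopf("sequences have unequal widths: %s", paste(w, collapse = ", "))
  }
  chars <- matrix(unlist(strsplit(sequences, "")), ncol = w, byrow = TRUE)
  prob <- matrix(0, nrow = w, ncol = length(.AA),
                 dimnames = list(position = seq_len(w), aa = .AA))
  for (j in seq_len(w)) {
    counts <- table(factor(chars[, j], levels = .AA)) + pseudocount
    tot <- sum(counts)
    if (tot == 0) {
      .warnf("no valid residue at position %d; using a uniform column", j)
      prob[j, ] <- 1 / length(.AA)
    } else {
      prob[j, ] <- counts / tot
    }
  }
  structure(prob, class = c("pssm", "matrix"),
            n_sequences = length(sequences), width = w)
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM: width %d, built from %d sequence(s)\n",
              attr(x, "width"), attr(x, "n_sequences")))
  consensus <- colnames(x)[apply(unclass(x), 1L, which.max)]
  cat("  consensus:", paste(consensus, collapse = ""), "\n")
  invisible(x)
}

#' Score a phosphosite window against a PSSM
#'
#' The motif enrichment score of a window is the sum over positions of the
#' PSSM frequency of the window's residue at that position:
#' `sum_j P[window[j], j]`, ranging from 0 (no residue ever observed in
#' training) to the window width (every residue invariant in training).
#' Unknown residues (`X`) and edge padding (`_`) contribute 0. Vectorized
#' over windows.
#'
#' @param windows character vector of amino-acid windows, same width as the
#'   PSSM.
#' @param pssm a [build_pssm()] object.
#' @return Numeric score(s) in `[0, width]`.
#' @examples
#' motif_score("AK", build_pssm(c("AK", "AR")))
#' @export
motif_score <- function(windows, pssm) {
  stopifnot(inherits(pssm, "pssm"))
  windows <- toupper(windows)
  w <- attr(pssm, "width")
  if (any(nchar(windows) != w)) {
    .stopf("window width must equal the PSSM width (%d)", w)
  }
  chars <- matrix(unlist(strsplit(windows, "")), ncol = w, byrow = TRUE)
  p <- unclass(pssm)
  vapply(seq_len(nrow(chars)), function(i) {
    col <- match(chars[i, ], colnames(p))  # X/_ -> NA -> contributes 0
    sum(p[cbind(seq_len(w), col)], na.rm = TRUE)
  }, numeric(1))
}

#' Per-cluster motif enrichment
#'
#' Scores every site's sequence window against a kinase PSSM and summarizes
#' each cluster by its median score; the cluster(s) with the highest median
#' are the candidate home of that kinase's substrates. Sites without a
#' window are skipped (their count is reported).
#'
#' @param model a `"clue_clustering"` (or the `best_model` of a [clue()]
#'   fit).
#' @param windows named character vector mapping site identifiers to
#'   amino-acid windows.
#' @param pssm a [build_pssm()] object.
#' @return A list with `median_score` (per cluster; `NA` for clusters with
#'   no sequenced site), `top_cluster` (indices of all clusters tying the
#'   maximum median), `n_scored` and `n_skipped`.
#' @export
cluster_motif_enrichment <- function(model, windows, pssm) {
  stopifnot(inherits(model, "clue_clustering"))
  if (is.null(names(windows))) .stopf("windows must be named by site identifier")
  common <- intersect(names(model$cluster), names(windows))
  n_skipped <- length(model$cluster) - length(common)
  if (length(common) == 0L) .stopf("no clustered site has a sequence window")
  if (n_skipped > 0L) {
    message(sprintf("cluster_motif_enrichment: %d site(s) without a window skipped",
                    n_skipped))
  }
  scores <- motif_score(windows[common], pssm)
  cl <- model$cluster[common]
  med <- vapply(seq_len(model$k), function(i) {
    s <- scores[cl == i]
    if (length(s) == 0L) NA_real_ else stats::median(s)
  }, numeric(1))
  top <- which(med == max(med, na.rm = TRUE))
  list(median_score = med, top_cluster = top,
       n_scored = length(common), n_skipped = n_skipped)
}

#' Read site-keyed sequence windows
#'
#' Accepts either FASTA (headers are site identifiers; read via the
#' Biostrings parser) or a two-column TSV (site identifier, window).
#'
#' @param path input file.
#' @param format `"auto"` (default; FASTA when the first non-empty line
#'   starts with `>`), `"fasta"` or `"tsv"`.
#' @return Named character vector of windows.
#' @export
read_windows <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(first)][1]
    format <- if (!is.na(first) && startsWith(first, ">")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      .stopf("reading FASTA windows requires the Biostrings package")
    }
    seqs <- Biostrings::readAAStringSet(path)
    out <- as.character(seqs)
    names(out) <- sub("\\s.*$", "", names(seqs))
    out
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (ncol(tab) < 2L) .stopf("window TSV needs two columns: site, window")
    stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
  }
}

#' Serialize a PSSM to TSV (positions as rows, amino acids as columns)
#'
#' @param pssm a [build_pssm()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  tab <- data.frame(position = seq_len(nrow(pssm)), unclass(pssm),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
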