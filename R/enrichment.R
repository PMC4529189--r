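#' One-sided Fisher's exact test for kinase-cluster enrichment
#'
#' Tests over-representation of a kinase's substrates inside one cluster.
#' The 2x2 contingency counts are: `a` substrates of the kinase inside the
#' cluster, `b` its substrates outside, `c` cluster sites not annotated to
#' the kinase, and `d` sites neither in the cluster nor annotated. Under the
#' null of no association with all margins fixed, `a` is hypergeometric, and
#' the one-sided p-value for enrichment (odds ratio > 1) is the upper tail
#' `P(X >= a)` with population `a+b+c+d`, `a+b` successes and `a+c` draws.
#'
#' @param a,b,c,d non-negative integer contingency counts.
#' @return The one-sided p-value in (0, 1]. Degenerate margins (`a+b == 0` or
#'   `a+c == 0`) return 1. Vectorized over the counts.
#' @examples
#' fisher_one_sided(5, 5, 5, 85)
#' @export
fisher_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) .stopf("contingency counts must be non-negative")
  n <- a + b + c + d
  if (any(n <= 0)) .stopf("empty universe")
  p <- stats::phyper(a - 1, m = a + b, n = c + d, k = a + c,
                     lower.tail = FALSE)
  # phyper upper tail at a-1 already returns 1 when a == 0 or margins vanish
  pmin(p, 1)
}

#' Per-cluster summary p-value: the best kinase
#'
#' The information content of one cluster is summarized by the smallest
#' enrichment p-value over all eligible kinases. A cluster with no eligible
#' kinase is uninformative and scores 1 (neutral in the downstream
#' combination, since log(1) = 0).
#'
#' @param p_row numeric vector of per-kinase p-values for one cluster (may be
#'   empty); all entries must lie in (0, 1].
#' @return A single p-value.
#' @export
cluster_min_p <- function(p_row) {
  if (length(p_row) == 0L) return(1)
  if (any(!is.finite(p_row) | p_row <= 0 | p_row > 1)) {
    .stopf("p-values must lie in (0, 1]")
  }
  min(p_row)
}

#' Combine per-cluster p-values by Fisher's combined probability test
#'
#' The k per-cluster p-values are combined through the statistic
#' `X = -2 * sum(log(p))`, referred to a chi-squared distribution with
#' `d = 2k` degrees of freedom: `P = P(chi^2_d > X)`. The enrichment score is
#' `E = -log10(P)`. The tail is evaluated in log space so that partitionings
#' with many very small p-values keep full resolution.
#'
#' @param cluster_ps numeric vector of k per-cluster p-values in (0, 1].
#'   Zeros are floored to the smallest positive double with a warning.
#' @return A list with elements `p` (the combined p-value `P`), `log10_p`
#'   (its log10, exact even when `p` underflows), `score` (`E = -log10(P)`),
#'   `statistic` (`X`) and `df` (`2k`).
#' @examples
#' combine_fisher(c(0.01, 0.5))
#' @export
combine_fisher <- function(cluster_ps) {
  k <- length(cluster_ps)
  if (k < 1L) .stopf("need at least one cluster p-value")
  if (any(!is.finite(cluster_ps) | cluster_ps < 0 | cluster_ps > 1)) {
    .stopf("p-values must lie in (0, 1]")
  }
  if (any(cluster_ps == 0)) {
    .warnf("p-value of 0 floored to %.3g", .Machine$double.xmin)
    cluster_ps[cluster_ps == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(cluster_ps))
  log_p <- stats::pchisq(x, df = 2 * k, lower.tail = FALSE, log.p = TRUE)
  list(p = exp(log_p),
       log10_p = log_p / log(10),
       score = -log_p / log(10),
       statistic = x,
       df = 2L * k)
}

#' Score one clustering against a kinase-substrate database
#'
#' Computes the knowledge-based enrichment score of a partitioning: for every
#' (cluster, kinase) pair a one-sided Fisher's exact test of substrate
#' over-representation, per cluster the minimum p-value over kinases, and
#' across clusters Fisher's combined probability test with 2k degrees of
#' freedom. The universe is all clustered sites, annotated or not. Hard
#' cluster assignments are used (for fuzzy fits, the argmax-membership
#' cluster).
#'
#' @param model a clustering fit from [kmeans_fit()], [cmeans_fit()] or one
#'   element of [fit_repeated()].
#' @param db an [annotation_db()], already restricted to the dataset's sites
#'   via [restrict_to_dataset()]; sites unknown to the model are an error.
#' @return An object of class `"clue_enrichment"`: a list with `p` (k x m
#'   p-value matrix, clusters x kinases), `cluster_p` (per-cluster minima),
#'   `combined_p`, `log10_p`, `score`, `df`, `cluster_sizes`, `n_sites`.
#' @export
score_clustering <- function(model, db) {
  stopifnot(inherits(model, "clue_clustering"), inherits(db, "annotation_db"))
  cl <- model$cluster
  k <- model$k
  n <- length(cl)
  unknown <- setdiff(unique(unlist(db, use.names = FALSE)), names(cl))
  if (length(unknown)) {
    .stopf("annotation sites absent from the clustered matrix: %s%s",
           paste(utils::head(unknown, 5), collapse = ", "),
           if (length(unknown) > 5) sprintf(" (+%d more)", length(unknown) - 5) else "")
  }
  sizes <- tabulate(cl, nbins = k)
  m <- length(db)
  p <- matrix(1, nrow = k, ncol = m,
              dimnames = list(cluster = NULL, kinase = names(db)))
  for (j in seq_len(m)) {
    K <- length(db[[j]])
    a <- tabulate(cl[db[[j]]], nbins = k)
    p[, j] <- stats::phyper(a - 1, m = K, n = n - K, k = sizes,
                            lower.tail = FALSE)
  }
  cluster_p <- if (m > 0L) apply(p, 1L, min) else rep(1, k)
  comb <- combine_fisher(cluster_p)
  structure(list(p = p,
                 cluster_p = cluster_p,
                 combined_p = comb$p,
                 log10_p = comb$log10_p,
                 score = comb$score,
                 statistic = comb$statistic,
                 df = comb$df,
                 cluster_sizes = sizes,
                 n_sites = n),
            class = "clue_enrichment")
}

#' @export
print.clue_enrichment <- function(x, ...) {
  cat(sprintf("Enrichment of %d clusters against %d kinases over %d sites\n",
              nrow(x$p), ncol(x$p), x$n_sites))
  cat(sprintf("  combined P = %.4g (chi^2 df %d), enrichment score E = %.3f\n",
              x$combined_p, x$df, x$score))
  invisible(x)
}

#' Report kinases enriched within each cluster
#'
#' @param table a `"clue_enrichment"` from [score_clustering()].
#' @param alpha significance level for the raw Fisher p-value; default 0.05.
#' @param adjust apply Benjamini-Hochberg correction across kinases within
#'   each cluster before thresholding. Off by default (the conventional
#'   report uses raw p < 0.05).
#' @return A list with one data.frame per cluster (`kinase`, `p`), each
#'   sorted by increasing p-value.
#' @export
enriched_kinases <- function(table, alpha = 0.05, adjust = FALSE) {
  stopifnot(inherits(table, "clue_enrichment"))
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must lie in (0, 1)")
  lapply(seq_len(nrow(table$p)), function(i) {
    p <- table$p[i, ]
    crit <- if (adjust) stats::p.adjust(p, "BH") else p
    sel <- which(crit < alpha)
    sel <- sel[order(p[sel])]
    data.frame(kinase = colnames(table$p)[sel], p = unname(p[sel]),
               stringsAsFactors = FALSE)
  })
}

#' Min-max normalization of per-k objective curves
#'
#' Rescales an objective curve to [0, 1] so that cluster-number selection
#' curves from different methods can be co-plotted. Curves from methods that
#' minimize their objective are flipped (`1 - normalized`) so that higher is
#' always better.
#'
#' @param scores numeric vector (>= 2 values, not all equal).
#' @param direction `"maximize"` or `"minimize"`.
#' @return Normalized scores with minimum 0 and maximum 1.
#' @export
minmax_normalize <- function(scores, direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  if (length(scores) < 2L) .stopf("need at least two scores")
  rng <- range(scores)
  if (rng[1] == rng[2]) .stopf("all scores equal; normalization undefined")
  s <- (scores - rng[1]) / (rng[2] - rng[1])
  if (direction == "minimize") 1 - s else s
}
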