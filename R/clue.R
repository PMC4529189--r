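#' Knowledge-guided selection of the number of temporal clusters
#'
#' Fits the full cluster-number sweep: for every `k` in `k_range` the profile
#' matrix is partitioned `repeats` times from different random starts, each
#' partitioning is scored against the kinase-substrate annotation database
#' (per-cluster one-sided Fisher's exact tests, per-cluster minimum p-value,
#' Fisher's combined probability test with 2k degrees of freedom, enrichment
#' score `E = -log10(P)`), and the per-k scores are averaged over restarts
#' to form the score-vs-k curve. The optimal `k` is selected from the
#' restarts: by default each restart index votes for its own argmax-k and
#' the modal vote wins (`select = "modal"`), which is robust to single bad
#' restarts at the true k; `select = "mean"` takes the argmax of the
#' restart-averaged score instead. Ties resolve toward the smallest `k`.
#' The best single run at the selected `k` is kept as the representative
#' clustering.
#'
#' The fit self-calibrates against an empirical null: the best model at each
#' k is re-scored after randomly permuting the annotation database over the
#' dataset's sites. When the real mean-score curve fails to clearly exceed
#' this permutation null (peak below twice the null's peak), or is all zero,
#' the fit is flagged `uninformative`: no cluster number dominates because
#' the database carries no temporal signal for this dataset.
#'
#' @param m numeric phosphosite-by-time matrix; row names are site
#'   identifiers matching the annotation database.
#' @param db an [annotation_db()]. It is restricted to the rows of `m` (with
#'   `min_substrates`) before scoring.
#' @param k_range integer range of cluster numbers to evaluate. Default
#'   `2:20`.
#' @param repeats random restarts per k. Default 10.
#' @param method `"cmeans"` (fuzzy c-means, default) or `"kmeans"`.
#' @param fuzzifier fuzziness exponent for c-means. Default 2.
#' @param seed integer; all restarts derive their seeds from it.
#' @param standardize z-score rows (population SD) before clustering.
#'   Default `TRUE`; profile-shape clustering is the intended use.
#' @param min_substrates minimum in-dataset substrates for a kinase to enter
#'   the enrichment tests. Default 2.
#' @param select how the optimal `k` is chosen from the restarts: `"modal"`
#'   (default; per-restart argmax votes, modal vote wins) or `"mean"`
#'   (argmax of the restart-averaged score).
#'
#' @return An object of class `"clue"`: list with `k_values`, `mean_score`,
#'   `per_run_scores` (k x repeats matrix), `optimal_k`, `best_model` (a
#'   `"clue_clustering"`), `best_table` (a `"clue_enrichment"`),
#'   `null_score` (per-k permutation-null scores), `uninformative` flag, the
#'   clustered `data`, and the call parameters.
#'   Methods: [print.clue()], [summary.clue()], [plot.clue()],
#'   [coef.clue()], [predict.clue()], [fitted.clue()], [residuals.clue()].
#'
#' @examples
#' sim <- simulate_phospho(n_clusters = 3, sites_per_cluster = 40, seed = 1)
#' db <- simulate_annotations(sim$labels, g = 3, n_groups = 10,
#'                            group_size = 15, seed = 1)
#' fit <- clue(sim$matrix, db, k_range = 2:6, repeats = 2, seed = 1)
#' fit$optimal_k
#' @export
clue <- function(m, db, k_range = 2:20, repeats = 10L,
                 method = c("cmeans", "kmeans"), fuzzifier = 2,
                 seed = 1L, standardize = TRUE, min_substrates = 2L,
                 select = c("modal", "mean")) {
  method <- match.arg(method)
  select <- match.arg(select)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > nrow(m)) {
    .stopf("k_range must lie within [2, %d]", nrow(m))
  }
  if (standardize) m <- standardize_rows(m)
  db <- restrict_to_dataset(db, rownames(m), min_substrates = min_substrates)

  per_run <- matrix(NA_real_, nrow = length(k_range), ncol = repeats,
                    dimnames = list(k = k_range, run = seq_len(repeats)))
  models <- vector("list", length(k_range))
  tables <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    fits <- fit_repeated(m, k, repeats = repeats, method = method,
                         base_seed = seed + (ki - 1L) * repeats,
                         fuzzifier = fuzzifier)
    tabs <- lapply(fits, score_clustering, db = db)
    per_run[ki, ] <- vapply(tabs, `[[`, numeric(1), "score")
    best <- which.max(per_run[ki, ])
    models[[ki]] <- fits[[best]]
    tables[[ki]] <- tabs[[best]]
  }
  mean_score <- rowMeans(per_run)
  opt_i <- if (select == "modal") {
    # each restart index votes for its own best k; modal vote wins
    # (which.max on a table resolves ties toward the smallest k)
    votes <- apply(per_run, 2L, which.max)
    as.integer(names(which.max(table(votes))))
  } else {
    which.max(mean_score)  # which.max takes the first (smallest k) tie
  }

  # permutation null: relabel the database's sites by a random bijection and
  # re-score the per-k best models; real signal must clearly exceed it
  ids <- rownames(m)
  permuted <- with_seed(seed + 777L, sample(ids))
  lookup <- stats::setNames(permuted, ids)
  null_db <- annotation_db(lapply(db, function(s) unname(lookup[s])),
                           species = attr(db, "species"))
  null_score <- vapply(models, function(mod) {
    score_clustering(mod, null_db)$score
  }, numeric(1))
  uninformative <- all(mean_score < 1e-12) ||
    max(mean_score) < 2 * max(null_score)
  structure(list(k_values = k_range,
                 mean_score = unname(mean_score),
                 per_run_scores = per_run,
                 optimal_k = k_range[opt_i],
                 best_model = models[[opt_i]],
                 best_table = tables[[opt_i]],
                 null_score = null_score,
                 uninformative = uninformative,
                 data = m,
                 method = method,
                 fuzzifier = if (method == "cmeans") fuzzifier else NA_real_,
                 repeats = repeats,
                 select = select,
                 seed = seed,
                 min_substrates = min_substrates,
                 n_kinases = length(db),
                 call = match.call()),
            class = "clue")
}

#' @export
print.clue <- function(x, ...) {
  cat("Knowledge-guided cluster-number selection\n")
  cat(sprintf("  %d sites x %d time points, %d eligible kinases\n",
              nrow(x$data), ncol(x$data), x$n_kinases))
  cat(sprintf("  method %s, k in [%d, %d], %d restarts per k, seed %d\n",
              x$method, min(x$k_values), max(x$k_values), x$repeats, x$seed))
  cat(sprintf("  optimal k = %d (%s selection; mean enrichment score %.2f)\n",
              x$optimal_k, x$select,
              x$mean_score[match(x$optimal_k, x$k_values)]))
  if (x$uninformative) {
    cat("  WARNING: no cluster number dominates; the annotation database\n")
    cat("  appears uninformative for this dataset.\n")
  }
  invisible(x)
}

#' Summarize a cluster-number selection fit
#'
#' @param object a `"clue"` fit.
#' @param alpha significance level for the per-cluster enriched-kinase
#'   report. Default 0.05.
#' @param ... unused.
#' @return An object of class `"summary.clue"`, printed as the score-vs-k
#'   table plus the enriched kinases of each cluster of the best clustering.
#' @export
summary.clue <- function(object, alpha = 0.05, ...) {
  enr <- enriched_kinases(object$best_table, alpha = alpha)
  structure(list(fit = object,
                 score_table = data.frame(k = object$k_values,
                                          mean_score = object$mean_score),
                 enriched = enr,
                 alpha = alpha),
            class = "summary.clue")
}

#' @export
print.summary.clue <- function(x, ...) {
  print(x$fit)
  cat("\nMean enrichment score by k:\n")
  tab <- x$score_table
  tab$mean_score <- round(tab$mean_score, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("\nEnriched kinases per cluster at k = %d (p < %g):\n",
              x$fit$optimal_k, x$alpha))
  for (i in seq_along(x$enriched)) {
    e <- x$enriched[[i]]
    cat(sprintf("  cluster %d (%d sites): %s\n", i,
                x$fit$best_model$size[i],
                if (nrow(e) == 0L) "-" else
                  paste(sprintf("%s (p=%.2g)", e$kinase, e$p), collapse = ", ")))
  }
  invisible(x)
}

#' Plot the enrichment-score curve of a sweep
#'
#' Draws the restart-averaged enrichment score against the number of
#' clusters and highlights the selected optimum.
#'
#' @param x a `"clue"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.clue <- function(x, ...) {
  graphics::plot(x$k_values, x$mean_score, type = "b", pch = 19,
                 xlab = "number of clusters k",
                 ylab = "mean enrichment score  -log10(P)", ...)
  i <- match(x$optimal_k, x$k_values)
  graphics::points(x$optimal_k, x$mean_score[i], col = "red", pch = 19,
                   cex = 1.5)
  graphics::legend("bottomright", legend = sprintf("optimal k = %d", x$optimal_k),
                   col = "red", pch = 19, bty = "n")
  invisible(x)
}

#' @export
coef.clue <- function(object, ...) {
  object$best_model$centers
}

#' Assign new temporal profiles to the selected clusters
#'
#' New profiles are standardized the same way as the training data (row
#' z-score) when the fit was standardized, then assigned to the fitted
#' centroids: fuzzy memberships via the c-means membership equation for
#' `method = "cmeans"`, nearest-centroid for `"kmeans"`.
#'
#' @param object a `"clue"` fit.
#' @param newdata numeric profile matrix with the same number of time points.
#' @param type `"cluster"` for hard assignments (default) or `"membership"`
#'   for the full membership matrix.
#' @param ... unused.
#' @return An integer vector of cluster indices, or an n x k membership
#'   matrix.
#' @export
predict.clue <- function(object, newdata,
                         type = c("cluster", "membership"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$data)) {
    .stopf("newdata has %d time points; the fit used %d",
           ncol(newdata), ncol(object$data))
  }
  z <- .zscore_rows(newdata)
  centers <- object$best_model$centers
  d2 <- outer(rowSums(z^2), rep(1, nrow(centers))) -
    2 * z %*% t(centers) + outer(rep(1, nrow(z)), rowSums(centers^2))
  d2[d2 < 0] <- 0
  if (object$method == "cmeans") {
    expo <- 1 / (object$fuzzifier - 1)
    u <- (1 / pmax(d2, .Machine$double.eps))^expo
    coincident <- d2 <= .Machine$double.eps
    if (any(coincident)) {
      u[rowSums(coincident) > 0, ] <- 0
      u[coincident] <- 1
    }
    u <- u / rowSums(u)
  } else {
    u <- matrix(0, nrow(z), nrow(centers))
    u[cbind(seq_len(nrow(z)), max.col(-d2, ties.method = "first"))] <- 1
  }
  if (type == "membership") {
    rownames(u) <- rownames(newdata)
    u
  } else {
    cl <- max.col(u, ties.method = "first")
    names(cl) <- rownames(newdata)
    cl
  }
}

#' @export
fitted.clue <- function(object, ...) {
  f <- object$best_model$centers[object$best_model$cluster, , drop = FALSE]
  dimnames(f) <- dimnames(object$data)
  f
}

#' @export
residuals.clue <- function(object, ...) {
  object$data - fitted(object)
}

#' Write the per-k sweep scores to TSV
#'
#' @param fit a `"clue"` fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(fit, path) {
  stopifnot(inherits(fit, "clue"))
  tab <- data.frame(k = fit$k_values, mean_score = fit$mean_score,
                    fit$per_run_scores, check.names = FALSE)
  names(tab)[-(1:2)] <- paste0("run_", seq_len(fit$repeats))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
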