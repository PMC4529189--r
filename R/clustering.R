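# Clustering engines. Both wrap the standard implementations (stats::kmeans
# with Lloyd iterations, e1071::cmeans) behind a seeded, reproducible
# interface: initial centroids are k distinct data rows drawn uniformly at
# random under the given seed, matching the random-restart protocol used for
# cluster-number sweeps.

.check_k <- function(x, k) {
  if (k > nrow(x)) .stopf("k = %d exceeds the number of sites (%d)", k, nrow(x))
  if (k < 2L) .stopf("k must be >= 2")
  k
}

.init_centers <- function(x, k, seed) {
  .check_k(x, k)
  with_seed(seed, x[sample.int(nrow(x), k), , drop = FALSE])
}

.new_clustering <- function(k, centers, membership, cluster, objective,
                            method, seed, fuzzifier = NA_real_, iter = NA_integer_) {
  rownames(centers) <- NULL
  structure(list(k = k,
                 centers = centers,
                 membership = membership,
                 cluster = cluster,
                 size = tabulate(cluster, nbins = k),
                 objective = objective,
                 method = method,
                 fuzzifier = fuzzifier,
                 iter = iter,
                 seed = seed),
            class = "clue_clustering")
}

#' @export
print.clue_clustering <- function(x, ...) {
  cat(sprintf("%s clustering: %d clusters over %d sites (seed %s)\n",
              if (x$method == "cmeans") "Fuzzy c-means" else "k-means",
              x$k, length(x$cluster), format(x$seed)))
  cat("  sizes:", paste(x$size, collapse = ", "), "\n")
  invisible(x)
}

#' Cluster temporal profiles with classic k-means
#'
#' Lloyd's algorithm with Euclidean distance, initialized from `k` distinct
#' profiles drawn uniformly at random under `seed`; repeated calls with the
#' same seed are bit-identical. In the rare event that an iteration empties a
#' cluster the fit is restarted from a fresh seeded draw.
#'
#' @param m numeric site-by-time matrix (usually standardized via
#'   [standardize_rows()]).
#' @param k number of clusters, `2 <= k <= nrow(m)`.
#' @param seed integer seed for the centroid initialization.
#' @param max_iter iteration cap. Default 200.
#'
#' @return An object of class `"clue_clustering"` with elements `k`,
#'   `centers` (k x time matrix), `membership` (one-hot n x k matrix),
#'   `cluster` (named hard assignments), `size`, `objective` (total
#'   within-cluster sum of squares), `method`, `seed`.
#' @export
kmeans_fit <- function(m, k, seed = NULL, max_iter = 200L) {
  centers <- .init_centers(m, k, seed)
  fit <- NULL
  for (attempt in 0:9) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(m, centers = centers,
                                     algorithm = "Lloyd",
                                     iter.max = max_iter)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
    if (!grepl("empty cluster", conditionMessage(fit))) stop(fit)
    centers <- .init_centers(m, k, if (is.null(seed)) NULL else seed + 7907L * (attempt + 1L))
  }
  if (inherits(fit, "error")) stop(fit)
  membership <- matrix(0, nrow = nrow(m), ncol = k)
  membership[cbind(seq_len(nrow(m)), fit$cluster)] <- 1
  cl <- fit$cluster
  names(cl) <- rownames(m)
  .new_clustering(k, fit$centers, membership, cl,
                  objective = fit$tot.withinss, method = "kmeans",
                  seed = seed, iter = fit$iter)
}

#' Cluster temporal profiles with fuzzy c-means
#'
#' Bezdek's alternating updates: membership `u_si` proportional to
#' `(1/d(x_s, v_i)^2)^(1/(m-1))` normalized over clusters, centroids the
#' membership^fuzzifier-weighted means, iterated to convergence. A site
#' coincident with a centroid receives membership 1 there (the limit
#' convention). Initialization is the same seeded random-row draw as
#' [kmeans_fit()], so the two methods can be compared on identical starts.
#'
#' @inheritParams kmeans_fit
#' @param c number of clusters.
#' @param fuzzifier fuzziness exponent, > 1. Default 2 (the standard
#'   choice); values close to 1 approach hard k-means assignments.
#' @param tol relative convergence tolerance of the alternating updates.
#'   Default 1e-6.
#'
#' @return An object of class `"clue_clustering"`; `membership` rows sum
#'   to 1 and `cluster` is the argmax-membership assignment.
#' @export
cmeans_fit <- function(m, c, fuzzifier = 2, seed = NULL, max_iter = 200L,
                       tol = 1e-6) {
  if (fuzzifier <= 1) .stopf("fuzzifier must be > 1")
  # the whole fit runs under the seed: the backend shuffles row order
  # internally, which perturbs floating-point summation order
  fit <- with_seed(seed, {
    centers <- m[sample.int(nrow(m), .check_k(m, c)), , drop = FALSE]
    e1071::cmeans(m, centers = centers, m = fuzzifier,
                  iter.max = max_iter, verbose = FALSE,
                  dist = "euclidean", method = "cmeans",
                  control = list(reltol = tol))
  })
  cl <- fit$cluster
  names(cl) <- rownames(m)
  .new_clustering(c, fit$centers, fit$membership, cl,
                  objective = fit$withinerror, method = "cmeans",
                  seed = seed, fuzzifier = fuzzifier,
                  iter = fit$iter)
}

#' Fit the same clustering repeatedly from different random starts
#'
#' Runs `repeats` fits with seeds `base_seed, base_seed + 1, ...`, the
#' random-restart protocol used when sweeping cluster numbers. The returned
#' list is stable in order and reproducible from `base_seed`.
#'
#' @inheritParams kmeans_fit
#' @param repeats number of restarts (>= 1).
#' @param method `"cmeans"` (default) or `"kmeans"`.
#' @param base_seed integer seed of the first restart.
#' @param fuzzifier fuzziness exponent for `method = "cmeans"`.
#'
#' @return A list of `repeats` `"clue_clustering"` objects.
#' @export
fit_repeated <- function(m, k, repeats = 10L, method = c("cmeans", "kmeans"),
                         base_seed = 1L, fuzzifier = 2, max_iter = 200L) {
  method <- match.arg(method)
  if (repeats < 1L) .stopf("repeats must be >= 1")
  lapply(seq_len(repeats), function(r) {
    s <- as.integer(base_seed) + r - 1L
    if (method == "kmeans") {
      kmeans_fit(m, k, seed = s, max_iter = max_iter)
    } else {
      cmeans_fit(m, k, fuzzifier = fuzzifier, seed = s, max_iter = max_iter)
    }
  })
}

#' Write hard assignments and membership scores to TSV
#'
#' @param model a `"clue_clustering"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(model, path) {
  stopifnot(inherits(model, "clue_clustering"))
  mem <- model$membership
  colnames(mem) <- paste0("membership_", seq_len(ncol(mem)))
  # memberships are rounded: the last few bits of the underlying c-means
  # iteration are not reproducible across calls, the leading digits are
  tab <- data.frame(site = names(model$cluster),
                    cluster = unname(model$cluster),
                    membership = signif(mem[cbind(seq_along(model$cluster),
                                                  model$cluster)], 8),
                    signif(mem, 8),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
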