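#' The library of temporal profile templates
#'
#' Fourteen canonical 7-time-point patterns spanning the kinetic repertoire
#' commonly seen in stimulus-response phosphoproteomics: monotone rises and
#' falls (sharp, linear, late), transient spikes at different times, a broad
#' hump and valley, rise-to-plateau / plateau-to-fall shapes, oscillations in
#' both phases, and a fall-recover-rise pattern. Values are in arbitrary
#' abundance units with a 6-unit dynamic range, so that the unit-variance
#' Gaussian site noise used in the simulations constitutes moderate noise.
#' After row standardization all pairwise template distances exceed 1.6
#' (most exceed 2), i.e. the patterns are mutually distinct. The library is
#' shipped as a versioned fixture file so simulations are stable across
#' package versions.
#'
#' @return A 14 x 7 numeric matrix, template names as row names.
#' @export
temporal_templates <- function() {
  path <- system.file("extdata", "templates_v1.tsv", package = "phosClue",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  m
}

#' Simulate a temporal phosphoproteomics matrix
#'
#' Draws `n_clusters` templates uniformly without replacement from the
#' template library and generates `sites_per_cluster` phosphosites per
#' template as the template plus i.i.d. Gaussian noise with standard
#' deviation `sigma` at every time point. Optionally the time axis can be
#' thinned (`time_subset`) or the trailing `noisy_tail` time points replaced
#' by pure Gaussian noise around a flat level, emulating non-functional
#' late-course measurements with no shared structure.
#'
#' @param n_clusters number of templates to draw, between 2 and 14.
#' @param sites_per_cluster sites generated per template. Default 500.
#' @param sigma Gaussian noise SD per time point. Default 1.
#' @param time_subset indices of time points to retain (applied after
#'   generation), e.g. `c(1, 4, 7)`. Default all.
#' @param noisy_tail number of trailing retained time points to replace with
#'   pure noise. Default 0.
#' @param seed integer seed; generation is bit-reproducible.
#' @param templates template library matrix; defaults to
#'   [temporal_templates()].
#'
#' @return A list with `matrix` (site-by-time, rows named `s0001...`),
#'   `labels` (named integer vector: true template index per site) and
#'   `template_names`.
#' @export
simulate_phospho <- function(n_clusters, sites_per_cluster = 500L,
                             sigma = 1, time_subset = NULL,
                             noisy_tail = 0L, seed = 1L,
                             templates = temporal_templates()) {
  if (n_clusters < 2L || n_clusters > nrow(templates)) {
    .stopf("n_clusters must lie in [2, %d]", nrow(templates))
  }
  n_times <- ncol(templates)
  if (is.null(time_subset)) time_subset <- seq_len(n_times)
  if (noisy_tail >= length(time_subset)) {
    .stopf("noisy_tail must be smaller than the number of retained time points")
  }
  with_seed(seed, {
    chosen <- sample.int(nrow(templates), n_clusters)
    labels <- rep(chosen, each = sites_per_cluster)
    n <- length(labels)
    m <- templates[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * n_times, 0, sigma), nrow = n)
    m <- m[, time_subset, drop = FALSE]
    if (noisy_tail > 0L) {
      tail_idx <- seq(to = ncol(m), length.out = noisy_tail)
      m[, tail_idx] <- matrix(stats::rnorm(n * noisy_tail, 0, sigma), nrow = n)
    }
    ids <- sprintf("s%0*d", nchar(n), seq_len(n))
    rownames(m) <- ids
    colnames(m) <- paste0("t", time_subset)
    names(labels) <- ids
    list(matrix = m, labels = labels,
         template_names = rownames(templates)[chosen])
  })
}

#' Simulate a kinase-substrate annotation database
#'
#' Emulates a curated kinase-substrate resource for a simulated dataset:
#' `n_groups` kinase groups of `group_size` substrates each. `g` of them are
#' informative: each samples its substrates from the sites of one distinct
#' true template. With annotation noise `s`, `ceiling(s * group_size)`
#' members of every informative group are replaced by sites drawn from other
#' templates (mis-assigned substrates). The remaining `n_groups - g` groups
#' sample their substrates uniformly from all sites, carrying no temporal
#' information.
#'
#' @param labels named integer vector of true template indices per site, as
#'   returned by [simulate_phospho()].
#' @param g number of informative groups, `0 <= g <=` number of distinct
#'   templates present.
#' @param n_groups total kinase groups. Default 100.
#' @param group_size substrates per group. Default 50.
#' @param annotation_noise fraction of mis-assigned substrates per
#'   informative group, in `[0, 1)`. Default 0.
#' @param seed integer seed.
#'
#' @return An [annotation_db()] with kinases named `KIN_I01...` (informative)
#'   and `KIN_R01...` (random).
#' @export
simulate_annotations <- function(labels, g, n_groups = 100L,
                                 group_size = 50L, annotation_noise = 0,
                                 seed = 1L) {
  templates_present <- unique(labels)
  if (g < 0L || g > length(templates_present)) {
    .stopf("g must lie in [0, %d] (distinct templates present)",
           length(templates_present))
  }
  if (annotation_noise < 0 || annotation_noise >= 1) {
    .stopf("annotation_noise must lie in [0, 1)")
  }
  ids <- names(labels)
  db <- with_seed(seed, {
    sets <- list()
    informative <- sample(templates_present, g)
    for (t in seq_len(g)) {
      pool <- ids[labels == informative[t]]
      if (group_size > length(pool)) {
        .stopf("group_size (%d) exceeds sites per template (%d)",
               group_size, length(pool))
      }
      members <- sample(pool, group_size)
      n_noise <- ceiling(annotation_noise * group_size)
      if (n_noise > 0L) {
        other <- ids[labels != informative[t]]
        members <- c(members[seq_len(group_size - n_noise)],
                     sample(other, n_noise))
      }
      sets[[sprintf("KIN_I%02d", t)]] <- members
    }
    for (t in seq_len(n_groups - g)) {
      if (group_size > length(ids)) {
        .stopf("group_size (%d) exceeds the number of sites (%d)",
               group_size, length(ids))
      }
      sets[[sprintf("KIN_R%02d", t)]] <- sample(ids, group_size)
    }
    sets
  })
  annotation_db(db, species = "simulated")
}

#' Run a simulated cluster-number recovery scenario end to end
#'
#' For each replicate: simulate a matrix, simulate a matched annotation
#' database, and run the full sweep ([clue()]); record the selected optimal
#' k. Replicate seeds are derived as `seed + replicate - 1` for
#' auditability, so the whole scenario is deterministic given `seed`.
#'
#' @inheritParams simulate_phospho
#' @inheritParams simulate_annotations
#' @param replicates number of independent replicates. Default 10.
#' @param k_range,repeats,method,fuzzifier passed to [clue()].
#' @param seed base seed.
#'
#' @return A list with `optimal_k` (per replicate), `true_k`, `recovery`
#'   (fraction of replicates recovering the true k) and `uninformative`
#'   (per-replicate flags).
#' @export
run_scenario <- function(n_clusters, g, replicates = 10L,
                         sites_per_cluster = 500L, sigma = 1,
                         n_groups = 100L, group_size = 50L,
                         annotation_noise = 0, time_subset = NULL,
                         noisy_tail = 0L, k_range = 2:20, repeats = 10L,
                         method = c("cmeans", "kmeans"), fuzzifier = 2,
                         seed = 1L) {
  method <- match.arg(method)
  if (replicates < 1L) .stopf("replicates must be >= 1")
  res <- lapply(seq_len(replicates), function(r) {
    s <- seed + r - 1L
    sim <- simulate_phospho(n_clusters, sites_per_cluster, sigma,
                            time_subset = time_subset,
                            noisy_tail = noisy_tail, seed = s)
    db <- simulate_annotations(sim$labels, g = g, n_groups = n_groups,
                               group_size = group_size,
                               annotation_noise = annotation_noise,
                               seed = s + 500000L)
    fit <- clue(sim$matrix, db, k_range = k_range, repeats = repeats,
                method = method, fuzzifier = fuzzifier,
                seed = s * 1000L)
    list(optimal_k = fit$optimal_k, uninformative = fit$uninformative)
  })
  opt <- vapply(res, `[[`, integer(1), "optimal_k")
  list(optimal_k = opt,
       true_k = n_clusters,
       recovery = mean(opt == n_clusters),
       uninformative = vapply(res, `[[`, logical(1), "uninformative"))
}
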