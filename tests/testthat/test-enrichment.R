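test_that("one-sided Fisher p-values match direct enumeration of the overlap distribution", {
  # no overlap: upper tail from the minimum possible a is 1
  expect_equal(fisher_one_sided(0, 10, 10, 80), 1)
  # margins (1,1,1): both tables equally likely, tail from a=1 is 1/2
  expect_equal(fisher_one_sided(1, 0, 0, 1), 0.5)
  # 5 of 10 substrates inside a 10-site cluster of a 100-site universe;
  # frozen value computed by direct summation of the probability formula
  expect_equal(fisher_one_sided(5, 5, 5, 85), 0.0006716277482650503,
               tolerance = 1e-12)
  expect_equal(fisher_one_sided(5, 5, 5, 85),
               fisher_tail_oracle(5, 5, 5, 85), tolerance = 1e-12)
  # degenerate margins
  expect_equal(fisher_one_sided(0, 0, 10, 10), 1)
  expect_equal(fisher_one_sided(0, 10, 0, 10), 1)
  expect_error(fisher_one_sided(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher p-values agree with fisher.test and decrease in the overlap", {
  set.seed(13)
  for (rep in 1:25) {
    N <- sample(10:60, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    a <- sample(max(0, K + n - N):min(K, n), 1)
    counts <- c(a, K - a, n - a, N - K - n + a)
    ft <- fisher.test(matrix(counts, 2, byrow = TRUE),
                      alternative = "greater")$p.value
    expect_equal(fisher_one_sided(counts[1], counts[2], counts[3], counts[4]),
                 ft, tolerance = 1e-9)
  }
  # fixed margins, growing overlap: p strictly decreases
  p_seq <- vapply(0:10, function(a) {
    fisher_one_sided(a, 10 - a, 10 - a, 80 + a)
  }, numeric(1))
  expect_true(all(diff(p_seq) < 0))
})

test_that("per-cluster minimum p-value follows the convention for empty rows", {
  expect_equal(cluster_min_p(c(0.3, 0.01, 0.8)), 0.01)
  expect_equal(cluster_min_p(numeric()), 1)
  expect_equal(cluster_min_p(c(1, 1, 1)), 1)
  expect_error(cluster_min_p(c(0.5, 0)), "0, 1")
  expect_error(cluster_min_p(c(0.5, 1.2)), "0, 1")
})

test_that("Fisher combination matches the even-df closed form", {
  all_ones <- combine_fisher(rep(1, 5))
  expect_equal(all_ones$statistic, 0)
  expect_equal(all_ones$p, 1)
  expect_equal(all_ones$score, 0)

  # one p-value with 2 df: the combination returns it unchanged
  one <- combine_fisher(0.1)
  expect_equal(one$p, 0.1, tolerance = 1e-12)
  expect_equal(one$score, 1, tolerance = 1e-12)

  two <- combine_fisher(c(0.01, 0.5))
  expect_equal(two$statistic, 10.59663473309607, tolerance = 1e-12)
  expect_equal(two$p, 0.03149158683274019, tolerance = 1e-12)
  expect_equal(two$p, chisq_tail_even_df(two$statistic, 2), tolerance = 1e-12)
  expect_equal(two$df, 4L)

  expect_warning(fl <- combine_fisher(c(0, 0.5)), "floored")
  expect_true(fl$score > 0 && is.finite(fl$score))
})

test_that("combining k identical p-values is monotone in the p-value", {
  for (k in c(2, 5, 10)) {
    ps <- c(0.9, 0.5, 0.1, 0.01, 1e-6)
    scores <- vapply(ps, function(p) combine_fisher(rep(p, k))$score,
                     numeric(1))
    expect_true(all(diff(scores) > 0))
  }
})

test_that("coherent partitions outscore split partitions of the same data", {
  # 30 sites, 3 true groups of 10; 3 kinases each annotating one group
  truth <- rep(1:3, each = 10)
  ids <- sprintf("s%02d", 1:30)
  db <- annotation_db(list(KA = ids[1:10], KB = ids[11:20], KC = ids[21:30]))

  coherent <- toy_cluster_model(truth)
  aligned <- score_clustering(coherent, db)

  # split the first group across two clusters, merge the remainder oddly
  split1 <- toy_cluster_model(c(rep(1, 5), rep(2, 5), rep(2, 10), rep(3, 10)))
  expect_gt(aligned$score, score_clustering(split1, db)$score)
  # any relabeling of the coherent partition scores identically
  relabeled <- toy_cluster_model(c(3, 1, 2)[truth])
  expect_equal(score_clustering(relabeled, db)$score, aligned$score,
               tolerance = 1e-12)
})

test_that("scoring handles empty databases, site reordering, and unknown sites", {
  truth <- rep(1:3, each = 10)
  model <- toy_cluster_model(truth)
  empty <- annotation_db(list())
  tab <- score_clustering(model, empty)
  expect_equal(tab$cluster_p, rep(1, 3))
  expect_equal(tab$score, 0)

  ids <- names(model$cluster)
  db <- annotation_db(list(KA = ids[1:10], KB = ids[11:20]))
  base <- score_clustering(model, db)
  # permuting site order leaves the score unchanged
  perm <- sample(seq_along(truth))
  shuffled <- model
  shuffled$cluster <- model$cluster[perm]
  shuffled$membership <- model$membership[perm, ]
  expect_equal(score_clustering(shuffled, db)$score, base$score,
               tolerance = 1e-12)

  db_bad <- annotation_db(list(KA = c(ids[1:5], "missing1", "missing2")))
  expect_error(score_clustering(model, db_bad), "missing1")
})

test_that("enriched kinases are thresholded and sorted per cluster", {
  truth <- rep(1:2, each = 10)
  ids <- sprintf("s%02d", 1:20)
  model <- toy_cluster_model(truth)
  db <- annotation_db(list(K1 = ids[1:8], K2 = ids[c(1, 11)],
                           K3 = ids[11:18]))
  tab <- score_clustering(model, db)
  enr <- enriched_kinases(tab, alpha = 0.05)
  expect_identical(enr[[1]]$kinase, "K1")
  expect_identical(enr[[2]]$kinase, "K3")
  # alpha near 1 lists every kinase with p < alpha (K3 has p = 1 in
  # cluster 1: zero overlap, excluded)
  all_in <- enriched_kinases(tab, alpha = 0.999999)
  expect_equal(nrow(all_in[[1]]), 2L)
  expect_identical(all_in[[1]]$kinase, c("K1", "K2"))
  expect_true(all(diff(all_in[[1]]$p) >= 0))
  # empty table -> empty lists
  empty <- score_clustering(model, annotation_db(list()))
  expect_true(all(vapply(enriched_kinases(empty), nrow, integer(1)) == 0L))
})

test_that("min-max normalization rescales to [0,1] in both directions", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(2, 4, 6), "minimize"), c(1, 0.5, 0))
  set.seed(3)
  s <- minmax_normalize(rnorm(20))
  expect_equal(range(s), c(0, 1))
  expect_error(minmax_normalize(c(3, 3, 3)), "equal")
  expect_error(minmax_normalize(5), "two scores")
})
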