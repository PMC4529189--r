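test_that("the template library holds 14 distinct 7-point patterns", {
  tl <- temporal_templates()
  expect_equal(dim(tl), c(14L, 7L))
  z <- standardize_rows(tl)
  d <- dist(z)
  expect_true(all(d > 1))  # mutually distinct after standardization
  expect_false(anyDuplicated(rownames(tl)) > 0)
})

test_that("simulated matrices have the designed size and composition", {
  sim4 <- simulate_phospho(4, sites_per_cluster = 500, seed = 1)
  expect_equal(nrow(sim4$matrix), 2000L)
  expect_equal(ncol(sim4$matrix), 7L)
  expect_equal(unname(table(sim4$labels)), rep(500L, 4), ignore_attr = TRUE)

  sim14 <- simulate_phospho(14, sites_per_cluster = 500, seed = 1)
  expect_equal(nrow(sim14$matrix), 7000L)
  expect_length(unique(sim14$labels), 14L)

  expect_error(simulate_phospho(15, seed = 1), "2, 14")
  expect_error(simulate_phospho(1, seed = 1), "2, 14")
})

test_that("zero noise reproduces the templates exactly; generation is seed-stable", {
  tl <- temporal_templates()
  sim <- simulate_phospho(3, sites_per_cluster = 5, sigma = 0, seed = 8)
  for (i in seq_along(sim$labels)) {
    expect_equal(unname(sim$matrix[i, ]), unname(tl[sim$labels[i], ]))
  }
  again <- simulate_phospho(3, sites_per_cluster = 5, sigma = 0, seed = 8)
  expect_identical(sim, again)
  noisy <- simulate_phospho(3, sites_per_cluster = 5, sigma = 1, seed = 8)
  expect_identical(simulate_phospho(3, sites_per_cluster = 5, seed = 8),
                   noisy)
})

test_that("site noise is centred on the template (law of large numbers)", {
  tl <- temporal_templates()
  sim <- simulate_phospho(2, sites_per_cluster = 1000, sigma = 1, seed = 2)
  for (tmpl in unique(sim$labels)) {
    rows <- sim$matrix[sim$labels == tmpl, ]
    expect_equal(unname(colMeans(rows)), unname(tl[tmpl, ]),
                 tolerance = 3 / sqrt(1000) * 4)  # ~4 SEs, all 7 points
  }
})

test_that("time subsetting and noisy tails reshape the matrix as declared", {
  sub <- simulate_phospho(3, sites_per_cluster = 10, seed = 5,
                          time_subset = c(1, 4, 7))
  expect_equal(colnames(sub$matrix), c("t1", "t4", "t7"))
  tl <- temporal_templates()
  flat <- simulate_phospho(3, sites_per_cluster = 200, seed = 5,
                           noisy_tail = 2)
  # the two replaced trailing columns are pure noise about 0
  tail_cols <- flat$matrix[, 6:7]
  expect_lt(abs(mean(tail_cols)), 0.1)
  expect_equal(sd(as.numeric(tail_cols)), 1, tolerance = 0.1)
  expect_error(simulate_phospho(3, sites_per_cluster = 5, seed = 1,
                                time_subset = c(1, 4), noisy_tail = 2),
               "noisy_tail")
})

test_that("simulated annotation databases follow the group design", {
  sim <- simulate_phospho(4, sites_per_cluster = 100, seed = 3)
  db <- simulate_annotations(sim$labels, g = 4, n_groups = 100,
                             group_size = 50, seed = 3)
  expect_length(db, 100L)
  expect_true(all(lengths(db) == 50L))
  expect_equal(sum(startsWith(names(db), "KIN_I")), 4L)

  # noise-free informative groups are label-pure
  for (kin in names(db)[startsWith(names(db), "KIN_I")]) {
    expect_length(unique(sim$labels[db[[kin]]]), 1L)
  }
  # informative groups cover distinct templates
  tmpl <- vapply(names(db)[startsWith(names(db), "KIN_I")],
                 function(kin) unique(sim$labels[db[[kin]]])[1], integer(1))
  expect_length(unique(tmpl), 4L)

  # g = 0: every group is a uniform sample, none informative
  db0 <- simulate_annotations(sim$labels, g = 0, n_groups = 20,
                              group_size = 30, seed = 3)
  expect_true(all(startsWith(names(db0), "KIN_R")))
  purity <- vapply(db0, function(s) {
    max(table(sim$labels[s])) / length(s)
  }, numeric(1))
  expect_true(all(purity < 0.9))
})

test_that("annotation noise mis-assigns exactly the requested fraction", {
  sim <- simulate_phospho(4, sites_per_cluster = 100, seed = 3)
  # the template owned by each informative group is fixed by the seed, so
  # read it off the noise-free database built under the same seed
  clean <- simulate_annotations(sim$labels, g = 4, n_groups = 10,
                                group_size = 50, seed = 3)
  informative <- names(clean)[startsWith(names(clean), "KIN_I")]
  own <- vapply(informative,
                function(kin) unique(sim$labels[clean[[kin]]])[1], integer(1))
  for (nz in c(0.1, 0.2, 0.4, 0.8)) {
    db <- simulate_annotations(sim$labels, g = 4, n_groups = 10,
                               group_size = 50, annotation_noise = nz,
                               seed = 3)
    for (kin in informative) {
      labs <- sim$labels[db[[kin]]]
      expect_length(labs, 50L)
      expect_equal(sum(labs != own[[kin]]), ceiling(nz * 50))
    }
  }
  expect_error(simulate_annotations(sim$labels, g = 5, seed = 1), "0, 4")
  expect_error(simulate_annotations(sim$labels, g = 2, group_size = 101,
                                    n_groups = 3, seed = 1), "exceeds")
})

test_that("impoverished time designs lead to underestimated cluster numbers", {
  # three retained time points collapse several templates into similar
  # shapes, so the selected k falls below the simulated truth
  sparse <- run_scenario(8, g = 8, replicates = 3, sites_per_cluster = 200,
                         time_subset = c(1, 4, 7), seed = 11)
  expect_true(all(sparse$optimal_k < 8))
  # trailing pure-noise time points likewise cost resolution
  tail2 <- run_scenario(8, g = 8, replicates = 3, sites_per_cluster = 200,
                        noisy_tail = 2, seed = 11)
  expect_true(all(tail2$optimal_k <= 8))
})
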