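test_that("Overton subtraction has the right fixed points and bounds", {
  edges <- 0:10
  same <- histogram_pair(edges, rep(10, 10), rep(10, 10))
  expect_equal(overton_percent_positive(same), 0)

  disjoint <- histogram_pair(edges, c(rep(0, 5), rep(20, 5)), c(rep(20, 5), rep(0, 5)))
  expect_equal(overton_percent_positive(disjoint), 100)

  half <- histogram_pair(edges, c(rep(10, 5), rep(10, 5)), c(rep(20, 5), rep(0, 5)))
  expect_equal(overton_percent_positive(half), 50)

  expect_error(histogram_pair(edges, rep(1, 9), rep(1, 10)),
               class = "poolscreen_invalid_input")
  expect_error(histogram_pair(c(0, 1, 1, 2), rep(1, 3), rep(1, 3)),
               class = "poolscreen_invalid_input")
})

test_that("Overton recovers the shifted fraction of a synthetic mixture", {
  ev <- simulate_flow_events(n_events = 10000, shifted_fraction = 0.5,
                             shift = 6, seed = 9)
  est <- overton_percent_positive(ev$sample, ev$control, bins = 256)
  expect_lt(abs(est - 50), 2)
  # Monte-Carlo oracle: the realized shifted fraction
  expect_lt(abs(est - 100 * ev$truth$n_shifted / 10000), 2)
})

test_that("Overton is monotone in the location shift and bounded", {
  prev <- -Inf
  for (shift in c(0, 0.5, 1, 2, 4, 8)) {
    ev <- simulate_flow_events(n_events = 5000, shifted_fraction = 1,
                               shift = shift, seed = 3)
    est <- overton_percent_positive(ev$sample, ev$control, bins = 256)
    expect_gte(est, prev - 1e-9)
    expect_gte(est, 0)
    expect_lte(est, 100)
    prev <- est
  }
  expect_gt(prev, 95)    # fully shifted far mixture approaches 100
})

test_that("GFP-positive area counts background-subtracted suprathreshold pixels", {
  expect_equal(gfp_positive_area(matrix(0, 5, 5), 0, threshold = 1), 0)
  expect_equal(gfp_positive_area(matrix(60, 5, 5), background = 10, threshold = 50), 1)
  img <- matrix(10, 4, 4); img[1:2, 1] <- 100
  expect_equal(gfp_positive_area(img, background = 10, threshold = 50), 2 / 16)
  expect_error(gfp_positive_area(matrix(1, 2, 2), 0, threshold = 0),
               class = "poolscreen_invalid_config")
  expect_error(gfp_positive_area(matrix(numeric(0), 0, 0), 0, 1),
               class = "poolscreen_invalid_input")
})

test_that("well Z-scores standardize against the whole experiment", {
  r <- tibble::tibble(pool_index = 1:3, replicate = 1L, signal = c(1, 2, 3))
  z <- well_zscores(r)
  expect_equal(z$z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)  # population SD
  expect_equal(round(z$z[3], 4), 1.2247)

  const <- tibble::tibble(pool_index = 1:4, replicate = 1L, signal = rep(2, 4))
  expect_error(well_zscores(const), class = "poolscreen_degenerate_experiment")

  sim <- withr::with_seed(5, tibble::tibble(pool_index = rep(1:40, each = 2),
                                            replicate = rep(1:2, 40),
                                            signal = rnorm(80, 3, 2)))
  z80 <- well_zscores(sim)
  expect_lt(abs(mean(z80$z)), 1e-9)
  expect_lt(abs(sqrt(mean(z80$z^2)) - 1), 1e-9)
})

test_that("replicate aggregation is a shifted geometric mean", {
  z <- tibble::tibble(pool_index = c(1, 1, 2, 2, 3), z = c(2, 2, 0, 8, 1.5))
  s <- aggregate_replicates(z, offset = 10)
  expect_equal(s$score[s$pool_index == 1], 2)
  expect_equal(s$score[s$pool_index == 2], sqrt(10 * 18) - 10)   # ~3.4164
  expect_equal(s$score[s$pool_index == 3], 1.5)                  # single replicate
  expect_error(aggregate_replicates(tibble::tibble(pool_index = 1, z = -11),
                                    offset = 10),
               class = "poolscreen_offset_too_small")
})

test_that("positive-well calling thresholds the aggregated score", {
  s <- tibble::tibble(pool_index = c(1, 2), score = c(5, 0.1))
  expect_equal(call_positive_wells(s, 3), 1L)
  expect_equal(call_positive_wells(s, Inf), integer(0))
  expect_equal(call_positive_wells(s, -Inf), c(1L, 2L))
})

test_that("deconvolution scores targets by signature support", {
  d <- fig_design
  # full signature positive -> unique exact candidate
  sig <- signature(d, "T07")
  cand <- deconvolute(d, sig)
  expect_identical(cand$target_id[1], "T07")
  expect_true(cand$exact[1])
  expect_equal(sum(cand$exact), 1)

  # half the signature positive -> support 0.5, not exact
  cand_half <- deconvolute(d, sig[1])
  row <- cand_half[cand_half$target_id == "T07", ]
  expect_equal(row$support, 0.5)
  expect_false(row$exact)

  # positives from the union of two disjoint signatures -> both exact
  sigs <- lapply(d$target_ids, function(id) signature(d, id))
  names(sigs) <- d$target_ids
  pair <- NULL
  for (i in seq_along(sigs)) {
    for (j in seq_along(sigs)) {
      if (j <= i) next
      if (length(intersect(sigs[[i]], sigs[[j]])) == 0) pair <- c(i, j)
    }
  }
  expect_false(is.null(pair))
  both <- deconvolute(d, union(sigs[[pair[1]]], sigs[[pair[2]]]))
  exact_ids <- both$target_id[both$exact]
  expect_true(all(d$target_ids[pair] %in% exact_ids))
  # any further exact candidate must have its signature inside the union too
  for (id in exact_ids) {
    expect_true(all(sigs[[id]] %in% union(sigs[[pair[1]]], sigs[[pair[2]]])))
  }

  # empty positive set -> no-candidates result, not an error
  none <- deconvolute(d, integer(0))
  expect_equal(nrow(none), 0)
})

test_that("the full analysis chain recovers a simulated cognate target", {
  d <- fig_design
  sim <- simulate_screen(d, true_targets = "T11", mu_pos = 10, mu_neg = 1,
                         sigma = 1, seed = 4)
  res <- analyze_screen(sim$readouts, d, z_threshold = 1)
  expect_s3_class(res, "screen_result")
  expect_equal(sort(res$positive_pools), sim$truth$positive_pools)
  expect_identical(tidy(res)$target_id[1], "T11")
  expect_true(tidy(res)$exact[1])
  g <- glance(res)
  expect_equal(g$top_candidate, "T11")
  expect_equal(g$n_exact, 1)
})
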