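test_that("a frozen process yields maps with no anagenetic events", {
  tr <- simulate_tree(0.3, 0, 10, seed = 2)
  sts <- setNames(rep("E", 10), tr$tip.label)
  fit <- list(family = "DEC", params = c(d = 0, e = 0, j = 0))
  maps <- sample_maps(tr, sts, fit, n_maps = 5, seed = 3)
  ev <- extract_events(maps)
  expect_false(any(ev$type %in% c("dispersal", "extirpation")))
  expect_true(all(vapply(maps, function(h) h$root_state, "") == "E"))
})

test_that("stochastic mapping is deterministic given a seed", {
  set.seed(61)
  tr <- simulate_tree(0.2, 0.05, 25)
  h <- simulate_range_evolution(tr, 0.06, 0.02, 0, "DEC")
  fit <- list(family = "DEC", params = c(d = 0.06, e = 0.02, j = 0))
  m1 <- sample_maps(tr, h$tip_states, fit, n_maps = 4, seed = 10)
  m2 <- sample_maps(tr, h$tip_states, fit, n_maps = 4, seed = 10)
  expect_identical(extract_events(m1), extract_events(m2))
})

test_that("uniformization matches Gillespie simulation in expectation", {
  # endpoint-marginalized uniformization paths (endpoint drawn from P(t))
  # must reproduce the unconditional forward process event counts
  Q <- anagenetic_generator(0.08, 0.04)
  t_br <- 5
  P <- hotspotdiv:::ctmc_transition(Q, t_br)
  set.seed(71)
  n_rep <- 4000
  unif_counts <- replicate(n_rep, {
    b <- sample.int(7, 1, prob = P[1, ])
    nrow(hotspotdiv:::sample_ctmc_path(Q, 1L, b, t_br))
  })
  gil_counts <- replicate(n_rep, {
    p <- hotspotdiv:::.sim_ctmc_path(Q, 1L, t_br)
    if (is.null(p$jumps)) 0L else nrow(p$jumps)
  })
  se <- sqrt(var(unif_counts) / n_rep + var(gil_counts) / n_rep)
  expect_lt(abs(mean(unif_counts) - mean(gil_counts)), 3 * se)
})

test_that("lineage counts reduce to the lineages-through-time curve", {
  tr <- simulate_tree(0.4, 0, 40, seed = 5)
  sts <- setNames(rep("H", 40), tr$tip.label)
  fit <- list(family = "DEC", params = c(d = 0, e = 0, j = 0))
  maps <- sample_maps(tr, sts, fit, n_maps = 3, seed = 1)
  root_age <- max(ape::node.depth.edgelength(tr))
  bins <- time_bins(0, floor(root_age), 1)
  cnt <- lineage_counts(maps, "H", bins)
  # oracle: count branches spanning each boundary directly on the tree
  depths <- ape::node.depth.edgelength(tr)
  age <- root_age - depths
  tr2 <- ape::reorder.phylo(tr, "postorder")
  ltt <- vapply(bins$end, function(tau)
    sum(age[tr2$edge[, 1]] >= tau & age[tr2$edge[, 2]] < tau), numeric(1))
  expect_equal(cnt$median, ltt)
  # counts never occupied region are all zero
  expect_true(all(lineage_counts(maps, "E", bins)$median == 0))
  # pure-birth single-region counts are non-decreasing toward the present
  expect_true(all(diff(rev(cnt$median)) >= 0))
})

test_that("dispersal rate series divide binned event medians by older-bin lineages", {
  bins <- time_bins(2, 8, 2)  # three bins
  counts <- list(per_map = matrix(c(10, 8, 6), 5, 3, byrow = TRUE),
                 median = c(10, 8, 6), bins = bins, region = "H")
  ev <- do.call(rbind, lapply(1:5, function(m)
    data.frame(map = m, type = "dispersal", age = rep(3, 4),
               source = "N", destination = "H")))
  rs <- dispersal_rate_series(ev, counts, "N", "H", bins, n_maps = 5,
                              lineage_floor = 2)
  expect_equal(rs$median[1], 4 / 8)    # events in [2,4) over lineages at [4,6)
  expect_equal(rs$median[2], 0)
  expect_true(is.na(rs$median[3]))     # no older bin available
  expect_error(dispersal_rate_series(ev, counts, "H", "H", bins, 5), "differ")
  # no events anywhere: zero rates wherever the denominator is defined
  ev0 <- ev[0, ]
  rs0 <- dispersal_rate_series(ev0, counts, "N", "H", bins, n_maps = 5,
                               lineage_floor = 2)
  expect_equal(rs0$median[1:2], c(0, 0))
})

test_that("rate series mask bins at or below the lineage floor", {
  bins <- time_bins(2, 8, 2)
  counts <- list(per_map = matrix(c(20, 10, 3), 4, 3, byrow = TRUE),
                 median = c(20, 10, 3), bins = bins, region = "H")
  ev <- data.frame(map = 1, type = "dispersal", age = 5, source = "N",
                   destination = "H")
  rs <- dispersal_rate_series(ev, counts, "N", "H", bins, n_maps = 4,
                              lineage_floor = 9)
  expect_true(is.na(rs$median[2]))     # denominator 3 <= floor of 9
  expect_false(is.na(rs$median[1]))    # denominator 10 > 9 stays defined
  rs10 <- dispersal_rate_series(ev, counts, "N", "H", bins, n_maps = 4,
                                lineage_floor = 10)
  expect_true(is.na(rs10$median[1]))   # the floor itself is masked
})

test_that("standardized differences use the pooled SD and percentile intervals", {
  bins <- time_bins(2, 6, 2)
  mk <- function(m) structure(list(bins = bins, per_map = m,
                                   median = apply(m, 2, median),
                                   q10 = apply(m, 2, quantile, 0.1),
                                   q90 = apply(m, 2, quantile, 0.9),
                                   series = "x"), class = "rate_series")
  a <- mk(matrix(c(1, 2, 1, 2, 1, 2), 3, 2))
  d0 <- standardized_difference(a, a)
  expect_equal(d0$delta_median, c(0, 0))
  expect_equal(d0$delta_q10, c(0, 0)); expect_equal(d0$delta_q90, c(0, 0))
  expect_equal(unname(d0$aggregate["median"]), 0)
  # standardization divides the constant offset by the pooled SD
  b <- mk(a$per_map + 2)
  d1 <- standardized_difference(b, a)
  s_pool <- sd(c(a$per_map, a$per_map + 2))
  expect_equal(unname(d1$delta_median), rep(2 / s_pool, 2), tolerance = 1e-12)
  expect_equal(d1$pooled_sd, s_pool)
  const <- mk(matrix(1, 3, 2))
  expect_error(standardized_difference(const, const), "zero")
})

test_that("colonization ages read the oldest occupancy of a region", {
  tr <- simulate_tree(0.3, 0, 15, seed = 9)
  sts <- setNames(rep("H", 15), tr$tip.label)
  fit <- list(family = "DEC", params = c(d = 0, e = 0, j = 0))
  maps <- sample_maps(tr, sts, fit, n_maps = 3, seed = 2)
  root_age <- max(ape::node.depth.edgelength(tr))
  ca <- colonization_age(maps, "H")
  expect_equal(ca$median, root_age, tolerance = 1e-9)
  expect_error(colonization_age(maps, "E"), "never occupied")
})

test_that("map event counts calibrate against the generating truth", {
  set.seed(81)
  types <- c("dispersal", "extirpation", "sympatry", "vicariance")
  R <- 12
  diffs <- matrix(NA_real_, R, 4, dimnames = list(NULL, types))
  for (i in seq_len(R)) {
    tr <- simulate_tree(0.15, 0.05, 40)
    h <- simulate_range_evolution(tr, 0.05, 0.02, 0, "DEC")
    fit <- list(family = "DEC", params = c(d = 0.05, e = 0.02, j = 0),
                condition_survival = TRUE)
    maps <- sample_maps(tr, h$tip_states, fit, n_maps = 8)
    cm <- table(factor(extract_events(maps)$type, types)) / 8
    ct <- table(factor(extract_events(h)$type, types))
    diffs[i, ] <- as.numeric(cm - ct)
  }
  z <- colMeans(diffs) / (apply(diffs, 2, sd) / sqrt(R))
  expect_true(all(abs(z) < 4))
})
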