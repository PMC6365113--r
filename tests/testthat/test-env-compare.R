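test_that("terrain ruggedness matches hand-evaluated pixel neighborhoods", {
  flat <- matrix(5, 6, 6)
  cell_of <- matrix(rep(1:4, each = 9)[1:36], 6, 6)
  expect_true(all(terrain_ruggedness(flat, cell_of) == 0))
  # 3x3 grid, center 1, ring 0; one "cell" per pixel
  e <- matrix(0, 3, 3); e[2, 2] <- 1
  tri <- terrain_ruggedness(e, matrix(1:9, 3, 3))
  expect_equal(unname(tri["5"]), 1)          # center: all 8 neighbors differ
  expect_equal(unname(tri["1"]), 1 / 3)      # corner: 3 neighbors, one is 1
  expect_equal(unname(tri["2"]), 1 / 5)      # edge: 5 neighbors, one is 1
  # translation invariance
  expect_equal(terrain_ruggedness(e + 100, matrix(1:9, 3, 3)), tri)
  expect_error(terrain_ruggedness(matrix(1, 1, 1), matrix(1L)), "single-pixel")
})

test_that("climate velocity is the temporal rate over the spatial gradient", {
  cells <- grid_cells(8, 8)
  pres <- setNames(3 * cells$x, cells$cell_id)          # slope 3 per 100 km
  past <- pres - 6                                       # uniform change
  ccv <- climate_velocity(pres, past, cells, elapsed = 2, cell_km = 100,
                          floor = 1e-12)
  expect_equal(unname(ccv), rep((6 / 2) / 0.03, 64))     # gradient 0.03/km
  expect_equal(unname(climate_velocity(pres, pres, cells, 2, 100, 1e-12)),
               rep(0, 64))
  # doubling the spatial slope halves the velocity
  ccv2 <- climate_velocity(2 * pres, 2 * pres - 6, cells, 2, 100, 1e-12)
  expect_equal(unname(ccv2), unname(ccv) / 2)
  flat <- setNames(rep(1, 64), cells$cell_id)
  expect_error(climate_velocity(flat, flat - 1, cells, 2, 100, NULL),
               "gradient")
})

test_that("tectonic movement pools per-neighbor distance SDs and honors isometry", {
  cells <- data.frame(x = c(1, 2), y = 1, cell_id = c("a", "b"))
  traj <- array(0, c(2, 2, 2))
  traj[, 1, 1] <- c(0, 100); traj[, 2, 1] <- c(0, 102)   # 100 -> 102 km apart
  tm <- tectonic_movement(traj, cells, radius_km = 1000)
  expect_equal(unname(tm), rep(sqrt(2), 2))
  # rigid translation of everything: all distances preserved
  cells3 <- grid_cells(4, 4)
  base <- cbind(cells3$x, cells3$y) * 100
  traj3 <- array(0, c(16, 3, 2))
  for (tt in 1:3) traj3[, tt, ] <- base + (tt - 1) * c(500, 300)[1]
  tm3 <- tectonic_movement(traj3, cells3)
  expect_true(all(abs(tm3) < 1e-9))
  expect_error(tectonic_movement(array(0, c(2, 1, 2)), cells), "2 time")
})

test_that("the correlation screen drops the later-listed of a correlated pair", {
  cells <- grid_cells(6, 6)
  set.seed(51)
  v1 <- rnorm(36)
  env <- rbind(
    data.frame(cell_id = cells$cell_id, variable = "alpha", value = v1),
    data.frame(cell_id = cells$cell_id, variable = "beta", value = rnorm(36)),
    data.frame(cell_id = cells$cell_id, variable = "gamma",
               value = 2 * v1 + 0.01 * rnorm(36)))
  out <- screen_correlated(env, 0.70)
  expect_equal(attr(out, "dropped"), "gamma")
  expect_setequal(unique(out$variable), c("alpha", "beta"))
})

test_that("environmental SAR contrasts standardize, test and correct per family", {
  cells <- grid_cells(10, 10)
  W <- spatial_weights(cells, 100, 1000)
  part <- region_partition(cells$cell_id, cells$x <= 3)
  hot <- as.numeric(cells$x <= 3)
  set.seed(52)
  env <- rbind(
    data.frame(cell_id = cells$cell_id, variable = "strong",
               value = 3 * hot + rnorm(100)),
    data.frame(cell_id = cells$cell_id, variable = "nil",
               value = rnorm(100)))
  res <- env_sar_contrast(env, part, W)
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 2))
  expect_true(res$significant[res$variable == "strong"])
  expect_gt(res$beta[res$variable == "strong"], 0)
  sc <- attr(res, "scaling")
  expect_named(sc$strong, c("mean", "sd"))
  # zero-variance variables are skipped with a warning
  env2 <- rbind(env, data.frame(cell_id = cells$cell_id, variable = "const",
                                value = 1))
  expect_warning(res2 <- env_sar_contrast(env2, part, W), "zero variance")
  expect_false("const" %in% res2$variable)
})

test_that("with zero weights the standardized contrast equals the OLS contrast", {
  cells <- grid_cells(8, 8)
  W <- spatial_weights(cells, 100, 1000)
  W$W[] <- 0; W$eigenvalues[] <- 0
  part <- region_partition(cells$cell_id, cells$x <= 2)
  hot <- as.numeric(cells$x <= 2)
  set.seed(53)
  y <- 1.2 * hot + rnorm(64)
  env <- data.frame(cell_id = cells$cell_id, variable = "v", value = y)
  res <- env_sar_contrast(env, part, W)
  z <- (y - mean(y)) / sd(y)
  expect_equal(res$beta, unname(coef(lm(z ~ hot))[2]), tolerance = 1e-8)
})
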