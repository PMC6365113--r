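test_that("DR equals the hand-computed inverse equal-splits values", {
  t2 <- ape::read.tree(text = "(a:2.5,b:2.5);")
  expect_equal(unname(compute_dr(t2)), rep(1 / 2.5, 2))
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(unname(compute_dr(bal)), rep(2 / 3, 4))  # ES = 1 + 1/2
  cat4 <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1);")
  dr <- compute_dr(cat4)
  expect_equal(unname(dr["a"]), 1 / 1.75)   # 3 edges: 1 + 1/2 + 1/4
  expect_equal(unname(dr["b"]), 4 / 7)
  expect_equal(unname(dr["c"]), 2 / 3)      # 2 edges: 1 + 1/2
  expect_equal(unname(dr["d"]), 1)          # single unit edge
})

test_that("DR is scale-equivariant and invariant to relabeling and ladderization", {
  set.seed(14)
  tr <- simulate_tree(0.3, 0.1, 20)
  dr <- compute_dr(tr)
  tr3 <- tr; tr3$edge.length <- tr$edge.length * 3.7
  expect_equal(compute_dr(tr3), dr / 3.7)
  expect_equal(compute_dr(ape::ladderize(tr))[names(dr)], dr)
})

test_that("quartile assignment splits near-equally with documented remainders", {
  dr8 <- setNames((1:8) / 10, paste0("s", 1:8))
  q8 <- assign_quartiles(dr8)
  expect_equal(as.vector(table(q8)), rep(2L, 4))
  expect_setequal(names(q8)[q8 == "Q1"], c("s1", "s2"))
  dr5 <- setNames((1:5) / 10, paste0("s", 1:5))
  q5 <- assign_quartiles(dr5)
  expect_equal(as.vector(table(q5)), c(2L, 1L, 1L, 1L))
  expect_warning(qt <- assign_quartiles(setNames(rep(1, 4), letters[1:4])),
                 "equal")
  expect_equal(unname(qt[order(names(qt))]),
               factor(paste0("Q", 1:4), paste0("Q", 1:4)))
})

test_that("quartile regressions have OLS residual structure and detect planted excess", {
  occ <- random_occ(80, 8, 8, seed = 6)
  dr <- setNames(runif(80), occ$species)
  q <- assign_quartiles(dr)
  res <- quartile_residuals(occ, q)
  expect_equal(sum(res$resid_q1), 0, tolerance = 1e-8)
  expect_equal(sum(res$resid_q4), 0, tolerance = 1e-8)
  expect_lt(abs(sum(res$resid_q4 * res$sr)), 1e-6 * sd(res$sr) * nrow(res))
  # perfect-fit case: q1 exactly a quarter of SR in every cell
  cells <- grid_cells(4, 4)
  pres <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(species = sprintf("sp%02d", 1:(4 * cells$x[i])),
               cell_id = cells$cell_id[i])))
  occ2 <- occurrence_grid(pres, cells, 100)
  qq <- setNames(factor(paste0("Q", rep(1:4, 4)), paste0("Q", 1:4)),
                 sprintf("sp%02d", 1:16))
  res2 <- quartile_residuals(occ2, qq)
  expect_equal(res2$resid_q1, rep(0, nrow(res2)), tolerance = 1e-10)
  expect_error(quartile_residuals(occ_from_list(list(A = c("c1", "c2"))), qq),
               "constant")
})

test_that("the Hodges-Lehmann contrast enumerates pairwise differences", {
  vals <- setNames(c(3, 4, 1, 2), sprintf("c%d", 1:4))
  part <- region_partition(sprintf("c%d", 1:4), c(TRUE, TRUE, FALSE, FALSE))
  ct <- hotspot_contrast(vals, part)
  expect_equal(ct$estimate, 2)   # pairwise diffs {1, 2, 2, 3}
  expect_equal(ct$n_hot, 2); expect_equal(ct$n_non, 2)
  # location-shift consistency and interval coverage of the true shift
  set.seed(9)
  x <- rnorm(300); y <- rnorm(300) + 1
  ids <- sprintf("c%d", 1:600)
  part2 <- region_partition(ids, rep(c(TRUE, FALSE), each = 300))
  ct2 <- hotspot_contrast(setNames(c(y, x), ids), part2)
  expect_lt(abs(ct2$estimate - 1), 0.3)
  expect_true(ct2$conf.int[1] < 1 && 1 < ct2$conf.int[2])
  expect_error(hotspot_contrast(vals, region_partition(sprintf("c%d", 1:4),
                                                       rep(TRUE, 4))),
               "2 cells")
})

test_that("branch rates average descendant tip DR and import from CSV", {
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  dr <- setNames(c(1, 2, 3, 4), c("a", "b", "c", "d"))
  br <- dr_branch_rates(bal, dr)
  tipedge <- match(1:4, bal$edge[, 2])
  expect_equal(br[tipedge], unname(dr[bal$tip.label]))
  inner <- setdiff(seq_len(nrow(bal$edge)), tipedge)
  expect_setequal(br[inner], c(mean(dr[c("a", "b")]), mean(dr[c("c", "d")])))
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(child = bal$edge[, 2], rate = br), tmp,
            row.names = FALSE)
  expect_equal(read_branch_rates(tmp, bal), br)
})
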