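test_that("anagenetic generator has the expected transition structure", {
  Q <- anagenetic_generator(0.1, 0.05)
  expect_equal(rowSums(Q), rep(0, 7), tolerance = 1e-12,
               ignore_attr = TRUE)
  offdiag <- Q - diag(diag(Q))
  expect_true(all(offdiag >= 0))
  expect_equal(Q["H", "HN"], 0.1)
  expect_equal(Q["H", "HE"], 0.1)
  expect_equal(Q["HN", "H"], 0.05)   # loss of N
  expect_equal(Q["HN", "N"], 0.05)   # loss of H
  expect_equal(Q["H", "null"], 0.05) # extirpation of the only area
  expect_equal(unname(Q["null", ]), rep(0, 7))  # null absorbing
  # range-size cap: two-area ranges cannot gain
  expect_equal(Q["HN", "HE"], 0); expect_equal(Q["HN", "NE"], 0)
  expect_equal(anagenetic_generator(0, 0), matrix(0, 7, 7),
               ignore_attr = TRUE)
})

test_that("directional dispersal matrices feed the generator per ordered pair", {
  d <- matrix(0.01, 3, 3); d[2, 1] <- 0.09  # N -> H
  Q <- anagenetic_generator(d, 0)
  expect_equal(Q["N", "HN"], 0.09)
  expect_equal(Q["H", "HN"], 0.01)
})

test_that("cladogenetic weight tables match the family definitions", {
  states <- biogeo_states()
  for (fam in c("DEC", "DIVALIKE", "BAYAREALIKE")) for (j in c(0, 0.8, 2)) {
    tabs <- cladogenetic_weights(fam, j)
    for (i in 1:6) expect_equal(sum(tabs[[i]][, "prob"]), 1, tolerance = 1e-12)
  }
  dec <- cladogenetic_weights("DEC", 0)
  # two-area DEC parent: 4 subset-sympatry + 2 vicariance outcomes, each 1/6
  hn <- dec[["HN"]]
  expect_equal(nrow(hn), 6)
  expect_equal(unname(hn[, "prob"]), rep(1 / 6, 6))
  got <- sort(paste(states[hn[, 1]], states[hn[, 2]]))
  expect_equal(got, sort(c("H HN", "N HN", "HN H", "HN N", "H N", "N H")))
  # single-area parent: forced sympatric copy
  expect_equal(unname(dec[["H"]]), matrix(c(1, 1, 1), 1),
               ignore_attr = TRUE)
  # DIVALIKE two-area parent: vicariance only
  diva <- cladogenetic_weights("DIVALIKE", 0)[["HE"]]
  expect_equal(sort(paste(states[diva[, 1]], states[diva[, 2]])),
               sort(c("H E", "E H")))
  # BAYAREALIKE: full-range copy
  bay <- cladogenetic_weights("BAYAREALIKE", 0)[["HN"]]
  expect_equal(unname(bay), matrix(c(4, 4, 1), 1), ignore_attr = TRUE)
})

test_that("founder events appear only with j > 0 and are typed correctly", {
  t0 <- describe_model("DEC", 0)
  expect_false(any(t0$type == "founder"))
  t1 <- describe_model("DEC", 1.5)
  f <- t1[t1$parent == "HN" & t1$type == "founder", ]
  expect_true(all(f$left == "E" | f$right == "E"))
  expect_equal(classify_clado(4, 1, 2), "vicariance")  # HN -> (H, N)
  expect_equal(classify_clado(1, 1, 1), "sympatry")
  expect_equal(classify_clado(1, 1, 3), "founder")     # H -> (H, E)
})

test_that("pruning equals exhaustive enumeration on all small trees and families", {
  set.seed(42)
  for (nt in 3:5) {
    tr <- simulate_tree(0.3, 0.1, nt)
    sts <- setNames(sample(biogeo_states(), nt, replace = TRUE), tr$tip.label)
    for (fam in c("DEC", "DIVALIKE", "BAYAREALIKE")) for (j in c(0, 1.2)) {
      d <- runif(1, 0.01, 0.3); e <- runif(1, 0, 0.2)
      l1 <- tree_likelihood(tr, sts, fam, d, e, j)
      l2 <- brute_loglik(tr, sts, fam, d, e, j)
      expect_lt(abs(l1 - l2) / abs(l2), 1e-10)
    }
  }
})

test_that("likelihood is invariant to the order of children at a node", {
  set.seed(5)
  tr <- simulate_tree(0.3, 0, 6)
  sts <- setNames(sample(biogeo_states(), 6, replace = TRUE), tr$tip.label)
  l1 <- tree_likelihood(tr, sts, "DEC", 0.1, 0.03, 0.5)
  tr2 <- ape::rotate(tr, 7)   # swap the root's children
  l2 <- tree_likelihood(tr2, sts, "DEC", 0.1, 0.03, 0.5)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("frozen process reduces the likelihood to the root prior", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(tree_likelihood(tr, c(a = "H", b = "H"), "DEC", 0, 0),
               log(1 / 6))
  expect_equal(tree_likelihood(tr, c(a = "E", b = "E"), "BAYAREALIKE", 0, 0),
               log(1 / 6))
  # discordant single-area tips under frozen DEC: only root HN vicariance
  # explains them, prior 1/6 times outcome weight 1/6
  expect_equal(tree_likelihood(tr, c(a = "H", b = "N"), "DEC", 0, 0),
               log(1 / 36))
  # under BAYAREALIKE (no vicariance) the same data are impossible
  expect_error(tree_likelihood(tr, c(a = "H", b = "N"), "BAYAREALIKE", 0, 0),
               "zero")
})

test_that("AICc follows the closed formula and model tables rank correctly", {
  expect_equal(aicc(-10, 2, 10), 24 + 12 / 7)
  expect_error(aicc(-10, 9, 10), "undefined")
  fake <- function(a, d = 1) structure(
    list(family = "DEC", founder = FALSE, params = c(d = d, e = 0, j = 0),
         loglik = -a / 2, k = 2, n = 50, aicc = a, data_hash = 1),
    class = "biogeo_fit")
  tb <- model_table(list(m1 = fake(100), m2 = fake(100)))
  expect_equal(tb$weight, c(0.5, 0.5))
  tb2 <- model_table(list(m1 = fake(100), m2 = fake(102)))
  expect_equal(tb2$weight, c(0.731, 0.269), tolerance = 1e-3)
  expect_true(tb2$best[1] && !tb2$best[2])
  expect_equal(model_table(list(fake(5)))$weight, 1)
  bad <- fake(100); bad$data_hash <- 99
  expect_error(model_table(list(fake(100), bad)), "differing data")
})

test_that("founder-augmented fits never lose likelihood to their nested base", {
  set.seed(21)
  tr <- simulate_tree(0.2, 0.05, 40)
  h <- simulate_range_evolution(tr, 0.06, 0.02, 0, "DEC")
  f0 <- fit_model(tr, h$tip_states, "DEC", FALSE, n_starts = 1)
  f1 <- fit_model(tr, h$tip_states, "DEC", TRUE, n_starts = 2)
  expect_gte(f1$loglik, f0$loglik - 0.01)
  expect_equal(f0$k, 2L); expect_equal(f1$k, 3L)
  expect_true(is.finite(f0$aicc))
})

test_that("tip coding follows the 20% range-fraction rule with H > N > E priority", {
  cells <- grid_cells(10, 2)
  part <- region_partition(cells$cell_id,
                           cells$x <= 3,        # columns 1-3 hotspot
                           ifelse(cells$y == 1, "realm1", "realm2"))
  # realm1 = row y=1; species occupy chosen cells
  id <- function(x, y) cells$cell_id[cells$x == x & cells$y == y]
  occ <- occ_from_list(list(
    half = c(sapply(1:5, id, y = 1)),                     # 3 H + 2 N cells
    edge = c(id(1, 1), sapply(1:9, id, y = 2)),           # 1 H + 9 E
    tri  = c(sapply(1:3, id, y = 1), sapply(4:6, id, y = 1),
             sapply(1:4, id, y = 2))                      # 3 H, 3 N, 4 E
  ), cells)
  st <- code_tip_ranges(occ, part, "realm1", 0.20)
  expect_equal(unname(st["half"]), "HN")     # fractions 0.6 / 0.4
  expect_equal(unname(st["edge"]), "E")      # H fraction 0.1 < 0.2
  # all three qualify (0.3, 0.3, 0.4): two largest kept, H before N on ties
  expect_equal(unname(st["tri"]), "HE")
  expect_equal(attr(st, "coerced"), "tri")
})
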