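test_that("simulated trees are ultrametric, binary, correctly sized and seeded", {
  tr <- simulate_tree(0.2, 0.05, 30, seed = 11)
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(length(tr$tip.label), 30)
  tr2 <- simulate_tree(0.2, 0.05, 30, seed = 11)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # two tips: both branch lengths equal by construction
  t2 <- simulate_tree(1, 0, 2, seed = 3)
  expect_equal(t2$edge.length[1], t2$edge.length[2])
})

test_that("pure-birth root ages match the Yule expectation", {
  set.seed(77)
  n <- 20
  ages <- replicate(400, {
    tr <- simulate_tree(1, 0, n)
    max(ape::node.depth.edgelength(tr))
  })
  expected <- sum(1 / (2:n))
  se <- sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - expected), 3 * se)
})

test_that("range evolution honors the no-event limit and determinism", {
  tr <- simulate_tree(0.3, 0, 12, seed = 4)
  h <- simulate_range_evolution(tr, 0, 0, 0, "DEC", root_state = "H", seed = 5)
  expect_true(all(h$tip_states == "H"))
  ev <- extract_events(h)
  expect_true(all(ev$type == "sympatry"))
  expect_equal(h$resimulations, 0L)
  h1 <- simulate_range_evolution(tr, 0.08, 0.02, 0.5, "DEC", seed = 9)
  h2 <- simulate_range_evolution(tr, 0.08, 0.02, 0.5, "DEC", seed = 9)
  expect_identical(h1$segments, h2$segments)
  expect_identical(h1$tip_states, h2$tip_states)
})

test_that("dispersal-event counts on a branch match the closed-form expectation", {
  # single-area start, e = 0: exactly one gain is possible (size cap), so
  # the expected dispersal count is P(gain) = 1 - exp(-2 d t)
  d <- 0.06; t_br <- 4
  tr <- ape::read.tree(text = sprintf("(a:%g,b:%g);", t_br, t_br))
  set.seed(123)
  counts <- replicate(1500, {
    h <- simulate_range_evolution(tr, d, 0, 0, "DEC", root_state = "N")
    sum(extract_events(h)$type == "dispersal")
  })
  # 2 tip branches per replicate (the root split copies the range)
  expected <- 2 * (1 - exp(-2 * d * t_br))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("true histories and the event extractor share one representation", {
  tr <- simulate_tree(0.25, 0.05, 25, seed = 8)
  h <- simulate_range_evolution(tr, 0.07, 0.03, 0.8, "DEC", seed = 2)
  ev <- extract_events(h)
  clado <- ev[ev$type %in% c("sympatry", "vicariance", "founder"), ]
  expect_equal(nrow(clado), nrow(h$node_events))
  expect_equal(as.vector(table(factor(clado$type, c("sympatry", "vicariance",
                                                    "founder")))),
               as.vector(table(factor(h$node_events$type,
                                      c("sympatry", "vicariance", "founder")))))
  ana <- ev[ev$type %in% c("dispersal", "extirpation"), ]
  n_trans <- sum(table(h$segments$edge) - 1)
  expect_equal(nrow(ana), n_trans)
  # founder destinations are single areas outside the source range
  fo <- ev[ev$type == "founder", ]
  if (nrow(fo)) {
    expect_true(all(nchar(fo$destination) == 1))
    expect_false(any(mapply(grepl, fo$destination, fo$source)))
  }
})

test_that("occupancy patches stay inside their regions and seed deterministically", {
  cfg <- sim_config(seed = 3, n_species = 40, grid_nx = 12, grid_ny = 10)
  cells <- simulate_grid(cfg, seed = 31)
  tr <- simulate_tree(cfg$birth, cfg$death, cfg$n_species, seed = 32)
  h <- simulate_range_evolution(tr, cfg$d_true, cfg$e_true, 0, "DEC", seed = 33)
  occ <- simulate_occurrence_grid(tr, h$tip_states, cfg, cells, seed = 34)
  expect_true(all(occ$range_size >= 1))
  region_of <- setNames(cells$region, cells$cell_id)
  for (sp in occ$species) {
    areas <- strsplit(unname(h$tip_states[sp]), "")[[1]]
    got <- unique(region_of[occ$presence$cell_id[occ$presence$species == sp]])
    expect_true(all(got %in% areas))
  }
  occ2 <- simulate_occurrence_grid(tr, h$tip_states, cfg, cells, seed = 34)
  expect_identical(occ$presence, occ2$presence)
})

test_that("degenerate single-cell patches force WE to equal SR", {
  cfg <- sim_config(seed = 5, n_species = 30, grid_nx = 10, grid_ny = 10,
                    patch_meanlog_h = -10, patch_meanlog = -10,
                    patch_sdlog = 1e-6)
  cells <- simulate_grid(cfg, seed = 1)
  tr <- simulate_tree(cfg$birth, cfg$death, cfg$n_species, seed = 2)
  h <- simulate_range_evolution(tr, cfg$d_true, cfg$e_true, 0, "DEC", seed = 3)
  occ <- simulate_occurrence_grid(tr, h$tip_states, cfg, cells, seed = 4)
  expect_true(all(occ$range_size == 1))
  expect_equal(weighted_endemism(occ), species_richness(occ) + 0.0)
})

test_that("planted hotspot blobs cover the configured fraction of each realm", {
  cfg <- sim_config(seed = 2, grid_nx = 20, grid_ny = 20, hotspot_fraction = 0.2)
  cells <- simulate_grid(cfg, seed = 7)
  for (r in unique(cells$realm)) {
    sub <- cells[cells$realm == r, ]
    expect_equal(sum(sub$true_hotspot) / nrow(sub), 0.2, tolerance = 0.02)
  }
  expect_setequal(unique(cells$region), c("H", "N", "E"))
})

test_that("environmental layers are seeded and carry their ground truth", {
  cfg <- sim_config(seed = 4, grid_nx = 10, grid_ny = 10)
  cells <- simulate_grid(cfg, seed = 1)
  e1 <- simulate_env_layers(cells, cfg, seed = 10)
  e2 <- simulate_env_layers(cells, cfg, seed = 10)
  expect_identical(e1, e2)
  expect_equal(attr(e1, "true_effects"), cfg$env_effects)
  expect_setequal(unique(e1$variable), names(cfg$env_effects))
})

test_that("the joint region-dependent simulator returns consistent trees and states", {
  sim <- simulate_biogeo_tree(50, 0.12, 0.02, 0.03, 0.01, family = "DEC",
                              hotspot_birth_mult = 2, seed = 6)
  expect_equal(length(sim$tree$tip.label), 50)
  expect_true(ape::is.ultrametric(sim$tree, tol = 1e-8))
  expect_true(all(sim$tip_states %in% biogeo_states()))
  expect_named(sim$tip_states, sim$tree$tip.label)
  sim2 <- simulate_biogeo_tree(50, 0.12, 0.02, 0.03, 0.01, family = "DEC",
                               hotspot_birth_mult = 2, seed = 6)
  expect_identical(sim$tip_states, sim2$tip_states)
})

test_that("the bundled dataset generator is a pure function of its seed", {
  cfg <- sim_config(seed = 12, n_species = 25, grid_nx = 8, grid_ny = 8)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$occ$presence, d2$occ$presence)
  expect_identical(d1$env, d2$env)
})
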