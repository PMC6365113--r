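# Independent oracles and small fixture builders used across the suite.

# Naive likelihood by direct recursive summation over node states and
# cladogenetic outcomes (no rescaling, no pruning tables); exact on small
# trees, used to check the compiled pruning algorithm.
brute_loglik <- function(tree, tip_states, family, d, e, j,
                         prior = rep(1 / 6, 6)) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  st <- match(unname(tip_states[tree$tip.label]), biogeo_states())
  Q <- anagenetic_generator(d, e)
  ctab <- cladogenetic_weights(family, j)
  P <- lapply(seq_len(nrow(tree$edge)), function(k)
    hotspotdiv:::ctmc_transition(Q, tree$edge.length[k]))
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lik_node <- function(nd, state) {
    if (nd <= n) return(as.numeric(state == st[nd]))
    if (state == 7) return(0)
    tab <- ctab[[state]]
    kk <- kids[[as.character(nd)]]
    tot <- 0
    for (r in seq_len(nrow(tab)))
      tot <- tot + tab[r, 3] * lik_edge(kk[1], tab[r, 1]) *
        lik_edge(kk[2], tab[r, 2])
    tot
  }
  lik_edge <- function(k, start) {
    child <- tree$edge[k, 2]
    s <- 0
    for (end in 1:7) {
      pe <- P[[k]][start, end]
      if (pe > 0) s <- s + pe * lik_node(child, end)
    }
    s
  }
  log(sum(sapply(1:6, function(s) prior[s] * lik_node(n + 1, s))))
}

# random occurrence grid built directly from base sampling (independent of
# the package's range generator)
random_occ <- function(n_species = 50, nx = 8, ny = 8, seed = 1,
                       max_range = 10) {
  set.seed(seed)
  cells <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  cells$cell_id <- sprintf("c%03d", seq_len(nrow(cells)))
  pres <- do.call(rbind, lapply(seq_len(n_species), function(i) {
    k <- sample.int(max_range, 1)
    data.frame(species = sprintf("sp%03d", i),
               cell_id = sample(cells$cell_id, k))
  }))
  occurrence_grid(pres, cells, 100)
}

# small hand-made occurrence grid: species -> cell ids
occ_from_list <- function(spec_cells, cells = NULL, cell_km = 100) {
  pres <- do.call(rbind, lapply(names(spec_cells), function(sp)
    data.frame(species = sp, cell_id = spec_cells[[sp]])))
  if (is.null(cells)) {
    ids <- sort(unique(pres$cell_id))
    cells <- data.frame(cell_id = ids, x = seq_along(ids), y = 1L)
  }
  occurrence_grid(pres, cells, cell_km)
}

grid_cells <- function(nx, ny, cell_km = 100) {
  cells <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  cells$cell_id <- sprintf("c%04d", seq_len(nrow(cells)))
  cells
}
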