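#' Configuration for the synthetic study system
#'
#' Bundles every ground-truth parameter of the generators.  Defaults describe
#' the study conditions used throughout the tests and analysis scripts: a
#' 20x20 grid of 100-km cells split into two realms, 150 species, a
#' birth-death tree (0.15/0.05 events/lineage/Ma), DEC-type range evolution
#' with d = 0.05, e = 0.02, no founder events, clustered hotspots covering
#' 20% of each realm, narrow hotspot ranges (lognormal patch sizes), and
#' spatially autocorrelated environments (SAR lambda 0.5) with hotspot
#' effects on productivity, ruggedness and climate-change velocity.
#'
#' @param seed master seed.
#' @param n_species number of extant tips / species.
#' @param grid_nx,grid_ny grid dimensions; @param cell_km cell side (km).
#' @param birth,death speciation and extinction rates (events/lineage/Ma).
#' @param d_true,e_true,j_true range-evolution truth; `d_true` may be a 3x3
#'   matrix for directional dispersal.
#' @param family,founder generating model family and founder flag.
#' @param n_realms number of vertical realm bands; @param focal_realm index
#'   of the realm whose hotspot/non-hotspot split defines areas H and N.
#' @param hotspot_fraction fraction of each realm's cells planted as
#'   hotspot.
#' @param patch_meanlog_h,patch_meanlog,patch_sdlog lognormal patch-size
#'   parameters (hotspot-restricted vs other species).
#' @param env_effects named standardized hotspot effect sizes for the
#'   environment table; @param sar_lambda spatial error autocorrelation.
#' @return `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_species = 150L, grid_nx = 20L,
                       grid_ny = 20L, cell_km = 100, birth = 0.15,
                       death = 0.05, d_true = 0.05, e_true = 0.02,
                       j_true = 0, family = "DEC", founder = FALSE,
                       n_realms = 2L, focal_realm = 1L,
                       hotspot_fraction = 0.20,
                       patch_meanlog_h = log(3), patch_meanlog = log(8),
                       patch_sdlog = 0.7,
                       env_effects = c(npp = 1, habitats = 0.5, tri = 1,
                                       ccv_temp = -0.8, ccv_prec = -0.8,
                                       tectonic = 0),
                       sar_lambda = 0.5) {
  stopifnot(hotspot_fraction > 0, hotspot_fraction < 1,
            birth > death, death >= 0, all(d_true >= 0), e_true >= 0,
            j_true >= 0, abs(sar_lambda) < 1, n_species >= 3)
  structure(as.list(environment()), class = "sim_config")
}

.derive_seed <- function(seed, k) {
  # documented splitting rule for per-stage seeds; kept below 2^31
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% .Machine$integer.max)
}

#' Simulate a birth-death tree conditioned on a tip count
#'
#' Forward simulation from two crown lineages: waiting times are exponential
#' in the total event rate, and the process stops at the moment the
#' (n_tips+1)-th extant lineage would be born, so the returned reconstructed
#' (extant-only) tree has exactly `n_tips` tips.  Replicates where the clade
#' dies are discarded and re-drawn (the retry count is recorded as an
#' attribute).
#'
#' @param birth,death rates (events/lineage/Ma), `birth > death >= 0`.
#' @param n_tips number of extant tips (>= 3).
#' @param seed integer seed (optional).
#' @param max_retries bound on whole-clade extinction retries.
#' @return ultrametric binary `phylo` with tip labels `sp1..spN`; attribute
#'   `"retries"`.
#' @export
simulate_tree <- function(birth, death, n_tips, seed = NULL,
                          max_retries = 1000) {
  stopifnot(birth > death, death >= 0, n_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_retries)) {
    sim <- .sim_bd_forward(birth, death, n_tips)
    if (!is.null(sim)) {
      tree <- .lineages_to_phylo(sim)
      extinct <- paste0("t", which(sim$status == "extinct"))
      if (length(extinct)) tree <- ape::drop.tip(tree, extinct)
      tree$tip.label <- paste0("sp", seq_along(tree$tip.label))
      attr(tree, "retries") <- try - 1L
      return(tree)
    }
  }
  stop(sprintf(
    "birth-death simulation failed to reach %d tips in %d retries (birth=%g, death=%g)",
    n_tips, max_retries, birth, death))
}

# forward simulation core; returns lineage table or NULL on clade death
.sim_bd_forward <- function(birth, death, n_tips) {
  # lineage records
  parent <- c(0L, 0L); t_start <- c(0, 0)
  t_end <- c(NA_real_, NA_real_); status <- c("active", "active")
  active <- c(1L, 2L)
  t <- 0
  repeat {
    k <- length(active)
    if (k == 0L) return(NULL)
    rate <- k * (birth + death)
    t <- t + stats::rexp(1, rate)
    is_birth <- stats::runif(1) < birth / (birth + death)
    if (is_birth && k == n_tips) break  # stop just before the (n+1)-th birth
    lin <- active[sample.int(k, 1)]
    if (is_birth) {
      id <- length(parent) + c(1L, 2L)
      parent <- c(parent, lin, lin); t_start <- c(t_start, t, t)
      t_end <- c(t_end, NA, NA); status <- c(status, "active", "active")
      t_end[lin] <- t; status[lin] <- "split"
      active <- c(setdiff(active, lin), id)
    } else {
      t_end[lin] <- t; status[lin] <- "extinct"
      active <- setdiff(active, lin)
    }
  }
  t_end[active] <- t; status[active] <- "extant"
  list(parent = parent, t_start = t_start, t_end = t_end, status = status,
       extant = status == "extant",
       tip_lineage = which(status != "split"))
}

# build an ape phylo from the lineage table (full tree incl. extinct tips);
# goes through a Newick string so node numbering follows ape's conventions
.lineages_to_phylo <- function(sim) {
  kids <- split(seq_along(sim$parent), sim$parent)
  nwk_of <- function(lin) {
    len <- sim$t_end[lin] - sim$t_start[lin]
    if (sim$status[lin] == "split") {
      ch <- kids[[as.character(lin)]]
      sprintf("(%s,%s):%.12g", nwk_of(ch[1]), nwk_of(ch[2]), len)
    } else sprintf("t%d:%.12g", lin, len)
  }
  crown <- kids[["0"]]
  txt <- sprintf("(%s,%s);", nwk_of(crown[1]), nwk_of(crown[2]))
  ape::read.tree(text = txt)
}

# Gillespie path of the anagenetic CTMC from `state` over `len`;
# returns list(jumps = matrix(time, state), end = final state)
.sim_ctmc_path <- function(Q, state, len) {
  t <- 0; jumps <- NULL
  repeat {
    rate <- -Q[state, state]
    if (rate <= 0) break
    t <- t + stats::rexp(1, rate)
    if (t >= len) break
    probs <- Q[state, ]; probs[state] <- 0
    state <- sample.int(7L, 1, prob = probs)
    jumps <- rbind(jumps, c(t, state))
  }
  list(jumps = jumps, end = state)
}

.sample_clado <- function(tab) {
  k <- if (nrow(tab) == 1L) 1L else
    sample.int(nrow(tab), 1, prob = tab[, "prob"])
  tab[k, ]
}

#' Simulate range evolution along a fixed tree
#'
#' Forward simulation of the anagenetic CTMC along every branch with a
#' cladogenetic outcome sampled at every internal node under the configured
#' family.  A branch whose range hits the null (empty) state is resimulated
#' (bounded retries) so tree and ranges stay consistent; the resimulation
#' count is reported.
#'
#' @param tree ultrametric `phylo`.
#' @param d,e,j,family model truth (`d` scalar or 3x3 directional matrix).
#' @param root_state range label for the root, or `NULL` to sample uniformly
#'   from the single-area ranges.
#' @param seed optional seed; @param max_retries per-branch bound.
#' @return object of class `biogeo_history` (the shared history
#'   representation also produced by [sample_maps()]): list with `tree`
#'   (postorder), `tip_states`, `root_state`, `segments` (edge, age_start,
#'   age_end, state), `node_events` (node, age, type, parent/left/right
#'   states), `resimulations`.
#' @export
simulate_range_evolution <- function(tree, d, e, j = 0, family = "DEC",
                                     root_state = NULL, seed = NULL,
                                     max_retries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  tree <- .prep_tree(tree)
  Q <- anagenetic_generator(d, e)
  ctab <- cladogenetic_weights(family, j)
  n <- length(tree$tip.label)
  root <- n + 1L
  depths <- ape::node.depth.edgelength(tree)
  root_age <- max(depths[seq_len(n)])
  age <- root_age - depths

  if (is.null(root_state)) root_state <- sample.int(3L, 1)
  else root_state <- .state_index(root_state)

  node_state <- integer(n + tree$Nnode)
  node_state[root] <- root_state
  nodes_pre <- c(root, rev(tree$edge[, 2][tree$edge[, 2] > n]))
  ev_node <- integer(0); ev_age <- numeric(0)
  ev_par <- integer(0); ev_l <- integer(0); ev_r <- integer(0)
  segments <- list(); resims <- 0L

  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  # preorder: reverse postorder guarantees parents before children
  for (nd in nodes_pre) {
    st <- node_state[nd]
    ev <- .sample_clado(ctab[[st]])
    kids <- children[[as.character(nd)]]
    ev_node <- c(ev_node, nd); ev_age <- c(ev_age, age[nd])
    ev_par <- c(ev_par, st)
    ev_l <- c(ev_l, unname(ev["left"])); ev_r <- c(ev_r, unname(ev["right"]))
    for (ki in seq_along(kids)) {
      edge_i <- kids[ki]
      child <- tree$edge[edge_i, 2]
      s0 <- unname(ev[c("left", "right")][ki])
      len <- tree$edge.length[edge_i]
      for (r in seq_len(max_retries)) {
        path <- .sim_ctmc_path(Q, s0, len)
        if (path$end != 7L && (is.null(path$jumps) || !any(path$jumps[, 2] == 7L)))
          break
        resims <- resims + 1L
        if (r == max_retries)
          stop("branch resimulation bound reached (range extinction too likely)")
      }
      segments[[length(segments) + 1L]] <-
        .path_to_segments(edge_i, age[tree$edge[edge_i, 1]], len, s0, path)
      node_state[child] <- path$end
    }
  }
  structure(list(tree = tree,
                 tip_states = stats::setNames(
                   biogeo_states()[node_state[seq_len(n)]], tree$tip.label),
                 root_state = biogeo_states()[root_state],
                 segments = .segments_df(segments),
                 node_events = .node_events_df(ev_node, ev_age, ev_par,
                                               ev_l, ev_r),
                 resimulations = resims),
            class = "biogeo_history")
}

# convert a jump path on one edge into age-indexed piecewise segment rows
# (matrix columns: edge, age_start, age_end, state index)
.path_to_segments <- function(edge_i, age_top, len, s0, path) {
  jt <- if (is.null(path$jumps)) numeric(0) else path$jumps[, 1]
  js <- if (is.null(path$jumps)) integer(0) else path$jumps[, 2]
  starts <- c(0, jt); ends <- c(jt, len); states <- c(s0, js)
  cbind(edge_i, age_top - starts, age_top - ends, states)
}

.segments_df <- function(rows) {
  m <- do.call(rbind, rows)
  data.frame(edge = as.integer(m[, 1]), age_start = m[, 2], age_end = m[, 3],
             state = biogeo_states()[m[, 4]])
}

.node_events_df <- function(node, age, parent, left, right) {
  type <- vapply(seq_along(node), function(k)
    classify_clado(parent[k], left[k], right[k]), character(1))
  st <- biogeo_states()
  data.frame(node = node, age = age, type = type, parent_state = st[parent],
             left_state = st[left], right_state = st[right])
}

#' Jointly simulate a tree and ranges with region-dependent rates
#'
#' Forward birth-death-dispersal simulation in which each lineage carries a
#' range state: lineages whose range includes the hotspot area H speciate at
#' `birth * hotspot_birth_mult`, dispersal may be directional (`d` a 3x3
#' matrix), and cladogenetic outcomes follow the configured family.  Used to
#' create ground truths where hotspot cladogenesis or directional dispersal
#' genuinely differ.  Stops just before the (n_tips+1)-th extant lineage
#' appears; whole-clade extinctions are retried.
#'
#' @inheritParams simulate_range_evolution
#' @param n_tips extant tip count; @param birth,death lineage rates;
#' @param hotspot_birth_mult speciation multiplier for ranges including H.
#' @return list with `tree` (reconstructed, extant-only, ultrametric),
#'   `tip_states`, `root_state`, and `event_counts` (true per-type counts on
#'   the full tree).
#' @export
simulate_biogeo_tree <- function(n_tips, birth, death, d, e, j = 0,
                                 family = "DEC", hotspot_birth_mult = 1,
                                 root_state = NULL, seed = NULL,
                                 max_retries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  Q <- anagenetic_generator(d, e)
  ctab <- cladogenetic_weights(family, j)
  has_H <- vapply(.STATE_SETS, function(s) 1L %in% s, logical(1))
  for (try in seq_len(max_retries)) {
    rs <- if (is.null(root_state)) sample.int(3L, 1) else .state_index(root_state)
    sim <- .sim_bd_ranges_forward(n_tips, birth, death, Q, ctab, has_H,
                                  hotspot_birth_mult, rs)
    if (is.null(sim)) next
    tree <- .lineages_to_phylo(sim)
    extinct <- paste0("t", which(sim$status == "extinct"))
    if (length(extinct)) tree <- ape::drop.tip(tree, extinct)
    lin_of <- as.integer(sub("^t", "", tree$tip.label))
    tip_states <- stats::setNames(biogeo_states()[sim$state[lin_of]],
                                  tree$tip.label)
    new_lab <- paste0("sp", seq_along(tree$tip.label))
    names(tip_states) <- new_lab; tree$tip.label <- new_lab
    return(list(tree = tree, tip_states = tip_states,
                root_state = biogeo_states()[rs],
                event_counts = sim$event_counts))
  }
  stop("joint simulation failed after ", max_retries, " retries")
}

.sim_bd_ranges_forward <- function(n_tips, birth, death, Q, ctab, has_H,
                                   mult, root_state) {
  parent <- c(0L, 0L); t_start <- c(0, 0)
  t_end <- c(NA_real_, NA_real_); status <- c("active", "active")
  # crown split at time 0 under the family's table
  ev0 <- .sample_clado(ctab[[root_state]])
  state <- c(unname(ev0["left"]), unname(ev0["right"]))
  active <- c(1L, 2L); t <- 0
  counts <- c(dispersal = 0, extirpation = 0, sympatry = 0,
              vicariance = 0, founder = 0)
  counts[classify_clado(root_state, ev0["left"], ev0["right"])] <-
    counts[classify_clado(root_state, ev0["left"], ev0["right"])] + 1
  repeat {
    k <- length(active)
    if (k == 0L) return(NULL)
    spec_r <- birth * ifelse(has_H[state[active]], mult, 1)
    ana_r <- -diag(Q)[state[active]]
    tot <- spec_r + death + ana_r
    t <- t + stats::rexp(1, sum(tot))
    lin <- active[sample.int(k, 1, prob = tot)]
    u <- stats::runif(1) * tot[match(lin, active)]
    sl <- spec_r[match(lin, active)]
    if (u < sl) {
      if (k == n_tips) break
      st <- state[lin]
      ev <- .sample_clado(ctab[[st]])
      counts[classify_clado(st, ev["left"], ev["right"])] <-
        counts[classify_clado(st, ev["left"], ev["right"])] + 1
      id <- length(parent) + c(1L, 2L)
      parent <- c(parent, lin, lin); t_start <- c(t_start, t, t)
      t_end <- c(t_end, NA, NA); status <- c(status, "active", "active")
      state <- c(state, unname(ev["left"]), unname(ev["right"]))
      t_end[lin] <- t; status[lin] <- "split"
      active <- c(setdiff(active, lin), id)
    } else if (u < sl + death) {
      t_end[lin] <- t; status[lin] <- "extinct"
      active <- setdiff(active, lin)
    } else {
      s <- state[lin]
      probs <- Q[s, ]; probs[s] <- 0
      ns <- sample.int(7L, 1, prob = probs)
      if (ns == 7L) {  # range extinction kills the lineage
        t_end[lin] <- t; status[lin] <- "extinct"
        active <- setdiff(active, lin)
        counts["extirpation"] <- counts["extirpation"] + 1
      } else {
        if (length(.state_set(ns)) > length(.state_set(s)))
          counts["dispersal"] <- counts["dispersal"] + 1
        else counts["extirpation"] <- counts["extirpation"] + 1
        state[lin] <- ns
      }
    }
  }
  t_end[active] <- t; status[active] <- "extant"
  list(parent = parent, t_start = t_start, t_end = t_end, status = status,
       state = state, extant = status == "extant",
       tip_lineage = which(status != "split"), event_counts = counts)
}

#' Build the synthetic grid with realms and planted hotspot cells
#'
#' Vertical realm bands; within each realm a contiguous hotspot blob of
#' `hotspot_fraction` of its cells is grown by seeded breadth-first
#' accretion, giving the clustered hotspot geometry real endemism centers
#' show.
#'
#' @param config a [sim_config()]; @param seed optional override.
#' @return data frame of cells: `cell_id`, `x`, `y`, `realm`,
#'   `true_hotspot`, `region` (H/N/E relative to the focal realm).
#' @export
simulate_grid <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nx <- config$grid_nx; ny <- config$grid_ny
  cells <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  cells$cell_id <- sprintf("c%04d", seq_len(nrow(cells)))
  band <- ceiling(cells$x / (nx / config$n_realms))
  cells$realm <- paste0("realm", pmin(band, config$n_realms))
  cells$true_hotspot <- FALSE
  for (r in unique(cells$realm)) {
    idx <- which(cells$realm == r)
    target <- max(1L, round(config$hotspot_fraction * length(idx)))
    blob <- .grow_patch(cells, idx, target, seed_cell = idx[sample.int(length(idx), 1)])
    cells$true_hotspot[blob] <- TRUE
  }
  focal <- paste0("realm", config$focal_realm)
  cells$region <- ifelse(cells$realm != focal, "E",
                         ifelse(cells$true_hotspot, "H", "N"))
  cells[, c("cell_id", "x", "y", "realm", "true_hotspot", "region")]
}

# breadth-first accretion of a contiguous patch within `allowed` row indices
.grow_patch <- function(cells, allowed, size, seed_cell) {
  size <- min(size, length(allowed))
  patch <- seed_cell
  repeat {
    if (length(patch) >= size) break
    px <- cells$x[patch]; py <- cells$y[patch]
    cand <- allowed[!(allowed %in% patch)]
    if (!length(cand)) break
    adj <- vapply(cand, function(i)
      any(abs(cells$x[i] - px) + abs(cells$y[i] - py) == 1), logical(1))
    frontier <- cand[adj]
    if (!length(frontier)) break
    patch <- c(patch, frontier[sample.int(length(frontier), 1)])
  }
  patch
}

#' Place species ranges on the grid
#'
#' Each species occupies, in every area of its range state, a contiguous
#' patch grown by seeded breadth-first accretion on the cell adjacency
#' graph; patch sizes are lognormal (heavy-tailed), with smaller patches for
#' hotspot-restricted species so weighted endemism concentrates in the
#' planted hotspots.
#'
#' @param tree `phylo` (tips = species); @param tip_ranges named range
#'   states; @param config a [sim_config()]; @param cells output of
#'   [simulate_grid()]; @param seed optional override.
#' @return an [occurrence_grid()].
#' @export
simulate_occurrence_grid <- function(tree, tip_ranges, config, cells,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  region_cells <- split(seq_len(nrow(cells)), cells$region)
  for (a in BIOGEO_AREAS)
    if (!length(region_cells[[a]]))
      stop("region has zero cells: ", a)
  pres <- list()
  for (sp in names(tip_ranges)) {
    areas <- strsplit(tip_ranges[[sp]], "")[[1]]
    meanlog <- if (identical(areas, "H")) config$patch_meanlog_h
               else config$patch_meanlog
    total <- max(1L, round(stats::rlnorm(1, meanlog, config$patch_sdlog)))
    k <- length(areas)
    sizes <- total %/% k + as.integer(seq_len(k) <= total %% k)
    for (ai in seq_len(k)) {
      if (sizes[ai] == 0L) next
      allowed <- region_cells[[areas[ai]]]
      size <- min(length(allowed), sizes[ai])
      seed_cell <- allowed[sample.int(length(allowed), 1)]
      patch <- .grow_patch(cells, allowed, size, seed_cell)
      pres[[length(pres) + 1L]] <- data.frame(species = sp,
                                              cell_id = cells$cell_id[patch])
    }
  }
  occurrence_grid(do.call(rbind, pres), cells, config$cell_km)
}

#' Simulate spatially autocorrelated environmental layers
#'
#' Each variable is `effect * hotspot_indicator + u` with `u` a simultaneous
#' autoregressive error field on the rook-adjacency graph of the grid
#' (innovation SD 1), so the true standardized hotspot effects are known.
#'
#' @param cells grid from [simulate_grid()]; @param config a [sim_config()];
#' @param partition optional [region_partition()]; defaults to the planted
#'   truth; @param seed optional override.
#' @return long data frame `cell_id`, `variable`, `value`; attributes
#'   `true_effects` and `sar_lambda`.
#' @export
simulate_env_layers <- function(cells, config, partition = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hot <- if (is.null(partition)) cells$true_hotspot
         else cells$cell_id %in% partition$cell_id[partition$class == "hotspot"]
  W <- spatial_weights(cells, config$cell_km, radius_km = config$cell_km * 1.01)
  effs <- config$env_effects
  u <- simulate_sar_error(W, config$sar_lambda, 1, length(effs))
  out <- do.call(rbind, lapply(seq_along(effs), function(i)
    data.frame(cell_id = cells$cell_id, variable = names(effs)[i],
               value = effs[i] * hot + u[, i])))
  attr(out, "true_effects") <- effs
  attr(out, "sar_lambda") <- config$sar_lambda
  out
}

#' Synthetic sub-cell elevation with rugged hotspots
#'
#' @param cells grid; @param k pixels per cell side; @param relief noise SD
#'   added inside hotspot cells on top of the base SD of 10 m;
#' @param seed optional.
#' @return list with `elev` (pixel matrix), `cell_of` (integer matrix of
#'   cell row indices per pixel).
#' @export
simulate_elevation <- function(cells, k = 3, relief = 150, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nx <- max(cells$x); ny <- max(cells$y)
  px <- nx * k; py <- ny * k
  cell_of <- matrix(0L, px, py)
  for (i in seq_len(nrow(cells)))
    cell_of[(cells$x[i] - 1) * k + seq_len(k),
            (cells$y[i] - 1) * k + seq_len(k)] <- i
  base <- outer(seq_len(px), seq_len(py), function(i, j) 500 + 2 * i + 1 * j)
  noise_sd <- ifelse(cells$true_hotspot[cell_of], 10 + relief, 10)
  elev <- base + matrix(stats::rnorm(px * py, sd = noise_sd), px, py)
  list(elev = elev, cell_of = cell_of)
}

#' Synthetic present and past climate layers
#'
#' Present climate follows a smooth latitudinal gradient with noise; the
#' past layer shifts the present by a realm-wide offset that is damped
#' inside hotspot cells (hotspots as climatically stable refugia), giving a
#' known negative hotspot effect on climate-change velocity.
#'
#' @param cells grid; @param elapsed time between layers (Ma; default the
#'   0.021 Ma since the Last Glacial Maximum); @param shift climate offset
#'   outside hotspots; @param stability multiplier (< 1) inside hotspots;
#' @param seed optional.
#' @return list `present`, `past` (named per-cell vectors), `elapsed`.
#' @export
simulate_climate_history <- function(cells, elapsed = 0.021, shift = 3,
                                     stability = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  present <- 25 - 0.8 * cells$y + stats::rnorm(nrow(cells), sd = 0.3)
  delta <- shift * ifelse(cells$true_hotspot, stability, 1)
  past <- present - delta + stats::rnorm(nrow(cells), sd = 0.2)
  list(present = stats::setNames(present, cells$cell_id),
       past = stats::setNames(past, cells$cell_id), elapsed = elapsed)
}

#' Synthetic plate-motion trajectories for grid cells
#'
#' Cells drift as rigid realm blocks plus small independent jitter that is
#' larger outside hotspots, giving a known ordering of tectonic mobility.
#'
#' @param cells grid; @param n_times time slices (65 Ma to present);
#' @param jitter_non,jitter_hot per-step cell jitter SD (km) outside/inside
#'   hotspots; @param seed optional.
#' @return array (cells x time x 2) of positions in km.
#' @export
simulate_cell_trajectories <- function(cells, n_times = 14, jitter_non = 20,
                                       jitter_hot = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cells)
  pos <- array(0, c(n, n_times, 2))
  pos[, 1, 1] <- cells$x * 100; pos[, 1, 2] <- cells$y * 100
  realms <- unique(cells$realm)
  for (tt in 2:n_times) {
    drift <- matrix(stats::rnorm(2 * length(realms), sd = 50), ncol = 2,
                    dimnames = list(realms, NULL))
    jit <- ifelse(cells$true_hotspot, jitter_hot, jitter_non)
    pos[, tt, 1] <- pos[, tt - 1, 1] + drift[cells$realm, 1] +
      stats::rnorm(n, sd = jit)
    pos[, tt, 2] <- pos[, tt - 1, 2] + drift[cells$realm, 2] +
      stats::rnorm(n, sd = jit)
  }
  pos
}

#' Generate the complete synthetic data set
#'
#' Runs every generator off one master seed (per-stage seeds derived by a
#' fixed splitting rule) and returns all pipeline inputs plus the ground
#' truth.
#'
#' @param config a [sim_config()].
#' @return list: `config`, `tree`, `history` (true `biogeo_history`),
#'   `tip_ranges`, `cells`, `occ`, `env`, `elevation`, `climate`,
#'   `trajectories`, `true_partition`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  s <- function(k) .derive_seed(config$seed, k)
  tree <- simulate_tree(config$birth, config$death, config$n_species, s(1))
  hist <- simulate_range_evolution(tree, config$d_true, config$e_true,
                                   config$j_true, config$family, seed = s(2))
  cells <- simulate_grid(config, seed = s(3))
  occ <- simulate_occurrence_grid(hist$tree, hist$tip_states, config, cells,
                                  seed = s(4))
  env <- simulate_env_layers(cells, config, seed = s(5))
  elevation <- simulate_elevation(cells, seed = s(6))
  climate <- simulate_climate_history(cells, seed = s(7))
  traj <- simulate_cell_trajectories(cells, seed = s(8))
  truep <- region_partition(cells$cell_id, cells$true_hotspot, cells$realm,
                            metric = "true")
  list(config = config, tree = hist$tree, history = hist,
       tip_ranges = hist$tip_states, cells = cells, occ = occ, env = env,
       elevation = elevation, climate = climate, trajectories = traj,
       true_partition = truep)
}
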