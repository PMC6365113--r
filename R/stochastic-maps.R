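#' Sample biogeographic stochastic mappings
#'
#' Draws explicit range-evolution histories consistent with the tip data
#' under a fitted (or supplied) model: a backward pruning pass stores the
#' conditional likelihood tables, joint node states are then sampled root-to-
#' tips together with cladogenetic outcomes, and each branch history is
#' sampled conditional on its endpoint states by uniformization.
#'
#' @param tree ultrametric `phylo`; @param tip_states named range states;
#' @param fit a `biogeo_fit` from [fit_model()], or a list with elements
#'   `family` and `params` (`d`, `e`, `j`).
#' @param n_maps number of histories (default 50).
#' @param seed optional seed.
#' @return list of `biogeo_history` objects (shared representation with
#'   [simulate_range_evolution()]).
#' @export
sample_maps <- function(tree, tip_states, fit, n_maps = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- .prep_tree(tree)
  st <- .match_tip_states(tree, tip_states)
  n <- length(tree$tip.label)
  p <- fit$params
  Q <- anagenetic_generator(p[["d"]], p[["e"]])
  ctab <- cladogenetic_weights(fit$family, p[["j"]])
  prior <- if (!is.null(fit$root_prior)) fit$root_prior else rep(1 / 6, 6)
  cond <- isTRUE(fit$condition_survival)
  tabs <- biogeo_pruning(tree$edge, tree$edge.length, n, st, Q, ctab,
                         prior, TRUE, cond)
  depths <- ape::node.depth.edgelength(tree)
  root_age <- max(depths[seq_len(n)])
  age <- root_age - depths
  root <- n + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  nodes_preorder <- c(root, rev(tree$edge[, 2][tree$edge[, 2] > n]))

  npre <- length(nodes_preorder)
  lapply(seq_len(n_maps), function(m) {
    node_state <- integer(n + tree$Nnode)
    node_state[seq_len(n)] <- st
    w <- prior * tabs$cl[root, 1:6]
    node_state[root] <- sample.int(6L, 1, prob = w)
    segments <- vector("list", nrow(tree$edge))
    ev_par <- integer(npre); ev_l <- integer(npre); ev_r <- integer(npre)
    for (k in seq_len(npre)) {
      nd <- nodes_preorder[k]
      i <- node_state[nd]
      kids <- children[[as.character(nd)]]
      eL <- kids[1]; eR <- kids[2]
      tab <- ctab[[i]]
      wo <- tab[, "prob"] * tabs$up[eL, tab[, "left"]] *
        tabs$up[eR, tab[, "right"]]
      pick <- if (nrow(tab) == 1L) 1L else sample.int(nrow(tab), 1, prob = wo)
      l <- tab[pick, "left"]; r <- tab[pick, "right"]
      ev_par[k] <- i; ev_l[k] <- l; ev_r[k] <- r
      for (ki in 1:2) {
        e <- kids[ki]
        s_top <- if (ki == 1) l else r
        child <- tree$edge[e, 2]
        len <- tree$edge.length[e]
        if (child > n) {
          wch <- tabs$P[s_top, 1:6, e] * tabs$cl[child, 1:6]
          node_state[child] <- sample.int(6L, 1, prob = wch)
        }
        jumps <- sample_ctmc_path(Q, s_top, node_state[child], len)
        path <- list(jumps = if (nrow(jumps)) jumps else NULL,
                     end = node_state[child])
        segments[[e]] <- .path_to_segments(e, age[nd], len, s_top, path)
      }
    }
    structure(list(tree = tree,
                   tip_states = stats::setNames(
                     biogeo_states()[st], tree$tip.label),
                   root_state = biogeo_states()[node_state[root]],
                   segments = .segments_df(segments),
                   node_events = .node_events_df(nodes_preorder, age[nodes_preorder],
                                                 ev_par, ev_l, ev_r),
                   resimulations = 0L),
              class = "biogeo_history")
  })
}

#' Flatten histories to a typed event table
#'
#' Anagenetic events come from state changes along branch segments
#' (dispersal rows carry the source and gained area; extirpation rows the
#' lost area); cladogenetic events sit at node ages, with within-region
#' cladogenesis assigned to the region(s) occupied by both daughters.
#'
#' @param maps list of `biogeo_history` (or a single one).
#' @return data frame: `map`, `type` (`dispersal`, `extirpation`,
#'   `sympatry`, `vicariance`, `founder`), `age`, `source`, `destination`.
#' @export
extract_events <- function(maps) {
  if (inherits(maps, "biogeo_history")) maps <- list(maps)
  lk <- .state_pair_lookup()
  out <- lapply(seq_along(maps), function(m) {
    h <- maps[[m]]
    seg <- h$segments
    si <- match(seg$state, biogeo_states())
    same <- seg$edge[-1] == seg$edge[-nrow(seg)]
    from <- si[-nrow(seg)][same]; to <- si[-1][same]
    age <- seg$age_start[-1][same]
    gain <- lk$size[to] > lk$size[from]
    ana <- data.frame(
      map = rep(m, length(age)),
      type = ifelse(gain, "dispersal", "extirpation"),
      age = age,
      source = ifelse(gain, biogeo_states()[from], lk$diff[cbind(from, to)]),
      destination = ifelse(gain, lk$diff[cbind(to, from)], NA_character_))
    ne <- h$node_events
    li <- match(ne$left_state, biogeo_states())
    ri <- match(ne$right_state, biogeo_states())
    pi <- match(ne$parent_state, biogeo_states())
    jump_left <- lk$size[li] == 1 & !lk$contains[cbind(pi, li)]
    nd <- data.frame(
      map = m, type = ne$type, age = ne$age, source = ne$parent_state,
      destination = ifelse(ne$type == "founder",
                           ifelse(jump_left, ne$left_state, ne$right_state),
                           lk$inter[cbind(li, ri)]))
    rbind(ana, nd)
  })
  do.call(rbind, out)
}

# lookup tables over state-index pairs: set difference, intersection,
# containment of the column state's areas in the row state, range size
.state_pair_lookup <- function() {
  sets <- lapply(1:6, .state_set)
  n <- 6
  diffm <- matrix(NA_character_, n, n)
  interm <- matrix(NA_character_, n, n)
  contains <- matrix(FALSE, n, n)
  for (i in 1:n) for (k in 1:n) {
    diffm[i, k] <- paste(BIOGEO_AREAS[setdiff(sets[[i]], sets[[k]])],
                         collapse = "")
    interm[i, k] <- paste(BIOGEO_AREAS[intersect(sets[[i]], sets[[k]])],
                          collapse = "")
    contains[i, k] <- all(sets[[k]] %in% sets[[i]])
  }
  list(diff = diffm, inter = interm, contains = contains,
       size = vapply(sets, length, integer(1)))
}

#' Per-bin lineage counts in a region
#'
#' Counts, at the older boundary of each bin and in each map, the branches
#' whose range at that time includes the region; returns the per-map matrix
#' and the across-map median.
#'
#' @param maps list of `biogeo_history`; @param region single area label
#'   (`"H"`, `"N"` or `"E"`); @param bins matrix/data frame with columns
#'   `start`, `end` (Ma, start < end, so `end` is the older boundary).
#' @return list with `per_map` (maps x bins) and `median`.
#' @export
lineage_counts <- function(maps, region, bins = time_bins()) {
  if (inherits(maps, "biogeo_history")) maps <- list(maps)
  per_map <- t(vapply(maps, function(h) {
    vapply(seq_len(nrow(bins)), function(b) {
      tau <- bins$end[b]
      seg <- h$segments
      on <- seg$age_start >= tau & seg$age_end < tau & grepl(region, seg$state)
      sum(on)
    }, numeric(1))
  }, numeric(nrow(bins))))
  list(per_map = per_map, median = apply(per_map, 2, stats::median),
       bins = bins, region = region)
}

#' Standard 2-Ma analysis bins on the 2-26 Ma window
#'
#' Half-open bins \[t, t+2) Ma; estimates younger than 2 Ma (ongoing
#' speciation) and older than 26 Ma (too few lineages) are excluded by
#' construction.
#'
#' @param from,to window bounds (Ma); @param width bin width (Ma).
#' @return data frame `start`, `end`.
#' @export
time_bins <- function(from = 2, to = 26, width = 2) {
  s <- seq(from, to - width, by = width)
  data.frame(start = s, end = s + width)
}

.bin_of <- function(age, bins) {
  idx <- findInterval(age, c(bins$start, bins$end[nrow(bins)]),
                      left.open = FALSE)
  idx[age >= bins$end[nrow(bins)] | age < bins$start[1]] <- NA
  idx
}

#' Time-binned directed dispersal rate series
#'
#' Per bin, the median (across maps) count of source-to-destination
#' dispersal events divided by the median lineage count of the normalizing
#' region in the previous (older) bin.  The normalizing region defaults to
#' the destination; bins whose denominator is at or below `lineage_floor`
#' are reported as `NA` (undefined), not zero.  Per-map rates (same
#' construction within each map) are kept for standardized differences.
#'
#' @param events table from [extract_events()]; @param counts a
#'   [lineage_counts()] result for the normalizing region; @param source,
#'   destination area labels; @param bins analysis bins; @param n_maps
#'   total number of maps (needed because maps with zero events drop out of
#'   the event table); @param lineage_floor mask denominator at or below
#'   this (default 10).
#' @return object of class `rate_series`: list with `bins`, `per_map`,
#'   `median`, `q10`, `q90`, `series` label.
#' @export
dispersal_rate_series <- function(events, counts, source, destination,
                                  bins = time_bins(), n_maps,
                                  lineage_floor = 10) {
  if (source == destination) stop("source and destination must differ")
  ev <- events[events$type == "dispersal" & events$source == source &
                 events$destination == destination, , drop = FALSE]
  ev$bin <- .bin_of(ev$age, bins)
  ev <- ev[!is.na(ev$bin), , drop = FALSE]
  cnt <- matrix(0, n_maps, nrow(bins))
  if (nrow(ev))
    for (k in seq_len(nrow(ev))) cnt[ev$map[k], ev$bin[k]] <-
      cnt[ev$map[k], ev$bin[k]] + 1
  .make_rate_series(cnt, counts, bins, lineage_floor,
                    paste0(source, "->", destination))
}

.make_rate_series <- function(event_counts, counts, bins, lineage_floor,
                              label) {
  nb <- nrow(bins)
  # denominator: lineages in the previous (older) bin = next bin index
  denom_map <- cbind(counts$per_map[, -1, drop = FALSE], NA)
  denom_med <- c(counts$median[-1], NA)
  per_map <- event_counts / denom_map
  per_map[!is.finite(per_map)] <- NA    # maps with no lineages in the bin
  per_map[, denom_med <= lineage_floor | is.na(denom_med)] <- NA
  med_events <- apply(event_counts, 2, stats::median)
  med <- med_events / denom_med
  med[denom_med <= lineage_floor | is.na(denom_med)] <- NA
  structure(list(bins = bins, per_map = per_map, median = med,
                 q10 = apply(per_map, 2, stats::quantile, 0.10, na.rm = TRUE,
                             names = FALSE),
                 q90 = apply(per_map, 2, stats::quantile, 0.90, na.rm = TRUE,
                             names = FALSE),
                 series = label), class = "rate_series")
}

#' Time-binned cladogenesis rate series for a region
#'
#' Two estimators: `"branch_rates"` averages the per-branch speciation rates
#' over the branch segments assigned to the region in each bin (segments are
#' split at bin boundaries and weight each bin by the time they overlap);
#' `"event_counts"` divides within-region cladogenesis events (both
#' daughters occupy the region) by the lineage count of the previous older
#' bin, mirroring the dispersal series.
#'
#' @param maps list of `biogeo_history`; @param region area label;
#' @param branch_rates per-edge speciation rates (e.g.
#'   [dr_branch_rates()]), required for the branch-rate estimator;
#' @param estimator which estimator; @param bins analysis bins;
#' @param lineage_floor denominator mask for the event-count estimator.
#' @return a `rate_series`.
#' @export
cladogenesis_rate_series <- function(maps, region, branch_rates = NULL,
                                     estimator = c("branch_rates",
                                                   "event_counts"),
                                     bins = time_bins(), lineage_floor = 10) {
  estimator <- match.arg(estimator)
  if (inherits(maps, "biogeo_history")) maps <- list(maps)
  nb <- nrow(bins)
  if (estimator == "event_counts") {
    cnt <- t(vapply(maps, function(h) {
      ne <- h$node_events
      within <- vapply(seq_len(nrow(ne)), function(k)
        grepl(region, ne$left_state[k]) && grepl(region, ne$right_state[k]),
        logical(1))
      b <- .bin_of(ne$age[within], bins)
      tabulate(b[!is.na(b)], nb)
    }, numeric(nb)))
    counts <- lineage_counts(maps, region, bins)
    return(.make_rate_series(cnt, counts, bins, lineage_floor,
                             paste0("clado:", region)))
  }
  stopifnot(!is.null(branch_rates))
  per_map <- t(vapply(maps, function(h) {
    seg <- h$segments
    seg <- seg[grepl(region, seg$state), , drop = FALSE]
    vapply(seq_len(nb), function(b) {
      ov <- pmin(seg$age_start, bins$end[b]) - pmax(seg$age_end, bins$start[b])
      keep <- ov > 0
      if (!any(keep)) return(NA_real_)
      sum(branch_rates[seg$edge[keep]] * ov[keep]) / sum(ov[keep])
    }, numeric(1))
  }, numeric(nb)))
  structure(list(bins = bins, per_map = per_map,
                 median = apply(per_map, 2, stats::median, na.rm = TRUE),
                 q10 = apply(per_map, 2, stats::quantile, 0.10, na.rm = TRUE,
                             names = FALSE),
                 q90 = apply(per_map, 2, stats::quantile, 0.90, na.rm = TRUE,
                             names = FALSE),
                 series = paste0("clado-branch:", region)),
            class = "rate_series")
}

#' Standardized hotspot minus non-hotspot rate difference
#'
#' Per map and bin, (a - b) divided by the SD of all rate values pooled over
#' both series, all maps and all bins; reported as the across-map median
#' with a 10th-90th percentile interval per bin, plus an aggregate over the
#' whole window (per-map mean over defined bins).
#'
#' @param a,b `rate_series` on matching bins.
#' @return list with `bins`, `delta_median`, `delta_q10`, `delta_q90`,
#'   `aggregate` (median, q10, q90), `pooled_sd`.
#' @export
standardized_difference <- function(a, b) {
  stopifnot(identical(a$bins, b$bins))
  pooled_sd <- stats::sd(c(a$per_map, b$per_map), na.rm = TRUE)
  if (!is.finite(pooled_sd) || pooled_sd == 0)
    stop("pooled SD of the rate values is zero; difference undefined")
  d <- (a$per_map - b$per_map) / pooled_sd
  agg <- rowMeans(d, na.rm = TRUE)
  agg[!is.finite(agg)] <- NA
  list(bins = a$bins,
       delta_median = apply(d, 2, stats::median, na.rm = TRUE),
       delta_q10 = apply(d, 2, stats::quantile, 0.10, na.rm = TRUE,
                         names = FALSE),
       delta_q90 = apply(d, 2, stats::quantile, 0.90, na.rm = TRUE,
                         names = FALSE),
       aggregate = c(median = stats::median(agg, na.rm = TRUE),
                     q10 = stats::quantile(agg, 0.10, na.rm = TRUE,
                                           names = FALSE),
                     q90 = stats::quantile(agg, 0.90, na.rm = TRUE,
                                           names = FALSE)),
       pooled_sd = pooled_sd)
}

#' Median colonization age of a region
#'
#' Per map, the oldest time at which any lineage occupies the region (the
#' root age when the root range already includes it); median across maps.
#'
#' @param maps list of `biogeo_history`; @param region area label.
#' @return list with `median` (Ma) and `per_map`.
#' @export
colonization_age <- function(maps, region) {
  if (inherits(maps, "biogeo_history")) maps <- list(maps)
  ages <- vapply(maps, function(h) {
    seg <- h$segments[grepl(region, h$segments$state), , drop = FALSE]
    if (!nrow(seg)) return(NA_real_)
    max(seg$age_start)
  }, numeric(1))
  if (all(is.na(ages))) stop("region ", region, " never occupied in any map")
  list(median = stats::median(ages, na.rm = TRUE), per_map = ages)
}
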