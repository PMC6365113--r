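#' Tip-level diversification rate (inverse equal splits, the DR statistic)
#'
#' For each tip, the equal-splits measure ES is the sum of the edge lengths
#' on the tip-to-root path with the j-th edge (counting from the tip)
#' down-weighted by 2^(j-1); DR = 1/ES.  High DR marks tips embedded in
#' recent, rapid splitting; low DR marks long, isolated branches.
#'
#' @param tree rooted binary `phylo` with branch lengths in Ma.
#' @return named numeric vector of DR per tip.
#' @export
compute_dr <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  # preorder accumulation: es(child) = edge_length + es(parent)/2
  es <- numeric(n + tree$Nnode)
  for (e in nrow(tree$edge):1) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    es[child] <- tree$edge.length[e] + es[parent] / 2
  }
  if (any(es[seq_len(n)] <= 0))
    stop("zero-length root-to-tip path at tip: ",
         paste(tree$tip.label[which(es[seq_len(n)] <= 0)], collapse = ", "))
  stats::setNames(1 / es[seq_len(n)], tree$tip.label)
}

#' Split species into DR quartiles
#'
#' Species are ranked by DR ascending (ties broken by name) and split into
#' four near-equal groups: Q1 holds the slowest, oldest lineages ("ancient")
#' and Q4 the fastest ("recent").  When the count is not divisible by 4 the
#' extra species go to the lower quartiles first.
#'
#' @param dr named per-species DR values.
#' @return named factor with levels `Q1`..`Q4`.
#' @export
assign_quartiles <- function(dr) {
  n <- length(dr)
  if (n < 4) stop("need at least 4 species for quartiles")
  if (length(unique(dr)) == 1L)
    warning("all DR values equal; quartiles are a name-ordered split")
  ord <- order(dr, names(dr))
  base <- n %/% 4L
  sizes <- base + as.integer(seq_len(4L) <= n %% 4L)
  q <- factor(rep(paste0("Q", 1:4), times = sizes), levels = paste0("Q", 1:4))
  stats::setNames(q[order(ord)], names(dr))
}

#' Residuals of quartile-richness regressions
#'
#' Fits, over the cells of the analysis domain, the two ordinary
#' least-squares regressions Q1 richness ~ total SR and Q4 richness ~ total
#' SR.  Positive residuals mark cells with an excess of ancient (Q1) or
#' recent (Q4) lineages for their richness; negative residuals a deficit.
#'
#' @param occ an [occurrence_grid()].
#' @param quartiles factor from [assign_quartiles()]; species missing from
#'   it (e.g. not in the tree) are excluded from quartile counts but still
#'   contribute to total SR.
#' @param cells optional subset of cell ids (e.g. one realm); defaults to
#'   all occupied cells.
#' @return data frame with `cell_id`, `sr`, `q1`, `q4`, `resid_q1`,
#'   `resid_q4`.
#' @export
quartile_residuals <- function(occ, quartiles, cells = NULL) {
  sr <- species_richness(occ)
  occupied <- names(sr)[sr > 0]
  if (is.null(cells)) cells <- occupied else cells <- intersect(cells, occupied)
  if (length(unique(sr[cells])) == 1L)
    stop("total SR is constant across cells; regression undefined")
  q1 <- species_richness(occ, names(quartiles)[quartiles == "Q1"])[cells]
  q4 <- species_richness(occ, names(quartiles)[quartiles == "Q4"])[cells]
  srx <- sr[cells]
  f1 <- stats::lm(q1 ~ srx)
  f4 <- stats::lm(q4 ~ srx)
  data.frame(cell_id = cells, sr = as.numeric(srx),
             q1 = as.numeric(q1), q4 = as.numeric(q4),
             resid_q1 = unname(stats::residuals(f1)),
             resid_q4 = unname(stats::residuals(f4)))
}

#' Hodges-Lehmann contrast between hotspot and non-hotspot cells
#'
#' Point estimate = median of all pairwise (hotspot - non-hotspot)
#' differences, enumerated exactly when there are at most `max_pairs` pairs
#' and otherwise estimated from a seeded random subsample of pairs; the 95%
#' confidence interval comes from inverting the Wilcoxon rank-sum test.
#'
#' @param values named per-cell values (names = cell ids).
#' @param partition a [region_partition()].
#' @param conf.level confidence level for the rank-sum interval.
#' @param max_pairs exact-enumeration ceiling (default 1e6).
#' @param seed seed for the subsampling fallback.
#' @return list with `estimate`, `conf.int`, `statistic`, `p.value`,
#'   `n_hot`, `n_non`.
#' @export
hotspot_contrast <- function(values, partition, conf.level = 0.95,
                             max_pairs = 1e6, seed = 1L) {
  hot <- values[as.character(partition$cell_id[partition$class == "hotspot"])]
  non <- values[as.character(partition$cell_id[partition$class == "non-hotspot"])]
  hot <- hot[!is.na(hot)]; non <- non[!is.na(non)]
  if (length(hot) < 2 || length(non) < 2)
    stop("need at least 2 cells in each class")
  np <- as.numeric(length(hot)) * length(non)
  if (np <= max_pairs) {
    est <- stats::median(outer(hot, non, "-"))
  } else {
    set.seed(seed)
    i <- sample.int(length(hot), max_pairs, replace = TRUE)
    k <- sample.int(length(non), max_pairs, replace = TRUE)
    est <- stats::median(hot[i] - non[k])
  }
  wt <- suppressWarnings(stats::wilcox.test(hot, non, conf.int = TRUE,
                                            conf.level = conf.level))
  list(estimate = est, conf.int = as.numeric(wt$conf.int),
       statistic = unname(wt$statistic), p.value = wt$p.value,
       n_hot = length(hot), n_non = length(non))
}

#' Per-branch speciation rates from tip DR values
#'
#' Default branch-rate provider for the cladogenesis rate series: each branch
#' gets the mean DR of its descendant tips.  External per-branch estimates
#' (e.g. from a macroevolutionary mixture model) can be used instead via
#' [read_branch_rates()].
#'
#' @param tree `phylo`; @param dr named per-tip DR (defaults to
#'   [compute_dr()]).
#' @return numeric vector of rates, one per row of `tree$edge`.
#' @export
dr_branch_rates <- function(tree, dr = compute_dr(tree)) {
  tree2 <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree2$tip.label)
  nn <- n + tree2$Nnode
  sumdr <- numeric(nn); cnt <- integer(nn)
  sumdr[seq_len(n)] <- dr[tree2$tip.label]; cnt[seq_len(n)] <- 1L
  for (e in seq_len(nrow(tree2$edge))) {
    p <- tree2$edge[e, 1]; ch <- tree2$edge[e, 2]
    sumdr[p] <- sumdr[p] + sumdr[ch]; cnt[p] <- cnt[p] + cnt[ch]
  }
  rates <- (sumdr / cnt)[tree2$edge[, 2]]
  # report in the caller's edge order
  ord <- match(paste(tree$edge[, 1], tree$edge[, 2]),
               paste(tree2$edge[, 1], tree2$edge[, 2]))
  rates[ord]
}

#' Read externally estimated per-branch rates
#'
#' CSV interface for substituting branch speciation rates from an external
#' program for the DR-based default (columns `child` = child node id of the
#' branch in the tree's node numbering, `rate`).
#'
#' @param path CSV path; @param tree the `phylo` the ids refer to.
#' @return numeric vector ordered as `tree$edge` rows.
#' @export
read_branch_rates <- function(path, tree) {
  df <- utils::read.csv(path)
  stopifnot(all(c("child", "rate") %in% names(df)))
  idx <- match(tree$edge[, 2], df$child)
  if (anyNA(idx)) stop("branch rates missing for some edges")
  df$rate[idx]
}
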