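#' Code species into the three-area state space
#'
#' Assigns each species one of the six range states from the fractions of its
#' occupied cells falling in the focal realm's hotspot cells (H), the focal
#' realm's non-hotspot cells (N), and all remaining realms (E).  A region is
#' scored present when it holds at least `threshold` of the species' cells.
#' If more than two regions qualify, the two with the largest fractions are
#' kept (ties broken by the priority order H > N > E); if none qualifies, the
#' single region with the largest fraction is used.
#'
#' @param occ an [occurrence_grid()].
#' @param partition a [region_partition()] delineated on the same cells.
#' @param realm focal realm name.
#' @param threshold presence threshold on the range fraction (default 0.20).
#' @return named character vector of range states per species; attribute
#'   `"coerced"` lists species whose >2 qualifying regions were coerced.
#' @export
code_tip_ranges <- function(occ, partition, realm, threshold = 0.20) {
  stopifnot(threshold > 0, threshold <= 1)
  part <- merge(occ$presence, partition, by = "cell_id")
  region <- ifelse(part$realm != realm, "E",
                   ifelse(part$class == "hotspot", "H", "N"))
  tab <- table(factor(part$species, levels = occ$species),
               factor(region, levels = BIOGEO_AREAS))
  if (any(rowSums(tab) == 0))
    stop("species with zero occupied cells: ",
         paste(rownames(tab)[rowSums(tab) == 0], collapse = ", "))
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  coerced <- character(0)
  states <- vapply(seq_len(nrow(frac)), function(i) {
    f <- frac[i, ]
    qual <- which(f >= threshold)
    if (length(qual) == 0L) qual <- which.max(f)
    if (length(qual) > 2L) {
      # keep the two largest; order() on (-fraction, priority index) breaks
      # ties in the documented H > N > E order
      qual <- qual[order(-f[qual], qual)][1:2]
      coerced <<- c(coerced, rownames(frac)[i])
    }
    .state_label(sort(match(names(f)[qual], BIOGEO_AREAS)))
  }, character(1))
  names(states) <- rownames(frac)
  attr(states, "coerced") <- coerced
  states
}

.prep_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) stop("tree must be binary")
  ape::reorder.phylo(tree, "postorder")
}

#' Log-likelihood of tip range states under a range-evolution model
#'
#' Felsenstein pruning over the rooted tree with matrix exponentials of the
#' anagenetic generator along branches and the family's cladogenetic outcome
#' distribution at internal nodes; per-node rescaling guards underflow.  The
#' root state distribution defaults to uniform over the six non-null ranges.
#'
#' @param tree an ultrametric `phylo` tree with branch lengths in Ma.
#' @param tip_states named character vector of range states (names = tip
#'   labels), or unnamed in tip order.
#' @param family model family (`"DEC"`, `"DIVALIKE"`, `"BAYAREALIKE"`).
#' @param d,e,j anagenetic dispersal and extirpation rates and founder
#'   weight.
#' @param root_prior probability vector over the six range states.
#' @param condition_survival condition each branch on the range not dying
#'   (renormalizes transition rows by 1 - P(null)); use when the data come
#'   from a generator that resimulates extinct ranges, so estimator and
#'   generator share the same survival conditioning.  Default `FALSE`
#'   (plain unconditioned pruning).
#' @return natural-log likelihood (scalar).
#' @export
tree_likelihood <- function(tree, tip_states, family = "DEC", d, e, j = 0,
                            root_prior = rep(1 / 6, 6),
                            condition_survival = FALSE) {
  tree <- .prep_tree(tree)
  st <- .match_tip_states(tree, tip_states)
  Q <- anagenetic_generator(d, e)
  cl <- cladogenetic_weights(family, j)
  res <- biogeo_pruning(tree$edge, tree$edge.length, length(tree$tip.label),
                        st, Q, cl, root_prior, FALSE, condition_survival)
  res$loglik
}

.match_tip_states <- function(tree, tip_states) {
  if (!is.null(names(tip_states))) {
    miss <- setdiff(tree$tip.label, names(tip_states))
    if (length(miss)) stop("tips without coded states: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    tip_states <- tip_states[tree$tip.label]
  } else stopifnot(length(tip_states) == length(tree$tip.label))
  .state_index(unname(tip_states))
}

#' Small-sample corrected AIC
#'
#' @param loglik maximized log-likelihood; @param k parameter count;
#' @param n sample size (number of tips).
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Maximum-likelihood fit of one range-evolution model
#'
#' Bounded multi-start derivative-free optimization of (d, e[, j]) for one of
#' the six model variants (three families, with or without founder events).
#' Bounds are d, e in \[1e-12, 5\] events/Ma and j in \[0, 3\].
#'
#' @inheritParams tree_likelihood
#' @param founder logical; include the founder (+J) parameter.
#' @param n_starts number of optimization starts (first start from a fixed
#'   moderate point, the rest jittered).
#' @return object of class `biogeo_fit`: list with `family`, `founder`,
#'   `params` (d, e, j), `loglik`, `k`, `n`, `aicc`, `convergence`.
#' @export
fit_model <- function(tree, tip_states, family = "DEC", founder = FALSE,
                      root_prior = rep(1 / 6, 6), n_starts = 2,
                      condition_survival = FALSE) {
  tree <- .prep_tree(tree)
  st <- .match_tip_states(tree, tip_states)
  n <- length(tree$tip.label)
  if (n < 10) warning("fewer than 10 tips: parameter estimates will be weak")
  edge <- tree$edge; el <- tree$edge.length

  nll <- function(par) {
    d <- par[1]; e <- par[2]; j <- if (founder) par[3] else 0
    Q <- anagenetic_generator(d, e)
    cw <- cladogenetic_weights(family, j)
    ll <- tryCatch(
      biogeo_pruning(edge, el, n, st, Q, cw, root_prior, FALSE,
                     condition_survival)$loglik,
      error = function(err) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  depth <- max(ape::node.depth.edgelength(tree))
  lower <- c(1e-12, 1e-12, if (founder) 0)
  upper <- c(5, 5, if (founder) 3)
  start0 <- c(1 / depth, 0.5 / depth, if (founder) 0.1)
  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- if (s == 1) start0
      else if (s == 2 && founder) c(start0[1:2], 0)  # nested-boundary start
      else pmin(pmax(start0 * stats::runif(length(start0), 0.2, 5),
                     lower), upper)
    fit <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200, factr = 1e9)),
      error = function(err) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed for ", family,
                          if (founder) "+J")
  k <- 2L + as.integer(founder)
  params <- c(d = best$par[1], e = best$par[2],
              j = if (founder) best$par[3] else 0)
  structure(list(
    family = family, founder = founder, params = params,
    loglik = -best$value, k = k, n = n, aicc = aicc(-best$value, k, n),
    root_prior = root_prior, convergence = best$convergence,
    condition_survival = condition_survival,
    data_hash = .data_hash(tree, st)), class = "biogeo_fit")
}

.data_hash <- function(tree, st) {
  # cheap content fingerprint used to refuse mixing fits on different data
  sum(tree$edge.length) + sum(st * seq_along(st)) + length(st) * 1e6
}

#' @export
print.biogeo_fit <- function(x, ...) {
  cat(sprintf("%s%s fit: lnL = %.3f, AICc = %.3f\n",
              x$family, if (x$founder) "+J" else "", x$loglik, x$aicc))
  print(round(x$params, 5))
  invisible(x)
}

#' Fit all six model variants and rank them
#'
#' @inheritParams fit_model
#' @return list with `fits` (all six `biogeo_fit` objects) and `table`
#'   (the [model_table()] ranking).
#' @export
fit_all_models <- function(tree, tip_states, root_prior = rep(1 / 6, 6),
                           n_starts = 2, condition_survival = FALSE) {
  grid <- expand.grid(family = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                      founder = c(FALSE, TRUE), stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(grid)), function(i)
    fit_model(tree, tip_states, grid$family[i], grid$founder[i],
              root_prior, n_starts, condition_survival))
  names(fits) <- paste0(grid$family, ifelse(grid$founder, "+J", ""))
  list(fits = fits, table = model_table(fits))
}

#' Model-comparison table from a set of fits
#'
#' Ranks fits on identical data by AICc with differences and Akaike weights.
#'
#' @param fits list of `biogeo_fit` objects on the same data.
#' @return data frame sorted by AICc with `delta_aicc`, `weight`, `best`.
#' @export
model_table <- function(fits) {
  stopifnot(length(fits) >= 1)
  hashes <- vapply(fits, function(f) f$data_hash, numeric(1))
  if (max(hashes) - min(hashes) > 1e-6 * max(1, abs(mean(hashes))))
    stop("fits were computed on differing data")
  a <- vapply(fits, function(f) f$aicc, numeric(1))
  d <- a - min(a)
  w <- exp(-d / 2); w <- w / sum(w)
  out <- data.frame(
    model = if (!is.null(names(fits))) names(fits) else
      vapply(fits, function(f) paste0(f$family, if (f$founder) "+J" else ""),
             character(1)),
    d = vapply(fits, function(f) f$params[["d"]], numeric(1)),
    e = vapply(fits, function(f) f$params[["e"]], numeric(1)),
    j = vapply(fits, function(f) f$params[["j"]], numeric(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = a, delta_aicc = d, weight = w, row.names = NULL)
  out <- out[order(out$aicc), ]
  out$best <- seq_len(nrow(out)) == 1L
  out
}
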