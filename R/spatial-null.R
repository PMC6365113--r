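#' Ripley's K with translation edge correction
#'
#' Empirical K function of a point pattern in a rectangular window, using
#' the translation correction weight |W| / ((a - |dx|)(b - |dy|)) per
#' ordered pair and intensity estimate n(n-1)/|W|^2.
#'
#' @param xy two-column matrix of coordinates; @param window `c(xmin, xmax,
#'   ymin, ymax)`; @param r radii at which to evaluate.
#' @return data frame `r`, `K`.
#' @export
ripley_k <- function(xy, window, r) {
  n <- nrow(xy)
  a <- window[2] - window[1]; b <- window[4] - window[3]
  area <- a * b
  dx <- abs(outer(xy[, 1], xy[, 1], "-"))
  dy <- abs(outer(xy[, 2], xy[, 2], "-"))
  d <- sqrt(dx^2 + dy^2)
  w <- area / ((a - dx) * (b - dy))
  diag(d) <- Inf
  lam2 <- n * (n - 1) / area^2
  K <- vapply(r, function(rr) sum(w[d <= rr]) / (lam2 * area), numeric(1))
  data.frame(r = r, K = K)
}

# closed-form K of a Thomas process
.thomas_k <- function(r, kappa, sigma) {
  pi * r^2 + (1 - exp(-r^2 / (4 * sigma^2))) / kappa
}

#' Fit a Thomas cluster process by minimum contrast
#'
#' Matches the empirical Ripley K (translation-corrected) to the Thomas
#' closed form K(r) = pi r^2 + (1/kappa)(1 - exp(-r^2 / (4 sigma^2))) by
#' minimizing the integrated squared difference of K^(1/4) (the usual
#' variance-stabilizing exponent); the offspring mean mu is set from the
#' observed intensity.
#'
#' @param xy point coordinates (e.g. hotspot cell centers, km);
#' @param window rectangle `c(xmin, xmax, ymin, ymax)`;
#' @param rmax contrast range (default a quarter of the shorter side).
#' @return object of class `cluster_fit`: `kappa` (parents per unit area),
#'   `sigma` (cluster scale), `mu` (mean offspring per parent), `window`,
#'   `n_points`, `weak_clustering` flag (sigma at its upper bound, i.e. no
#'   detectable cluster signal), `contrast`.
#' @export
fit_cluster_process <- function(xy, window, rmax = NULL) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 30) stop("need at least 30 points to fit the cluster process")
  a <- window[2] - window[1]; b <- window[4] - window[3]
  if (is.null(rmax)) rmax <- min(a, b) / 4
  r <- seq(rmax / 50, rmax, length.out = 50)
  Khat <- ripley_k(xy, window, r)$K
  q <- 0.25
  obj <- function(par) {
    kappa <- exp(par[1]); sigma <- exp(par[2])
    sum((Khat^q - .thomas_k(r, kappa, sigma)^q)^2)
  }
  sigma_hi <- min(a, b)  # beyond this the cluster signal is unidentifiable
  # coarse grid in log space (the contrast surface is multimodal for
  # blob-like patterns), then a simplex polish from the grid optimum
  # the parent intensity is kept within a factor 10 of the point intensity
  # so the fitted process stays simulable (at most ~10 n parents per window)
  kgrid <- log(n / (a * b)) + seq(log(1e-4), log(10), length.out = 25)
  sgrid <- seq(log(rmax / 100), log(sigma_hi), length.out = 15)
  grid <- expand.grid(k = kgrid, s = sgrid)
  vals <- vapply(seq_len(nrow(grid)), function(i)
    obj(c(grid$k[i], grid$s[i])), numeric(1))
  p0 <- unlist(grid[which.min(vals), ])
  o <- tryCatch(
    stats::optim(p0, obj, method = "L-BFGS-B",
                 lower = c(min(kgrid), min(sgrid)),
                 upper = c(max(kgrid), log(sigma_hi))),
    error = function(e) NULL)
  best <- if (!is.null(o) && o$value < min(vals)) o
          else list(par = p0, value = min(vals))
  kappa <- unname(exp(best$par[1]))
  sigma <- unname(min(exp(best$par[2]), sigma_hi))
  structure(list(kappa = kappa, sigma = sigma,
                 mu = n / (kappa * a * b), window = window, n_points = n,
                 weak_clustering = sigma > 0.9 * sigma_hi,
                 contrast = best$value, r = r, K_obs = Khat),
            class = "cluster_fit")
}

#' Simulate a Thomas process realization
#'
#' Poisson parents in the window expanded by 4 sigma, Poisson(mu) offspring
#' per parent with isotropic Gaussian(sigma) displacement, clipped to the
#' window.
#'
#' @param fit a `cluster_fit` (or list with `kappa`, `sigma`, `mu`,
#'   `window`).
#' @return two-column coordinate matrix.
#' @export
simulate_thomas <- function(fit) {
  w <- fit$window
  pad <- 4 * fit$sigma
  ext <- c(w[1] - pad, w[2] + pad, w[3] - pad, w[4] + pad)
  lambda_par <- fit$kappa * (ext[2] - ext[1]) * (ext[4] - ext[3])
  if (lambda_par > 1e6)
    stop("fitted parent intensity implies > 1e6 parents in the window; ",
         "refusing to simulate a degenerate fit")
  n_par <- stats::rpois(1, lambda_par)
  if (n_par == 0) return(matrix(numeric(0), 0, 2))
  px <- stats::runif(n_par, ext[1], ext[2])
  py <- stats::runif(n_par, ext[3], ext[4])
  noff <- stats::rpois(n_par, fit$mu)
  x <- rep(px, noff) + stats::rnorm(sum(noff), sd = fit$sigma)
  y <- rep(py, noff) + stats::rnorm(sum(noff), sd = fit$sigma)
  keep <- x >= w[1] & x <= w[2] & y >= w[3] & y <= w[4]
  cbind(x[keep], y[keep])
}

#' Simulate size-matched control hotspot sets
#'
#' Each control set simulates the fitted cluster process, snaps points to
#' the nearest candidate cell, deduplicates, and then repairs the count to
#' exactly `n_cells`: missing cells are added by nearest-neighbor accretion
#' (unselected cell closest to the current set) and excess cells are trimmed
#' farthest-first; ties break on cell id so repair is deterministic given
#' the seed.
#'
#' @param fit a `cluster_fit`; @param cells candidate cells (data frame with
#'   `cell_id`, `x`, `y`); @param cell_km cell size; @param n_cells target
#'   hotspot count (the real set's size); @param n_sets number of control
#'   sets (default 50); @param seed optional.
#' @return list of [region_partition()]s over `cells`.
#' @export
simulate_controls <- function(fit, cells, cell_km, n_cells, n_sets = 50,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_cells > nrow(cells)) stop("window too small to place ", n_cells,
                                  " hotspot cells")
  xy <- cbind(cells$x, cells$y) * cell_km
  ord0 <- order(cells$cell_id)
  lapply(seq_len(n_sets), function(s) {
    pts <- simulate_thomas(fit)
    sel <- logical(nrow(cells))
    if (nrow(pts)) {
      nearest <- apply(pts, 1, function(p)
        which.min((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2))
      sel[unique(nearest)] <- TRUE
    }
    # repair count
    while (sum(sel) < n_cells) {
      if (!any(sel)) { sel[sample.int(length(sel), 1)] <- TRUE; next }
      dmin <- apply(xy[!sel, , drop = FALSE], 1, function(p)
        min((xy[sel, 1] - p[1])^2 + (xy[sel, 2] - p[2])^2))
      cand <- which(!sel)
      pick <- cand[order(dmin, cells$cell_id[cand])][1]
      sel[pick] <- TRUE
    }
    while (sum(sel) > n_cells) {
      cand <- which(sel)
      dnn <- vapply(cand, function(i) {
        others <- setdiff(cand, i)
        min((xy[others, 1] - xy[i, 1])^2 + (xy[others, 2] - xy[i, 2])^2)
      }, numeric(1))
      drop <- cand[order(-dnn, cells$cell_id[cand])][1]
      sel[drop] <- FALSE
    }
    region_partition(cells$cell_id, sel,
                     if ("realm" %in% names(cells)) cells$realm else "all",
                     metric = paste0("control", s))
  })
}

#' Rank a real statistic inside a control distribution
#'
#' Empirical quantile of the real value among the control values, flagged
#' when it falls outside the two-sided 90% envelope (rank < 0.05 or >
#' 0.95), matching an alpha = 0.10 convention.
#'
#' @param real_value statistic from the real delineation; @param
#'   control_values the same statistic across control sets (>= 20).
#' @return list `rank`, `outside`, `n_controls`.
#' @export
null_envelope <- function(real_value, control_values) {
  control_values <- control_values[is.finite(control_values)]
  if (length(control_values) < 20) stop("need at least 20 control values")
  if (stats::sd(control_values) == 0)
    stop("control distribution is constant; envelope undefined")
  rank <- mean(control_values < real_value) +
    0.5 * mean(control_values == real_value)
  list(rank = rank, outside = rank < 0.05 || rank > 0.95,
       n_controls = length(control_values))
}

#' Same-class contiguity of a partition
#'
#' For every cell, the median Euclidean distance to same-class cells within
#' `radius_km`; class means are compared with Welch's t test.  Cells with no
#' same-class neighbor in the radius are excluded and counted.
#'
#' @param partition a [region_partition()]; @param cells coordinates
#'   (`cell_id`, `x`, `y`); @param cell_km cell size; @param radius_km
#'   search radius (default 1000 km).
#' @return list with `means` (per class), `t`, `p.value`, `df`,
#'   `n_isolated`, `per_cell`.
#' @export
contiguity <- function(partition, cells, cell_km = 100, radius_km = 1000) {
  idx <- match(partition$cell_id, cells$cell_id)
  xy <- cbind(cells$x[idx], cells$y[idx]) * cell_km
  D <- as.matrix(stats::dist(xy))
  diag(D) <- Inf
  cls <- partition$class
  same <- outer(cls, cls, "==")
  med <- vapply(seq_len(nrow(D)), function(i) {
    dd <- D[i, same[i, ] & D[i, ] <= radius_km]
    if (!length(dd)) return(NA_real_)
    stats::median(dd)
  }, numeric(1))
  n_isolated <- sum(is.na(med))
  hot <- med[cls == "hotspot"]; non <- med[cls == "non-hotspot"]
  hot <- hot[!is.na(hot)]; non <- non[!is.na(non)]
  if (length(hot) < 2 || length(non) < 2)
    stop("each class needs >= 2 cells with same-class neighbors in radius")
  if (stats::sd(hot) + stats::sd(non) < 1e-12) {
    # degenerate geometry (e.g. a perfect checkerboard): no variance to test
    eq <- abs(mean(hot) - mean(non)) < 1e-12
    tt <- list(statistic = if (eq) 0 else Inf, p.value = if (eq) 1 else 0,
               parameter = NA_real_)
  } else tt <- stats::t.test(hot, non)
  list(means = c(hotspot = mean(hot), `non-hotspot` = mean(non)),
       t = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), n_isolated = n_isolated,
       per_cell = data.frame(cell_id = partition$cell_id, class = cls,
                             median_dist = med))
}
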