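#' Terrain ruggedness index on a pixel grid, averaged per cell
#'
#' Per pixel, the mean absolute elevation difference from its 8 neighbors
#' (border pixels use the neighbors they have); the cell value is the mean
#' over the pixels in the cell.  Invariant to adding a constant elevation.
#'
#' @param elev elevation pixel matrix; @param cell_of integer matrix (same
#'   shape) giving the cell index of each pixel.
#' @return named numeric vector of TRI per cell index.
#' @export
terrain_ruggedness <- function(elev, cell_of) {
  if (length(elev) < 2) stop("single-pixel grid: TRI undefined")
  nr <- nrow(elev); nc <- ncol(elev)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    si <- ri - di; sj <- rj - dj
    acc[si, sj] <- acc[si, sj] + abs(elev[si, sj] - elev[ri, rj])
    cnt[si, sj] <- cnt[si, sj] + 1
  }
  tri <- acc / cnt
  tapply(as.vector(tri), as.vector(cell_of), mean)
}

#' Climate-change velocity (temporal rate over spatial gradient)
#'
#' CCV = |present - past| / elapsed divided by the magnitude of the local
#' spatial gradient of the present layer (central differences on the cell
#' grid).  Gradients below `floor` (default the 1st percentile of the
#' positive gradients) are clamped so flat terrain does not blow up.
#'
#' @param present,past named per-cell climate vectors; @param cells grid
#'   (`cell_id`, `x`, `y`); @param elapsed time between layers; @param
#'   cell_km spatial step; @param floor gradient floor (units of climate
#'   per km); `NULL` for the percentile default.
#' @return named per-cell CCV (distance per time).
#' @export
climate_velocity <- function(present, past, cells, elapsed, cell_km = 100,
                             floor = NULL) {
  stopifnot(elapsed > 0)
  nx <- max(cells$x); ny <- max(cells$y)
  M <- matrix(NA_real_, nx, ny)
  M[cbind(cells$x, cells$y)] <- present[cells$cell_id]
  gx <- matrix(NA_real_, nx, ny); gy <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    xl <- if (i > 1) M[i - 1, j] else NA; xr <- if (i < nx) M[i + 1, j] else NA
    yl <- if (j > 1) M[i, j - 1] else NA; yr <- if (j < ny) M[i, j + 1] else NA
    gx[i, j] <- .cdiff(xl, M[i, j], xr, cell_km)
    gy[i, j] <- .cdiff(yl, M[i, j], yr, cell_km)
  }
  grad <- sqrt(gx^2 + gy^2)[cbind(cells$x, cells$y)]
  pos <- grad[grad > 0 & is.finite(grad)]
  if (!length(pos)) stop("present layer has zero spatial gradient everywhere; ",
                         "set an explicit gradient floor")
  if (is.null(floor)) floor <- stats::quantile(pos, 0.01, names = FALSE)
  grad <- pmax(grad, floor)
  temporal <- abs(present[cells$cell_id] - past[cells$cell_id]) / elapsed
  stats::setNames(as.numeric(temporal / grad), cells$cell_id)
}

.cdiff <- function(lo, mid, hi, h) {
  if (!is.na(lo) && !is.na(hi)) (hi - lo) / (2 * h)
  else if (!is.na(hi)) (hi - mid) / h
  else if (!is.na(lo)) (mid - lo) / h
  else 0
}

#' Tectonic mobility: pooled SD of inter-neighbor distances over time
#'
#' For each cell, the distance to each neighbor (within `radius_km` at the
#' first time slice) is tracked through the position history; the value is
#' the pooled sample SD of the per-neighbor distance series around their
#' per-neighbor means (n-1 denominators pooled across neighbors).  Zero for
#' rigid motion.
#'
#' @param traj array (cells x times x 2) of positions (km); @param cells
#'   grid data frame; @param radius_km neighborhood radius.
#' @return named per-cell SD (km).
#' @export
tectonic_movement <- function(traj, cells, radius_km = 1000) {
  if (dim(traj)[2] < 2) stop("need at least 2 time points")
  n <- dim(traj)[1]; nt <- dim(traj)[2]
  p0 <- traj[, 1, ]
  D0 <- as.matrix(stats::dist(p0))
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(D0[i, ] > 0 & D0[i, ] <= radius_km)
    if (!length(nb)) { out[i] <- NA; next }
    ss <- 0
    for (k in nb) {
      dk <- sqrt((traj[i, , 1] - traj[k, , 1])^2 +
                   (traj[i, , 2] - traj[k, , 2])^2)
      ss <- ss + sum((dk - mean(dk))^2)
    }
    out[i] <- sqrt(ss / (length(nb) * (nt - 1)))
  }
  stats::setNames(out, cells$cell_id)
}

#' Drop later-listed variables that are highly rank-correlated
#'
#' @param env long table (`cell_id`, `variable`, `value`); @param rho_max
#'   Spearman threshold (default 0.70): of any pair above it, the variable
#'   listed later is removed.
#' @return the screened table; attribute `"dropped"`.
#' @export
screen_correlated <- function(env, rho_max = 0.70) {
  wide <- .env_wide(env)
  vars <- colnames(wide)
  drop <- character(0)
  for (i in seq_along(vars)) for (k in seq_along(vars)) {
    if (k <= i || vars[k] %in% drop || vars[i] %in% drop) next
    rho <- stats::cor(wide[, i], wide[, k], method = "spearman",
                      use = "complete.obs")
    if (is.finite(rho) && abs(rho) > rho_max) drop <- c(drop, vars[k])
  }
  out <- env[!(env$variable %in% drop), , drop = FALSE]
  attr(out, "dropped") <- drop
  out
}

.env_wide <- function(env) {
  vars <- unique(env$variable)
  ids <- unique(env$cell_id)
  m <- matrix(NA_real_, length(ids), length(vars),
              dimnames = list(ids, vars))
  m[cbind(match(env$cell_id, ids), match(env$variable, vars))] <- env$value
  m
}

#' Standardized SAR contrasts of environment between hotspot classes
#'
#' Per variable: center and scale to unit SD, fit the SAR error model with
#' the hotspot indicator as the sole predictor (plus intercept), and report
#' the standardized coefficient with Bonferroni-corrected significance
#' across the variable set.  Zero-variance variables are skipped with a
#' warning.
#'
#' @param env long table (`cell_id`, `variable`, `value`); @param partition
#'   a [region_partition()]; @param W [spatial_weights()] on the same cells
#'   (1000-km rule); @param alpha familywise level (default 0.05).
#' @return data frame: `variable`, `beta`, `se`, `lambda`, `p_raw`,
#'   `p_bonferroni`, `significant`; attribute `"scaling"` records each
#'   variable's mean and SD for exact back-transformation.
#' @export
env_sar_contrast <- function(env, partition, W, alpha = 0.05) {
  wide <- .env_wide(env)
  ids <- rownames(wide)
  stopifnot(identical(sort(ids), sort(as.character(W$cell_id))))
  wide <- wide[as.character(W$cell_id), , drop = FALSE]
  hot <- as.numeric(W$cell_id %in%
                      partition$cell_id[partition$class == "hotspot"])
  if (sum(hot) < 2 || sum(1 - hot) < 2) stop("need >= 2 cells per class")
  X <- cbind(intercept = 1, hotspot = hot)
  vars <- colnames(wide)
  res <- list(); scaling <- list()
  for (v in vars) {
    y <- wide[, v]
    s <- stats::sd(y)
    if (!is.finite(s) || s == 0) {
      warning("variable ", v, " has zero variance; skipped")
      next
    }
    scaling[[v]] <- c(mean = mean(y), sd = s)
    fit <- fit_sar_error((y - mean(y)) / s, X, W)
    res[[v]] <- data.frame(variable = v, beta = fit$coefficients[2],
                           se = fit$se[2], lambda = fit$lambda,
                           p_raw = fit$p.value[2])
  }
  out <- do.call(rbind, res)
  m <- nrow(out)
  out$p_bonferroni <- pmin(1, out$p_raw * m)
  out$significant <- out$p_bonferroni < alpha
  rownames(out) <- NULL
  attr(out, "scaling") <- scaling
  out
}
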