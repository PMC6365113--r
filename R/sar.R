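#' Row-standardized spatial weights from cell coordinates
#'
#' Binary symmetric neighbors within `radius_km` (Euclidean distance on the
#' projected grid, cell centers at `(x, y) * cell_km`), row-standardized.
#' Eigenvalues of the row-standardized matrix (real, via the symmetric
#' similarity transform) are cached for the SAR log-determinant.
#'
#' @param cells data frame with `cell_id`, `x`, `y`.
#' @param cell_km cell side in km.
#' @param radius_km neighbor radius in km (default 1000, the rule used for
#'   all spatial models here).
#' @return object of class `spatial_weights`: list with `W` (dense row-
#'   standardized matrix), `cell_id`, `eigenvalues`, `isolated` (cell ids
#'   with no neighbor in radius).
#' @export
spatial_weights <- function(cells, cell_km = 100, radius_km = 1000) {
  xy <- cbind(cells$x, cells$y) * cell_km
  D <- as.matrix(stats::dist(xy))
  B <- (D > 0 & D <= radius_km) * 1
  rs <- rowSums(B)
  isolated <- cells$cell_id[rs == 0]
  W <- B / ifelse(rs == 0, 1, rs)
  # W = D^-1 B with B symmetric: eigenvalues of W equal those of the
  # symmetric D^-1/2 B D^-1/2 on the non-isolated block, plus zeros
  keep <- rs > 0
  ev <- rep(0, nrow(B))
  if (any(keep)) {
    s <- 1 / sqrt(rs[keep])
    M <- B[keep, keep, drop = FALSE] * tcrossprod(s)
    ev[seq_len(sum(keep))] <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  }
  structure(list(W = W, cell_id = cells$cell_id, eigenvalues = ev,
                 isolated = isolated),
            class = "spatial_weights")
}

#' Maximum-likelihood SAR error model
#'
#' Fits y = X beta + u with u = lambda W u + eps, eps iid Gaussian, by
#' profile likelihood over lambda: for fixed lambda the model is a GLS fit
#' of (I - lambda W) y on (I - lambda W) X, and the log-determinant
#' log|I - lambda W| is evaluated exactly from the cached eigenvalues of W.
#' lambda is searched on the admissible interval bounded by the reciprocal
#' extreme eigenvalues.
#'
#' @param y response per cell; @param X model matrix (no intercept added —
#'   pass one explicitly or use a formula upstream); @param W a
#'   [spatial_weights()] object.
#' @return object of class `sar_fit`: `coefficients`, `se`, `z`, `p.value`,
#'   `lambda`, `lambda_se`, `sigma2`, `loglik`, `residuals` (response
#'   residuals y - X beta) and `sar_residuals` (whitened residuals
#'   (I - lambda W)(y - X beta)).
#' @export
fit_sar_error <- function(y, X, W) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(W$W) == n)
  if (n <= ncol(X) + 2) stop("too few cells for the predictor count")
  ev <- W$eigenvalues
  lo <- if (min(ev) < 0) 1 / min(ev) + 1e-9 else -0.999
  hi <- if (max(ev) > 0) 1 / max(ev) - 1e-9 else 0.999

  # profile over lambda works on the pre-multiplied Wy, WX so no dense
  # (I - lambda W) is ever formed inside the search
  Wy <- W$W %*% y
  WX <- W$W %*% X
  profile <- function(lambda) {
    Ay <- y - lambda * Wy; AX <- X - lambda * WX
    fit <- stats::lm.fit(AX, Ay)
    rss <- sum(fit$residuals^2)
    s2 <- rss / n
    ld <- sum(log(1 - lambda * ev))
    ll <- -n / 2 * (log(2 * pi * s2) + 1) + ld
    list(ll = ll, beta = fit$coefficients, s2 = s2)
  }

  if (max(abs(W$W)) == 0) {
    opt_lambda <- 0
  } else {
    opt <- stats::optimize(function(l) -profile(l)$ll, c(lo, hi), tol = 1e-8)
    opt_lambda <- opt$minimum
  }
  pr <- profile(opt_lambda)
  beta <- pr$beta
  AX <- X - opt_lambda * WX
  covb <- pr$s2 * solve(crossprod(AX))
  se <- sqrt(diag(covb))
  z <- beta / se
  resid <- as.numeric(y - X %*% beta)
  # lambda SE from the numerical curvature of the profile log-likelihood
  h <- min(1e-4, (hi - lo) / 100)
  l0 <- pr$ll
  lp <- profile(min(opt_lambda + h, hi))$ll
  lm_ <- profile(max(opt_lambda - h, lo))$ll
  d2 <- (lp - 2 * l0 + lm_) / h^2
  lambda_se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  structure(list(coefficients = as.numeric(beta), se = se, z = as.numeric(z),
                 p.value = 2 * stats::pnorm(-abs(as.numeric(z))),
                 lambda = opt_lambda, lambda_se = lambda_se,
                 sigma2 = pr$s2, loglik = l0,
                 residuals = resid,
                 sar_residuals = as.numeric(resid - opt_lambda * W$W %*% resid)),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("SAR error fit: lambda = %.4f, lnL = %.3f\n", x$lambda, x$loglik))
  print(data.frame(beta = x$coefficients, se = x$se, z = x$z, p = x$p.value))
  invisible(x)
}

#' Simulate a SAR error field
#'
#' Draws u = (I - lambda W)^{-1} eps with iid Gaussian eps, the error
#' process the SAR model assumes; used by the synthetic environment
#' generator and the calibration tests.
#'
#' @param W a [spatial_weights()]; @param lambda autocorrelation in (-1, 1);
#' @param sigma innovation SD; @param n_rep number of fields.
#' @return matrix (cells x n_rep).
#' @export
simulate_sar_error <- function(W, lambda, sigma = 1, n_rep = 1) {
  n <- nrow(W$W)
  A <- diag(n) - lambda * W$W
  if (abs(det_check <- min(abs(1 - lambda * W$eigenvalues))) < 1e-10)
    stop("(I - lambda W) is singular at lambda = ", lambda,
         " (eigenvalue bound 1/", max(abs(W$eigenvalues)), ")")
  eps <- matrix(stats::rnorm(n * n_rep, sd = sigma), n, n_rep)
  solve(A, eps)
}
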