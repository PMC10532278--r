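#' Local quadratic weighted least squares fit
#'
#' Fits \eqn{y \approx \gamma_0 + \gamma_1 (a - a_t) + \gamma_2 (a - a_t)^2}
#' by weighted least squares (the closed-form normal equations).  When the
#' design is singular (fewer than three distinct moderator values with
#' positive weight) the quadratic term, and if necessary the linear term, is
#' dropped; dropped coefficients are returned as zero.
#'
#' @param y numeric response vector (missing values allowed; dropped).
#' @param a numeric moderator vector.
#' @param at focal point (scalar).
#' @param w nonnegative weight vector.
#' @return numeric vector \code{c(intercept, slope, curvature)}.
#' @examples
#' a <- seq(-1, 1, length.out = 20)
#' localQuadraticFit(1 + 2 * a + 3 * a^2, a, at = 0, w = rep(1, 20))
#' @export
localQuadraticFit <- function(y, a, at, w) {
  keep <- !is.na(y) & w > 0
  y <- y[keep]; d <- a[keep] - at; w <- w[keep]
  if (length(y) == 0L) stop("no observations with positive weight")
  ndist <- length(unique(d))
  for (deg in seq(min(2L, ndist - 1L), 0L)) {
    X <- outer(d, 0:deg, `^`)
    XtW <- t(X * w)
    cf <- tryCatch(solve(XtW %*% X, XtW %*% y), error = function(e) NULL)
    if (!is.null(cf) && all(is.finite(cf))) {
      return(c(cf, numeric(2L - deg)))
    }
  }
  c(stats::weighted.mean(y, w), 0, 0)
}

#' Positive definite repair by eigenvalue clipping
#'
#' Clips eigenvalues below \code{floor} times the largest eigenvalue,
#' reassembles the matrix, and rescales the diagonal back to the input
#' diagonal (when positive).  Idempotent on matrices that are already
#' positive definite.
#'
#' @param M symmetric matrix.
#' @param floor relative eigenvalue floor (default 1e-4).
#' @return positive definite matrix of the same dimension.
#' @export
repairPositiveDefinite <- function(M, floor = 1e-4) {
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8))) {
    stop("input must be symmetric")
  }
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  thresh <- floor * max(max(ev$values), 0)
  if (thresh <= 0) thresh <- floor
  if (min(ev$values) >= thresh) return(M)
  lam <- pmax(ev$values, thresh)
  out <- ev$vectors %*% (lam * t(ev$vectors))
  d0 <- diag(M)
  if (all(d0 > 0)) {
    s <- sqrt(d0 / diag(out))
    out <- out * tcrossprod(s)
  }
  (out + t(out)) / 2
}

#' Focal-point density
#'
#' Normalized kernel weight mass per focal point,
#' \eqn{\hat f(a_t) = W_t / \sum_s W_s}; used as the weight in parameter
#' curve means and standard deviations.
#'
#' @param weights an [LsemWeights-class].
#' @return numeric vector summing to 1.
#' @export
gridDensity <- function(weights) weights@density

#' Kernel-weighted conditional means and covariance matrices
#'
#' At each focal point, the conditional mean of every indicator is estimated
#' by local quadratic regression in the centered moderator; residuals from
#' these local fits then yield the conditional covariance matrix, either by
#' direct kernel weighting
#' \eqn{\hat\sigma_{ij}(a_t) = W_t^{-1}\sum_n w_{nt} e_{nit} e_{njt}}
#' (\code{mode = "weighted"}) or as the intercept of a second local
#' quadratic regression of the residual products on the centered moderator
#' (\code{mode = "local_regression"}).  Missing indicator values are handled
#' by pairwise deletion with per-pair weight renormalization; resulting
#' matrices (and any indefinite estimate) are repaired by
#' [repairPositiveDefinite()] when \code{pd = TRUE}.
#'
#' @param x numeric matrix or data.frame of indicators (N x I).
#' @param a numeric moderator vector of length N.
#' @param weights an [LsemWeights-class] aligned with \code{x}.
#' @param residualize logical; residualize the mean structure by local
#'   quadratic regression (default) instead of subtracting the plain
#'   kernel-weighted mean.
#' @param mode \code{"weighted"} or \code{"local_regression"}.
#' @param pd logical; repair non-positive-definite conditional covariance
#'   matrices.
#' @param pd_floor relative eigenvalue floor for the repair.
#' @return an [LsemMoments-class] object.
#' @export
localMoments <- function(x, a, weights, residualize = TRUE,
                         mode = c("weighted", "local_regression"),
                         pd = TRUE, pd_floor = 1e-4) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  N <- nrow(x); I <- ncol(x)
  stopifnot(length(a) == N, nrow(weights@weights) == N)
  grid <- weights@grid
  Tn <- length(grid)
  has_na <- anyNA(x)

  means <- matrix(NA_real_, I, Tn, dimnames = list(colnames(x), NULL))
  mean_coef <- array(0, c(I, 3, Tn))
  covs <- array(NA_real_, c(I, I, Tn),
                dimnames = list(colnames(x), colnames(x), NULL))
  repaired <- logical(Tn)

  if (!has_na) {
    # complete data: compiled path over all focal points at once
    res <- .local_moments_cpp(x, a, weights@weights, grid, residualize,
                              if (mode == "weighted") 1L else 2L)
    means[] <- res$means
    mean_coef[] <- res$coefs
    for (t in seq_len(Tn)) {
      S <- res$covs[, , t]
      if (pd) {
        S2 <- repairPositiveDefinite(S, pd_floor)
        repaired[t] <- !isTRUE(all.equal(S2, S, tolerance = 1e-12))
        S <- S2
      }
      covs[, , t] <- S
    }
    return(new("LsemMoments", grid = grid, means = means,
               mean_coef = mean_coef, cov = covs, Wt = weights@Wt,
               density = weights@density, pd_repaired = repaired,
               mode = mode, indicators = colnames(x)))
  }

  pairs <- which(lower.tri(diag(I), diag = TRUE), arr.ind = TRUE)

  for (t in seq_len(Tn)) {
    w <- weights@weights[, t]
    d <- a - grid[t]
    if (has_na) {
      allmiss <- vapply(seq_len(I), function(i) {
        all(is.na(x[w > 0, i]))
      }, logical(1))
      if (any(allmiss)) {
        stop("indicator(s) entirely missing at focal point ",
             signif(grid[t], 4), ": ",
             paste(colnames(x)[allmiss], collapse = ", "))
      }
    }

    # conditional means and residuals (pairwise-deletion path)
    E <- matrix(NA_real_, N, I)
    for (i in seq_len(I)) {
      if (residualize) {
        cf <- localQuadraticFit(x[, i], a, grid[t], w)
      } else {
        keep <- !is.na(x[, i]) & w > 0
        cf <- c(stats::weighted.mean(x[keep, i], w[keep]), 0, 0)
      }
      mean_coef[i, , t] <- cf
      E[, i] <- x[, i] - (cf[1] + cf[2] * d + cf[3] * d^2)
    }
    means[, t] <- mean_coef[, 1, t]

    # conditional covariance from pairwise-complete cases with per-pair
    # weight renormalization
    {
      S <- matrix(0, I, I)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        keep <- !is.na(E[, i]) & !is.na(E[, j]) & w > 0
        if (!any(keep)) {
          stop("no complete pairs for (", colnames(x)[i], ", ",
               colnames(x)[j], ") at focal point ", signif(grid[t], 4))
        }
        if (mode == "weighted") {
          v <- sum(w[keep] * E[keep, i] * E[keep, j]) / sum(w[keep])
        } else {
          v <- localQuadraticFit(E[, i] * E[, j], a, grid[t], w)[1]
        }
        S[i, j] <- S[j, i] <- v
      }
    }
    if (pd) {
      S2 <- repairPositiveDefinite(S, pd_floor)
      repaired[t] <- !isTRUE(all.equal(S2, S, tolerance = 1e-12))
      S <- S2
    }
    covs[, , t] <- S
  }

  new("LsemMoments", grid = grid, means = means, mean_coef = mean_coef,
      cov = covs, Wt = weights@Wt, density = weights@density,
      pd_repaired = repaired, mode = mode, indicators = colnames(x))
}
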