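#' Weighted mean and standard deviation of a parameter curve
#'
#' \eqn{\hat M = \sum_t \hat f(a_t) \hat\theta(a_t)} and
#' \eqn{\widehat{SD} = \sqrt{\sum_t \hat f(a_t) (\hat\theta(a_t) - \hat M)^2}},
#' with the focal-point density \eqn{\hat f} as weights.
#'
#' @param theta numeric parameter curve over the focal points.
#' @param f focal-point density (nonnegative, sums to 1).
#' @return named numeric vector \code{c(M = ..., SD = ...)}.
#' @examples
#' curveMeanSd(c(0, 1), c(.5, .5))  # M = 0.5, SD = 0.5
#' @export
curveMeanSd <- function(theta, f) {
  stopifnot(length(theta) == length(f), all(f >= 0))
  if (abs(sum(f) - 1) > 1e-8) stop("density must sum to 1")
  M <- sum(f * theta)
  c(M = M, SD = sqrt(sum(f * (theta - M)^2)))
}

#' Bootstrap bias correction of the curve standard deviation
#'
#' The naive curve SD is positively biased under no true variation.  The
#' bootstrap estimate of the bias of \eqn{SD^2} is
#' \eqn{\hat B = mean(SD^{*2}) - \widehat{SD}^2}, giving the clamped
#' bias-corrected estimate
#' \eqn{\widehat{SD}_{bc} = \sqrt{\max(0, 2\widehat{SD}^2 - mean(SD^{*2}))}}.
#'
#' @param sd_hat curve SD from the original sample.
#' @param sd_reps vector of curve SDs from resampling replicates.
#' @return list with \code{sd_bc} and \code{se} (SD of the replicate SDs).
#' @export
sdBiasCorrected <- function(sd_hat, sd_reps) {
  stopifnot(length(sd_reps) >= 2)
  list(sd_bc = sqrt(max(0, 2 * sd_hat^2 - mean(sd_reps^2))),
       se = stats::sd(sd_reps))
}

#' Significance test for parameter-curve variation based on the SD
#'
#' \eqn{t = \widehat{SD}_{bc} / SE} referred to the standard normal; the
#' p-value is the one-sided upper tail (variation is a one-directional
#' alternative since SD is nonnegative).
#'
#' @param sd_bc bias-corrected curve SD.
#' @param se bootstrap standard error of the curve SD.
#' @return list with \code{t} and \code{p}; both NA (with a warning) when
#'   \code{se} is zero, in which case the test is undefined.
#' @export
sdTest <- function(sd_bc, se) {
  if (!isTRUE(se > 0)) {
    warning("SE of the curve SD is zero; SD test undefined")
    return(list(t = NA_real_, p = NA_real_))
  }
  t <- sd_bc / se
  list(t = t, p = stats::pnorm(t, lower.tail = FALSE))
}

#' Wald test of parameter-curve equality across focal points
#'
#' Tests \eqn{H\xi = 0} for the curve vector
#' \eqn{\xi = (\theta(a_1), \ldots, \theta(a_T))} with the (T-1) x T
#' first-difference contrast matrix H and a resampling covariance V:
#' \eqn{\chi^2 = (H\hat\xi)^\top (H V H^\top)^{-1} (H\hat\xi)} with T-1
#' degrees of freedom.  A singular \eqn{H V H^\top} is handled by the
#' Moore-Penrose pseudo-inverse with rank-adjusted degrees of freedom.
#'
#' @param xi estimated parameter curve (length T).
#' @param V T x T covariance matrix of the curve (e.g. from bootstrap).
#' @param H optional contrast matrix; defaults to first differences.
#' @return list with \code{chisq}, \code{df}, \code{p}, \code{H}.
#' @export
waldEqualityTest <- function(xi, V, H = NULL) {
  Tn <- length(xi)
  if (is.null(H)) {
    H <- diff(diag(Tn))
  }
  stopifnot(ncol(H) == Tn, all(dim(V) == Tn))
  hv <- H %*% V %*% t(H)
  hxi <- drop(H %*% xi)
  qrr <- qr(hv)
  if (qrr$rank == nrow(hv)) {
    chisq <- drop(crossprod(hxi, solve(hv, hxi)))
    df <- nrow(H)
  } else {
    chisq <- drop(crossprod(hxi, MASS::ginv(hv) %*% hxi))
    df <- qrr$rank
  }
  chisq <- max(0, chisq)
  p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  list(chisq = chisq, df = df, p = p, H = H)
}

#' Wald test of a functional form for a parameter curve
#'
#' Regresses the estimated curve on functions of the moderator (e.g. linear
#' and quadratic terms) by generalized least squares with the resampling
#' covariance V, and tests whether the non-intercept coefficient block is
#' zero.
#'
#' @param xi estimated parameter curve (length T).
#' @param grid focal points.
#' @param V T x T covariance matrix of the curve.
#' @param hypothesis one-sided formula in the moderator variable \code{m},
#'   e.g. \code{~ m + I(m^2)} (the default: linear plus quadratic trend).
#' @return list with \code{coef} (GLS coefficients), \code{chisq},
#'   \code{df}, \code{p}.
#' @export
waldFunctionalTest <- function(xi, grid, V, hypothesis = ~ m + I(m^2)) {
  X <- stats::model.matrix(hypothesis, data.frame(m = grid))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient hypothesis design matrix")
  Vi <- tryCatch(solve(V), error = function(e) MASS::ginv(V))
  XtVi <- crossprod(X, Vi)
  covb <- tryCatch(solve(XtVi %*% X), error = function(e) MASS::ginv(XtVi %*% X))
  b <- drop(covb %*% XtVi %*% xi)
  names(b) <- colnames(X)
  keep <- which(colnames(X) != "(Intercept)")
  if (length(keep) == 0L) stop("hypothesis contains no testable terms")
  bb <- b[keep]
  Vb <- covb[keep, keep, drop = FALSE]
  chisq <- max(0, drop(crossprod(bb, tryCatch(solve(Vb, bb),
                error = function(e) MASS::ginv(Vb) %*% bb))))
  df <- length(keep)
  list(coef = b, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}
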