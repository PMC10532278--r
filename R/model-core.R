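#' Materialize model matrices at a parameter vector
#'
#' Fills the loading matrix \eqn{\Lambda}, structural matrix \eqn{B}, factor
#' covariance matrix \eqn{\Phi} and residual covariance matrix \eqn{\Psi} of
#' a model with the fixed values from the model specification and the free
#' values from a named parameter vector.
#'
#' @param model an [LsemModel-class].
#' @param theta named numeric vector covering every free parameter label.
#' @return list with elements \code{lambda}, \code{beta}, \code{phi},
#'   \code{psi} (symmetric), named by indicators/factors.
#' @export
modelMatrices <- function(model, theta) {
  pt <- model@partable
  I <- length(model@indicators)
  nf <- length(model@factors)
  lambda <- matrix(0, I, nf, dimnames = list(model@indicators, model@factors))
  beta <- matrix(0, nf, nf, dimnames = list(model@factors, model@factors))
  phi <- matrix(0, nf, nf, dimnames = list(model@factors, model@factors))
  psi <- matrix(0, I, I, dimnames = list(model@indicators, model@indicators))
  missing <- setdiff(pt$label[pt$free], names(theta))
  if (length(missing)) {
    stop("theta misses free parameter(s): ", paste(missing, collapse = ", "))
  }
  for (k in seq_len(nrow(pt))) {
    v <- if (pt$free[k]) unname(theta[pt$label[k]]) else pt$value[k]
    r <- pt$row[k]; cc <- pt$col[k]
    switch(pt$mat[k],
      lambda = { lambda[r, cc] <- v },
      beta = { beta[r, cc] <- v },
      phi = { phi[r, cc] <- v; phi[cc, r] <- v },
      psi = { psi[r, cc] <- v; psi[cc, r] <- v }
    )
  }
  list(lambda = lambda, beta = beta, phi = phi, psi = psi)
}

#' Model-implied covariance matrix
#'
#' Computes \eqn{\Sigma(\theta) = \Lambda (I-B)^{-1} \Phi [(I-B)^{-1}]^\top
#' \Lambda^\top + \Psi}, which reduces to \eqn{\Lambda \Phi \Lambda^\top +
#' \Psi} when no structural paths are present.
#'
#' @inheritParams modelMatrices
#' @return symmetric I x I matrix with indicator dimnames.
#' @examples
#' m <- lsemModel("F =~ 1*X1 + 1*X2 + 1*X3")
#' impliedCovariance(m, c("F~~F" = 1, "X1~~X1" = 1, "X2~~X2" = 1, "X3~~X3" = 1))
#' @export
impliedCovariance <- function(model, theta) {
  mats <- modelMatrices(model, theta)
  nf <- length(model@factors)
  if (any(mats$beta != 0)) {
    ImB <- diag(nf) - mats$beta
    d <- det(ImB)
    if (!is.finite(d) || abs(d) < 1e-12) stop("singular (I - B)")
    G <- solve(ImB)
    C <- G %*% mats$phi %*% t(G)
  } else {
    C <- mats$phi
  }
  Sigma <- mats$lambda %*% C %*% t(mats$lambda) + mats$psi
  (Sigma + t(Sigma)) / 2
}

#' Maximum likelihood discrepancy between two covariance matrices
#'
#' \eqn{D(S, \Sigma) = \log|\Sigma| + tr(S \Sigma^{-1}) - \log|S| - I}.
#' Nonnegative, and zero exactly when \eqn{S = \Sigma}.
#'
#' @param S sample covariance matrix (symmetric positive definite).
#' @param Sigma model-implied covariance matrix (symmetric positive definite).
#' @return nonnegative scalar.
#' @examples
#' mlDiscrepancy(diag(2), 2 * diag(2))  # 2*log(2) - 1
#' @export
mlDiscrepancy <- function(S, Sigma) {
  stopifnot(is.matrix(S), is.matrix(Sigma), all(dim(S) == dim(Sigma)))
  cS <- tryCatch(chol(S), error = function(e) NULL)
  cSig <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cS) || is.null(cSig)) stop("inputs must be positive definite")
  I <- nrow(S)
  ld_S <- 2 * sum(log(diag(cS)))
  ld_Sig <- 2 * sum(log(diag(cSig)))
  tr <- sum(S * chol2inv(cSig))
  max(0, ld_Sig + tr - ld_S - I)
}

#' Standardized solution (correlation metric)
#'
#' Converts a parameter vector to the fully standardized metric: factor
#' (co)variances become correlations, loadings are rescaled by (total) factor
#' SD over indicator SD, structural coefficients by the SD ratio of the
#' involved factors, and residual (co)variances by the indicator SDs.  When
#' structural paths are present, factor SDs are the total (reduced-form)
#' standard deviations.
#'
#' @inheritParams modelMatrices
#' @return named numeric vector of standardized parameters (all labels).
#' @export
standardizeSolution <- function(model, theta) {
  mats <- modelMatrices(model, theta)
  nf <- length(model@factors)
  if (any(mats$beta != 0)) {
    G <- solve(diag(nf) - mats$beta)
    Veta <- G %*% mats$phi %*% t(G)
  } else {
    Veta <- mats$phi
  }
  Sigma <- mats$lambda %*% Veta %*% t(mats$lambda) + mats$psi
  sd_f <- sqrt(diag(Veta))
  sd_x <- sqrt(diag(Sigma))
  if (any(sd_f <= 0) || any(sd_x <= 0)) stop("zero implied variance")
  pt <- model@partable
  out <- numeric(nrow(pt))
  for (k in seq_len(nrow(pt))) {
    v <- if (pt$free[k]) unname(theta[pt$label[k]]) else pt$value[k]
    r <- pt$row[k]; cc <- pt$col[k]
    out[k] <- switch(pt$mat[k],
      lambda = v * sd_f[cc] / sd_x[r],
      beta = v * sd_f[cc] / sd_f[r],
      phi = if (r == cc) 1 else Veta[r, cc] / (sd_f[r] * sd_f[cc]),
      psi = v / (sd_x[r] * sd_x[cc])
    )
  }
  stats::setNames(out, pt$label)
}
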