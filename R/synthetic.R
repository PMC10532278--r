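# Data-generating model presets, exact-moment population construction, and
# the Monte Carlo harness for recovery and size/power experiments.

#' Data-generating model presets for moderator-dependent factor models
#'
#' Three invariance profiles over a moderator grid (default ages 6..18, 13
#' points), for a two-factor model with three indicators per factor (or its
#' one-factor first block):
#' \describe{
#'   \item{dgm1}{all measurement and structural parameters vary with the
#'     moderator except the residual variances: free loadings move linearly
#'     within 0.5-0.9, factor variances and the factor correlation
#'     (0.4-0.75) change linearly, and indicator means have a mild linear
#'     trend.}
#'   \item{dgm2}{loadings and residual variances invariant; factor
#'     variances and correlation vary as in dgm1.}
#'   \item{dgm3}{everything invariant (the null model for type-I error
#'     studies).}
#' }
#' Anchor loadings (first indicator per factor) are fixed at 1 so the
#' generating curves live in the same identification as a fitted model with
#' a unit first loading.  Residual variances are 0.5 throughout.
#'
#' @param preset \code{"dgm1"}, \code{"dgm2"} or \code{"dgm3"}.
#' @param n_factors 1 or 2.
#' @param grid moderator grid (default \code{6:18}).
#' @param group_size population group size per moderator value (default
#'   10000).
#' @return an object of class \code{lsemDGM}: a list with the preset name,
#'   grid, group size, indicator/factor names, fitted-model syntax, a
#'   function \code{pars(a)} returning the loading matrix, factor
#'   covariance matrix, residual covariance matrix and mean vector at
#'   moderator value a, and \code{sigma(a)} returning the implied
#'   population covariance matrix.
#' @examples
#' dgm <- lsemDGM("dgm3", n_factors = 1)
#' dgm$sigma(12)
#' @export
lsemDGM <- function(preset = c("dgm1", "dgm2", "dgm3"), n_factors = 2,
                    grid = 6:18, group_size = 10000) {
  preset <- match.arg(preset)
  stopifnot(n_factors %in% 1:2, length(grid) >= 2)
  mid <- mean(range(grid)); half <- diff(range(grid)) / 2
  uf <- function(a) (a - mid) / half

  indicators <- c("X1", "X2", "X3", "Y1", "Y2", "Y3")[seq_len(3 * n_factors)]
  factors <- c("FX", "FY")[seq_len(n_factors)]

  pars <- function(a) {
    u <- uf(a)
    l2x <- switch(preset, dgm1 = 0.7 + 0.2 * u, dgm2 = 0.7, dgm3 = 0.7)
    l3x <- switch(preset, dgm1 = 0.7 - 0.2 * u, dgm2 = 0.8, dgm3 = 0.8)
    l2y <- switch(preset, dgm1 = 0.7 - 0.2 * u, dgm2 = 0.7, dgm3 = 0.7)
    l3y <- switch(preset, dgm1 = 0.7 + 0.2 * u, dgm2 = 0.8, dgm3 = 0.8)
    phx <- switch(preset, dgm1 = 0.5 + 0.15 * u, dgm2 = 0.5 + 0.15 * u,
                  dgm3 = 0.5)
    phy <- switch(preset, dgm1 = 0.6 - 0.15 * u, dgm2 = 0.6 - 0.15 * u,
                  dgm3 = 0.6)
    rho <- switch(preset, dgm1 = 0.575 + 0.175 * u, dgm2 = 0.575 + 0.175 * u,
                  dgm3 = 0.6)
    mu1 <- switch(preset, dgm1 = 0.2 * u, dgm2 = 0, dgm3 = 0)
    I <- 3 * n_factors
    lambda <- matrix(0, I, n_factors,
                     dimnames = list(indicators, factors))
    lambda[1:3, 1] <- c(1, l2x, l3x)
    if (n_factors == 2) lambda[4:6, 2] <- c(1, l2y, l3y)
    phi <- matrix(phx, 1, 1)
    if (n_factors == 2) {
      phi <- matrix(c(phx, rho * sqrt(phx * phy),
                      rho * sqrt(phx * phy), phy), 2, 2)
    }
    dimnames(phi) <- list(factors, factors)
    psi <- diag(0.5, I)
    dimnames(psi) <- list(indicators, indicators)
    mu <- rep(mu1, I)
    names(mu) <- indicators
    list(lambda = lambda, phi = phi, psi = psi, mu = mu)
  }
  sigma <- function(a) {
    p <- pars(a)
    S <- p$lambda %*% p$phi %*% t(p$lambda) + p$psi
    (S + t(S)) / 2
  }

  syntax <- "FX =~ X1 + X2 + X3"
  if (n_factors == 2) syntax <- paste(syntax, "FY =~ Y1 + Y2 + Y3", sep = "\n")

  structure(list(preset = preset, grid = as.numeric(grid),
                 group_size = group_size, n_factors = n_factors,
                 indicators = indicators, factors = factors,
                 model_syntax = syntax, pars = pars, sigma = sigma),
            class = "lsemDGM")
}

#' True parameter curves of a DGM preset
#'
#' Evaluates the generating parameter curves at the grid, keyed by the
#' labels of the fitted model with unit anchor loadings, plus
#' \code{std__FX~~FY} for the factor correlation.
#'
#' @param dgm an \code{lsemDGM}.
#' @return matrix label x focal point of true values.
#' @export
dgmTrueCurves <- function(dgm) {
  labs <- character(0)
  out <- sapply(dgm$grid, function(a) {
    p <- dgm$pars(a)
    v <- c()
    for (f in seq_len(dgm$n_factors)) {
      idx <- (3 * (f - 1) + 1):(3 * f)
      fac <- dgm$factors[f]
      v <- c(v,
             stats::setNames(p$lambda[idx[2:3], f],
                             paste0(fac, "=~", dgm$indicators[idx[2:3]])),
             stats::setNames(p$phi[f, f], paste0(fac, "~~", fac)))
    }
    if (dgm$n_factors == 2) {
      v <- c(v, "FX~~FY" = p$phi[1, 2],
             "std__FX~~FY" = p$phi[1, 2] / sqrt(p$phi[1, 1] * p$phi[2, 2]))
    }
    v <- c(v, stats::setNames(diag(p$psi),
                              paste0(dgm$indicators, "~~", dgm$indicators)))
    v
  })
  out
}

#' Exact-moment synthetic population
#'
#' For each moderator grid value, draws a multivariate normal block and
#' re-standardizes it (whitening and recoloring via Cholesky factors) so
#' that the per-group sample mean equals the target mean exactly and the
#' per-group sample covariance (with denominator n) equals the target
#' covariance matrix exactly.  Local moment estimation on the full
#' population with a uniform kernel of half-grid-spacing bandwidth
#' therefore reproduces the generating covariance curves to numerical
#' precision.
#'
#' @param dgm an \code{lsemDGM}.
#' @param group_size rows per moderator value (default from the DGM spec);
#'   must exceed the number of indicators plus 2.
#' @param seed integer seed.
#' @return data.frame with the indicator columns and the moderator column
#'   \code{age}.
#' @export
makePopulation <- function(dgm, group_size = dgm$group_size, seed = 1) {
  I <- length(dgm$indicators)
  if (group_size <= I + 2) stop("group_size must exceed #indicators + 2")
  set.seed(seed)
  blocks <- lapply(dgm$grid, function(a) {
    Sig <- dgm$sigma(a)
    ev <- min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("target covariance not positive definite at a = ", a)
    p <- dgm$pars(a)
    Z <- matrix(stats::rnorm(group_size * I), group_size, I)
    Zc <- scale(Z, center = TRUE, scale = FALSE)
    Sz <- crossprod(Zc) / group_size
    Zw <- Zc %*% solve(chol(Sz))
    X <- Zw %*% chol(Sig)
    X <- sweep(X, 2, p$mu, `+`)
    colnames(X) <- dgm$indicators
    cbind(as.data.frame(X), age = a)
  })
  do.call(rbind, blocks)
}

#' Subsample a population dataset
#'
#' @param population data.frame (e.g. from [makePopulation()]).
#' @param N sample size.
#' @param seed integer seed (NULL: use the current RNG state).
#' @param replace sample with replacement.
#' @return data.frame of N rows.
#' @export
drawSample <- function(population, N, seed = NULL, replace = FALSE) {
  if (!replace && N > nrow(population)) {
    stop("N exceeds the population size for sampling without replacement")
  }
  if (!is.null(seed)) set.seed(seed)
  population[sample.int(nrow(population), N, replace = replace), ,
             drop = FALSE]
}

#' Weighted bias and RMSE of estimated parameter curves
#'
#' Given estimates \eqn{\hat\theta_r(a_t)} over replications r, the true
#' curve and focal-point proportions f:
#' \eqn{wBias = \sum_t f(a_t) |mean_r(\hat\theta_r(a_t)) - \theta(a_t)|} and
#' \eqn{wRMSE = \sum_t f(a_t) \sqrt{mean_r (\hat\theta_r(a_t) -
#' \theta(a_t))^2}}.
#'
#' @param est T x R matrix of estimates (focal points by replications).
#' @param truth true curve (length T).
#' @param f focal-point proportions (sum to 1).
#' @return named vector \code{c(wBias, wRMSE)}; the pointwise bias vector is
#'   attached as attribute \code{"bias"}.
#' @examples
#' weightedBiasRmse(matrix(c(0.1, -0.1)), c(0, 0), c(.5, .5))  # 0.1, 0.1
#' @export
weightedBiasRmse <- function(est, truth, f) {
  est <- as.matrix(est)
  stopifnot(nrow(est) == length(truth), length(f) == length(truth))
  err <- sweep(est, 1, truth)
  bias_t <- rowMeans(err)
  rmse_t <- sqrt(rowMeans(err^2))
  out <- c(wBias = sum(f * abs(bias_t)), wRMSE = sum(f * rmse_t))
  attr(out, "bias") <- bias_t
  out
}

# default estimation settings of the simulation harness: one-factor model,
# invariant free loadings, DIF effects, gaussian kernel
.harnessFit <- function(dat, dgm, h = 2, cov_mode = "weighted",
                        par_quadratic = character(), warm = NULL) {
  inv <- paste0(dgm$factors[1], "=~", dgm$indicators[2:3])
  if (length(par_quadratic)) inv <- setdiff(inv, par_quadratic)
  lsemEstimate(dat, "age", dgm$model_syntax, grid = dgm$grid,
               kernel = "gaussian", h = h, par_invariant = inv,
               par_quadratic = par_quadratic, cov_mode = cov_mode,
               est_dif = TRUE, wt_min = 0, warm = warm)
}

#' Monte Carlo parameter recovery study
#'
#' Draws repeated subsamples from an exact-moment population, fits the
#' joint local model with invariant free loadings and DIF effects, and
#' summarizes accuracy of selected parameter curves (factor variance,
#' invariant loading, DIF effect of that loading) by pointwise bias, the
#' density-weighted absolute bias
#' \eqn{wBias = \sum_t f(a_t) |Bias(\hat\theta(a_t))|} and the
#' density-weighted root mean square error
#' \eqn{wRMSE = \sum_t f(a_t) \sqrt{mean_r (\hat\theta_r(a_t) -
#' \theta(a_t))^2}}, with the population moderator proportions as f.
#'
#' @param dgm an \code{lsemDGM}.
#' @param N vector of sample sizes.
#' @param reps Monte Carlo replications per sample size.
#' @param h bandwidth factor.
#' @param cov_mode conditional covariance estimator passed to the fits.
#' @param par_quadratic optional labels estimated under a quadratic
#'   parameter constraint instead of invariance.
#' @param seed integer seed.
#' @param population optional pre-built population data.frame.
#' @param group_size population group size when \code{population} is NULL.
#' @return list of class \code{lsemSimulation} with elements \code{report}
#'   (data.frame: N, parameter, wBias, wRMSE, converged share) and
#'   \code{bias} (pointwise bias arrays).
#' @export
runRecoveryStudy <- function(dgm, N = c(250, 500, 1000, 2000), reps = 200,
                             h = 2, cov_mode = "weighted",
                             par_quadratic = character(), seed = 1,
                             population = NULL, group_size = 2000) {
  if (is.null(population)) {
    population <- makePopulation(dgm, group_size = group_size, seed = seed)
  }
  truth <- dgmTrueCurves(dgm)
  fac <- dgm$factors[1]
  sel <- c(paste0(fac, "~~", fac), paste0(fac, "=~", dgm$indicators[2]),
           paste0("dif__", fac, "=~", dgm$indicators[2]))
  truth_sel <- rbind(truth[sel[1], ], truth[sel[2], ], truth[sel[2], ])
  rownames(truth_sel) <- sel
  Tn <- length(dgm$grid)
  f <- rep(1 / Tn, Tn)

  set.seed(seed)
  report <- list(); bias_arr <- list()
  for (n in N) {
    est <- array(NA_real_, c(length(sel), Tn, reps))
    okr <- logical(reps)
    warm <- NULL
    for (r in seq_len(reps)) {
      dat <- drawSample(population, n)
      fit <- tryCatch(.harnessFit(dat, dgm, h = h, cov_mode = cov_mode,
                                  par_quadratic = par_quadratic),
                      error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      m <- .curveMatrices(fit)
      if (!all(sel %in% rownames(m$est))) next
      est[, , r] <- m$est[sel, ]
      okr[r] <- TRUE
    }
    if (!any(okr)) stop("no converged replications at N = ", n)
    est <- est[, , okr, drop = FALSE]
    for (k in seq_along(sel)) {
      em <- est[k, , , drop = TRUE]
      if (is.null(dim(em))) em <- matrix(em, nrow = Tn)
      ws <- weightedBiasRmse(em, truth_sel[k, ], f)
      report[[length(report) + 1L]] <- data.frame(
        N = n, parameter = sel[k],
        wBias = ws["wBias"], wRMSE = ws["wRMSE"],
        converged = mean(okr), stringsAsFactors = FALSE)
      bias_arr[[paste(n, sel[k])]] <- attr(ws, "bias")
    }
  }
  structure(list(report = do.call(rbind, report), bias = bias_arr,
                 seed = seed, reps = reps),
            class = "lsemSimulation")
}

#' Monte Carlo size/power study for parameter-variation tests
#'
#' Draws repeated subsamples, fits the joint local model with invariant
#' free loadings and DIF effects, bootstraps each fit, and records
#' rejections of the bias-corrected-SD test and the Wald equality test for
#' the latent factor variance, the DIF effects of the invariant loadings,
#' and the residual variances.
#'
#' @param dgm an \code{lsemDGM}.
#' @param N sample size per replication.
#' @param reps Monte Carlo replications.
#' @param R_boot bootstrap replicates per replication.
#' @param levels nominal significance levels.
#' @param h bandwidth factor.
#' @param seed integer seed.
#' @param population optional pre-built population data.frame.
#' @param group_size population group size when \code{population} is NULL.
#' @return list of class \code{lsemSimulation} with \code{report} (per
#'   parameter and pooled rejection rates per test and level, plus mean raw
#'   and bias-corrected SD) and \code{draws} (per-replication p-values).
#' @export
runSizePowerStudy <- function(dgm, N = 1000, reps = 500, R_boot = 100,
                              levels = c(0.05, 0.01), h = 2, seed = 1,
                              population = NULL, group_size = 2000) {
  if (is.null(population)) {
    population <- makePopulation(dgm, group_size = group_size, seed = seed)
  }
  fac <- dgm$factors[1]
  params <- c(paste0(fac, "~~", fac),
              paste0("dif__", fac, "=~", dgm$indicators[2:3]),
              paste0(dgm$indicators[1:3], "~~", dgm$indicators[1:3]))

  set.seed(seed)
  bootseeds <- sample.int(2^31 - 1, reps)
  sd_p <- wald_p <- sd_raw <- sd_bc <- matrix(
    NA_real_, reps, length(params), dimnames = list(NULL, params))
  okr <- logical(reps)
  for (r in seq_len(reps)) {
    dat <- drawSample(population, N)
    res <- tryCatch({
      fit <- .harnessFit(dat, dgm, h = h)
      boot <- lsemBootstrap(fit, dat, R = R_boot, seed = bootseeds[r])
      lsemSummary(fit, boot)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(res)) next
    idx <- match(params, res$parameter)
    if (anyNA(idx)) next
    sd_p[r, ] <- res$p[idx]
    wald_p[r, ] <- res$wald_p[idx]
    sd_raw[r, ] <- res$SD[idx]
    sd_bc[r, ] <- res$SD_bc[idx]
    okr[r] <- TRUE
  }
  if (!any(okr)) stop("no converged replications")

  rows <- list()
  for (lev in levels) {
    for (pp in c(params, "pooled")) {
      if (pp == "pooled") {
        sp <- as.vector(sd_p[okr, ]); wp <- as.vector(wald_p[okr, ])
        msd <- mean(sd_raw[okr, ]); mbc <- mean(sd_bc[okr, ])
      } else {
        sp <- sd_p[okr, pp]; wp <- wald_p[okr, pp]
        msd <- mean(sd_raw[okr, pp]); mbc <- mean(sd_bc[okr, pp])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pp, level = lev,
        sd_test_rate = mean(sp < lev, na.rm = TRUE),
        wald_test_rate = mean(wp < lev, na.rm = TRUE),
        mean_SD = msd, mean_SD_bc = mbc,
        reps = sum(okr), stringsAsFactors = FALSE)
    }
  }
  structure(list(report = do.call(rbind, rows),
                 draws = list(sd_p = sd_p, wald_p = wald_p,
                              sd_raw = sd_raw, sd_bc = sd_bc, ok = okr),
                 seed = seed, N = N, R_boot = R_boot),
            class = "lsemSimulation")
}

#' @export
print.lsemSimulation <- function(x, ...) {
  cat("LSEM Monte Carlo simulation report\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
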