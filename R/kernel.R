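#' Kernel functions for local weighting
#'
#' All kernels satisfy \eqn{K(0) = 1}, symmetry, nonnegativity and are
#' nonincreasing in \eqn{|x|}: Gaussian \eqn{K(x) = \exp(-x^2/2)};
#' Epanechnikov \eqn{K(x) = (1 - x^2)} on \eqn{|x| \le 1} (the classical
#' density-estimation kernel rescaled so that \eqn{K(0)=1}; relative weights
#' are unaffected because the local moment formulas are scale invariant in
#' the weights); uniform \eqn{K(x) = 1} on \eqn{|x| \le 1}.
#'
#' @param kernel kernel name: \code{"gaussian"}, \code{"epanechnikov"} or
#'   \code{"uniform"}.
#' @param x numeric vector of scaled distances.
#' @return numeric vector of kernel values in \[0, 1\].
#' @examples
#' kernelValue("gaussian", c(0, 1))  # 1, exp(-0.5)
#' kernelValue("epanechnikov", 2)    # 0
#' @export
kernelValue <- function(kernel, x) {
  switch(match.arg(kernel, c("gaussian", "epanechnikov", "uniform")),
    gaussian = exp(-x^2 / 2),
    epanechnikov = ifelse(abs(x) <= 1, 1 - x^2, 0),
    uniform = as.numeric(abs(x) <= 1)
  )
}

#' Bandwidth from the bandwidth factor
#'
#' \eqn{bw = h N^{-1/5} \sigma_A}, the scale on which kernel distances to a
#' focal point are measured.  \code{h = 1.1} is the classical
#' density-estimation choice; \code{h = 2} is the simulation-backed default
#' for local SEM parameter curves.
#'
#' @param h dimensionless bandwidth factor (> 0).
#' @param N number of subjects.
#' @param sigma_A standard deviation of the moderator (> 0).
#' @return bandwidth in moderator units.
#' @examples
#' lsemBandwidth(2, 1027, 1.23)
#' @export
lsemBandwidth <- function(h, N, sigma_A) {
  stopifnot(h > 0, N >= 1)
  if (!isTRUE(sigma_A > 0)) stop("degenerate moderator: sigma_A must be > 0")
  h * N^(-1 / 5) * sigma_A
}

#' Focal grid construction
#'
#' Builds the grid of focal points at which local models are evaluated.
#' \code{"equidistant:T"} spans the 5th to 95th percentile of the moderator
#' with T equally spaced points (T capped at the number of distinct
#' values); \code{"percentile:T"} places points at T equally spaced
#' empirical percentiles; a numeric vector is used as-is.
#'
#' @param a numeric moderator vector.
#' @param spec grid specification: numeric vector, \code{"equidistant:T"},
#'   or \code{"percentile:T"}.  Default \code{"equidistant:13"}.
#' @return strictly increasing numeric vector of focal points.
#' @export
makeFocalGrid <- function(a, spec = "equidistant:13") {
  a <- a[is.finite(a)]
  if (is.numeric(spec)) {
    grid <- sort(unique(spec))
  } else {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    Tn <- if (length(parts) > 1) as.integer(parts[2]) else 13L
    Tn <- min(Tn, length(unique(a)))
    if (Tn < 1L) stop("focal grid needs at least one point")
    grid <- switch(match.arg(parts[1], c("equidistant", "percentile")),
      equidistant = {
        rng <- stats::quantile(a, c(0.05, 0.95), names = FALSE)
        if (Tn == 1L) mean(rng) else seq(rng[1], rng[2], length.out = Tn)
      },
      percentile = {
        p <- seq(0.5 / Tn, 1 - 0.5 / Tn, length.out = Tn)
        unique(stats::quantile(a, p, names = FALSE))
      }
    )
  }
  if (length(grid) < 1L) stop("empty focal grid")
  grid
}

#' Kernel weight matrix over a focal grid
#'
#' Computes \eqn{w_{nt} = K((a_n - a_t)/bw)} for every subject n and focal
#' point t.  Sampling weights, when given, are fused multiplicatively.
#' Focal points whose total weight mass \eqn{W_t} falls below \code{wt_min}
#' are dropped with a warning (covariance matrices are not estimable from
#' vanishing weight mass).
#'
#' @param a numeric moderator vector (finite).
#' @param grid focal points, e.g. from [makeFocalGrid()].
#' @param kernel kernel name (see [kernelValue()]).
#' @param h bandwidth factor; used when \code{bw} is not supplied.
#' @param bw bandwidth in moderator units; overrides \code{h}.
#' @param sampling_weights optional nonnegative subject weights.
#' @param wt_min minimum weight mass per retained focal point (default 0:
#'   keep all).
#' @return an [LsemWeights-class] object.
#' @examples
#' a <- rep(6:18, each = 20)
#' w <- computeWeights(a, 6:18, kernel = "gaussian", h = 2)
#' colSums(weightMatrix(w))
#' @export
computeWeights <- function(a, grid, kernel = "gaussian", h = 2, bw = NULL,
                           sampling_weights = NULL, wt_min = 0) {
  if (!all(is.finite(a))) stop("moderator values must be finite")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  N <- length(a)
  if (is.null(bw)) {
    bw <- lsemBandwidth(h, N, stats::sd(a))
  } else {
    h <- NA_real_
  }
  if (!isTRUE(bw > 0)) stop("bandwidth must be positive")
  W <- vapply(grid, function(at) kernelValue(kernel, (a - at) / bw),
              numeric(N))
  W <- matrix(W, nrow = N)
  if (!is.null(sampling_weights)) {
    stopifnot(length(sampling_weights) == N, all(sampling_weights >= 0))
    W <- W * sampling_weights
  }
  Wt <- colSums(W)
  dropped <- which(Wt < wt_min | Wt <= 0)
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " focal point(s) with weight mass below the floor (",
            format(wt_min), "): ",
            paste(signif(grid[dropped], 4), collapse = ", "))
    W <- W[, -dropped, drop = FALSE]
    grid <- grid[-dropped]
    Wt <- Wt[-dropped]
  }
  if (length(grid) == 0L) stop("all focal points dropped; decrease wt_min or widen bw")
  new("LsemWeights", weights = W, grid = as.numeric(grid), Wt = Wt,
      density = Wt / sum(Wt), kernel = kernel, bw = bw, h = h,
      dropped = as.integer(dropped))
}
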