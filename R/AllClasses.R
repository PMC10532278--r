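#' @import methods
NULL

#' Symbolic structural equation model
#'
#' An \code{LsemModel} holds the symbolic structure of a covariance-structure
#' SEM: which cells of the loading matrix \eqn{\Lambda}, the structural
#' coefficient matrix \eqn{B}, the factor (co)variance matrix \eqn{\Phi} and
#' the residual (co)variance matrix \eqn{\Psi} are free (with a label) or
#' fixed (with a value).  Objects are created from lavaan-style model syntax
#' by [lsemModel()].
#'
#' @slot indicators character vector of observed variable names (ordered).
#' @slot factors character vector of latent variable names (ordered).
#' @slot partable data.frame with one row per model matrix cell that is part
#'   of the model: columns \code{lhs}, \code{op}, \code{rhs}, \code{mat}
#'   (one of \code{"lambda"}, \code{"beta"}, \code{"phi"}, \code{"psi"}),
#'   \code{row}, \code{col}, \code{free} (logical), \code{value} (fixed value
#'   or start value) and \code{label}.
#' @slot syntax the original model syntax text.
#' @export
setClass("LsemModel",
  representation(
    indicators = "character",
    factors = "character",
    partable = "data.frame",
    syntax = "character"
  )
)

setValidity("LsemModel", function(object) {
  pt <- object@partable
  need <- c("lhs", "op", "rhs", "mat", "row", "col", "free", "value", "label")
  if (!all(need %in% names(pt))) {
    return("partable misses required columns")
  }
  if (any(duplicated(pt$label[pt$free]))) {
    return("free parameters must carry unique labels")
  }
  beta <- pt[pt$mat == "beta", , drop = FALSE]
  if (nrow(beta) > 0 && any(beta$row == beta$col)) {
    return("structural matrix B must have a zero diagonal")
  }
  sym <- pt[pt$mat %in% c("phi", "psi"), , drop = FALSE]
  if (nrow(sym) > 0 && any(sym$row < sym$col)) {
    return("phi/psi cells must be stored lower-triangular (row >= col)")
  }
  TRUE
})

#' Kernel weight matrix over a focal grid
#'
#' Links each of N subjects to each of T focal points of the moderator via
#' kernel weights \eqn{w_{nt} = K((a_n - a_t)/bw)}.
#'
#' @slot weights N x T numeric matrix of kernel weights in \[0, 1\]
#'   (optionally fused multiplicatively with sampling weights, in which case
#'   the upper bound no longer applies).
#' @slot grid numeric vector of T focal points (strictly increasing).
#' @slot Wt numeric vector of column sums of \code{weights}.
#' @slot density normalized focal-point density \eqn{\hat f(a_t) = W_t / \sum_s W_s}.
#' @slot kernel kernel name, one of \code{"gaussian"}, \code{"epanechnikov"},
#'   \code{"uniform"}.
#' @slot bw bandwidth in moderator units.
#' @slot h dimensionless bandwidth factor (NA when \code{bw} was supplied
#'   directly).
#' @slot dropped integer indices of focal points removed because their weight
#'   mass fell below the estimability floor.
#' @export
setClass("LsemWeights",
  representation(
    weights = "matrix",
    grid = "numeric",
    Wt = "numeric",
    density = "numeric",
    kernel = "character",
    bw = "numeric",
    h = "numeric",
    dropped = "integer"
  )
)

setValidity("LsemWeights", function(object) {
  if (ncol(object@weights) != length(object@grid)) {
    return("weight matrix columns must match focal grid length")
  }
  if (is.unsorted(object@grid, strictly = TRUE)) {
    return("focal grid must be strictly increasing")
  }
  if (any(object@Wt <= 0)) {
    return("every retained focal point needs positive weight mass")
  }
  if (abs(sum(object@density) - 1) > 1e-8) {
    return("focal-point density must sum to 1")
  }
  TRUE
})

#' Local (conditional) moments at the focal points
#'
#' Kernel-weighted conditional means and conditional covariance matrices of
#' the indicators at each focal point, after residualizing the mean structure
#' by local quadratic regression.
#'
#' @slot grid focal points.
#' @slot means I x T matrix of conditional means \eqn{\hat\mu_i(a_t)}.
#' @slot mean_coef I x 3 x T array of local quadratic mean coefficients
#'   (intercept, slope, curvature in \eqn{a - a_t}).
#' @slot cov I x I x T array of conditional covariance matrices
#'   \eqn{\hat\Sigma_t} (positive definite after repair).
#' @slot Wt weight mass per focal point.
#' @slot density normalized focal-point density.
#' @slot pd_repaired logical per focal point: was eigenvalue repair applied.
#' @slot mode covariance estimation mode, \code{"weighted"} or
#'   \code{"local_regression"}.
#' @slot indicators indicator names.
#' @export
setClass("LsemMoments",
  representation(
    grid = "numeric",
    means = "matrix",
    mean_coef = "array",
    cov = "array",
    Wt = "numeric",
    density = "numeric",
    pd_repaired = "logical",
    mode = "character",
    indicators = "character"
  )
)

#' Fitted local structural equation model
#'
#' Result of [lsemEstimate()]: parameter curves over the focal grid, the
#' invariant parameter block, optional DIF effect curves, and fit statistics.
#'
#' @slot model the [LsemModel-class] that was fitted.
#' @slot mode estimation mode, \code{"pointwise"}, \code{"joint"} or
#'   \code{"mgm"}.
#' @slot grid focal points (or bin midpoints for MGM).
#' @slot curves data.frame of parameter curves with columns \code{parameter},
#'   \code{focal_index}, \code{a_t}, \code{estimate}, \code{standardized},
#'   \code{is_invariant}, \code{is_dif}.
#' @slot invariant character vector of labels constrained invariant.
#' @slot constraints the constraint lists used (invariant / linear /
#'   quadratic / piecewise).
#' @slot fit list of fit information: global statistics in \code{global}
#'   (joint/MGM), per-focal-point statistics in \code{pointwise}, objective
#'   value, convergence flags, iteration counts.
#' @slot moments the [LsemMoments-class] used for estimation.
#' @slot weights the [LsemWeights-class] used for estimation.
#' @slot config echo of estimation settings (kernel, bandwidth, modes, seed).
#' @export
setClass("LsemFit",
  representation(
    model = "LsemModel",
    mode = "character",
    grid = "numeric",
    curves = "data.frame",
    invariant = "character",
    constraints = "list",
    fit = "list",
    moments = "LsemMoments",
    weights = "LsemWeights",
    config = "list"
  )
)

setValidity("LsemFit", function(object) {
  cv <- object@curves
  if (length(object@invariant)) {
    inv <- cv[cv$parameter %in% object@invariant & !cv$is_dif, , drop = FALSE]
    if (nrow(inv)) {
      rng <- tapply(inv$estimate, inv$parameter, function(x) diff(range(x)))
      if (any(rng > 1e-8)) {
        return("invariant parameters must have identical values at every focal point")
      }
    }
  }
  if (any(cv$is_dif) && length(object@invariant) == 0L) {
    return("DIF curves exist only when invariant parameters are present")
  }
  TRUE
})

#' Bootstrap (or replication-design) replicates of LSEM parameter curves
#'
#' @slot curves 3-d array parameter x focal point x replicate of raw
#'   estimates.
#' @slot std_curves matching array of standardized estimates.
#' @slot parameters parameter names (rows of \code{curves}).
#' @slot grid focal points.
#' @slot density focal-point density of the original fit.
#' @slot design \code{"nonparametric"}, \code{"cluster"} or
#'   \code{"repl_design"}.
#' @slot repl_factor scale factor used for the curve covariance matrix V.
#' @slot seed integer seed used for resampling.
#' @slot dropped number of non-converged replicates that were discarded.
#' @export
setClass("LsemBoot",
  representation(
    curves = "array",
    std_curves = "array",
    parameters = "character",
    grid = "numeric",
    density = "numeric",
    design = "character",
    repl_factor = "numeric",
    seed = "integer",
    dropped = "integer"
  )
)
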