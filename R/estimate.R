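# Pointwise, joint, MGM and DIF estimation over the focal grid.

# assemble the named parameter vector at focal point t from the long
# (label, group, value) table
.thetaAt <- function(values, t) {
  v <- values[values$group == t, , drop = FALSE]
  stats::setNames(v$value, v$label)
}

# curves data.frame from a long value table
.curvesFrame <- function(model, values, grid, invariant, is_dif = FALSE) {
  labs <- unique(values$label)
  out <- do.call(rbind, lapply(labs, function(l) {
    v <- values[values$label == l, , drop = FALSE]
    data.frame(parameter = l, focal_index = v$group, a_t = grid[v$group],
               estimate = v$value, standardized = NA_real_,
               is_invariant = l %in% invariant, is_dif = is_dif,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# fill the standardized column of a curves frame, given the full (possibly
# DIF-substituted) parameter vector at each focal point
.addStandardized <- function(curves, model, theta_by_t) {
  for (t in seq_along(theta_by_t)) {
    std <- standardizeSolution(model, theta_by_t[[t]])
    sel <- curves$focal_index == t
    curves$standardized[sel] <- std[curves$parameter[sel]]
  }
  curves
}

# DIF effects (one constrained fit with all focal points): every free
# parameter is fixed at its focal-point-specific joint estimate, while the
# formerly invariant labels are freed per focal point.
.difFit <- function(model, Slist, Wt, grid, theta_by_t, invariant,
                    start_work = NULL) {
  fv <- lapply(theta_by_t, function(th) th[setdiff(names(th), invariant)])
  fitGroups(model, Slist, Wt, grid = grid, fixed_values = fv,
            start_work = start_work)
}

#' Estimate a local structural equation model
#'
#' Fits an SEM at each focal point of a continuous moderator using
#' kernel-weighted conditional covariance matrices.  Pointwise estimation
#' fits an independent model per focal point; joint estimation minimizes the
#' weight-summed discrepancy across all focal points in one problem and
#' supports invariance and polynomial parameter constraints across the
#' moderator; \code{type = "mgm"} discretizes the moderator into groups and
#' fits a classical multiple-group model (identical to the uniform-kernel
#' local model with bandwidth half the grid spacing when the moderator is
#' grid-valued).
#'
#' @param data data.frame containing indicator columns and the moderator.
#' @param moderator name of the moderator column.
#' @param model an [LsemModel-class] or lavaan-style model syntax.
#' @param grid focal grid specification (see [makeFocalGrid()]); for
#'   \code{type = "mgm"} the number of groups.
#' @param kernel kernel name (see [kernelValue()]).
#' @param h bandwidth factor (default 2, the simulation-backed choice; 1.1
#'   is the classical density-estimation value).
#' @param bw bandwidth in moderator units; overrides \code{h}.
#' @param sampling_weights optional subject sampling weights (fused
#'   multiplicatively with kernel weights).
#' @param type \code{"lsem"} (kernel weighting) or \code{"mgm"}
#'   (discretized multiple-group model).
#' @param est_joint logical; joint estimation (one problem across focal
#'   points).  Defaults to TRUE when any cross-focal-point constraint is
#'   given, otherwise pointwise estimation is used (the two coincide when no
#'   constraints are present).
#' @param par_invariant labels of parameters held equal across focal points.
#' @param par_linear,par_quadratic labels of parameters constrained to
#'   (piecewise) linear/quadratic curves over the focal points.
#' @param pw_linear,pw_quadratic segment counts for the piecewise variants.
#' @param residualize logical; residualize the mean structure by local
#'   quadratic regression before computing conditional covariances.
#' @param cov_mode conditional covariance estimator: \code{"weighted"}
#'   (kernel-weighted cross products) or \code{"local_regression"} (local
#'   quadratic regression of residual products).
#' @param pd logical; repair non-positive-definite conditional covariance
#'   matrices.
#' @param pd_floor relative eigenvalue floor of the repair.
#' @param est_dif logical; estimate DIF effect curves for the invariant
#'   parameters (requires a nonempty \code{par_invariant}).
#' @param wt_min minimal kernel weight mass per retained focal point;
#'   defaults to 5 times the number of indicators.
#' @param standardized logical; add fully standardized estimates.
#' @param warm optional list of working-scale start vectors from a previous
#'   fit of the identical configuration (\code{joint}, \code{pointwise},
#'   \code{dif}); used internally to warm-start resampling replicates.
#' @param verbose logical; print per-focal-point progress.
#' @return an [LsemFit-class] object.
#' @examples
#' set.seed(1)
#' pop <- makePopulation(lsemDGM("dgm3", n_factors = 1), group_size = 200)
#' dat <- drawSample(pop, 800)
#' fit <- lsemEstimate(dat, "age", "FX =~ X1 + X2 + X3",
#'                     par_invariant = c("FX=~X2", "FX=~X3"))
#' fit
#' @export
lsemEstimate <- function(data, moderator, model, grid = "equidistant:13",
                         kernel = "gaussian", h = 2, bw = NULL,
                         sampling_weights = NULL,
                         type = c("lsem", "mgm"), est_joint = NULL,
                         par_invariant = character(),
                         par_linear = character(),
                         par_quadratic = character(),
                         pw_linear = 1L, pw_quadratic = 1L,
                         residualize = TRUE,
                         cov_mode = c("weighted", "local_regression"),
                         pd = TRUE, pd_floor = 1e-4, est_dif = FALSE,
                         wt_min = NULL, standardized = TRUE, warm = NULL,
                         verbose = FALSE) {
  type <- match.arg(type)
  cov_mode <- match.arg(cov_mode)
  if (is.character(model)) model <- lsemModel(model)
  if (!moderator %in% names(data)) {
    stop("moderator column '", moderator, "' not found in data")
  }
  miss <- setdiff(model@indicators, names(data))
  if (length(miss)) {
    stop("indicator column(s) not found in data: ", paste(miss, collapse = ", "))
  }
  a <- data[[moderator]]
  if (!is.numeric(a)) stop("moderator must be numeric")
  x <- as.matrix(data[model@indicators])
  I <- ncol(x)
  if (is.null(wt_min)) wt_min <- 5 * I

  has_constraints <- length(par_invariant) + length(par_linear) +
    length(par_quadratic) > 0
  if (is.null(est_joint)) est_joint <- has_constraints
  if (has_constraints && !est_joint) {
    stop("cross-focal-point constraints require joint estimation")
  }
  if (est_dif && length(par_invariant) == 0L) {
    stop("DIF effects require invariant parameters (par_invariant)")
  }

  if (type == "mgm") {
    n_groups <- if (is.numeric(grid) && length(grid) == 1L) as.integer(grid)
                else length(unique(a))
    wobj <- .mgmWeights(a, n_groups)
    residualize <- FALSE  # classical per-group moments: deviations from bin means
  } else {
    gridv <- makeFocalGrid(a, grid)
    wobj <- computeWeights(a, gridv, kernel = kernel, h = h, bw = bw,
                           sampling_weights = sampling_weights,
                           wt_min = wt_min)
  }
  moments <- localMoments(x, a, wobj, residualize = residualize,
                          mode = cov_mode, pd = pd, pd_floor = pd_floor)
  gridv <- moments@grid
  Tn <- length(gridv)
  Slist <- lapply(seq_len(Tn), function(t) moments@cov[, , t])
  Wt <- if (type == "mgm") wobj@Wt else moments@Wt

  mode <- if (type == "mgm") "mgm" else if (est_joint) "joint" else "pointwise"
  fitinfo <- list(mode = mode)

  if (mode == "pointwise") {
    fits <- vector("list", Tn)
    prev <- NULL
    for (t in seq_len(Tn)) {
      if (verbose) message("focal point ", t, "/", Tn, " (a=", signif(gridv[t], 4), ")")
      start_t <- if (!is.null(warm)) warm$pointwise[[t]] else prev
      fits[[t]] <- tryCatch({
        f <- fitGroups(model, Slist[[t]], Wt[t], start_work = start_t)
        if (!is.null(start_t)) {
          # a warm start can land in a different basin than the default
          # start values; keep whichever optimum is lower
          f2 <- fitGroups(model, Slist[[t]], Wt[t])
          if (f2$objective < f$objective - 1e-10) f <- f2
        }
        f
      }, error = function(e) e)
      if (!inherits(fits[[t]], "error")) prev <- fits[[t]]$theta_work
    }
    bad <- vapply(fits, inherits, logical(1), what = "error")
    if (any(bad)) {
      warning("estimation failed at focal point(s) ",
              paste(which(bad), collapse = ", "))
    }
    if (all(bad)) stop("estimation failed at every focal point")
    values <- do.call(rbind, lapply(which(!bad), function(t) {
      v <- fits[[t]]$values
      v$group <- t
      v
    }))
    pw_stats <- do.call(rbind, lapply(seq_len(Tn), function(t) {
      if (bad[t]) return(NULL)
      st <- fitStatistics(fits[[t]], effective_n = Wt[t])
      data.frame(focal_index = t, a_t = gridv[t], converged = fits[[t]]$convergence,
                 chisq = st$chisq, df = st$df, rmsea = st$rmsea,
                 srmr = st$srmr, cfi = st$cfi, tli = st$tli, gfi = st$gfi)
    }))
    fitinfo$pointwise <- pw_stats
    fitinfo$objective <- sum(vapply(fits[!bad], `[[`, numeric(1), "objective"))
    fitinfo$converged <- all(vapply(fits[!bad], `[[`, logical(1), "convergence"))
    fitinfo$theta_work <- list(pointwise = lapply(fits, function(f) {
      if (inherits(f, "error")) NULL else f$theta_work
    }))
    jointfit <- NULL
  } else {
    jointfit <- fitGroups(model, Slist, Wt, par_invariant = par_invariant,
                          par_linear = par_linear,
                          par_quadratic = par_quadratic,
                          pw_linear = pw_linear, pw_quadratic = pw_quadratic,
                          grid = gridv,
                          start_work = if (!is.null(warm)) warm$joint else NULL)
    values <- jointfit$values
    effn <- if (type == "mgm") sum(Wt) else sum(Wt)
    fitinfo$global <- fitStatistics(jointfit, effective_n = effn)
    fitinfo$objective <- jointfit$objective
    fitinfo$converged <- jointfit$convergence
    fitinfo$iterations <- jointfit$iterations
    fitinfo$theta_work <- list(joint = jointfit$theta_work)
  }

  curves <- .curvesFrame(model, values, gridv, par_invariant)
  theta_by_t <- lapply(seq_len(Tn), function(t) .thetaAt(values, t))
  present <- vapply(theta_by_t, function(th) length(th) > 0, logical(1))
  if (standardized) {
    curves <- .addStandardized(curves, model, theta_by_t[present])
  }

  if (est_dif) {
    dif <- .difFit(model, Slist, Wt, gridv, theta_by_t, par_invariant,
                   start_work = if (!is.null(warm)) warm$dif else NULL)
    dif_curves <- .curvesFrame(model, dif$values, gridv, par_invariant,
                               is_dif = TRUE)
    if (standardized) {
      dif_theta <- lapply(seq_len(Tn), function(t) {
        th <- theta_by_t[[t]]
        dt <- .thetaAt(dif$values, t)
        th[names(dt)] <- dt
        th
      })
      dif_curves <- .addStandardized(dif_curves, model, dif_theta)
    }
    curves <- rbind(curves, dif_curves)
    fitinfo$theta_work$dif <- dif$theta_work
    fitinfo$dif_converged <- dif$convergence
  }

  cfg <- list(kernel = if (type == "mgm") "membership" else wobj@kernel,
              h = wobj@h, bw = wobj@bw, type = type, est_joint = est_joint,
              residualize = residualize, cov_mode = cov_mode, pd = pd,
              pd_floor = pd_floor, wt_min = wt_min, moderator = moderator,
              grid_spec = if (is.character(grid)) grid else "explicit",
              pw_linear = pw_linear, pw_quadratic = pw_quadratic,
              par_linear = par_linear, par_quadratic = par_quadratic,
              est_dif = est_dif, N = nrow(data))

  new("LsemFit", model = model, mode = mode, grid = gridv, curves = curves,
      invariant = par_invariant,
      constraints = list(par_invariant = par_invariant,
                         par_linear = par_linear,
                         par_quadratic = par_quadratic,
                         pw_linear = pw_linear, pw_quadratic = pw_quadratic),
      fit = fitinfo, moments = moments, weights = wobj, config = cfg)
}

# membership (0/1) weights for the discretized multiple-group model;
# equal-frequency bins unless the moderator has at most n_groups distinct
# values, in which case the distinct values are the groups
.mgmWeights <- function(a, n_groups) {
  ux <- sort(unique(a))
  if (length(ux) <= n_groups) {
    bin <- match(a, ux)
    centers <- ux
  } else {
    br <- stats::quantile(a, probs = seq(0, 1, length.out = n_groups + 1),
                          names = FALSE)
    br[1] <- -Inf; br[n_groups + 1] <- Inf
    br <- unique(br)
    bin <- cut(a, br, labels = FALSE, include.lowest = TRUE)
    centers <- as.numeric(tapply(a, bin, mean))
  }
  tab <- tabulate(bin, nbins = length(centers))
  if (any(tab == 0)) stop("empty moderator group in MGM discretization")
  W <- matrix(0, length(a), length(centers))
  W[cbind(seq_along(a), bin)] <- 1
  new("LsemWeights", weights = W, grid = as.numeric(centers),
      Wt = as.numeric(tab), density = tab / sum(tab), kernel = "membership",
      bw = NA_real_, h = NA_real_, dropped = integer(0))
}

#' DIF effect curves for a fitted joint model
#'
#' Frees each invariant parameter at every focal point while holding all
#' focal-point-specific parameters fixed at their joint estimates, and
#' re-minimizes the discrepancy pointwise.  The resulting curves show what
#' the invariant parameters would look like without the invariance
#' constraint.
#'
#' @param fit an [LsemFit-class] from joint estimation with a nonempty
#'   invariant set.
#' @return data.frame of DIF curves (columns as in \code{lsemCurves}).
#' @export
lsemDif <- function(fit) {
  if (length(fit@invariant) == 0L) {
    stop("DIF effects require invariant parameters in the fit")
  }
  cv <- fit@curves[!fit@curves$is_dif, , drop = FALSE]
  Tn <- length(fit@grid)
  Slist <- lapply(seq_len(Tn), function(t) fit@moments@cov[, , t])
  theta_by_t <- lapply(seq_len(Tn), function(t) {
    sel <- cv$focal_index == t
    stats::setNames(cv$estimate[sel], cv$parameter[sel])
  })
  dif <- .difFit(fit@model, Slist, fit@moments@Wt, fit@grid, theta_by_t,
                 fit@invariant)
  out <- .curvesFrame(fit@model, dif$values, fit@grid, fit@invariant,
                      is_dif = TRUE)
  dif_theta <- lapply(seq_len(Tn), function(t) {
    th <- theta_by_t[[t]]
    dt <- .thetaAt(dif$values, t)
    th[names(dt)] <- dt
    th
  })
  .addStandardized(out, fit@model, dif_theta)
}
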