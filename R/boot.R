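# Resampling-based inference: bootstrap, replication designs, permutation.

# re-run the full estimation pipeline (weights -> moments -> fit) on
# modified data, warm-started from the original solution
.refit <- function(fit, data, sampling_weights = NULL) {
  cfg <- fit@config
  lsemEstimate(data, cfg$moderator, fit@model,
               grid = if (cfg$type == "mgm") length(fit@grid) else fit@grid,
               kernel = if (cfg$type == "mgm") "gaussian" else cfg$kernel,
               bw = fit@weights@bw,
               sampling_weights = sampling_weights,
               type = cfg$type, est_joint = cfg$est_joint,
               par_invariant = fit@invariant,
               par_linear = cfg$par_linear,
               par_quadratic = cfg$par_quadratic,
               pw_linear = cfg$pw_linear, pw_quadratic = cfg$pw_quadratic,
               residualize = cfg$residualize, cov_mode = cfg$cov_mode,
               pd = cfg$pd, pd_floor = cfg$pd_floor, est_dif = cfg$est_dif,
               wt_min = cfg$wt_min, standardized = TRUE,
               warm = fit@fit$theta_work)
}

# --- fast replicate machinery -------------------------------------------
# Resampling re-estimates the model hundreds of times on perturbed data
# with an unchanged parameter layout, so the engine structures are built
# once and only their data (S_t, W_t) are swapped per replicate.

.engSetData <- function(eng, Slist, ng) {
  I <- eng$I
  eng$S <- array(unlist(Slist), c(I, I, eng$G))
  eng$Ng <- as.numeric(ng)
  eng$logdetS <- vapply(Slist, function(S) {
    as.numeric(determinant(S, logarithm = TRUE)$modulus)
  }, numeric(1))
  eng
}

.engSolve <- function(eng, start, tolgrad) {
  o <- stats::nlminb(start, .eng_objective, gradient = .eng_gradient,
                     hessian = .eng_hessian, engine = eng,
                     control = list(iter.max = 500L, eval.max = 1000L,
                                    rel.tol = 1e-12))
  if (max(abs(.eng_gradient(o$par, eng))) > tolgrad) {
    o <- stats::nlminb(o$par, .eng_objective, gradient = .eng_gradient,
                       engine = eng,
                       control = list(iter.max = 1000L, eval.max = 2000L,
                                      rel.tol = 1e-12))
    if (max(abs(.eng_gradient(o$par, eng))) > tolgrad) {
      stop("replicate fit did not converge")
    }
  }
  o
}

# one-time setup of the cached engines and index maps for .replicateCurves
.replicateSetup <- function(fit) {
  cfg <- fit@config
  model <- fit@model
  Tn <- length(fit@grid)
  Slist <- lapply(seq_len(Tn), function(t) fit@moments@cov[, , t])
  Wt <- fit@moments@Wt
  pt <- model@partable
  labels <- pt$label[pt$free]
  corr_labels <- pt$label[pt$mat == "phi" & pt$row != pt$col & pt$free]
  phi_diag <- stats::setNames(pt$label[pt$mat == "phi" & pt$row == pt$col],
                              model@factors[pt$col[pt$mat == "phi" &
                                                     pt$row == pt$col]])
  corr_parts <- lapply(corr_labels, function(l) {
    k <- which(pt$label == l)[1]
    c(phi_diag[model@factors[pt$row[k]]], phi_diag[model@factors[pt$col[k]]])
  })
  names(corr_parts) <- corr_labels

  setup <- list(cfg = cfg, model = model, Tn = Tn, labels = labels,
                corr_labels = corr_labels, corr_parts = corr_parts,
                has_beta = any(pt$mat == "beta"),
                mode = fit@mode, est_dif = isTRUE(cfg$est_dif),
                invariant = fit@invariant, grid = fit@grid,
                bw = fit@weights@bw, kernel = cfg$kernel)

  if (fit@mode == "pointwise") {
    setup$eng_point <- .buildEngine(model, Slist[1], Wt[1])
    setup$warm_point <- fit@fit$theta_work$pointwise
  } else {
    setup$eng_joint <- .buildEngine(model, Slist, Wt,
                                    par_invariant = fit@invariant,
                                    par_linear = cfg$par_linear,
                                    par_quadratic = cfg$par_quadratic,
                                    pw_linear = cfg$pw_linear,
                                    pw_quadratic = cfg$pw_quadratic,
                                    grid = fit@grid)
    setup$warm_joint <- fit@fit$theta_work$joint
    if (setup$est_dif) {
      # unconstrained engine: every free parameter focal-point-specific;
      # DIF minimization frees the invariant block with all else masked
      setup$eng_full <- .buildEngine(model, Slist, Wt, grid = fit@grid)
      pn <- setup$eng_full$par_names
      setup$full_lab <- sub("@[0-9]+$", "", pn)
      setup$full_grp <- as.integer(sub("^.*@", "", pn))
      setup$act <- which(setup$full_lab %in% fit@invariant)
      setup$dif_labels <- unique(setup$full_lab[setup$act])
    }
  }
  setup
}

# raw (and factor-correlation standardized) curve matrices for one
# resampled dataset; must agree with a fresh lsemEstimate on the same data
.replicateCurves <- function(setup, data2, sampling_weights = NULL) {
  cfg <- setup$cfg
  a <- data2[[cfg$moderator]]
  x <- as.matrix(data2[setup$model@indicators])
  w <- computeWeights(a, setup$grid, kernel = setup$kernel, bw = setup$bw,
                      sampling_weights = sampling_weights,
                      wt_min = cfg$wt_min)
  if (length(w@grid) != setup$Tn) stop("focal grid changed in replicate")
  mom <- localMoments(x, a, w, residualize = cfg$residualize,
                      mode = cfg$cov_mode, pd = cfg$pd,
                      pd_floor = cfg$pd_floor)
  Slist <- lapply(seq_len(setup$Tn), function(t) mom@cov[, , t])
  Wt <- mom@Wt
  tolgrad <- 1e-6 * max(1, sum(Wt))

  est <- matrix(NA_real_, length(setup$labels), setup$Tn,
                dimnames = list(setup$labels, NULL))
  if (setup$mode == "pointwise") {
    eng <- setup$eng_point
    for (t in seq_len(setup$Tn)) {
      eng <- .engSetData(eng, Slist[t], Wt[t])
      st <- setup$warm_point[[t]]
      if (is.null(st)) st <- eng$theta0
      o <- .engSolve(eng, st, 1e-6 * max(1, Wt[t]))
      v <- .engValues(eng, o$par)
      est[v$label, t] <- v$value
    }
    vals_theta <- lapply(seq_len(setup$Tn), function(t) est[, t])
  } else {
    eng <- .engSetData(setup$eng_joint, Slist, Wt)
    o <- .engSolve(eng, setup$warm_joint, tolgrad)
    v <- .engValues(eng, o$par)
    est[cbind(match(v$label, setup$labels), v$group)] <- v$value
    vals_theta <- lapply(seq_len(setup$Tn), function(t) {
      sel <- v$group == t
      stats::setNames(v$value[sel], v$label[sel])
    })
  }

  dif <- NULL
  if (isTRUE(setup$est_dif) && setup$mode != "pointwise") {
    engf <- .engSetData(setup$eng_full, Slist, Wt)
    base <- numeric(length(engf$par_names))
    for (k in seq_along(base)) {
      val <- est[setup$full_lab[k], setup$full_grp[k]]
      base[k] <- if (engf$plog[k]) log(max(val, 1e-8)) else val
    }
    act <- setup$act
    fm <- function(ta) {
      th <- base; th[act] <- ta
      .eng_objective(th, engf)
    }
    gm <- function(ta) {
      th <- base; th[act] <- ta
      .eng_gradient(th, engf)[act]
    }
    hm <- function(ta) {
      th <- base; th[act] <- ta
      .eng_hessian(th, engf)[act, act, drop = FALSE]
    }
    o <- stats::nlminb(base[act], fm, gradient = gm, hessian = hm,
                       control = list(iter.max = 500L, eval.max = 1000L,
                                      rel.tol = 1e-12))
    if (max(abs(gm(o$par))) > tolgrad) stop("DIF replicate did not converge")
    thf <- base; thf[act] <- o$par
    xa <- thf; xa[engf$plog] <- exp(thf[engf$plog])
    dif <- matrix(NA_real_, length(setup$dif_labels), setup$Tn,
                  dimnames = list(paste0("dif__", setup$dif_labels), NULL))
    for (k in act) {
      dif[paste0("dif__", setup$full_lab[k]), setup$full_grp[k]] <- xa[k]
    }
  }
  if (!is.null(dif)) est <- rbind(est, dif)

  std <- matrix(NA_real_, nrow(est), setup$Tn, dimnames = dimnames(est))
  for (l in setup$corr_labels) {
    if (setup$has_beta) {
      for (t in seq_len(setup$Tn)) {
        sv <- standardizeSolution(setup$model, vals_theta[[t]])
        std[l, t] <- sv[l]
      }
    } else {
      pr <- setup$corr_parts[[l]]
      std[l, ] <- est[l, ] / sqrt(est[pr[1], ] * est[pr[2], ])
    }
  }
  list(est = est, std = std, density = mom@density)
}

# parameter-key x focal-point matrices (raw and standardized) from a fit
.curveMatrices <- function(fit) {
  cv <- fit@curves
  key <- paste0(ifelse(cv$is_dif, "dif__", ""), cv$parameter)
  keys <- unique(key)
  Tn <- length(fit@grid)
  est <- std <- matrix(NA_real_, length(keys), Tn,
                       dimnames = list(keys, NULL))
  est[cbind(match(key, keys), cv$focal_index)] <- cv$estimate
  std[cbind(match(key, keys), cv$focal_index)] <- cv$standardized
  list(est = est, std = std)
}

#' Bootstrap an estimated local structural equation model
#'
#' Re-estimates the full model (local moments and parameter curves) on
#' resampled data.  Three replicate designs are available: nonparametric
#' (subjects resampled with replacement), cluster (whole clusters resampled
#' with replacement, for dependent data), and a user-supplied replication
#' design (an N x R matrix of replicate weights, e.g. jackknife or balanced
#' repeated replication, with an explicit \code{repl_factor} scale for the
#' covariance computation; 1/R corresponds to the bootstrap convention).
#' Replicates are warm-started from the original solution.
#'
#' @param fit an [LsemFit-class].
#' @param data the data.frame the fit was estimated from.
#' @param R number of replicates (ignored for \code{repl_design}).
#' @param cluster optional cluster id vector (length N) or the name of a
#'   column in \code{data}; switches to the cluster bootstrap.
#' @param repl_design optional N x R matrix of replicate weights.
#' @param repl_factor covariance scale factor; defaults to 1/R for the
#'   bootstrap designs, required for \code{repl_design}.
#' @param seed integer seed for the resampling draws.
#' @param verbose print progress every 25 replicates.
#' @return an [LsemBoot-class] object.
#' @export
lsemBootstrap <- function(fit, data, R = 200, cluster = NULL,
                          repl_design = NULL, repl_factor = NULL,
                          seed = 1, verbose = FALSE) {
  N <- nrow(data)
  if (!is.null(repl_design)) {
    design <- "repl_design"
    repl_design <- as.matrix(repl_design)
    stopifnot(nrow(repl_design) == N)
    R <- ncol(repl_design)
    if (is.null(repl_factor)) {
      stop("repl_factor must be given for a user replication design")
    }
  } else if (!is.null(cluster)) {
    design <- "cluster"
    if (is.character(cluster) && length(cluster) == 1L) {
      cluster <- data[[cluster]]
    }
    stopifnot(length(cluster) == N)
    if (is.null(repl_factor)) repl_factor <- 1 / R
  } else {
    design <- "nonparametric"
    if (is.null(repl_factor)) repl_factor <- 1 / R
  }
  stopifnot(R >= 2)

  ref <- .curveMatrices(fit)
  keys <- rownames(ref$est)
  Tn <- ncol(ref$est)
  est <- std <- array(NA_real_, c(length(keys), Tn, R),
                      dimnames = list(keys, NULL, NULL))
  ok <- logical(R)
  fast <- fit@config$type == "lsem"
  setup <- if (fast) .replicateSetup(fit) else NULL

  one <- function(data2, sw = NULL) {
    if (fast) {
      .replicateCurves(setup, data2, sampling_weights = sw)
    } else {
      rf <- .refit(fit, data2, sampling_weights = sw)
      if (!isTRUE(rf@fit$converged)) stop("replicate did not converge")
      m <- .curveMatrices(rf)
      list(est = m$est, std = m$std)
    }
  }

  set.seed(seed)
  for (r in seq_len(R)) {
    res <- tryCatch({
      if (design == "repl_design") {
        one(data, sw = repl_design[, r])
      } else if (design == "cluster") {
        ids <- unique(cluster)
        pick <- sample(ids, length(ids), replace = TRUE)
        idx <- unlist(lapply(pick, function(g) which(cluster == g)),
                      use.names = FALSE)
        one(data[idx, , drop = FALSE])
      } else {
        idx <- sample.int(N, N, replace = TRUE)
        one(data[idx, , drop = FALSE])
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(res) && identical(rownames(res$est), keys)) {
      est[, , r] <- res$est
      std[, , r] <- res$std
      ok[r] <- TRUE
    }
    if (verbose && r %% 25 == 0) message("replicate ", r, "/", R)
  }

  dropped <- sum(!ok)
  if (dropped > 0.2 * R) {
    stop("more than 20% of replicates failed (", dropped, " of ", R, ")")
  }
  new("LsemBoot", curves = est[, , ok, drop = FALSE],
      std_curves = std[, , ok, drop = FALSE], parameters = keys,
      grid = fit@grid, density = fit@moments@density, design = design,
      repl_factor = repl_factor, seed = as.integer(seed),
      dropped = as.integer(dropped))
}

#' Resampling covariance matrix of a parameter curve
#'
#' \eqn{V = c \sum_r (\xi^*_r - \bar\xi^*)(\xi^*_r - \bar\xi^*)^\top} with
#' the design's scale factor c (\code{repl_factor}; 1/R for bootstrap).
#'
#' @param boot an [LsemBoot-class].
#' @param parameter parameter key (use prefix \code{dif__} for DIF curves).
#' @param standardized use the standardized replicate curves.
#' @return T x T covariance matrix.
#' @export
curveCov <- function(boot, parameter, standardized = FALSE) {
  arr <- if (standardized) boot@std_curves else boot@curves
  if (!parameter %in% boot@parameters) {
    stop("unknown parameter key: ", parameter)
  }
  Xi <- t(arr[parameter, , , drop = TRUE])  # R x T
  if (is.null(dim(Xi))) Xi <- matrix(Xi, ncol = length(boot@grid))
  ctr <- sweep(Xi, 2, colMeans(Xi))
  boot@repl_factor * crossprod(ctr)
}

#' Pointwise resampling standard errors of the parameter curves
#'
#' @param boot an [LsemBoot-class].
#' @param standardized use the standardized replicate curves.
#' @return parameter x focal point matrix of standard errors (square roots
#'   of the diagonal of the replicate covariance).
#' @export
pointwiseSE <- function(boot, standardized = FALSE) {
  arr <- if (standardized) boot@std_curves else boot@curves
  out <- vapply(seq_along(boot@grid), function(t) {
    X <- arr[, t, , drop = FALSE][, 1, ]
    if (is.null(dim(X))) X <- matrix(X, nrow = length(boot@parameters))
    apply(X, 1, function(v) {
      sqrt(boot@repl_factor * sum((v - mean(v))^2))
    })
  }, numeric(length(boot@parameters)))
  out <- matrix(out, nrow = length(boot@parameters),
                dimnames = list(boot@parameters, NULL))
  out
}

#' Curve summaries with bootstrap inference
#'
#' For every parameter curve (including DIF effect curves, keyed
#' \code{dif__<label>}, and the standardized factor correlations, keyed
#' \code{std__<label>}): the density-weighted curve mean M and standard
#' deviation SD, the bootstrap bias-corrected SD, its standard error, the
#' one-sided normal test of curve variation (t, p), and the Wald equality
#' test across focal points (chi-square, df, p).  Parameters constrained
#' invariant have SD identically zero and undefined tests (reported NA).
#'
#' @param fit an [LsemFit-class].
#' @param boot an [LsemBoot-class] for the same fit; NULL gives the
#'   no-inference summary (M and SD only).
#' @return data.frame with columns \code{parameter}, \code{M}, \code{SD},
#'   \code{SD_bc}, \code{SE}, \code{t}, \code{p}, \code{wald_chisq},
#'   \code{wald_df}, \code{wald_p}.
#' @export
lsemSummary <- function(fit, boot = NULL) {
  mats <- .curveMatrices(fit)
  f <- fit@moments@density
  model <- fit@model
  pt <- model@partable
  corr_labels <- pt$label[pt$mat == "phi" & pt$row != pt$col & pt$free]

  rows <- list()
  addrow <- function(key, xi, reps, V) {
    ms <- curveMeanSd(xi, f)
    # floor numerical noise on constrained-invariant curves
    if (ms["SD"] < 1e-10) ms["SD"] <- 0
    sd_bc <- se <- tval <- pval <- wchi <- wp <- NA_real_
    wdf <- NA_integer_
    if (!is.null(reps)) {
      sdr <- apply(reps, 2, function(z) curveMeanSd(z, f)["SD"])
      sdr[sdr < 1e-10] <- 0
      bc <- sdBiasCorrected(ms["SD"], sdr)
      sd_bc <- bc$sd_bc; se <- bc$se
      if (isTRUE(se > 0)) {
        ts <- sdTest(sd_bc, se)
        tval <- ts$t; pval <- ts$p
      }
      if (!is.null(V) && any(abs(V) > 0)) {
        wt <- waldEqualityTest(xi, V)
        wchi <- wt$chisq; wdf <- wt$df; wp <- wt$p
      }
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = key, M = unname(ms["M"]), SD = unname(ms["SD"]),
      SD_bc = sd_bc, SE = se, t = tval, p = pval,
      wald_chisq = wchi, wald_df = wdf, wald_p = wp,
      stringsAsFactors = FALSE)
  }

  getReps <- function(arr, key) {
    reps <- arr[key, , , drop = TRUE]  # T x R
    if (is.null(dim(reps))) reps <- matrix(reps, nrow = length(fit@grid))
    reps
  }
  for (key in rownames(mats$est)) {
    xi <- mats$est[key, ]
    reps <- V <- NULL
    if (!is.null(boot) && key %in% boot@parameters) {
      reps <- getReps(boot@curves, key)
      V <- curveCov(boot, key)
    }
    addrow(key, xi, reps, V)
  }
  # standardized factor correlations
  for (lab in corr_labels) {
    xi <- mats$std[lab, ]
    reps <- V <- NULL
    if (!is.null(boot) && lab %in% boot@parameters) {
      reps <- getReps(boot@std_curves, lab)
      V <- curveCov(boot, lab, standardized = TRUE)
    }
    addrow(paste0("std__", lab), xi, reps, V)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation test for parameter-curve variation
#'
#' Randomly permutes the moderator column (preserving its multiset of
#' values), re-estimates the full model, and compares the observed curve SD
#' of each parameter against the permutation null distribution.  The
#' p-value uses the add-one convention \eqn{(1 + \#\{SD^* \ge
#' \widehat{SD}\}) / (B + 1)}.
#'
#' @param fit an [LsemFit-class].
#' @param data the data.frame the fit was estimated from.
#' @param B number of permutations.
#' @param seed integer seed.
#' @param verbose print progress every 25 permutations.
#' @return data.frame with columns \code{parameter}, \code{SD_obs},
#'   \code{p}; the permutation SD draws are attached as attribute
#'   \code{"replicates"} (parameter x B matrix), with \code{"B"},
#'   \code{"seed"} and \code{"dropped"} attributes.
#' @export
lsemPermutationTest <- function(fit, data, B = 1000, seed = 1,
                                verbose = FALSE) {
  stopifnot(B >= 1)
  mats <- .curveMatrices(fit)
  f <- fit@moments@density
  sd_obs <- apply(mats$est, 1, function(z) curveMeanSd(z, f)["SD"])
  keys <- rownames(mats$est)
  reps <- matrix(NA_real_, length(keys), B, dimnames = list(keys, NULL))
  moderator <- fit@config$moderator
  fast <- fit@config$type == "lsem"
  setup <- if (fast) .replicateSetup(fit) else NULL
  set.seed(seed)
  for (b in seq_len(B)) {
    d2 <- data
    d2[[moderator]] <- sample(d2[[moderator]])
    res <- tryCatch({
      if (fast) {
        .replicateCurves(setup, d2)
      } else {
        pf <- .refit(fit, d2)
        m <- .curveMatrices(pf)
        list(est = m$est, density = pf@moments@density)
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(res) && identical(rownames(res$est), keys)) {
      reps[, b] <- apply(res$est, 1, function(z) {
        curveMeanSd(z, res$density)["SD"]
      })
    }
    if (verbose && b %% 25 == 0) message("permutation ", b, "/", B)
  }
  okb <- colSums(is.na(reps)) == 0
  dropped <- sum(!okb)
  if (dropped > 0.2 * B) {
    stop("more than 20% of permutation replicates failed")
  }
  reps <- reps[, okb, drop = FALSE]
  Beff <- ncol(reps)
  p <- vapply(seq_along(keys), function(k) {
    (1 + sum(reps[k, ] >= sd_obs[k])) / (Beff + 1)
  }, numeric(1))
  out <- data.frame(parameter = keys, SD_obs = unname(sd_obs), p = p,
                    stringsAsFactors = FALSE)
  attr(out, "replicates") <- reps
  attr(out, "B") <- Beff
  attr(out, "seed") <- seed
  attr(out, "dropped") <- dropped
  out
}
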