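# Construction of the numerical fitting problem: maps free model parameters
# (possibly shared across groups, or constrained to polynomial curves over
# the focal grid) onto a working parameter vector, and drives the compiled
# objective/gradient through nlminb.

.isVarianceRow <- function(pt) pt$mat %in% c("phi", "psi") & pt$row == pt$col

# polynomial / spline basis over focal positions z (continuity at knots via
# a truncated power basis); one segment means a plain polynomial
.polyBasis <- function(z, degree, segments) {
  zc <- (z - mean(z)) / max(stats::sd(z), .Machine$double.eps)
  X <- outer(zc, 0:degree, `^`)
  colnames(X) <- paste0("b", 0:degree)
  if (segments > 1) {
    knots <- stats::quantile(zc, probs = seq_len(segments - 1) / segments,
                             names = FALSE, type = 7)
    K <- vapply(knots, function(k) pmax(zc - k, 0)^degree,
                numeric(length(zc)))
    colnames(K) <- paste0("k", seq_len(segments - 1))
    X <- cbind(X, K)
  }
  X
}

.startValues <- function(model, Slist) {
  pt <- model@partable
  Sbar <- Reduce(`+`, Slist) / length(Slist)
  # anchor indicator per factor: first loading cell in that column
  anchor <- integer(length(model@factors))
  for (f in seq_along(model@factors)) {
    lf <- pt[pt$mat == "lambda" & pt$col == f, , drop = FALSE]
    fx <- lf[!lf$free & !is.na(lf$value) & lf$value != 0, , drop = FALSE]
    anchor[f] <- if (nrow(fx)) fx$row[1] else lf$row[1]
  }
  start <- numeric(nrow(pt))
  for (k in seq_len(nrow(pt))) {
    start[k] <- switch(pt$mat[k],
      lambda = 0.7,
      beta = 0,
      phi = if (pt$row[k] == pt$col[k]) {
        max(0.5 * Sbar[anchor[pt$row[k]], anchor[pt$row[k]]], 0.05)
      } else 0,
      psi = if (pt$row[k] == pt$col[k]) {
        max(0.5 * Sbar[pt$row[k], pt$row[k]], 0.05)
      } else 0
    )
  }
  stats::setNames(start, pt$label)
}

# Build the engine list consumed by the compiled objective/gradient.
# fixed_values: optional list (length G) of named vectors; a label present
# there is fixed at that value in that group instead of being estimated.
.buildEngine <- function(model, Slist, ng, par_invariant = character(),
                         par_linear = character(), par_quadratic = character(),
                         pw_linear = 1L, pw_quadratic = 1L, grid = NULL,
                         fixed_values = NULL) {
  pt <- model@partable
  G <- length(Slist)
  I <- length(model@indicators)
  nf <- length(model@factors)
  if (is.null(grid)) grid <- seq_len(G)
  stopifnot(length(grid) == G, length(ng) == G)
  overlap <- intersect(par_invariant, c(par_linear, par_quadratic))
  overlap <- c(overlap, intersect(par_linear, par_quadratic))
  if (length(overlap)) {
    stop("parameter(s) in more than one constraint class: ",
         paste(unique(overlap), collapse = ", "))
  }
  bad <- setdiff(c(par_invariant, par_linear, par_quadratic),
                 pt$label[pt$free])
  if (length(bad)) {
    stop("constraint on unknown or fixed parameter(s): ",
         paste(bad, collapse = ", "))
  }

  matcode <- c(lambda = 1L, beta = 2L, phi = 3L, psi = 4L)
  Lambda0 <- array(0, c(I, nf, G)); Beta0 <- array(0, c(nf, nf, G))
  Phi0 <- array(0, c(nf, nf, G)); Psi0 <- array(0, c(I, I, G))
  setbase <- function(g, m, r, cc, v) {
    if (m == 1L) Lambda0[r, cc, g] <<- v
    else if (m == 2L) Beta0[r, cc, g] <<- v
    else if (m == 3L) { Phi0[r, cc, g] <<- v }
    else { Psi0[r, cc, g] <<- v }
  }

  start_nat <- .startValues(model, Slist)
  isvar <- .isVarianceRow(pt)

  par_names <- character(0); plog <- logical(0); theta0 <- numeric(0)
  addpar <- function(name, logflag, start) {
    if (name %in% par_names) return(match(name, par_names))
    par_names <<- c(par_names, name)
    plog <<- c(plog, logflag)
    theta0 <<- c(theta0, if (logflag) log(max(start, 1e-4)) else start)
    length(par_names)
  }

  basis_cache <- list()
  getBasis <- function(deg, seg) {
    key <- paste(deg, seg)
    if (is.null(basis_cache[[key]])) {
      basis_cache[[key]] <<- .polyBasis(grid, deg, seg)
    }
    basis_cache[[key]]
  }

  ent <- list(); elabel <- character(0); egroup <- integer(0)
  pidx <- integer(0); pcoef <- numeric(0); eptr <- 0L

  for (k in seq_len(nrow(pt))) {
    lab <- pt$label[k]; m <- matcode[[pt$mat[k]]]
    r <- pt$row[k]; cc <- pt$col[k]
    if (!pt$free[k]) {
      for (g in seq_len(G)) setbase(g, m, r, cc, pt$value[k])
      next
    }
    for (g in seq_len(G)) {
      fx <- if (!is.null(fixed_values)) fixed_values[[g]][lab] else NA_real_
      if (length(fx) && !is.na(fx)) {
        setbase(g, m, r, cc, unname(fx))
        next
      }
      if (lab %in% par_invariant) {
        p <- addpar(lab, isvar[k], start_nat[lab])
        ids <- p; cfs <- 1
      } else if (lab %in% par_linear || lab %in% par_quadratic) {
        deg <- if (lab %in% par_linear) 1L else 2L
        seg <- if (lab %in% par_linear) pw_linear else pw_quadratic
        B <- getBasis(deg, seg)
        ids <- vapply(colnames(B), function(bn) {
          addpar(paste0(lab, "__", bn), FALSE,
                 if (bn == "b0") start_nat[lab] else 0)
        }, integer(1))
        cfs <- B[g, ]
      } else {
        p <- addpar(paste0(lab, "@", g), isvar[k], start_nat[lab])
        ids <- p; cfs <- 1
      }
      ent[[length(ent) + 1L]] <- c(g, m, r, cc)
      elabel <- c(elabel, lab); egroup <- c(egroup, g)
      pidx <- c(pidx, ids); pcoef <- c(pcoef, unname(cfs))
      eptr <- c(eptr, length(pidx))
    }
  }

  Scube <- array(unlist(Slist), c(I, I, G))
  logdetS <- vapply(Slist, function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0) stop("sample covariance matrix is not positive definite")
    as.numeric(d$modulus)
  }, numeric(1))

  list(
    I = I, nfac = nf, G = G,
    has_beta = any(pt$mat == "beta"),
    Lambda0 = Lambda0, Beta0 = Beta0, Phi0 = Phi0, Psi0 = Psi0,
    S = Scube, Ng = as.numeric(ng), logdetS = logdetS,
    entries = if (length(ent)) {
      e <- do.call(rbind, ent); storage.mode(e) <- "integer"; e
    } else matrix(0L, 0, 4),
    eptr = as.integer(eptr), pidx = as.integer(pidx), pcoef = pcoef,
    plog = plog, par_names = par_names, theta0 = theta0,
    elabel = elabel, egroup = egroup, grid = grid
  )
}

# natural-scale entry values (one per free label x group) at working theta
.engValues <- function(eng, theta) {
  x <- theta
  x[eng$plog] <- exp(theta[eng$plog])
  ne <- length(eng$elabel)
  vals <- numeric(ne)
  for (j in seq_len(ne)) {
    sel <- (eng$eptr[j] + 1L):eng$eptr[j + 1L]
    vals[j] <- sum(eng$pcoef[sel] * x[eng$pidx[sel]])
  }
  data.frame(label = eng$elabel, group = eng$egroup, value = vals,
             stringsAsFactors = FALSE)
}

#' Fit a (multiple-group) SEM to covariance matrices
#'
#' Minimizes the weighted ML discrepancy
#' \eqn{F(\theta) = \sum_g N_g D(S_g, \Sigma_g(\theta))} over the free model
#' parameters by quasi-Newton optimization with an analytic gradient.
#' Parameters may be group-specific (default), constrained equal across
#' groups (\code{par_invariant}), or constrained to follow a (piecewise)
#' linear or quadratic curve over the group positions (\code{par_linear},
#' \code{par_quadratic}), realized as equality constraints on first- and
#' second-order differences via a polynomial basis reparameterization.
#' Plain free variance parameters are log-parameterized internally so that
#' solutions stay admissible; results are reported on the natural scale.
#'
#' @param model an [LsemModel-class].
#' @param S a covariance matrix or list of per-group covariance matrices.
#' @param ng numeric vector of group weights (sample sizes, or kernel weight
#'   sums in joint local estimation).
#' @param par_invariant,par_linear,par_quadratic character vectors of free
#'   parameter labels per constraint class.
#' @param pw_linear,pw_quadratic number of contiguous segments for piecewise
#'   linear/quadratic constraints (1 = global polynomial).
#' @param grid optional numeric positions of the groups (focal points); used
#'   to build polynomial constraint bases.  Defaults to 1..G.
#' @param fixed_values optional list (length G) of named vectors fixing
#'   normally-free parameters at given values per group.
#' @param start_work optional working-scale start vector from a previous fit
#'   with an identical parameter layout (warm start).
#' @param restarts number of jittered restarts attempted on non-convergence.
#' @return list with elements \code{values} (data.frame label/group/value of
#'   all estimated cells), \code{par_names}, \code{theta_work},
#'   \code{objective}, \code{convergence}, \code{iterations},
#'   \code{per_group_discrepancy}, \code{implied} (I x I x G array),
#'   \code{engine}, \code{ng}, \code{npar}.
#' @examples
#' m <- lsemModel("F =~ X1 + X2 + X3")
#' S <- matrix(c(1, .5, .4, .5, 1.1, .45, .4, .45, .9), 3, 3,
#'             dimnames = list(paste0("X", 1:3), paste0("X", 1:3)))
#' fit <- fitGroups(m, S, ng = 100)
#' fit$objective  # ~0: the one-factor model is just-identified here
#' @export
fitGroups <- function(model, S, ng, par_invariant = character(),
                      par_linear = character(), par_quadratic = character(),
                      pw_linear = 1L, pw_quadratic = 1L, grid = NULL,
                      fixed_values = NULL, start_work = NULL, restarts = 3L) {
  if (is.matrix(S)) S <- list(S)
  eng <- .buildEngine(model, S, ng, par_invariant, par_linear, par_quadratic,
                      pw_linear, pw_quadratic, grid, fixed_values)
  npar <- length(eng$par_names)
  if (npar == 0L) {
    stop("model has no free parameters to estimate")
  }
  start <- eng$theta0
  if (!is.null(start_work)) {
    if (length(start_work) != npar) {
      stop("start_work length does not match the parameter layout")
    }
    start <- start_work
  }

  run <- function(s, newton = TRUE) {
    stats::nlminb(s, .eng_objective, gradient = .eng_gradient,
                  hessian = if (newton) .eng_hessian else NULL, engine = eng,
                  control = list(iter.max = 1000L, eval.max = 2000L,
                                 rel.tol = 1e-12))
  }
  tolgrad <- 1e-6 * max(1, sum(ng))
  best <- run(start)
  ok <- function(o) {
    is.finite(o$objective) && o$objective < 1e99 &&
      max(abs(.eng_gradient(o$par, eng))) < tolgrad
  }
  tries <- 0L
  while (!ok(best) && tries < restarts) {
    tries <- tries + 1L
    # alternate quasi-Newton (no Hessian) and jittered Newton restarts
    jit <- if (tries == 1L) start else start + stats::rnorm(npar, sd = 0.2)
    cand <- run(jit, newton = tries %% 2L == 0L)
    if ((ok(cand) && !ok(best)) || cand$objective < best$objective) {
      best <- cand
    }
  }
  conv <- ok(best)
  if (!conv) {
    warning("fitGroups did not reach the gradient tolerance after ",
            restarts, " restarts (objective ", signif(best$objective, 6), ")")
  }

  implied <- .eng_implied(best$par, eng)
  perg <- vapply(seq_along(S), function(g) {
    mlDiscrepancy(S[[g]], implied[, , g])
  }, numeric(1))

  list(values = .engValues(eng, best$par), par_names = eng$par_names,
       theta_work = best$par, objective = best$objective,
       convergence = conv, iterations = best$iterations,
       per_group_discrepancy = perg, implied = implied,
       engine = eng, ng = as.numeric(ng), npar = npar)
}

#' Fit statistics for a multiple-group covariance-structure fit
#'
#' Computes the chi-square analogue (the weighted discrepancy at the
#' minimum), RMSEA, SRMR, CFI, TLI and GFI against the diagonal-covariance
#' independence baseline.  With kernel-weighted groups the weight total is a
#' pseudo sample size, so these statistics are approximate in joint local
#' estimation.
#'
#' @param fit result of [fitGroups()].
#' @param effective_n effective total sample size; defaults to
#'   \code{sum(fit$ng)}.
#' @return list with \code{chisq}, \code{df}, \code{rmsea}, \code{srmr},
#'   \code{cfi}, \code{tli}, \code{gfi}, \code{baseline_chisq},
#'   \code{baseline_df}, \code{effective_n}.
#' @export
fitStatistics <- function(fit, effective_n = sum(fit$ng)) {
  eng <- fit$engine
  G <- eng$G; I <- eng$I
  chisq <- fit$objective
  df <- G * I * (I + 1) / 2 - fit$npar
  # independence baseline: diagonal covariance per group
  base <- 0
  for (g in seq_len(G)) {
    S <- eng$S[, , g]
    base <- base + eng$Ng[g] * (sum(log(diag(S))) - eng$logdetS[g])
  }
  df_base <- G * I * (I + 1) / 2 - G * I

  rmsea <- if (df > 0) sqrt(max(0, (chisq - df) / (df * effective_n))) else 0
  num <- max(chisq - df, 0)
  den <- max(chisq - df, base - df_base, 0)
  cfi <- if (den > 0) 1 - num / den else 1
  tli <- if (df > 0 && df_base > 0 && base / df_base > 1) {
    min(1, ((base / df_base) - (chisq / df)) / ((base / df_base) - 1))
  } else 1

  msq <- gfi_g <- numeric(G)
  for (g in seq_len(G)) {
    S <- eng$S[, , g]; Sig <- fit$implied[, , g]
    d <- sqrt(diag(S))
    res <- (S - Sig) / tcrossprod(d)
    lower <- res[lower.tri(res, diag = TRUE)]
    msq[g] <- mean(lower^2)
    Q <- solve(Sig, S)
    gfi_g[g] <- 1 - sum(diag((Q - diag(I)) %*% (Q - diag(I)))) /
      sum(diag(Q %*% Q))
  }
  w <- eng$Ng / sum(eng$Ng)
  list(chisq = chisq, df = df, rmsea = rmsea,
       srmr = sqrt(sum(w * msq)), cfi = max(0, min(1, cfi)), tli = tli,
       gfi = sum(w * gfi_g), baseline_chisq = base, baseline_df = df_base,
       effective_n = effective_n)
}
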