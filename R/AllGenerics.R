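#' Focal grid accessor
#' @param object an object with a focal grid (weights, moments or fit).
#' @return numeric vector of focal points.
#' @export
setGeneric("focalGrid", function(object) standardGeneric("focalGrid"))

#' Parameter curve accessor
#' @param object an [LsemFit-class].
#' @param dif logical; return DIF effect curves instead of main curves.
#' @return data.frame of parameter curves.
#' @export
setGeneric("lsemCurves", function(object, dif = FALSE) standardGeneric("lsemCurves"))

#' Conditional covariance accessor
#' @param object an [LsemMoments-class].
#' @return I x I x T array of conditional covariance matrices.
#' @export
setGeneric("conditionalCov", function(object) standardGeneric("conditionalCov"))

#' Weight matrix accessor
#' @param object an [LsemWeights-class].
#' @return N x T numeric matrix of kernel weights.
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))

#' @rdname focalGrid
#' @export
setMethod("focalGrid", "LsemWeights", function(object) object@grid)

#' @rdname focalGrid
#' @export
setMethod("focalGrid", "LsemMoments", function(object) object@grid)

#' @rdname focalGrid
#' @export
setMethod("focalGrid", "LsemFit", function(object) object@grid)

#' @rdname lsemCurves
#' @export
setMethod("lsemCurves", "LsemFit", function(object, dif = FALSE) {
  cv <- object@curves
  cv[cv$is_dif == dif, , drop = FALSE]
})

#' @rdname conditionalCov
#' @export
setMethod("conditionalCov", "LsemMoments", function(object) object@cov)

#' @rdname weightMatrix
#' @export
setMethod("weightMatrix", "LsemWeights", function(object) object@weights)

setMethod("show", "LsemModel", function(object) {
  pt <- object@partable
  cat("LsemModel:", length(object@indicators), "indicators,",
      length(object@factors), "factor(s),",
      sum(pt$free), "free parameters\n")
  cat("  indicators:", paste(object@indicators, collapse = ", "), "\n")
  cat("  factors:   ", paste(object@factors, collapse = ", "), "\n")
})

setMethod("show", "LsemWeights", function(object) {
  cat("LsemWeights:", nrow(object@weights), "subjects x",
      length(object@grid), "focal points\n")
  cat(sprintf("  kernel=%s bw=%.4g%s\n", object@kernel, object@bw,
              if (is.na(object@h)) "" else sprintf(" (h=%.3g)", object@h)))
  cat(sprintf("  W_t in [%.2f, %.2f]", min(object@Wt), max(object@Wt)))
  if (length(object@dropped)) {
    cat(";", length(object@dropped), "focal point(s) dropped")
  }
  cat("\n")
})

setMethod("show", "LsemMoments", function(object) {
  cat("LsemMoments:", length(object@indicators), "indicators at",
      length(object@grid), "focal points (mode:", object@mode, ")\n")
  if (any(object@pd_repaired)) {
    cat("  PD repair applied at", sum(object@pd_repaired), "focal point(s)\n")
  }
})

setMethod("show", "LsemFit", function(object) {
  cat("LsemFit (", object@mode, " estimation), ",
      length(object@grid), " focal points\n", sep = "")
  if (length(object@invariant)) {
    cat("  invariant:", paste(object@invariant, collapse = ", "), "\n")
  }
  gf <- object@fit$global
  if (!is.null(gf)) {
    cat(sprintf("  F=%.5f  chi2=%.2f (df=%d)  RMSEA=%.3f  SRMR=%.3f  CFI=%.3f\n",
                object@fit$objective, gf$chisq, gf$df, gf$rmsea, gf$srmr, gf$cfi))
  }
  cat("  curves:", length(unique(object@curves$parameter)), "parameters",
      if (any(object@curves$is_dif)) "(incl. DIF effects)" else "", "\n")
})

setMethod("show", "LsemBoot", function(object) {
  cat("LsemBoot:", dim(object@curves)[3], "replicates (design:",
      object@design, "), seed", object@seed, "\n")
  if (object@dropped > 0) {
    cat("  ", object@dropped, "non-converged replicate(s) dropped\n")
  }
})
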