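#' Parse lavaan-style model syntax into an LsemModel
#'
#' Supports the covariance-structure subset of lavaan syntax: \code{=~}
#' (factor loadings), \code{~~} (variances and covariances) and \code{~}
#' (structural regressions among factors).  A numeric prefix fixes a value,
#' e.g. \code{F =~ 1*X1 + X2}.  One statement per line; \code{#} starts a
#' comment.  If the first loading of a factor is not fixed explicitly, it is
#' fixed at 1 for identification.  Residual variances and factor variances
#' are added as free parameters automatically; covariances among exogenous
#' factors are free by default.
#'
#' @param syntax character: the model syntax (single string with newlines, a
#'   character vector of lines, or a path to a text file).
#' @return an [LsemModel-class] object.
#' @examples
#' m <- lsemModel("F =~ X1 + X2 + X3")
#' m
#' @export
lsemModel <- function(syntax) {
  if (length(syntax) == 1L && !grepl("[\n=~]", syntax) && file.exists(syntax)) {
    syntax <- readLines(syntax, warn = FALSE)
  }
  lines <- unlist(strsplit(syntax, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty model syntax")

  stmts <- lapply(lines, .parseLine)
  stmts <- do.call(rbind, stmts)
  # merge duplicate statements: a fixed specification wins over a free one,
  # otherwise the last occurrence is kept
  key <- paste(stmts$lhs, stmts$op, stmts$rhs)
  if (anyDuplicated(key)) {
    keep <- logical(nrow(stmts))
    for (k in unique(key)) {
      idx <- which(key == k)
      fx <- idx[!is.na(stmts$value[idx])]
      keep[if (length(fx)) fx[length(fx)] else idx[length(idx)]] <- TRUE
    }
    stmts <- stmts[keep, , drop = FALSE]
  }

  load_stmts <- stmts[stmts$op == "=~", , drop = FALSE]
  if (nrow(load_stmts) == 0L) stop("model defines no factor (no '=~' statement)")
  factors <- unique(load_stmts$lhs)
  indicators <- unique(load_stmts$rhs)
  if (any(indicators %in% factors)) {
    stop("names cannot be both factor and indicator: ",
         paste(intersect(indicators, factors), collapse = ", "))
  }
  for (f in factors) {
    if (!any(load_stmts$lhs == f)) stop("factor with zero indicators: ", f)
  }

  # every name in ~~ / ~ statements must be a known factor or indicator
  other <- stmts[stmts$op != "=~", , drop = FALSE]
  known <- c(factors, indicators)
  bad <- setdiff(c(other$lhs, other$rhs), known)
  if (length(bad)) {
    stop("unreferenced variable(s) in model syntax: ", paste(bad, collapse = ", "))
  }

  reg <- stmts[stmts$op == "~", , drop = FALSE]
  if (nrow(reg) > 0) {
    if (!all(c(reg$lhs, reg$rhs) %in% factors)) {
      stop("structural regressions ('~') are supported among factors only")
    }
    .checkAcyclic(reg, factors)
  }

  pt <- .buildPartable(stmts, factors, indicators)
  new("LsemModel", indicators = indicators, factors = factors,
      partable = pt, syntax = paste(lines, collapse = "\n"))
}

.parseLine <- function(line) {
  op <- if (grepl("=~", line, fixed = TRUE)) "=~"
        else if (grepl("~~", line, fixed = TRUE)) "~~"
        else if (grepl("~", line, fixed = TRUE)) "~"
        else stop("unknown operator in model syntax line: '", line, "'")
  parts <- strsplit(line, op, fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed model syntax line: '", line, "'")
  lhs <- trimws(parts[1])
  if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", lhs)) {
    stop("invalid left-hand-side name: '", lhs, "'")
  }
  terms <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) stop("empty right-hand side in line: '", line, "'")
  out <- lapply(terms, function(tm) {
    if (grepl("*", tm, fixed = TRUE)) {
      bits <- trimws(strsplit(tm, "*", fixed = TRUE)[[1]])
      val <- suppressWarnings(as.numeric(bits[1]))
      if (length(bits) != 2L || is.na(val)) {
        stop("malformed fixed-value term: '", tm, "'")
      }
      data.frame(lhs = lhs, op = op, rhs = bits[2], value = val)
    } else {
      data.frame(lhs = lhs, op = op, rhs = tm, value = NA_real_)
    }
  })
  do.call(rbind, out)
}

.checkAcyclic <- function(reg, factors) {
  adj <- matrix(FALSE, length(factors), length(factors),
                dimnames = list(factors, factors))
  adj[cbind(reg$lhs, reg$rhs)] <- TRUE  # edge dep <- pred
  remaining <- factors
  repeat {
    sinks <- remaining[rowSums(adj[remaining, remaining, drop = FALSE]) == 0]
    if (length(sinks) == 0L) {
      if (length(remaining)) stop("cyclic structural model (B) is not allowed")
      break
    }
    remaining <- setdiff(remaining, sinks)
    if (length(remaining) == 0L) break
  }
  invisible(TRUE)
}

.buildPartable <- function(stmts, factors, indicators) {
  fi <- function(x) match(x, factors)
  ii <- function(x) match(x, indicators)
  rows <- list()
  add <- function(lhs, op, rhs, mat, row, col, free, value) {
    label <- paste0(lhs, op, rhs)
    rows[[length(rows) + 1L]] <<- data.frame(
      lhs = lhs, op = op, rhs = rhs, mat = mat, row = row, col = col,
      free = free, value = value, label = label, stringsAsFactors = FALSE)
  }

  # loadings; auto-fix the first loading of a factor if none is fixed
  ld <- stmts[stmts$op == "=~", , drop = FALSE]
  for (f in factors) {
    lf <- ld[ld$lhs == f, , drop = FALSE]
    if (all(is.na(lf$value))) lf$value[1] <- 1
    for (k in seq_len(nrow(lf))) {
      add(f, "=~", lf$rhs[k], "lambda", ii(lf$rhs[k]), fi(f),
          free = is.na(lf$value[k]),
          value = if (is.na(lf$value[k])) NA_real_ else lf$value[k])
    }
  }

  # structural regressions (B rows: dependent, cols: predictor)
  reg <- stmts[stmts$op == "~", , drop = FALSE]
  endo <- unique(reg$lhs)
  for (k in seq_len(nrow(reg))) {
    add(reg$lhs[k], "~", reg$rhs[k], "beta", fi(reg$lhs[k]), fi(reg$rhs[k]),
        free = is.na(reg$value[k]),
        value = if (is.na(reg$value[k])) NA_real_ else reg$value[k])
  }

  # user (co)variances
  cv <- stmts[stmts$op == "~~", , drop = FALSE]
  for (k in seq_len(nrow(cv))) {
    a <- cv$lhs[k]; b <- cv$rhs[k]
    if (a %in% factors && b %in% factors) {
      i1 <- fi(a); i2 <- fi(b)
      lhs <- factors[min(i1, i2)]; rhs <- factors[max(i1, i2)]
      add(lhs, "~~", rhs, "phi", max(i1, i2), min(i1, i2),
          free = is.na(cv$value[k]),
          value = if (is.na(cv$value[k])) NA_real_ else cv$value[k])
    } else if (a %in% indicators && b %in% indicators) {
      i1 <- ii(a); i2 <- ii(b)
      lhs <- indicators[min(i1, i2)]; rhs <- indicators[max(i1, i2)]
      add(lhs, "~~", rhs, "psi", max(i1, i2), min(i1, i2),
          free = is.na(cv$value[k]),
          value = if (is.na(cv$value[k])) NA_real_ else cv$value[k])
    } else {
      stop("'~~' must relate two factors or two indicators: ",
           a, " ~~ ", b)
    }
  }
  have <- vapply(rows, function(r) paste(r$mat, r$row, r$col), "")

  # auto free factor variances
  for (f in seq_along(factors)) {
    if (!paste("phi", f, f) %in% have) {
      add(factors[f], "~~", factors[f], "phi", f, f, TRUE, NA_real_)
      have <- c(have, paste("phi", f, f))
    }
  }
  # auto free covariances among exogenous factors
  exo <- setdiff(factors, endo)
  if (length(exo) > 1) {
    ei <- fi(exo)
    for (p in seq_along(ei)) {
      for (q in seq_len(p - 1L)) {
        r <- max(ei[p], ei[q]); c <- min(ei[p], ei[q])
        if (!paste("phi", r, c) %in% have) {
          add(factors[c], "~~", factors[r], "phi", r, c, TRUE, NA_real_)
          have <- c(have, paste("phi", r, c))
        }
      }
    }
  }
  # auto free residual variances
  for (i in seq_along(indicators)) {
    if (!paste("psi", i, i) %in% have) {
      add(indicators[i], "~~", indicators[i], "psi", i, i, TRUE, NA_real_)
      have <- c(have, paste("psi", i, i))
    }
  }

  pt <- do.call(rbind, rows)
  rownames(pt) <- NULL
  pt
}
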