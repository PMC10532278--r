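#' Read a person-by-variable data table
#'
#' CSV with header; empty cells become missing values; row order is
#' preserved.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readLsemData <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path)
  utils::read.csv(path, na.strings = c("", "NA"), check.names = FALSE)
}

#' Write estimation outputs
#'
#' Writes the parameter curves as CSV (columns \code{parameter},
#' \code{focal_index}, \code{a_t}, \code{estimate}, \code{standardized},
#' \code{is_invariant}, \code{is_dif}), optionally a summary table as CSV,
#' and a JSON metadata file echoing the configuration, seeds, package
#' version and convergence information, so that a run can be audited and
#' reproduced.
#'
#' @param fit an [LsemFit-class].
#' @param curves_csv output path for the curve table.
#' @param meta_json output path for the metadata (NULL: skip).
#' @param summary optional summary data.frame (from [lsemSummary()]).
#' @param summary_csv output path for the summary (required when
#'   \code{summary} is given).
#' @param seed seed to record in the metadata.
#' @return invisibly, the vector of files written.
#' @export
writeLsemOutputs <- function(fit, curves_csv, meta_json = NULL,
                             summary = NULL, summary_csv = NULL, seed = NULL) {
  cols <- c("parameter", "focal_index", "a_t", "estimate", "standardized",
            "is_invariant", "is_dif")
  utils::write.csv(fit@curves[cols], curves_csv, row.names = FALSE)
  written <- curves_csv
  if (!is.null(summary)) {
    if (is.null(summary_csv)) stop("summary_csv path required")
    utils::write.csv(summary, summary_csv, row.names = FALSE)
    written <- c(written, summary_csv)
  }
  if (!is.null(meta_json)) {
    meta <- list(
      package = "localsem",
      version = as.character(utils::packageVersion("localsem")),
      config = fit@config,
      grid = fit@grid,
      invariant = fit@invariant,
      converged = isTRUE(fit@fit$converged),
      objective = fit@fit$objective,
      seed = seed
    )
    jsonlite::write_json(meta, meta_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    written <- c(written, meta_json)
  }
  invisible(written)
}

#' Export local moments for audit
#'
#' Long-format CSV of the conditional means and covariance entries per
#' focal point: columns \code{t}, \code{a_t}, \code{i}, \code{j},
#' \code{value} (\code{j} empty for means).
#'
#' @param moments an [LsemMoments-class].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeMoments <- function(moments, path) {
  I <- length(moments@indicators)
  rows <- list()
  for (t in seq_along(moments@grid)) {
    rows[[length(rows) + 1L]] <- data.frame(
      t = t, a_t = moments@grid[t], i = moments@indicators, j = "",
      value = moments@means[, t], stringsAsFactors = FALSE)
    idx <- which(lower.tri(diag(I), diag = TRUE), arr.ind = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      t = t, a_t = moments@grid[t],
      i = moments@indicators[idx[, 1]], j = moments@indicators[idx[, 2]],
      value = moments@cov[, , t][idx], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration
#'
#' YAML or JSON file describing an estimation run: \code{data},
#' \code{model}, \code{moderator} (required), plus any argument of
#' [lsemEstimate()] (\code{grid}, \code{kernel}, \code{h}, \code{bw},
#' \code{par_invariant}, ...) and optional \code{bootstrap} settings
#' (\code{R}, \code{seed}, \code{cluster}) and \code{output} paths
#' (\code{curves}, \code{summary}, \code{meta}).
#'
#' @param path configuration file (extension .yaml/.yml or .json).
#' @return named list.
#' @export
lsemRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  need <- setdiff(c("data", "model", "moderator"), names(cfg))
  if (length(need)) {
    stop("config misses required key(s): ", paste(need, collapse = ", "))
  }
  cfg
}

#' Execute a configured estimation run
#'
#' Reads the data and model, estimates the local SEM, optionally
#' bootstraps and summarizes, and writes the configured outputs.  A run is
#' a pure function of (input files, configuration, seed): repeated runs
#' produce identical files.
#'
#' @param config configuration list (see [lsemRunConfig()]) or path.
#' @return invisibly, list with \code{fit}, \code{boot} (or NULL) and
#'   \code{summary}.
#' @export
lsemRun <- function(config) {
  if (is.character(config)) config <- lsemRunConfig(config)
  dat <- readLsemData(config$data)
  model <- lsemModel(config$model)
  est_args <- config[intersect(names(config), names(formals(lsemEstimate)))]
  est_args$data <- dat
  est_args$model <- model
  if (!is.null(est_args$grid) && is.character(est_args$grid) &&
      !grepl(":", est_args$grid) && !grepl("^[a-z]", est_args$grid)) {
    est_args$grid <- as.numeric(strsplit(est_args$grid, ",")[[1]])
  }
  fit <- do.call(lsemEstimate, est_args)
  boot <- NULL
  summ <- lsemSummary(fit)
  seed <- NULL
  if (!is.null(config$bootstrap)) {
    bs <- config$bootstrap
    seed <- if (is.null(bs$seed)) 1L else as.integer(bs$seed)
    boot <- lsemBootstrap(fit, dat, R = if (is.null(bs$R)) 200 else bs$R,
                          cluster = bs$cluster, seed = seed)
    summ <- lsemSummary(fit, boot)
  }
  out <- config$output
  if (!is.null(out)) {
    writeLsemOutputs(fit,
                     curves_csv = out$curves,
                     meta_json = out$meta,
                     summary = if (!is.null(out$summary)) summ else NULL,
                     summary_csv = out$summary,
                     seed = seed)
  }
  invisible(list(fit = fit, boot = boot, summary = summ))
}
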