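# Flat key = value configuration files and CSV writers with a provenance
# comment block.

CONFIG_KEYS <- c("r", "k", "alpha", "a", "m", "beta", "rho", "delta",
                 "eta", "theta", "p0", "z0", "seed")

#' Read a flat key = value run configuration
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored. The eight model parameters are mandatory and validated via
#' \code{\link{plankton_params}}; \code{eta}, \code{theta}, \code{p0},
#' \code{z0} and \code{seed} are optional. Unknown keys are rejected with a
#' named error.
#'
#' @param path configuration file.
#' @return Object of class \code{run_config}: list with \code{params} and any
#'   optional fields present.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  unknown <- setdiff(keys, CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicated config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  if (any(is.na(vals)))
    stop("non-numeric value for key(s): ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  cfg <- as.list(vals); names(cfg) <- keys
  need <- c("r", "k", "alpha", "a", "m", "beta", "rho", "delta")
  missing_keys <- setdiff(need, keys)
  if (length(missing_keys))
    stop("missing required config key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  params <- do.call(plankton_params, cfg[need])
  out <- c(list(params = params), cfg[setdiff(keys, need)])
  if (!is.null(out$eta)) check_eta(out$eta)
  if (!is.null(out$theta)) check_theta(out$theta)
  structure(out, class = "run_config")
}

#' Write a run configuration back to a flat file
#'
#' Inverse of \code{\link{load_config}}; a save-load round trip reproduces
#' every numeric field exactly (values are written with full precision).
#'
#' @param config a \code{run_config}, or any list with a \code{params}
#'   element plus optional scalar fields.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  vals <- unlist(unclass(config$params))
  extra <- config[setdiff(names(config), "params")]
  vals <- c(vals, unlist(extra))
  lines <- sprintf("%s = %.17g", names(vals), vals)
  writeLines(lines, path)
  invisible(path)
}

#' Write a scan table as CSV with a provenance comment block
#'
#' RFC-4180 style CSV (one header line, deterministic row order) preceded by
#' `#` comment lines echoing the scan configuration. Rows are data-identical
#' across re-runs with the same seed; the timestamp line is excluded from
#' any determinism comparison.
#'
#' @param table a data frame (e.g. from \code{\link{bifurcation_scan}}).
#' @param path destination file.
#' @param config optional named list echoed into the comment block (the
#'   \code{meta} attribute of a \code{scan_table} is used by default).
#' @return \code{path}, invisibly.
#' @export
write_scan_table <- function(table, path, config = attr(table, "meta")) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             con)
  if (!is.null(config)) {
    flat <- unlist(config)
    writeLines(sprintf("# %s = %s", names(flat), as.character(flat)), con)
  }
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' Read back a scan table written by \code{\link{write_scan_table}}
#'
#' @param path CSV file with leading `#` comment lines.
#' @return Data frame (comment lines skipped).
#' @export
read_scan_table <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
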