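# numeric formatting: 17 significant digits round-trips doubles exactly
fmt_dbl <- function(x) sprintf("%.17g", x)

run_commands <- c("equilibrium", "dispersion", "threshold", "diagram",
                  "simulate", "converge")

param_keys <- c("b", "d", "beta0", "alpha", "mu", "gamma",
                "D1", "D2", "D3", "C_I")
config_keys <- c("nx", "ny", "dx", "dy", "dt", "t_end", "stationarity_tol",
                 "seed", "init_amp", "record_every")
other_keys <- c("command", "out", "verbosity", "plane", "k_max")

#' Parse a run configuration from a flat key=value file and/or CLI flags
#'
#' Builds a fully resolved run configuration: model parameters (pre-filled
#' with the baseline defaults of [epidemic_params()]), simulation settings
#' ([sim_config()]) and run metadata.  Values may come from a flat
#' `key = value` text file and/or from flags of the form
#' `c("--mu", "0.1", "--out", "runs/")`; flags take precedence over file
#' values, and the origin of every overridden key is recorded.  Unknown keys
#' are rejected by name; out-of-range values are rejected with the offending
#' key and its valid range.
#'
#' @param file optional path to a flat `key = value` (or `key=value`) text
#'   file; blank lines and `#` comments are ignored.
#' @param flags optional character vector of `--key value` pairs.
#' @return An object of class `"run_config"`: list with `command`, `params`
#'   ([epidemic_params()]), `sim` ([sim_config()]), `out`, `verbosity`,
#'   `plane`, `k_max`, and `provenance` (named character vector recording
#'   each explicitly set key and where it came from).
#' @export
parse_run_config <- function(file = NULL, flags = character()) {
  kv <- list(); origin <- character()
  if (!is.null(file)) {
    lines <- readLines(file, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L)
        stop("cannot parse config line: ", ln, call. = FALSE)
      kv[[m[2]]] <- trimws(m[3]); origin[m[2]] <- "file"
    }
  }
  if (length(flags)) {
    if (length(flags) %% 2L != 0L)
      stop("flags must come in --key value pairs", call. = FALSE)
    for (i in seq(1L, length(flags), by = 2L)) {
      key <- sub("^--", "", flags[i])
      if (!startsWith(flags[i], "--"))
        stop("expected a --key flag, got: ", flags[i], call. = FALSE)
      kv[[key]] <- flags[i + 1L]
      origin[key] <- if (!is.na(origin[key]) && origin[key] == "file")
        "flag (overrides file)" else "flag"
    }
  }
  known <- c(param_keys, config_keys, other_keys)
  bad <- setdiff(names(kv), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  as_num <- function(key) {
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v))
      stop(sprintf("key '%s': expected a number, got '%s'", key, kv[[key]]),
           call. = FALSE)
    v
  }
  p_args <- list()
  for (k in intersect(names(kv), param_keys)) p_args[[k]] <- as_num(k)
  params <- tryCatch(do.call(epidemic_params, p_args), error = function(e)
    stop(conditionMessage(e), call. = FALSE))

  c_args <- list()
  for (k in intersect(names(kv), config_keys)) c_args[[k]] <- as_num(k)
  sim <- do.call(sim_config, c_args)

  command <- kv[["command"]]
  if (!is.null(command) && !command %in% run_commands)
    stop("key 'command': must be one of ",
         paste(run_commands, collapse = ", "), call. = FALSE)
  plane <- kv[["plane"]]
  if (!is.null(plane) && !plane %in% c("k2_D1", "alpha_mu"))
    stop("key 'plane': must be 'k2_D1' or 'alpha_mu'", call. = FALSE)
  structure(list(command = command,
                 params = params, sim = sim,
                 out = kv[["out"]],
                 verbosity = if (is.null(kv[["verbosity"]])) 1L
                             else as.integer(as_num("verbosity")),
                 plane = plane,
                 k_max = if (is.null(kv[["k_max"]])) 2 else as_num("k_max"),
                 provenance = origin),
            class = "run_config")
}

# resolved configuration as a flat named list, for provenance metadata
config_metadata <- function(rc) {
  c(list(command = if (is.null(rc$command)) NA else rc$command,
         out = if (is.null(rc$out)) NA else rc$out),
    unclass(rc$params),
    unclass(rc$sim)[c("nx", "ny", "dx", "dy", "dt", "t_end",
                      "stationarity_tol", "init_amp", "record_every")],
    list(seed = if (is.null(rc$sim$seed)) NA else rc$sim$seed,
         provenance = as.list(rc$provenance)))
}

check_writable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir, call. = FALSE)
  if (file.access(dir, 2L) != 0L)
    stop("output directory is not writable: ", dir, call. = FALSE)
  invisible(path)
}

#' Write a dispersion curve as a delimited text table
#'
#' Tab-separated table with header `k2 re_lambda im_lambda`, full double
#' precision, plus a JSON metadata sidecar (`<path>.meta.json`) carrying the
#' parameters and noise intensity.
#'
#' @param dc a [dispersion_curve()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dispersion_table <- function(dc, path) {
  check_writable(path)
  df <- data.frame(k2 = fmt_dbl(dc$k2_grid),
                   re_lambda = fmt_dbl(dc$re_lambda),
                   im_lambda = fmt_dbl(dc$im_lambda))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(unclass(dc$params), list(C_I_used = dc$C_I,
                                     S0 = dc$steady_state$S0,
                                     I0 = dc$steady_state$I0,
                                     R0 = dc$steady_state$R0))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and read field snapshots
#'
#' A [field_state()] is written as three full-precision tab-separated
#' matrices (`<prefix>_S.tsv`, `<prefix>_I.tsv`, `<prefix>_R.tsv`) plus a
#' JSON metadata file (`<prefix>_meta.json`) with grid geometry, time,
#' parameters and the RNG seed.  The 17-significant-digit text encoding
#' round-trips IEEE doubles exactly, so `read_field_state()` restores a
#' bit-identical state.
#'
#' @param state a [field_state()].
#' @param prefix output path prefix.
#' @param p optional [epidemic_params()] stored in the metadata.
#' @param cfg optional [sim_config()] stored in the metadata (including the
#'   seed for stochastic runs).
#' @return `prefix`, invisibly (`write_field_state`); a `"field_state"`
#'   with a `"meta"` attribute (`read_field_state`).
#' @export
write_field_state <- function(state, prefix, p = NULL, cfg = NULL) {
  check_writable(paste0(prefix, "_meta.json"))
  wr <- function(m, suffix) {
    txt <- apply(m, 1L, function(row) paste(fmt_dbl(row), collapse = "\t"))
    writeLines(txt, paste0(prefix, "_", suffix, ".tsv"))
  }
  wr(state$S, "S"); wr(state$I, "I"); wr(state$R, "R")
  meta <- list(t = state$t, nx = nrow(state$S), ny = ncol(state$S),
               clipped = state$clipped)
  if (!is.null(p)) meta$params <- unclass(p)
  if (!is.null(cfg)) meta$config <- unclass(cfg)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_field_state
#' @export
read_field_state <- function(prefix) {
  rd <- function(suffix) {
    as.matrix(utils::read.table(paste0(prefix, "_", suffix, ".tsv"),
                                sep = "\t", header = FALSE,
                                colClasses = "numeric"))
  }
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  S <- unname(rd("S")); I <- unname(rd("I")); R <- unname(rd("R"))
  st <- field_state(S, I, R, t = meta$t,
                    clipped = if (is.null(meta$clipped)) 0L else meta$clipped)
  attr(st, "meta") <- meta
  st
}

#' Write a convergence report
#'
#' Tab-separated `(h, l2_error)` table plus JSON metadata with the fitted
#' order, residual, stationarity flags and study settings.
#'
#' @param report a [convergence_study()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_convergence_report <- function(report, path) {
  check_writable(path)
  df <- data.frame(h = fmt_dbl(report$h_values),
                   l2_error = fmt_dbl(report$l2_errors))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(fitted_order = report$fitted_order,
         fit_residual = report$fit_residual,
         h_ref = report$h_ref, C_I = report$C_I, t_end = report$t_end,
         stationary = report$stationary),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a stability diagram
#'
#' Tab-separated long-format table (`x`, `y`, `max_re_lambda`, `status`)
#' plus JSON metadata with the plane, axis names, noise intensity and the
#' baseline parameters.
#'
#' @param diag a [stability_region()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stability_diagram <- function(diag, path) {
  check_writable(path)
  grid <- expand.grid(i = seq_along(diag$x), j = seq_along(diag$y))
  df <- data.frame(x = fmt_dbl(diag$x[grid$i]),
                   y = fmt_dbl(diag$y[grid$j]),
                   max_re_lambda = fmt_dbl(diag$max_re_lambda[cbind(grid$i, grid$j)]),
                   status = diag$status[cbind(grid$i, grid$j)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(list(plane = diag$plane, C_I = diag$C_I), unclass(diag$params)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
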