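# ---------------------------------------------------------------------------
# Time-gridded trajectories and solver solutions.
# ---------------------------------------------------------------------------

#' Create a trajectory
#'
#' A trajectory holds a strictly increasing time grid with named state,
#' control, and multiplier columns plus time-invariant parameter values.
#'
#' @param time numeric vector (s), strictly increasing.
#' @param states,controls,multipliers numeric matrices with named columns and
#'   `length(time)` rows (may be `NULL`/empty).
#' @param parameters named numeric vector.
#' @return object of class `oc_trajectory`.
#' @export
trajectory <- function(time, states = NULL, controls = NULL,
                       multipliers = NULL, parameters = numeric(0)) {
  time <- as.numeric(time)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("time grid must be strictly increasing")
  fix <- function(m) {
    if (is.null(m)) return(matrix(0, length(time), 0))
    m <- as.matrix(m)
    if (nrow(m) != length(time))
      stop("column length ", nrow(m), " does not match time grid length ",
           length(time))
    m
  }
  states <- fix(states); controls <- fix(controls); multipliers <- fix(multipliers)
  nm <- c(colnames(states), colnames(controls), colnames(multipliers))
  if (anyDuplicated(nm)) stop("duplicate column names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  structure(list(time = time, states = states, controls = controls,
                 multipliers = multipliers,
                 parameters = parameters),
            class = "oc_trajectory")
}

#' @export
print.oc_trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$time), "time points on [",
      format(x$time[1]), ",", format(x$time[length(x$time)]), "] s;",
      ncol(x$states), "states,", ncol(x$controls), "controls,",
      ncol(x$multipliers), "multipliers,",
      length(x$parameters), "parameters\n")
  invisible(x)
}

#' @export
as.data.frame.oc_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$states, x$controls, x$multipliers,
             check.names = FALSE)
}

# Natural-cubic interpolant per column; endpoints reproduced exactly.
traj_interpolant <- function(traj, block = "states") {
  m <- traj[[block]]
  funs <- lapply(seq_len(ncol(m)), function(j)
    stats::splinefun(traj$time, m[, j], method = "fmm"))
  names(funs) <- colnames(m)
  funs
}

#' Resample a trajectory onto a new time grid
#'
#' Cubic interpolation of every column; grid endpoint values are preserved
#' exactly when the new grid shares the endpoints.
#'
#' @param traj an [trajectory()] object.
#' @param time new time grid within the trajectory's span.
#' @return resampled trajectory.
#' @export
resample_trajectory <- function(traj, time) {
  if (min(time) < traj$time[1] - 1e-12 ||
      max(time) > traj$time[length(traj$time)] + 1e-12)
    stop("new grid extends outside the trajectory span")
  rs <- function(block) {
    m <- traj[[block]]
    out <- vapply(seq_len(ncol(m)), function(j)
      stats::splinefun(traj$time, m[, j], method = "fmm")(time),
      numeric(length(time)))
    out <- matrix(out, nrow = length(time))
    colnames(out) <- colnames(m)
    out
  }
  trajectory(time, rs("states"), rs("controls"), rs("multipliers"),
             traj$parameters)
}

new_solution <- function(traj, success, status, objective, iterations,
                         goal_values, residuals, lam = NULL, z = NULL) {
  traj$success <- success
  traj$status <- status
  traj$objective <- objective
  traj$iterations <- iterations
  traj$goal_values <- goal_values
  traj$residuals <- residuals
  traj$lam <- lam
  traj$z <- z
  class(traj) <- c("oc_solution", "oc_trajectory")
  traj
}

#' @export
print.oc_solution <- function(x, ...) {
  cat("Solution [", x$status, "]: objective", format(x$objective),
      "in", x$iterations, "iterations\n")
  if (length(x$goal_values)) {
    cat("Goal breakdown:\n")
    for (nm in names(x$goal_values))
      cat("  ", nm, "=", format(x$goal_values[[nm]]), "\n")
  }
  if (length(x$residuals))
    cat("Residuals: max defect", format(x$residuals$defect),
        "| max path", format(x$residuals$path),
        "| max boundary", format(x$residuals$boundary), "\n")
  if (length(x$parameters))
    cat("Parameters:", paste(names(x$parameters), "=",
                             format(x$parameters), collapse = ", "), "\n")
  NextMethod()
}

#' @export
summary.oc_solution <- function(object, ...) {
  out <- list(status = object$status, objective = object$objective,
              iterations = object$iterations,
              goal_values = object$goal_values,
              residuals = object$residuals,
              parameters = object$parameters,
              horizon = range(object$time))
  class(out) <- "summary.oc_solution"
  out
}

#' @export
print.summary.oc_solution <- function(x, ...) {
  utils::str(x[!vapply(x, is.null, TRUE)])
  invisible(x)
}

#' @export
plot.oc_trajectory <- function(x, which = c("states", "controls"), ...) {
  which <- match.arg(which)
  m <- x[[which]]
  if (!ncol(m)) { warning("no ", which, " to plot"); return(invisible(x)) }
  graphics::matplot(x$time, m, type = "l", lty = 1, xlab = "time (s)",
                    ylab = which, ...)
  graphics::legend("topright", colnames(m), col = seq_len(ncol(m)),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# STO-style tab-separated time-series I/O.
#
# Dialect: a metadata header block terminated by `endheader`, then a
# tab-separated column-name row whose first column is `time`, then the data
# rows. Metadata lines are `key=value`; `name`, `nRows`, `nColumns` are
# always written. Values are written with 17 significant digits so that
# write -> read round-trips are bit-identical.
# ---------------------------------------------------------------------------

#' Write a trajectory as an STO-style time series
#'
#' @param traj a [trajectory()] object (or any data frame whose first column
#'   is time).
#' @param path output file path.
#' @param name dataset name written in the header.
#' @export
write_timeseries <- function(traj, path, name = "trajectory") {
  df <- if (inherits(traj, "oc_trajectory")) as.data.frame(traj) else
    as.data.frame(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               paste0("nRows=", nrow(df)),
               paste0("nColumns=", ncol(df)),
               "endheader",
               paste(colnames(df), collapse = "\t")), con)
  body <- apply(df, 1, function(r)
    paste(sprintf("%.17g", as.numeric(r)), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read an STO-style time series
#'
#' Columns are matched by name (the stored order is irrelevant); the first
#' column must be `time` and strictly increasing. Malformed headers,
#' duplicate columns, and non-monotonic time raise parse errors that cite
#' the offending line.
#'
#' @param path file path.
#' @return an [trajectory()] object with all non-time columns as states.
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "endheader")[1]
  if (is.na(hdr_end))
    stop("parse error in '", path, "': no 'endheader' line found")
  cn_line <- hdr_end + 1
  if (cn_line > length(lines))
    stop("parse error in '", path, "': missing column-name row (line ",
         cn_line, ")")
  cn <- strsplit(lines[cn_line], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(cn))
    stop("parse error in '", path, "' line ", cn_line,
         ": duplicate column names")
  if (cn[1] != "time")
    stop("parse error in '", path, "' line ", cn_line,
         ": first column must be 'time'")
  nr <- length(lines) - cn_line
  dat <- matrix(NA_real_, nr, length(cn))
  for (i in seq_len(nr)) {
    v <- suppressWarnings(as.numeric(
      strsplit(lines[cn_line + i], "\t", fixed = TRUE)[[1]]))
    if (length(v) != length(cn) || any(is.na(v)))
      stop("parse error in '", path, "' line ", cn_line + i,
           ": expected ", length(cn), " numeric fields")
    dat[i, ] <- v
  }
  tm <- dat[, 1]
  if (length(tm) > 1 && any(diff(tm) <= 0))
    stop("parse error in '", path, "' line ",
         cn_line + which(diff(tm) <= 0)[1] + 1,
         ": time column must be strictly increasing")
  st <- dat[, -1, drop = FALSE]
  colnames(st) <- cn[-1]
  trajectory(tm, states = st)
}
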