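# Trajectory container and basic kinematics.
#
# A trajectory is a single individual's time-ordered sequence of GPS fixes
# in a PROJECTED planar coordinate system (metres). Nothing in this package
# reprojects: hull areas and the time-scaled distance require a metric plane,
# so geodesic (lon/lat) input must be projected by the caller first.

#' Construct a trajectory from coordinate and time vectors
#'
#' Fixes are sorted by time on construction. Internally timestamps are
#' stored as numeric epoch seconds.
#'
#' @param x,y Projected planar coordinates in metres.
#' @param t Timestamps: numeric epoch seconds, or anything coercible via
#'   `as.POSIXct()`.
#' @param individual_id Identifier of the tracked animal.
#' @param crs_note Free-form record of the projection the coordinates are in.
#' @return An object of class `locoh_traj`: a list with elements
#'   `individual_id`, `fixes` (a data.frame with columns `t`, `x`, `y`,
#'   sorted by `t`) and `crs_note`.
#' @examples
#' tr <- trajectory(x = c(0, 10, 20, 30), y = c(0, 0, 5, 5), t = 0:3 * 3600)
#' n_fixes(tr)
#' @export
trajectory <- function(x, y, t, individual_id = "unknown", crs_note = "") {
  if (inherits(t, "POSIXt")) t <- as.numeric(t)
  t <- as.numeric(t)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) != length(t))
    stop("x, y and t must have equal length")
  if (anyNA(t) || anyNA(x) || anyNA(y) || any(!is.finite(c(x, y, t))))
    stop("trajectory coordinates and timestamps must be finite and non-missing")
  ord <- order(t)
  t <- t[ord]; x <- x[ord]; y <- y[ord]
  dup <- duplicated(t)
  if (any(dup)) {
    stop("duplicate timestamps are not allowed (one animal cannot be in two ",
         "places at once): ", paste(unique(t[dup]), collapse = ", "))
  }
  structure(
    list(individual_id = as.character(individual_id)[1],
         fixes = data.frame(t = t, x = x, y = y),
         crs_note = as.character(crs_note)[1]),
    class = "locoh_traj")
}

#' Number of fixes in a trajectory
#' @param traj A `locoh_traj`.
#' @return Integer count of fixes.
#' @export
n_fixes <- function(traj) {
  stopifnot(inherits(traj, "locoh_traj"))
  nrow(traj$fixes)
}

#' @export
print.locoh_traj <- function(x, ...) {
  fx <- x$fixes
  cat(sprintf("<locoh_traj> individual '%s': %d fixes\n", x$individual_id,
              nrow(fx)))
  if (nrow(fx) > 0) {
    cat(sprintf("  time span: %.0f .. %.0f s (%.1f h)\n", fx$t[1],
                fx$t[nrow(fx)], (fx$t[nrow(fx)] - fx$t[1]) / 3600))
    cat(sprintf("  x range: [%.1f, %.1f] m; y range: [%.1f, %.1f] m\n",
                min(fx$x), max(fx$x), min(fx$y), max(fx$y)))
  }
  if (nzchar(x$crs_note)) cat("  crs: ", x$crs_note, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.locoh_traj <- function(x, ...) x$fixes

# internal: subset a trajectory by fix indices (keeps time order)
traj_subset <- function(traj, idx) {
  structure(
    list(individual_id = traj$individual_id,
         fixes = traj$fixes[sort(idx), , drop = FALSE],
         crs_note = traj$crs_note),
    class = "locoh_traj")
}

.parse_timestamps <- function(ts) {
  ts <- trimws(as.character(ts))
  out <- suppressWarnings(as.numeric(ts))  # epoch seconds
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    parsed <- as.POSIXct(ts[miss], format = fmt, tz = "UTC")
    out[miss] <- as.numeric(parsed)
  }
  out
}

.default_columns <- c(individual_id = "individual_id", timestamp = "timestamp",
                      x = "x", y = "y")

#' Load a trajectory from a delimited text file
#'
#' Comma or tab delimiters are autodetected. Default column names are
#' `individual_id`, `timestamp`, `x`, `y`; other layouts are handled via
#' `column_map`. Timestamps may be epoch seconds or ISO-8601. Rows with
#' unparseable timestamps or missing coordinates are dropped and counted in
#' the load report (`attr(traj, "load_report")`); duplicated timestamps are
#' an error. Coordinates must be projected planar metres: Movebank-style
#' geographic columns (`location-long`/`location-lat`) are rejected unless
#' projected `x`/`y` columns are also present.
#'
#' @param path Path to the delimited file.
#' @param column_map Named character vector mapping the canonical names
#'   `individual_id`, `timestamp`, `x`, `y` to the file's column names,
#'   e.g. `c(timestamp = "date_time")`. Unmapped names use the defaults.
#' @return A `locoh_traj` with attribute `load_report`, a list with
#'   `n_rows`, `n_dropped` and `dropped_reasons`.
#' @export
load_trajectory <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"")
  cols <- .default_columns
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cols))
    if (length(bad) > 0) stop("unknown column_map keys: ",
                              paste(bad, collapse = ", "))
    cols[names(column_map)] <- column_map
  }
  have_xy <- all(cols[c("x", "y")] %in% names(df))
  if (!have_xy && any(c("location-long", "location-lat") %in% names(df))) {
    stop("geographic coordinates (location-long/location-lat) detected but ",
         "no projected x/y columns: project your data to planar metres ",
         "first; this tool never reprojects")
  }
  for (role in c("timestamp", "x", "y")) {
    if (!cols[[role]] %in% names(df))
      stop("required column '", cols[[role]], "' (", role, ") not found in ",
           path)
  }
  n_rows <- nrow(df)
  t <- .parse_timestamps(df[[cols[["timestamp"]]]])
  x <- suppressWarnings(as.numeric(df[[cols[["x"]]]]))
  y <- suppressWarnings(as.numeric(df[[cols[["y"]]]]))
  keep <- !is.na(t) & !is.na(x) & !is.na(y) & is.finite(x) & is.finite(y)
  n_bad <- sum(!keep)
  t <- t[keep]; x <- x[keep]; y <- y[keep]
  dup <- duplicated(t) | duplicated(t, fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate timestamps in ", path, ": ",
         paste(unique(sort(t[dup]))[1:min(5, length(unique(t[dup])))],
               collapse = ", "))
  }
  if (length(t) < 4)
    stop("fewer than 4 valid fixes in ", path,
         " (hull-based operations need at least 4)")
  id <- if (cols[["individual_id"]] %in% names(df)) {
    ids <- unique(as.character(df[[cols[["individual_id"]]]][keep]))
    if (length(ids) > 1)
      stop("multiple individuals in one file (", paste(ids, collapse = ", "),
           "); subset to a single individual first")
    ids
  } else "unknown"
  out <- trajectory(x, y, t, individual_id = id,
                    crs_note = "projected planar metres (as loaded)")
  attr(out, "load_report") <- list(
    n_rows = n_rows, n_dropped = n_bad,
    dropped_reasons = if (n_bad > 0) "unparseable timestamp or coordinates"
                      else character(0))
  out
}

#' Write a trajectory to a delimited text file
#'
#' Writes columns `individual_id`, `timestamp` (epoch seconds), `x`, `y`
#' at full double precision so that a load/write round trip reproduces the
#' fixes exactly.
#'
#' @param traj A `locoh_traj`.
#' @param path Output path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, sep = ",") {
  stopifnot(inherits(traj, "locoh_traj"))
  fx <- traj$fixes
  df <- data.frame(
    individual_id = rep(traj$individual_id, nrow(fx)),
    timestamp = formatC(fx$t, digits = 17, format = "g"),
    x = formatC(fx$x, digits = 17, format = "g"),
    y = formatC(fx$y, digits = 17, format = "g"))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Maximum observed speed of a trajectory
#'
#' The constant `v_max` used by the linear time-scaled distance: the maximum
#' over consecutive fix pairs of displacement divided by elapsed time, in
#' m/s. Speeds use consecutive fixes only, the standard velocity estimate
#' for discrete tracks.
#'
#' @param traj A `locoh_traj` with at least 2 fixes.
#' @return Maximum speed in m/s (>= 0).
#' @examples
#' tr <- trajectory(x = c(0, 6), y = c(0, 8), t = c(0, 5))
#' compute_vmax(tr)  # 10 m over 5 s = 2 m/s
#' @export
compute_vmax <- function(traj) {
  stopifnot(inherits(traj, "locoh_traj"))
  fx <- traj$fixes
  if (nrow(fx) < 2) stop("need at least 2 fixes to compute vmax")
  dt <- diff(fx$t)
  if (any(dt <= 0)) stop("non-increasing timestamps")  # precluded by class
  d <- sqrt(diff(fx$x)^2 + diff(fx$y)^2)
  max(d / dt)
}
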