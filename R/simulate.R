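# Seeded multi-patch trajectory simulator.
#
# The generator produces the two features the cross-validation method is
# sensitive to and nothing more: spatial clusters (Gaussian scatter around
# patch centres) and timed revisits (a dwell schedule with straight-line
# travel between patches at a fixed speed, discretized at the fix
# interval). Real telemetry has autocorrelated within-patch movement,
# tortuous travel and irregular sampling; none of that is emulated.

.default_patches <- function() {
  data.frame(x = c(0, 8000, 4000), y = c(0, 0, 7000),
             radius = c(300, 300, 300))
}

# fixes spent strictly between two patch centres when moving at
# `speed` m/s with one fix every `dt` s (arrival fix belongs to the next
# dwell). Deterministic: depends only on the centres.
.n_travel <- function(from, to, speed, dt) {
  d <- sqrt(sum((to - from)^2))
  max(ceiling(d / (speed * dt)) - 1, 0)
}

#' Configure the multi-patch trajectory simulator
#'
#' Defaults describe a mid-sized ungulate track: about 2900 hourly fixes
#' (the middle of typical collar deployments of a few thousand points)
#' over three patches 8 km apart, visited twice each so every patch is
#' revisited after a long absence, with 150 m within-patch scatter and
#' 1 m/s travel.
#'
#' @param seed Integer seed; simulation is deterministic given the seed.
#' @param n_points Total number of fixes. Must equal the schedule's dwell
#'   total plus the implied travel fixes; when `schedule` is `NULL` a
#'   default schedule is sized to hit `n_points` exactly.
#' @param dt Fix interval in seconds.
#' @param patches data.frame with columns `x`, `y` (centre, m) and
#'   `radius` (nominal patch extent, m; descriptive -- scatter is governed
#'   by `within_patch_sd`).
#' @param schedule data.frame with columns `patch` (row index into
#'   `patches`) and `dwell` (number of fixes spent in the patch), or
#'   `NULL` for the default two-pass rotation over all patches.
#' @param within_patch_sd Isotropic Gaussian scatter around the patch
#'   centre during a dwell, in metres.
#' @param travel_speed Speed of inter-patch travel in m/s; the simulated
#'   track's `compute_vmax()` is close to this by construction.
#' @return A `locoh_sim_config`.
#' @export
sim_config <- function(seed, n_points = 2900, dt = 3600, patches = NULL,
                       schedule = NULL, within_patch_sd = 150,
                       travel_speed = 1.0) {
  if (missing(seed)) stop("seed is required")
  if (is.null(patches)) patches <- .default_patches()
  patches <- as.data.frame(patches)
  if (!all(c("x", "y", "radius") %in% names(patches)))
    stop("patches needs columns x, y, radius")
  if (any(patches$radius <= 0)) stop("patch radius must be > 0")
  if (within_patch_sd <= 0 || travel_speed <= 0 || dt <= 0)
    stop("within_patch_sd, travel_speed and dt must be > 0")
  np <- nrow(patches)
  if (is.null(schedule)) {
    if (is.null(n_points)) n_points <- 2900
    visits <- rep(seq_len(np), 2)  # two passes: every patch is revisited
    travel <- sum(vapply(seq_len(length(visits) - 1), function(i) {
      a <- visits[i]; b <- visits[i + 1]
      .n_travel(c(patches$x[a], patches$y[a]), c(patches$x[b], patches$y[b]),
                travel_speed, dt)
    }, numeric(1)))
    dwell_total <- n_points - travel
    if (dwell_total < length(visits))
      stop("n_points too small for the default schedule")
    dwell <- rep(floor(dwell_total / length(visits)), length(visits))
    dwell[length(dwell)] <- dwell[length(dwell)] +
      dwell_total - sum(dwell)
    schedule <- data.frame(patch = visits, dwell = dwell)
  }
  schedule <- as.data.frame(schedule)
  if (!all(c("patch", "dwell") %in% names(schedule)))
    stop("schedule needs columns patch, dwell")
  if (any(schedule$patch < 1 | schedule$patch > np))
    stop("schedule references a patch that does not exist")
  if (any(schedule$dwell < 1)) stop("dwell counts must be >= 1")
  travel <- 0
  if (nrow(schedule) > 1)
    travel <- sum(vapply(seq_len(nrow(schedule) - 1), function(i) {
      a <- schedule$patch[i]; b <- schedule$patch[i + 1]
      .n_travel(c(patches$x[a], patches$y[a]), c(patches$x[b], patches$y[b]),
                travel_speed, dt)
    }, numeric(1)))
  total <- sum(schedule$dwell) + travel
  if (!is.null(n_points) && total != n_points)
    stop("unreachable schedule: dwells plus implied travel need ", total,
         " fixes but n_points = ", n_points)
  structure(list(n_points = total, dt = dt, patches = patches,
                 schedule = schedule, within_patch_sd = within_patch_sd,
                 travel_speed = travel_speed, seed = as.integer(seed),
                 rng = "Mersenne-Twister"),
            class = "locoh_sim_config")
}

#' Simulate a multi-patch trajectory
#'
#' During a dwell, fixes scatter isotropically (Gaussian,
#' `within_patch_sd`) around the patch centre. Between scheduled patches
#' the animal moves along the straight line between centres, advancing
#' `travel_speed * dt` metres per fix (final step shorter). Fixes are
#' emitted at a uniform interval `dt` starting at t = 0.
#'
#' @param config A [sim_config()].
#' @return A `locoh_traj` of exactly `config$n_points` fixes, with the
#'   generating configuration attached as attribute `sim_config`.
#' @examples
#' tr <- simulate_track(sim_config(seed = 1, n_points = 300))
#' compute_vmax(tr)  # close to the configured travel speed
#' @export
simulate_track <- function(config) {
  stopifnot(inherits(config, "locoh_sim_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed, kind = "Mersenne-Twister")
  P <- config$patches
  sch <- config$schedule
  step <- config$travel_speed * config$dt
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(nrow(sch))) {
    ctr <- c(P$x[sch$patch[i]], P$y[sch$patch[i]])
    nd <- sch$dwell[i]
    xs <- c(xs, ctr[1] + stats::rnorm(nd, 0, config$within_patch_sd))
    ys <- c(ys, ctr[2] + stats::rnorm(nd, 0, config$within_patch_sd))
    if (i < nrow(sch)) {
      nxt <- c(P$x[sch$patch[i + 1]], P$y[sch$patch[i + 1]])
      d <- sqrt(sum((nxt - ctr)^2))
      nt <- .n_travel(ctr, nxt, config$travel_speed, config$dt)
      if (nt > 0) {
        u <- (nxt - ctr) / d
        along <- seq_len(nt) * step
        xs <- c(xs, ctr[1] + u[1] * along)
        ys <- c(ys, ctr[2] + u[2] * along)
      }
    }
  }
  stopifnot(length(xs) == config$n_points)
  tr <- trajectory(xs, ys, seq_along(xs) * config$dt - config$dt,
                   individual_id = "sim",
                   crs_note = "synthetic planar metres")
  attr(tr, "sim_config") <- config
  tr
}
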