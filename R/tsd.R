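# Time-scaled distance (TSD) and nearest-neighbour retrieval.
#
# The linear TSD between fixes a and b is
#   sqrt( (xa - xb)^2 + (ya - yb)^2 + (s * vmax * (ta - tb))^2 )
# i.e. elapsed time is converted to an upper bound on distance travelled
# (vmax * dt) and scaled by the dimensionless factor s. With s = 0 the TSD
# reduces to plain Euclidean distance and LoCoH hulls are purely spatial.

#' Time-scaled distance parameters
#'
#' @param s Dimensionless time-scaling factor, `s >= 0`. `s = 0` gives the
#'   purely spatial LoCoH method.
#' @param vmax Maximum speed in m/s (see [compute_vmax()]), `vmax >= 0`.
#' @return A `locoh_tsd_params` list with elements `s`, `vmax` and their
#'   product `svmax`.
#' @export
tsd_params <- function(s, vmax) {
  s <- as.numeric(s); vmax <- as.numeric(vmax)
  if (length(s) != 1 || !is.finite(s) || s < 0) stop("s must be a single finite number >= 0")
  if (length(vmax) != 1 || !is.finite(vmax) || vmax < 0)
    stop("vmax must be a single finite number >= 0")
  structure(list(s = s, vmax = vmax, svmax = s * vmax),
            class = "locoh_tsd_params")
}

.as_fix <- function(f) {
  if (is.data.frame(f)) f <- as.list(f[1, , drop = FALSE])
  if (is.null(names(f)) && length(f) == 3) names(f) <- c("x", "y", "t")
  if (!all(c("x", "y", "t") %in% names(f)))
    stop("a fix needs named components x, y and t")
  list(x = as.numeric(f[["x"]]), y = as.numeric(f[["y"]]),
       t = as.numeric(f[["t"]]))
}

#' Time-scaled distance between two fixes
#'
#' @param a,b Fixes: named vectors/lists with components `x`, `y`, `t`, or
#'   unnamed numeric vectors `c(x, y, t)`, or one-row data.frames.
#' @param params A [tsd_params()] object.
#' @return The TSD in metres. Always `>=` the Euclidean distance, with
#'   equality when `s = 0` or the fixes are simultaneous.
#' @examples
#' p <- tsd_params(s = 0.01, vmax = 2)
#' tsd(c(0, 0, 0), c(0, 0, 100), p)  # pure time separation: 0.01*2*100 = 2 m
#' @export
tsd <- function(a, b, params) {
  stopifnot(inherits(params, "locoh_tsd_params"))
  a <- .as_fix(a); b <- .as_fix(b)
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 +
         (params$svmax * (a$t - b$t))^2)
}

#' Nearest neighbours of a fix under the time-scaled distance
#'
#' Returns the `k` fixes with smallest TSD to the parent fix. The parent is
#' always a member (its TSD is zero); by this package's convention `k`
#' therefore counts the parent itself, so a hull is built from exactly `k`
#' points and `k = n` is the all-points hull. Ties in TSD are broken by the
#' smaller fix index, making results deterministic.
#'
#' @param traj A `locoh_traj`.
#' @param parent_index 1-based index of the parent fix in time order.
#' @param k Number of members including the parent, `3 <= k <= n_fixes(traj)`.
#' @param params A [tsd_params()] object.
#' @return A `locoh_neighbors` list with `parent_index`, `member_indices`
#'   (ordered by increasing TSD, parent first) and `k`.
#' @export
nearest_neighbors <- function(traj, parent_index, k, params) {
  stopifnot(inherits(traj, "locoh_traj"), inherits(params, "locoh_tsd_params"))
  n <- n_fixes(traj)
  k <- as.integer(k)
  if (k < 3 || k > n) stop("k must satisfy 3 <= k <= ", n)
  parent_index <- as.integer(parent_index)
  if (parent_index < 1 || parent_index > n) stop("parent_index out of range")
  fx <- traj$fixes
  idx <- cpp_knn_tsd_one(fx$x, fx$y, fx$t, params$svmax, k, parent_index)
  structure(list(parent_index = parent_index, member_indices = idx, k = k),
            class = "locoh_neighbors")
}

# internal: neighbour matrix for every parent (n x k, 1-based indices)
knn_all <- function(x, y, t, svmax, k) {
  cpp_knn_tsd(x, y, t, svmax, as.integer(k))
}
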