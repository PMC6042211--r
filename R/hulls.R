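# Local convex hulls, hullsets and per-hull visit statistics.
#
# A hullset holds one local convex hull per generating fix, for one (k, s)
# pair. Its normalizer A_i is the SUM of hull areas -- overlaps are
# double-counted by design, because each hull contributes density
# independently. Polygons are stored flattened (concatenated CCW vertex
# arrays + offsets) so the C++ geometry kernels can scan them directly.

#' Build a single local convex hull
#'
#' Constructs the convex hull of a neighbour set's member coordinates.
#' Duplicate member coordinates are deduplicated first (the hull of a
#' multiset equals the hull of its support). Collinear or coincident member
#' sets yield a valid zero-area polygon flagged degenerate. Containment is
#' boundary-inclusive, so the parent fix is always among the enclosed
#' points even when it sits on the hull boundary.
#'
#' @param traj A `locoh_traj` (the generating point set; enclosed points are
#'   determined against all of its fixes).
#' @param members A `locoh_neighbors` object from [nearest_neighbors()].
#' @return A `locoh_hull` list: `parent_index`, `polygon` (closed CCW vertex
#'   matrix with columns `x`, `y`), `area` (m^2), `degenerate`,
#'   `enclosed_indices`, and `nsv`/`mnlv` (NA until [visit_stats()]).
#' @export
build_hull <- function(traj, members) {
  stopifnot(inherits(traj, "locoh_traj"), inherits(members, "locoh_neighbors"))
  if (members$k < 3) stop("a hull needs at least 3 member points")
  fx <- traj$fixes
  memb <- matrix(as.integer(members$member_indices), nrow = 1)
  h <- cpp_build_hulls(fx$x, fx$y, memb)
  m <- h$offsets[2]
  poly <- cbind(x = h$vx[seq_len(m)], y = h$vy[seq_len(m)])
  enc <- cpp_enclosed(h$vx, h$vy, h$offsets, h$bbox, fx$x, fx$y)[[1]]
  structure(
    list(parent_index = members$parent_index,
         polygon = rbind(poly, poly[1, , drop = FALSE]),
         area = h$areas[1],
         degenerate = h$degenerate[1],
         enclosed_indices = enc,
         nsv = NA_integer_, mnlv = NA_real_),
    class = "locoh_hull")
}

#' Build the full hullset for one (k, s) parameter pair
#'
#' One local convex hull per fix, each from the fix's `k` nearest neighbours
#' (parent included) under the time-scaled distance. `total_area` is the sum
#' of hull areas A_i, the normalizer of the hull-coverage density. With
#' `k = n` every hull is the global convex hull of the points, so
#' `total_area = n * area(global hull)`.
#'
#' @param traj A `locoh_traj`.
#' @param k Number of hull members including the parent,
#'   `3 <= k <= n_fixes(traj)`.
#' @param s Time-scaling factor, `>= 0`.
#' @param vmax Maximum speed in m/s; defaults to [compute_vmax()] on `traj`.
#' @param enclosed If `TRUE` (default) compute each hull's enclosed fix
#'   indices; scoring-only callers can skip this for speed.
#' @return A `locoh_hullset`; see Details for the flattened polygon layout.
#' @details The returned list carries `k`, `s`, `vmax`, `n`, `points` (the
#'   generating fixes), flattened polygons (`vx`, `vy`, `offsets`, `bbox`),
#'   per-hull `areas` and `degenerate` flags, `total_area`, and optionally
#'   `enclosed` (list of enclosed fix indices per hull). A hullset in which
#'   every hull is degenerate has `total_area = 0` and is unusable for
#'   density scoring; scoring functions raise an error on it.
#' @export
build_hullset <- function(traj, k, s, vmax = NULL, enclosed = TRUE) {
  stopifnot(inherits(traj, "locoh_traj"))
  n <- n_fixes(traj)
  k <- as.integer(k)
  if (k < 3 || k > n) stop("k must satisfy 3 <= k <= ", n)
  if (is.null(vmax)) vmax <- compute_vmax(traj)
  p <- tsd_params(s, vmax)
  fx <- traj$fixes
  memb <- knn_all(fx$x, fx$y, fx$t, p$svmax, k)
  h <- cpp_build_hulls(fx$x, fx$y, memb)
  hs <- structure(
    list(k = k, s = p$s, vmax = p$vmax, svmax = p$svmax,
         n = n, points = fx, members = memb,
         vx = h$vx, vy = h$vy, offsets = h$offsets, bbox = h$bbox,
         areas = h$areas, degenerate = h$degenerate,
         total_area = sum(h$areas),
         enclosed = NULL, nsv = NULL, mnlv = NULL, ivg = NULL),
    class = "locoh_hullset")
  if (enclosed)
    hs$enclosed <- cpp_enclosed(h$vx, h$vy, h$offsets, h$bbox, fx$x, fx$y)
  hs
}

#' @export
print.locoh_hullset <- function(x, ...) {
  cat(sprintf(
    "<locoh_hullset> n=%d hulls, k=%d, s=%g, vmax=%.4g m/s\n", x$n, x$k,
    x$s, x$vmax))
  cat(sprintf("  total hull area A = %.6g m^2 (%d degenerate hulls)\n",
              x$total_area, sum(x$degenerate)))
  if (!is.null(x$nsv))
    cat(sprintf("  visit stats (ivg=%g s): mean NSV %.2f, mean MNLV %.2f\n",
                x$ivg, mean(x$nsv), mean(x$mnlv)))
  invisible(x)
}

# internal: closed CCW polygon matrix of hull i
hull_polygon <- function(hullset, i) {
  a <- hullset$offsets[i] + 1L
  b <- hullset$offsets[i + 1L]
  poly <- cbind(x = hullset$vx[a:b], y = hullset$vy[a:b])
  rbind(poly, poly[1, , drop = FALSE])
}

# internal: visit segmentation. Enclosed fixes sorted by time; a gap
# strictly greater than ivg seconds starts a new visit.
.segment_visits <- function(times, ivg) {
  ts <- sort(times)
  1L + sum(diff(ts) > ivg)
}

#' Per-hull visit statistics: NSV and MNLV
#'
#' The fixes enclosed by a hull are sorted by time and segmented into
#' visits: a gap exceeding the inter-visit gap `ivg` starts a new visit.
#' NSV (number of separate visits) is the visit count; MNLV (mean number of
#' locations per visit) is the enclosed-fix count divided by NSV, so
#' `nsv * mnlv` equals the enclosed count exactly. The default
#' `ivg = 86400` s allows at most one visit per day; no canonical value
#' exists, so choose `ivg` to match the revisitation timescale of your
#' study system.
#'
#' @param x A `locoh_hull` or `locoh_hullset` (with enclosed indices).
#' @param ... Passed between methods.
#' @param ivg Inter-visit gap in seconds (> 0).
#' @return The input with `nsv`/`mnlv` filled (per hull for a hullset).
#' @export
visit_stats <- function(x, ...) UseMethod("visit_stats")

#' @rdname visit_stats
#' @param traj The generating `locoh_traj` (needed to look up fix times for
#'   a single hull).
#' @export
visit_stats.locoh_hull <- function(x, traj, ivg = 86400, ...) {
  stopifnot(inherits(traj, "locoh_traj"))
  if (!is.numeric(ivg) || length(ivg) != 1 || ivg <= 0)
    stop("ivg must be a single positive number of seconds")
  if (length(x$enclosed_indices) == 0) stop("hull has no enclosed fixes")
  times <- traj$fixes$t[x$enclosed_indices]
  x$nsv <- .segment_visits(times, ivg)
  x$mnlv <- length(times) / x$nsv
  x
}

#' @rdname visit_stats
#' @export
visit_stats.locoh_hullset <- function(x, ivg = 86400, ...) {
  if (!is.numeric(ivg) || length(ivg) != 1 || ivg <= 0)
    stop("ivg must be a single positive number of seconds")
  if (is.null(x$enclosed))
    x$enclosed <- cpp_enclosed(x$vx, x$vy, x$offsets, x$bbox,
                               x$points$x, x$points$y)
  t <- x$points$t
  x$nsv <- vapply(x$enclosed, function(e) .segment_visits(t[e], ivg),
                  integer(1))
  x$mnlv <- lengths(x$enclosed) / x$nsv
  x$ivg <- ivg
  x
}

# ---- GeoJSON export ---------------------------------------------------------

.geojson_polygon <- function(closed_matrix) {
  list(type = "Polygon",
       coordinates = list(lapply(seq_len(nrow(closed_matrix)), function(i)
         c(closed_matrix[i, 1], closed_matrix[i, 2]))))
}

#' Export a hullset as a GeoJSON FeatureCollection
#'
#' One Feature per hull, with properties `parent_index`, `area_m2`, and
#' `nsv`/`mnlv` when visit statistics have been computed. Coordinates are
#' the projected planar metres of the input (recorded in a top-level
#' `crs_note` member; GeoJSON proper assumes WGS84, which telemetry
#' projected to metres is not -- consumers must honour the note).
#'
#' @param hullset A `locoh_hullset`.
#' @param path Output path for the GeoJSON file.
#' @return Invisibly, `path`.
#' @export
hullset_geojson <- function(hullset, path) {
  stopifnot(inherits(hullset, "locoh_hullset"))
  feats <- lapply(seq_len(hullset$n), function(i) {
    props <- list(parent_index = i, area_m2 = hullset$areas[i],
                  degenerate = hullset$degenerate[i])
    if (!is.null(hullset$nsv)) {
      props$nsv <- hullset$nsv[i]
      props$mnlv <- hullset$mnlv[i]
    }
    list(type = "Feature", properties = props,
         geometry = .geojson_polygon(hull_polygon(hullset, i)))
  })
  obj <- list(type = "FeatureCollection",
              crs_note = "projected planar metres (not WGS84 lon/lat)",
              properties = list(k = hullset$k, s = hullset$s,
                                vmax = hullset$vmax,
                                total_area_m2 = hullset$total_area),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
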