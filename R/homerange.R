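# Isopleth home ranges and summary metrics.
#
# Isopleths follow the usual LoCoH construction: hulls are sorted by
# decreasing point density (enclosed-fix count) and unioned in order until
# the union encloses the requested fraction of fixes. The union area is
# computed exactly (overlaps counted once) and reported in km^2; internal
# geometry stays in m^2.

#' Build a utilization-distribution isopleth from a hullset
#'
#' Hulls are sorted by enclosed-fix count (descending; ties broken by
#' smaller area, then smaller parent index) and accumulated until at least
#' `ceiling(level * n)` distinct fixes are enclosed. The isopleth geometry
#' is the union of the selected hulls; its area counts overlaps once.
#'
#' @param hullset A `locoh_hullset` (enclosed indices are computed if
#'   missing).
#' @param level Fraction of fixes to enclose, in (0, 1].
#' @return A `locoh_isopleth`: `level`, `hull_order` (selected hull
#'   indices, in inclusion order), `polygons` (their closed CCW vertex
#'   matrices), `area_km2` (exact union area), `n_enclosed`.
#' @export
build_isopleth <- function(hullset, level = 0.95) {
  stopifnot(inherits(hullset, "locoh_hullset"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level > 1)
    stop("level must be in (0, 1]")
  if (all(hullset$degenerate))
    stop("all hulls are degenerate; no isopleth geometry exists")
  if (is.null(hullset$enclosed))
    hullset$enclosed <- cpp_enclosed(hullset$vx, hullset$vy, hullset$offsets,
                                     hullset$bbox, hullset$points$x,
                                     hullset$points$y)
  n <- hullset$n
  counts <- lengths(hullset$enclosed)
  ord <- order(-counts, hullset$areas, seq_len(n))
  need <- ceiling(level * n)
  covered <- logical(n)
  n_cov <- 0L
  sel <- integer(0)
  for (h in ord) {
    sel <- c(sel, h)
    e <- hullset$enclosed[[h]]
    new <- e[!covered[e]]
    covered[new] <- TRUE
    n_cov <- n_cov + length(new)
    if (n_cov >= need) break
  }
  area_m2 <- .union_area(hullset, sel)
  structure(list(level = level, hull_order = sel,
                 polygons = lapply(sel, function(i) hull_polygon(hullset, i)),
                 area_km2 = area_m2 / 1e6, n_enclosed = n_cov,
                 k = hullset$k, s = hullset$s),
            class = "locoh_isopleth")
}

# internal: exact union area (m^2) of a subset of a hullset's polygons
.union_area <- function(hullset, sel) {
  lens <- hullset$offsets[sel + 1L] - hullset$offsets[sel]
  idx <- sequence(lens, from = hullset$offsets[sel] + 1L)
  cpp_union_area(hullset$vx[idx], hullset$vy[idx], c(0L, cumsum(lens)))
}

#' @export
print.locoh_isopleth <- function(x, ...) {
  cat(sprintf(
    "<locoh_isopleth> level %.2f: %d hulls, %d fixes enclosed, %.4f km^2\n",
    x$level, length(x$hull_order), x$n_enclosed, x$area_km2))
  invisible(x)
}

#' Summarize a hullset as home-range metrics
#'
#' Reports the isopleth home-range area together with the unweighted hull
#' means of NSV (revisitation) and MNLV (visit duration).
#'
#' @param hullset A `locoh_hullset`.
#' @param level Isopleth level for the home-range area (default 0.95).
#' @param ivg Inter-visit gap in seconds for the visit statistics.
#' @return A `locoh_hr_summary` list: `hr_area_km2`, `mean_nsv`,
#'   `mean_mnlv`, `k`, `s`, `level`, `ivg`.
#' @export
summarize_home_range <- function(hullset, level = 0.95, ivg = 86400) {
  stopifnot(inherits(hullset, "locoh_hullset"))
  if (is.null(hullset$nsv) || is.null(hullset$ivg) || hullset$ivg != ivg)
    hullset <- visit_stats(hullset, ivg = ivg)
  iso <- build_isopleth(hullset, level)
  structure(list(hr_area_km2 = iso$area_km2,
                 mean_nsv = mean(hullset$nsv),
                 mean_mnlv = mean(hullset$mnlv),
                 k = hullset$k, s = hullset$s, level = level, ivg = ivg),
            class = "locoh_hr_summary")
}

#' @export
print.locoh_hr_summary <- function(x, ...) {
  cat(sprintf("<locoh_hr_summary> k=%d, s=%g (isopleth %.2f, ivg %g s)\n",
              x$k, x$s, x$level, x$ivg))
  cat(sprintf("  home range area: %.4f km^2\n", x$hr_area_km2))
  cat(sprintf("  mean NSV (visits/hull): %.3f\n", x$mean_nsv))
  cat(sprintf("  mean MNLV (locations/visit): %.3f\n", x$mean_mnlv))
  invisible(x)
}

#' Export an isopleth as GeoJSON
#'
#' The geometry is written as a MultiPolygon whose members are the selected
#' hulls (which may overlap; the exact dissolved union area in km^2 is
#' recorded in the properties). Coordinates are the input's projected
#' planar metres, flagged in `crs_note`.
#'
#' @param iso A `locoh_isopleth`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
isopleth_geojson <- function(iso, path) {
  stopifnot(inherits(iso, "locoh_isopleth"))
  geom <- list(type = "MultiPolygon",
               coordinates = lapply(iso$polygons, function(poly)
                 list(lapply(seq_len(nrow(poly)), function(i)
                   c(poly[i, 1], poly[i, 2])))))
  obj <- list(type = "FeatureCollection",
              crs_note = "projected planar metres (not WGS84 lon/lat)",
              features = list(list(
                type = "Feature",
                properties = list(level = iso$level,
                                  area_km2 = iso$area_km2,
                                  n_hulls = length(iso$hull_order),
                                  k = iso$k, s = iso$s,
                                  note = "member polygons may overlap; area_km2 is the dissolved union area"),
                geometry = geom)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
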