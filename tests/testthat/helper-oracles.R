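# Independent brute-force oracles. Nothing here shares code with the
# production path: distances via outer loops, hulls via grDevices::chull,
# containment via a naive ray cast, union areas via inclusion-exclusion
# with Sutherland-Hodgman clipping.

o_tsd <- function(a, b, s, vmax) {
  sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (s * vmax * (a[3] - b[3]))^2)
}

# k smallest TSDs to parent over all fixes, ties by smaller index
o_knn <- function(fx, parent, k, s, vmax) {
  d <- vapply(seq_len(nrow(fx)), function(i)
    o_tsd(c(fx$x[i], fx$y[i], fx$t[i]),
          c(fx$x[parent], fx$y[parent], fx$t[parent]), s, vmax),
    numeric(1))
  order(d, seq_along(d))[seq_len(k)]
}

o_shoelace <- function(poly) {  # open vertex matrix, any orientation
  n <- nrow(poly)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(poly[j, 1] * poly[, 2] - poly[, 1] * poly[j, 2])) / 2
}

# convex hull of points as an open CCW matrix (chull returns clockwise)
o_hull <- function(xy) {
  xy <- unique(xy)
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  xy[rev(idx), , drop = FALSE]
}

# boundary-inclusive even-odd containment, naive loop
o_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1
  }
  if (n == 1) return(px == poly[1, 1] && py == poly[1, 2])
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    scale <- (abs(xj - xi) + abs(yj - yi)) * (abs(px - xi) + abs(py - yi)) + 1
    if (abs(cr) <= 1e-9 * scale) {
      dot <- (px - xi) * (xj - xi) + (py - yi) * (yj - yi)
      len2 <- (xj - xi)^2 + (yj - yi)^2
      if (dot >= -1e-9 * scale && dot <= len2 + 1e-9 * scale) return(TRUE)
    }
    if ((yi > py) != (yj > py)) {
      if (px < xi + (py - yi) * (xj - xi) / (yj - yi)) inside <- !inside
    }
    j <- i
  }
  inside
}

# end-to-end score recomputation: naive k-NN, chull hulls, naive
# point-in-polygon, natural-log score with the 1/A^2 fallback
o_cv_score <- function(splits, k, s, vmax) {
  total <- 0
  for (sp in splits) {
    fx <- sp$train$fixes
    hulls <- lapply(seq_len(nrow(fx)), function(p) {
      memb <- o_knn(fx, p, k, s, vmax)
      o_hull(cbind(fx$x[memb], fx$y[memb]))
    })
    A <- sum(vapply(hulls, o_shoelace, numeric(1)))
    for (j in seq_len(nrow(sp$test))) {
      g <- sum(vapply(hulls, function(h)
        o_point_in_poly(sp$test$x[j], sp$test$y[j], h), logical(1)))
      total <- total + if (g >= 1) log(g / A) else log(1 / A^2)
    }
  }
  total
}

# Sutherland-Hodgman: clip convex `subject` by convex CCW `clip`,
# both open matrices; NULL when the intersection is empty/degenerate
o_clip <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    a <- clip[i, ]; b <- clip[i %% nc + 1, ]
    inp <- out
    if (is.null(inp) || nrow(inp) == 0) return(NULL)
    out <- matrix(numeric(0), ncol = 2)
    m <- nrow(inp)
    sides <- (b[1] - a[1]) * (inp[, 2] - a[2]) -
             (b[2] - a[2]) * (inp[, 1] - a[1])
    for (j in seq_len(m)) {
      jn <- j %% m + 1
      if (sides[j] >= 0) out <- rbind(out, inp[j, ])
      if ((sides[j] > 0 && sides[jn] < 0) || (sides[j] < 0 && sides[jn] > 0)) {
        t <- sides[j] / (sides[j] - sides[jn])
        out <- rbind(out, inp[j, ] + t * (inp[jn, ] - inp[j, ]))
      }
    }
  }
  if (is.null(out) || nrow(out) < 3) NULL else out
}

# union area of convex polygons by inclusion-exclusion (<= ~12 polygons)
o_union_area <- function(polys) {
  n <- length(polys)
  total <- 0
  for (mask in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    inter <- polys[[sel[1]]]
    for (s2 in sel[-1]) {
      inter <- o_clip(inter, polys[[s2]])
      if (is.null(inter)) break
    }
    if (!is.null(inter))
      total <- total + (-1)^(length(sel) + 1) * o_shoelace(inter)
  }
  total
}

# exhaustive full-resolution (k, s) search with the production scorer and
# the surface tie rule (highest score, then smaller k, then smaller s)
o_exhaustive_best <- function(traj, scheme, vmax, k_values, s_values) {
  splits <- split_train_test(traj, scheme)
  cells <- expand.grid(k = k_values, s = s_values, KEEP.OUT.ATTRS = FALSE)
  cells$score <- vapply(seq_len(nrow(cells)), function(i)
    suppressWarnings(
      cv_score(traj, cells$k[i], cells$s[i], splits, vmax = vmax)),
    numeric(1))
  cells[order(-cells$score, cells$k, cells$s), ][1, ]
}
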