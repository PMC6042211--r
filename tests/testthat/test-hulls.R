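test_that("build_hull matches shoelace on toy coordinate sets", {
  # triangle (0,0) (1,0) (0,1): area 0.5
  tr <- trajectory(x = c(0, 1, 0), y = c(0, 0, 1), t = 1:3)
  h <- build_hull(tr, nearest_neighbors(tr, 1, 3, tsd_params(0, 1)))
  expect_equal(h$area, 0.5)
  expect_false(h$degenerate)
  expect_setequal(h$enclosed_indices, 1:3)
  # polygon is closed
  expect_equal(h$polygon[1, ], h$polygon[nrow(h$polygon), ])

  # collinear members: degenerate, area 0, still a valid object
  tr2 <- trajectory(x = c(0, 1, 2), y = c(0, 1, 2), t = 1:3)
  h2 <- build_hull(tr2, nearest_neighbors(tr2, 1, 3, tsd_params(0, 1)))
  expect_true(h2$degenerate)
  expect_equal(h2$area, 0)
  expect_true(1 %in% h2$enclosed_indices)  # parent on the segment

  # unit square corners + centre: area 1, all 5 points enclosed
  tr3 <- trajectory(x = c(0, 1, 1, 0, 0.5), y = c(0, 0, 1, 1, 0.5), t = 1:5)
  h3 <- build_hull(tr3, nearest_neighbors(tr3, 5, 5, tsd_params(0, 1)))
  expect_equal(h3$area, 1.0)
  expect_setequal(h3$enclosed_indices, 1:5)
})

test_that("duplicate member coordinates are deduplicated before hulling", {
  tr <- trajectory(x = c(0, 0, 1, 0), y = c(0, 0, 0, 1), t = 1:4)
  h <- build_hull(tr, nearest_neighbors(tr, 1, 4, tsd_params(0, 1)))
  expect_equal(h$area, 0.5)
  expect_equal(nrow(h$polygon), 4)  # 3 vertices + closure
})

test_that("k = n makes every hull the global hull; total area is additive", {
  tr <- random_track(15, seed = 4)
  hs <- build_hullset(tr, k = 15, s = 0.02)
  global_area <- o_shoelace(o_hull(cbind(tr$fixes$x, tr$fixes$y)))
  expect_equal(hs$areas, rep(global_area, 15))
  expect_equal(hs$total_area, 15 * global_area)
})

test_that("hullset areas equal the independent chull/shoelace oracle", {
  tr <- random_track(10, seed = 31, extent = 1)
  hs <- build_hullset(tr, k = 3, s = 0)
  fx <- tr$fixes
  oracle <- vapply(1:10, function(p) {
    memb <- o_knn(fx, p, 3, 0, compute_vmax(tr))
    o_shoelace(o_hull(cbind(fx$x[memb], fx$y[memb])))
  }, numeric(1))
  expect_equal(hs$areas, oracle, tolerance = 1e-12)
  expect_equal(hs$total_area, sum(oracle), tolerance = 1e-12)
})

test_that("an all-collinear trajectory yields a fully degenerate hullset", {
  tr <- trajectory(x = 1:10, y = 2 * (1:10), t = 1:10)
  hs <- build_hullset(tr, k = 4, s = 0)
  expect_true(all(hs$degenerate))
  expect_equal(hs$total_area, 0)
  expect_error(log_density(hs, c(0, 0)), "degenerate")
})

test_that("hull area is monotone non-decreasing in k for a fixed parent", {
  tr <- random_track(40, seed = 13)
  areas <- vapply(3:40, function(k) build_hullset(tr, k, 0.01)$areas[17],
                  numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("enclosed indices equal a naive point-in-polygon loop (n = 50)", {
  tr <- random_track(50, seed = 6)
  hs <- build_hullset(tr, k = 8, s = 0.01)
  fx <- tr$fixes
  for (i in seq_len(hs$n)) {
    poly <- locohcv:::hull_polygon(hs, i)
    naive <- which(vapply(seq_len(50), function(j)
      o_point_in_poly(fx$x[j], fx$y[j], poly), logical(1)))
    expect_equal(hs$enclosed[[i]], naive)
  }
  # parent always enclosed, even as a hull vertex
  expect_true(all(vapply(seq_len(hs$n), function(i)
    i %in% hs$enclosed[[i]], logical(1))))
})

test_that("visit segmentation matches the hand-built examples", {
  p0 <- tsd_params(0, 1)
  # one bout: times 0, 60, 120 within ivg 3600
  tr <- trajectory(x = c(0, 1, 0, 900), y = c(0, 0, 1, 900),
                   t = c(0, 60, 120, 5000))
  h <- visit_stats(build_hull(tr, nearest_neighbors(tr, 1, 3, p0)),
                   tr, ivg = 3600)
  expect_equal(h$nsv, 1L)
  expect_equal(h$mnlv, 3)

  # two bouts: gap 99940 s > 3600 s
  tr2 <- trajectory(x = c(0, 1, 0, 1, 900), y = c(0, 0, 1, 1, 900),
                    t = c(0, 60, 1e5, 100060, 2e5))
  h2 <- visit_stats(build_hull(tr2, nearest_neighbors(tr2, 1, 4, p0)),
                    tr2, ivg = 3600)
  expect_equal(h2$nsv, 2L)
  expect_equal(h2$mnlv, 2.0)

  expect_error(visit_stats(h2, tr2, ivg = 0), "ivg")
})

test_that("nsv * mnlv equals the enclosed count on every hull of a fixture", {
  tr <- two_patch_track(n = 80, seed = 3)
  hs <- visit_stats(build_hullset(tr, k = 6, s = 0.01), ivg = 86400)
  expect_equal(hs$nsv * hs$mnlv, lengths(hs$enclosed))
  expect_true(all(hs$nsv >= 1))
  expect_true(all(hs$mnlv >= 1))
})

test_that("hullset GeoJSON export is valid and self-describing", {
  tr <- random_track(12, seed = 1)
  hs <- visit_stats(build_hullset(tr, k = 4, s = 0), ivg = 3600)
  f <- withr::local_tempfile(fileext = ".geojson")
  hullset_geojson(hs, f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 12)
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_equal(ring[[1]], ring[[length(ring)]])  # closed ring
  expect_equal(gj$features[[1]]$properties$parent_index, 1)
  expect_true(is.numeric(gj$features[[1]]$properties$nsv) ||
                is.integer(gj$features[[1]]$properties$nsv))
})
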