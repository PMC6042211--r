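test_that("random splits partition the track deterministically", {
  tr <- random_track(100, seed = 1)
  sc <- split_scheme(n_splits = 3, test_fraction = 0.25, seed = 7)
  sp <- split_train_test(tr, sc)
  expect_length(sp, 3)
  for (s in sp) {
    expect_equal(length(s$test_idx), 25)
    expect_equal(length(s$train_idx), 75)
    expect_length(intersect(s$train_idx, s$test_idx), 0)
    expect_setequal(union(s$train_idx, s$test_idx), 1:100)
  }
  sp2 <- split_train_test(tr, split_scheme(3, 0.25, seed = 7))
  expect_identical(lapply(sp, `[[`, "test_idx"), lapply(sp2, `[[`, "test_idx"))
  # different seed, different splits
  sp3 <- split_train_test(tr, split_scheme(3, 0.25, seed = 8))
  expect_false(identical(lapply(sp, `[[`, "test_idx"),
                         lapply(sp3, `[[`, "test_idx")))
})

test_that("temporal blocks tile the track without overlap", {
  tr <- random_track(101, seed = 2)
  sc <- split_scheme(n_splits = 4, mode = "temporal-blocks", seed = 1)
  sp <- split_train_test(tr, sc)
  blocks <- lapply(sp, `[[`, "test_idx")
  expect_equal(sort(unlist(blocks)), 1:101)        # tiling
  expect_true(all(vapply(blocks, function(b)
    all(diff(b) == 1), logical(1))))               # contiguous
})

test_that("degenerate split parameters are rejected", {
  tr <- random_track(8, seed = 3)
  expect_error(split_train_test(tr, split_scheme(1, 0.05, seed = 1)),
               "empty test set")
  expect_error(split_train_test(tr, split_scheme(1, 0.7, seed = 1)),
               "fewer than 4 training")
  expect_error(split_scheme(1, 0.5), "seed")
  tr2 <- random_track(7, seed = 3)
  expect_error(split_train_test(tr2, split_scheme(1, 0.25, seed = 1)),
               "at least 8")
})

test_that("log_density implements log(g/A) with the 1/A^2 fallback", {
  t1 <- cbind(c(0, 5, 0), c(0, 0, 2))          # area 5
  t2 <- cbind(c(100, 105, 100), c(0, 0, 2))    # area 5
  hs <- make_hullset(list(t1, t2))
  expect_equal(hs$total_area, 10)
  expect_equal(log_density(hs, c(1, 0.3)), log(1 / 10))
  expect_equal(log_density(hs, c(50, 50)), log(1 / 100))
  # overlap: g = 2
  s1 <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
  s2 <- cbind(c(1, 3, 3, 1), c(0, 0, 2, 2))
  hs2 <- make_hullset(list(s1, s2))
  expect_equal(log_density(hs2, c(1.5, 1)), log(2 / 8))
  # vectorized over a matrix of points
  expect_equal(log_density(hs2, rbind(c(1.5, 1), c(50, 50))),
               c(log(2 / 8), log(1 / 64)))
})

test_that("sub-square-metre hullsets are rejected, not silently misordered", {
  tiny <- cbind(c(0, 0.5, 0), c(0, 0, 0.5))  # area 0.125
  expect_error(log_density(make_hullset(list(tiny)), c(0.1, 0.1)),
               "1 m\\^2")
})

test_that("at k = k_max the density collapses to 1 / global-hull-area", {
  tr <- random_track(20, seed = 12)
  hs <- build_hullset(tr, k = 20, s = 0.03)
  centroid <- c(mean(tr$fixes$x), mean(tr$fixes$y))
  a_global <- o_shoelace(o_hull(cbind(tr$fixes$x, tr$fixes$y)))
  expect_equal(log_density(hs, centroid), -log(a_global))
})

test_that("cv_score is additive over splits", {
  tr <- random_track(60, seed = 14)
  sp1 <- split_train_test(tr, split_scheme(1, 0.25, seed = 5))
  twice <- structure(list(sp1[[1]], sp1[[1]]), class = "locoh_splits")
  one <- cv_score(tr, 8, 0.01, sp1)
  expect_equal(cv_score(tr, 8, 0.01, twice), 2 * one)
})

test_that("cv_score equals the end-to-end brute-force oracle", {
  tr <- random_track(60, seed = 15)
  vmax <- compute_vmax(tr)
  splits <- split_train_test(tr, split_scheme(2, 0.25, seed = 9))
  got <- cv_score(tr, 6, 0, splits, vmax = vmax)
  want <- o_cv_score(splits, 6, 0, vmax)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("cv_score warns when most test points miss every hull", {
  tr <- random_track(60, seed = 16, extent = 5000)
  splits <- split_train_test(tr, split_scheme(1, 0.25, seed = 2))
  expect_warning(cv_score(tr, 3, 0, splits), "outside every training hull")
})

test_that("the default coarse grid is 40 k values by 6 s values", {
  cfg <- search_config()
  ks <- locohcv:::.k_grid(cfg, 800)
  ss <- locohcv:::.s_grid(cfg)
  expect_equal(ks, seq(4, 784, by = 20))
  expect_length(ks, 40)
  expect_equal(ss, seq(0, 0.05, by = 0.01))
  expect_equal(length(ks) * length(ss), 240)
})

test_that("coarse search evaluates the full grid and best is the argmax", {
  tr <- two_patch_track(n = 100, seed = 20)
  sc <- split_scheme(2, 0.25, seed = 3)
  cfg <- search_config(k_max_grid = 60)
  surf <- coarse_grid_search(tr, sc, config = cfg)
  expect_equal(nrow(surf$table), length(surf$k_values) * length(surf$s_values))
  tab <- surf$table
  manual <- tab[order(-tab$score, tab$k, tab$s), ][1, ]
  expect_equal(surf$best$k, manual$k)
  expect_equal(surf$best$s, manual$s)
  expect_equal(surf$best$score, manual$score)
  expect_true(all(is.finite(tab$score)))
})

test_that("ties resolve to the smallest k then smallest s", {
  tab <- expand.grid(k = c(4, 24), s = c(0, 0.01))
  tab$score <- -100
  b <- locohcv:::.best_cell(tab)
  expect_equal(c(b$k, b$s), c(4, 0))
})

test_that("refinement only improves and respects grid bounds", {
  tr <- two_patch_track(n = 100, seed = 22)
  sc <- split_scheme(2, 0.25, seed = 4)
  cfg <- search_config(k_max_grid = 40, s_max = 0.02)
  coarse <- coarse_grid_search(tr, sc, config = cfg)
  final <- refine_search(tr, sc, config = cfg, coarse = coarse)
  expect_gte(final$best$score, coarse$best$score)
  expect_true(all(final$table$k >= 4 & final$table$k <= 40))
  expect_true(all(final$table$s >= 0 & final$table$s <= 0.02 + 1e-12))
  # previously evaluated cells are carried over, not recomputed differently
  merged <- merge(coarse$table[c("k", "s", "score")],
                  final$table[c("k", "s", "score")], by = c("k", "s"))
  expect_equal(merged$score.x, merged$score.y)
})

test_that("identical inputs and seed reproduce an identical surface", {
  tr <- two_patch_track(n = 80, seed = 30)
  sc <- split_scheme(2, 0.25, seed = 6)
  cfg <- search_config(k_max_grid = 30)
  s1 <- select_parameters(tr, sc, config = cfg)
  s2 <- select_parameters(tr, sc, config = cfg)
  expect_identical(s1, s2)
})
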