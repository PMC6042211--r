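# Cross-validated selection of (k, s).
#
# The normalized hullset is read as a probability density: a location
# covered by g of the training hulls has density g / A, where A is the
# summed area of all training hulls (overlaps double-counted). The score of
# a parameter pair is the total natural-log probability of all held-out
# points across all training/testing splits,
#
#   P_{k,s} = sum_i sum_j log( g_{i,j} / A_i ),
#
# with test points outside every hull assigned probability 1 / A_i^2 so the
# score stays finite while still penalizing the miss (for A > 1 m^2,
# 1/A^2 < 1/A, strictly below any covered point). Large k inflates A and
# deflates every g/A, which is the natural penalty against the k = k_max
# degenerate optimum; small k produces hulls that miss the test points.

.save_seed <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv)
  else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    rm(".Random.seed", envir = .GlobalEnv)
}

#' Define a training/testing split scheme
#'
#' @param n_splits Number of train/test splits (`>= 1`).
#' @param test_fraction Fraction of fixes held out per split, in (0, 1).
#'   Ignored by `temporal-blocks`, where block size is `n / n_splits`.
#' @param mode `"random"` (each split holds out a seeded random subset) or
#'   `"temporal-blocks"` (split i holds out the i-th contiguous time block;
#'   the blocks tile the track).
#' @param seed Integer seed; splits are deterministic given the seed.
#' @return A `locoh_split_scheme`.
#' @export
split_scheme <- function(n_splits = 5, test_fraction = 0.25,
                         mode = c("random", "temporal-blocks"), seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required so splits are reproducible")
  n_splits <- as.integer(n_splits)
  if (n_splits < 1) stop("n_splits must be >= 1")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  structure(list(n_splits = n_splits, test_fraction = test_fraction,
                 mode = mode, seed = as.integer(seed)),
            class = "locoh_split_scheme")
}

#' Split a trajectory into training/testing sets
#'
#' Within each split, training and testing fixes partition the trajectory
#' (disjoint, both nonempty). Random mode draws an independent seeded test
#' subset per split; temporal-blocks mode holds out the i-th of `n_splits`
#' contiguous time blocks, which tile the track.
#'
#' @param traj A `locoh_traj` with at least 8 fixes.
#' @param scheme A [split_scheme()].
#' @return A `locoh_splits` list; element i has `train` (a `locoh_traj`),
#'   `test` (data.frame of held-out fixes) and the index vectors
#'   `train_idx`, `test_idx`.
#' @export
split_train_test <- function(traj, scheme) {
  stopifnot(inherits(traj, "locoh_traj"), inherits(scheme, "locoh_split_scheme"))
  n <- n_fixes(traj)
  if (n < 8) stop("need at least 8 fixes to split")
  test_sets <- if (scheme$mode == "random") {
    m <- floor(scheme$test_fraction * n)
    if (m < 1) stop("test_fraction yields an empty test set")
    if (n - m < 4) stop("test_fraction leaves fewer than 4 training fixes")
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(scheme$seed)
    lapply(seq_len(scheme$n_splits), function(i) sort(sample.int(n, m)))
  } else {
    if (n < scheme$n_splits) stop("more splits than fixes")
    bounds <- floor(seq(0, n, length.out = scheme$n_splits + 1))
    sets <- lapply(seq_len(scheme$n_splits),
                   function(i) seq.int(bounds[i] + 1L, bounds[i + 1L]))
    if (any(n - lengths(sets) < 4))
      stop("temporal blocks leave fewer than 4 training fixes")
    sets
  }
  out <- lapply(seq_along(test_sets), function(i) {
    te <- test_sets[[i]]
    tr <- setdiff(seq_len(n), te)
    list(train = traj_subset(traj, tr),
         test = traj$fixes[te, , drop = FALSE],
         train_idx = tr, test_idx = te)
  })
  structure(out, class = "locoh_splits", scheme = scheme)
}

#' Log density of the hull-coverage model at query points
#'
#' Returns `log(g / A)` where `g` is the number of hulls covering the point
#' (boundary-inclusive) and `A` the hullset's summed area; points covered
#' by no hull fall back to `log(1 / A^2)`. Areas are in m^2, and the
#' hullset must have `A > 1` m^2: below that the fallback would no longer
#' rank uncovered points worst, so sub-metre-square hullsets are rejected
#' rather than silently misordered.
#'
#' @param hullset A `locoh_hullset` (training hulls).
#' @param p A length-2 numeric `c(x, y)` or a 2-column matrix of points.
#' @return Numeric vector of natural-log densities, all finite.
#' @export
log_density <- function(hullset, p) {
  stopifnot(inherits(hullset, "locoh_hullset"))
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 2)
  A <- hullset$total_area
  if (A <= 0) stop("degenerate hullset: total hull area is zero")
  if (A <= 1)
    stop("total hull area <= 1 m^2; density fallback 1/A^2 would invert its ",
         "ordering -- are coordinates really in metres?")
  g <- cpp_count_containing(hullset$vx, hullset$vy, hullset$offsets,
                            hullset$bbox, p[, 1], p[, 2])
  ifelse(g >= 1, log(g / A), log(1 / A^2))
}

# internal scoring kernel for one (k, s) cell over prepared splits.
.score_cell <- function(splits, k, s, vmax) {
  svmax <- s * vmax
  total <- 0
  n_fallback <- 0L
  n_test <- 0L
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    fx <- sp$train$fixes
    if (k > nrow(fx))
      stop("k = ", k, " exceeds the ", nrow(fx), " training fixes of split ", i)
    memb <- knn_all(fx$x, fx$y, fx$t, svmax, k)
    h <- cpp_build_hulls(fx$x, fx$y, memb)
    A <- sum(h$areas)
    if (A <= 0)
      stop("degenerate training hullset (zero total area) in split ", i)
    if (A <= 1)
      stop("total hull area <= 1 m^2 in split ", i,
           "; are coordinates in metres?")
    g <- cpp_count_containing(h$vx, h$vy, h$offsets, h$bbox,
                              sp$test$x, sp$test$y)
    total <- total + sum(ifelse(g >= 1, log(g / A), log(1 / A^2)))
    n_fallback <- n_fallback + sum(g == 0L)
    n_test <- n_test + length(g)
  }
  list(score = total, frac_fallback = n_fallback / n_test)
}

#' Cross-validation score of one (k, s) parameter pair
#'
#' Builds a training hullset per split and sums [log_density()] over all
#' held-out points of all splits. The maximum speed `vmax` is computed once
#' on the full trajectory and reused for every training subset, so the TSD
#' geometry is identical across splits.
#'
#' @param traj A `locoh_traj`.
#' @param k,s Parameter pair to score.
#' @param scheme A [split_scheme()], or a precomputed `locoh_splits`.
#' @param vmax Maximum speed override in m/s; default [compute_vmax()] on
#'   the full trajectory.
#' @return The total log probability `P_{k,s}` (a single finite number).
#'   A warning is issued when more than half of all test points fall
#'   outside every hull (the score is then dominated by the fallback).
#' @export
cv_score <- function(traj, k, s, scheme, vmax = NULL) {
  stopifnot(inherits(traj, "locoh_traj"))
  splits <- if (inherits(scheme, "locoh_splits")) scheme
            else split_train_test(traj, scheme)
  if (is.null(vmax)) vmax <- compute_vmax(traj)
  res <- .score_cell(splits, as.integer(k), as.numeric(s), vmax)
  if (res$frac_fallback > 0.5)
    warning(sprintf(
      "%.0f%% of test points fell outside every training hull at k=%d, s=%g",
      100 * res$frac_fallback, k, s))
  res$score
}

#' Grid-search configuration for the coarse-to-fine (k, s) search
#'
#' Defaults follow the published efficient search: s from 0 to 0.05 in
#' coarse steps of 0.01, k from 4 to 800 in coarse steps of 20; a window of
#' 40 k values around the coarse peak rescanned in steps of 5; finally 10 k
#' values in steps of 1 with s refined in steps of 0.001 within one coarse
#' step of the stage-2 best. A finer `s_step_fine` (e.g. 1e-4) can be set
#' for high-resolution surfaces.
#'
#' @param s_min,s_max,s_step_coarse,s_step_fine s-grid bounds and steps.
#' @param k_min,k_max_grid,k_step_coarse,k_step_mid,k_step_fine k-grid
#'   bounds and per-stage steps.
#' @param refine_window_mid,refine_window_fine Half-widths (in k) of the
#'   stage-2 and stage-3 windows around the running best.
#' @return A `locoh_search_config`.
#' @export
search_config <- function(s_min = 0, s_max = 0.05, s_step_coarse = 0.01,
                          s_step_fine = 0.001,
                          k_min = 4L, k_max_grid = 800L, k_step_coarse = 20L,
                          k_step_mid = 5L, k_step_fine = 1L,
                          refine_window_mid = 20L, refine_window_fine = 5L) {
  cfg <- list(s_min = s_min, s_max = s_max, s_step_coarse = s_step_coarse,
              s_step_fine = s_step_fine, k_min = as.integer(k_min),
              k_max_grid = as.integer(k_max_grid),
              k_step_coarse = as.integer(k_step_coarse),
              k_step_mid = as.integer(k_step_mid),
              k_step_fine = as.integer(k_step_fine),
              refine_window_mid = as.integer(refine_window_mid),
              refine_window_fine = as.integer(refine_window_fine))
  if (cfg$s_min < 0 || cfg$s_max < cfg$s_min) stop("invalid s range")
  if (cfg$s_step_coarse <= 0 || cfg$s_step_fine <= 0) stop("invalid s steps")
  if (cfg$k_min < 3 || cfg$k_max_grid < cfg$k_min) stop("invalid k range")
  if (any(c(cfg$k_step_coarse, cfg$k_step_mid, cfg$k_step_fine) < 1))
    stop("invalid k steps")
  structure(cfg, class = "locoh_search_config")
}

# tie rule: highest score, then smaller k, then smaller s
.best_cell <- function(tab) {
  tab[order(-tab$score, tab$k, tab$s), , drop = FALSE][1, ]
}

.new_surface <- function(tab, meta) {
  tab <- tab[!duplicated(tab[c("k", "s")]), , drop = FALSE]
  tab <- tab[order(tab$k, tab$s), , drop = FALSE]
  rownames(tab) <- NULL
  k_values <- sort(unique(tab$k))
  s_values <- sort(unique(tab$s))
  scores <- matrix(NA_real_, length(k_values), length(s_values),
                   dimnames = list(k_values, s_values))
  scores[cbind(match(tab$k, k_values), match(tab$s, s_values))] <- tab$score
  b <- .best_cell(tab)
  structure(list(k_values = k_values, s_values = s_values, scores = scores,
                 table = tab,
                 best = list(k = b$k, s = b$s, score = b$score),
                 meta = meta),
            class = "locoh_surface")
}

#' @export
print.locoh_surface <- function(x, ...) {
  cat(sprintf("<locoh_surface> %d evaluated (k, s) cells\n", nrow(x$table)))
  cat(sprintf("  k in [%d, %d], s in [%g, %g]\n", min(x$k_values),
              max(x$k_values), min(x$s_values), max(x$s_values)))
  cat(sprintf("  best: k=%d, s=%g, P=%.6f\n", x$best$k, x$best$s,
              x$best$score))
  invisible(x)
}

# evaluate cells (k, s) not already present in cache_tab; returns rbind-ed
# table. Cache keys are exact (k, s) pairs; scores are deterministic, so a
# cache hit equals a recomputation.
.eval_cells <- function(splits, vmax, cells, cache_tab, stage, verbose) {
  key <- function(k, s) paste(k, format(s, digits = 15))
  have <- if (nrow(cache_tab)) key(cache_tab$k, cache_tab$s) else character(0)
  todo <- cells[!key(cells$k, cells$s) %in% have, , drop = FALSE]
  if (nrow(todo)) {
    res <- lapply(seq_len(nrow(todo)), function(i)
      .score_cell(splits, todo$k[i], todo$s[i], vmax))
    todo$score <- vapply(res, `[[`, numeric(1), "score")
    todo$frac_fallback <- vapply(res, `[[`, numeric(1), "frac_fallback")
    todo$stage <- stage
    out <- rbind(cache_tab, todo)
  } else {
    out <- cache_tab
  }
  if (verbose) {
    b <- .best_cell(out)
    message(sprintf("stage %d: %d new cells (%d total); best k=%d s=%g P=%.4f",
                    stage, nrow(todo), nrow(out), b$k, b$s, b$score))
  }
  out
}

.k_grid <- function(config, k_hi) {
  ks <- seq.int(config$k_min, min(config$k_max_grid, k_hi),
                by = config$k_step_coarse)
  ks
}

.s_grid <- function(config) {
  round(seq(config$s_min, config$s_max, by = config$s_step_coarse), 10)
}

#' Coarse grid search over (k, s)
#'
#' Evaluates `P_{k,s}` on the full coarse grid (defaults: k = 4, 24, ...,
#' 784 and s = 0, 0.01, ..., 0.05). The k grid is clipped to the training
#' size. Best cell follows the tie rule: highest score, then smaller k,
#' then smaller s (parsimony -- the finer model must strictly win).
#'
#' @param traj A `locoh_traj`.
#' @param scheme A [split_scheme()].
#' @param vmax Optional maximum-speed override (m/s).
#' @param config A [search_config()].
#' @param verbose Emit per-stage progress messages.
#' @return A `locoh_surface`: evaluated cells (`table`), the rectangular
#'   score matrix (`scores`, NA where unevaluated), and `best`.
#' @export
coarse_grid_search <- function(traj, scheme, vmax = NULL,
                               config = search_config(), verbose = FALSE) {
  stopifnot(inherits(traj, "locoh_traj"),
            inherits(config, "locoh_search_config"))
  splits <- split_train_test(traj, scheme)
  if (is.null(vmax)) vmax <- compute_vmax(traj)
  k_hi <- min(vapply(splits, function(sp) nrow(sp$train$fixes), integer(1)))
  cells <- expand.grid(k = .k_grid(config, k_hi), s = .s_grid(config),
                       KEEP.OUT.ATTRS = FALSE)
  empty <- data.frame(k = integer(0), s = numeric(0), score = numeric(0),
                      frac_fallback = numeric(0), stage = integer(0))
  tab <- .eval_cells(splits, vmax, cells, empty, 1L, verbose)
  .new_surface(tab, meta = list(vmax = vmax, scheme = unclass(scheme),
                                config = unclass(config), n = n_fixes(traj),
                                k_hi = k_hi))
}

#' Refine a coarse search surface (stages 2 and 3)
#'
#' Stage 2 rescans k within `refine_window_mid` of the coarse best at step
#' `k_step_mid`, still at coarse s resolution. Stage 3 rescans k within
#' `refine_window_fine` of the stage-2 best at step `k_step_fine`, with s
#' refined at `s_step_fine` within one coarse s step of the stage-2 best.
#' All windows are clipped to the legal grid; previously evaluated cells
#' are reused (scores are deterministic, so reuse equals recomputation).
#'
#' @param traj,scheme,vmax,config,verbose As in [coarse_grid_search()].
#' @param coarse The `locoh_surface` returned by [coarse_grid_search()]
#'   (must come from the same trajectory, scheme and config).
#' @return The merged final `locoh_surface` over all three stages.
#' @export
refine_search <- function(traj, scheme, vmax = NULL, config = search_config(),
                          coarse, verbose = FALSE) {
  stopifnot(inherits(coarse, "locoh_surface"))
  splits <- split_train_test(traj, scheme)
  if (is.null(vmax)) vmax <- compute_vmax(traj)
  k_hi <- coarse$meta$k_hi
  k_cap <- min(config$k_max_grid, k_hi)
  clip_k <- function(ks) unique(pmin(pmax(ks, config$k_min), k_cap))

  # stage 2: k window at coarse s resolution
  b1 <- coarse$best
  ks2 <- clip_k(seq.int(b1$k - config$refine_window_mid,
                        b1$k + config$refine_window_mid,
                        by = config$k_step_mid))
  cells2 <- expand.grid(k = ks2, s = .s_grid(config), KEEP.OUT.ATTRS = FALSE)
  tab <- .eval_cells(splits, vmax, cells2, coarse$table, 2L, verbose)
  b2 <- .best_cell(tab)

  # stage 3: fine k and fine s around the stage-2 best
  ks3 <- clip_k(seq.int(b2$k - config$refine_window_fine,
                        b2$k + config$refine_window_fine,
                        by = config$k_step_fine))
  s3 <- round(b2$s + seq(-config$s_step_coarse, config$s_step_coarse,
                         by = config$s_step_fine), 10)
  s3 <- s3[s3 >= config$s_min - 1e-12 & s3 <= config$s_max + 1e-12]
  cells3 <- expand.grid(k = ks3, s = s3, KEEP.OUT.ATTRS = FALSE)
  tab <- .eval_cells(splits, vmax, cells3, tab, 3L, verbose)

  .new_surface(tab, meta = c(coarse$meta, list(refined = TRUE)))
}

#' Select (k, s) by the full three-stage search
#'
#' Convenience wrapper running [coarse_grid_search()] then [refine_search()].
#'
#' @inheritParams coarse_grid_search
#' @return The final `locoh_surface`; `$best` holds the selected `k`, `s`
#'   and score.
#' @examples
#' \donttest{
#' tr <- simulate_track(sim_config(seed = 7, n_points = 250))
#' sc <- split_scheme(n_splits = 2, seed = 1)
#' surf <- select_parameters(tr, sc, config = search_config(k_max_grid = 60))
#' surf$best
#' }
#' @export
select_parameters <- function(traj, scheme, vmax = NULL,
                              config = search_config(), verbose = FALSE) {
  coarse <- coarse_grid_search(traj, scheme, vmax, config, verbose)
  refine_search(traj, scheme, vmax, config, coarse, verbose)
}
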