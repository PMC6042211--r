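# Fixtures are generated in code at test time; nothing is stored on disk.

# uniformly scattered fixes over a box several hundred metres across, in
# generic position, hourly sampling
random_track <- function(n, seed, extent = 500) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  trajectory(x = runif(n, 0, extent), y = runif(n, 0, extent),
             t = seq_len(n) * 3600, individual_id = "rand")
}

# two patches `sep_factor` * sd apart, revisited once each (A B A B)
two_patch_track <- function(n = 120, seed = 42, sd = 100, sep_factor = 20) {
  patches <- data.frame(x = c(0, sep_factor * sd), y = c(0, 0),
                        radius = c(2 * sd, 2 * sd))
  cfg <- sim_config(seed = seed, n_points = NULL, dt = 3600,
                    patches = patches,
                    schedule = data.frame(patch = c(1, 2, 1, 2),
                                          dwell = rep(n %/% 4, 4)),
                    within_patch_sd = sd, travel_speed = 1)
  simulate_track(cfg)
}

# single compact patch (no travel legs): hull coverage fills its bbox
one_patch_track <- function(n = 200, seed = 5, sd = 150) {
  cfg <- sim_config(seed = seed, n_points = n, dt = 3600,
                    patches = data.frame(x = 0, y = 0, radius = 2 * sd),
                    schedule = data.frame(patch = 1, dwell = n),
                    within_patch_sd = sd, travel_speed = 1)
  simulate_track(cfg)
}

# hand-built hullset from a list of open CCW polygon matrices
make_hullset <- function(polys, k = NA_integer_, s = NA_real_) {
  lens <- vapply(polys, nrow, integer(1))
  vx <- unlist(lapply(polys, function(p) p[, 1]))
  vy <- unlist(lapply(polys, function(p) p[, 2]))
  areas <- vapply(polys, o_shoelace, numeric(1))
  bbox <- t(vapply(polys, function(p)
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2])), numeric(4)))
  structure(list(k = k, s = s, vmax = NA_real_, svmax = NA_real_,
                 n = length(polys), points = NULL, members = NULL,
                 vx = vx, vy = vy, offsets = c(0L, cumsum(lens)),
                 bbox = bbox, areas = areas, degenerate = areas <= 0,
                 total_area = sum(areas), enclosed = NULL,
                 nsv = NULL, mnlv = NULL, ivg = NULL),
            class = "locoh_hullset")
}

# write a trajectory-style CSV from raw columns (for loader tests)
write_track_csv <- function(path, id, timestamp, x, y,
                            colnames = c("individual_id", "timestamp", "x", "y"),
                            sep = ",") {
  df <- data.frame(id, timestamp, x, y)
  names(df) <- colnames
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
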