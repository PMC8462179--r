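# Haulout automaton, colony assignment, trip segmentation/filtering,
# track regularization and trip metrics.

t0 <- as.POSIXct("2012-03-10 00:00:00", tz = "UTC")

wd <- function(times_min, states, seal = "s1") {
  data.frame(seal = seal, time = t0 + times_min * 60, dry = states)
}

test_that("haulout automaton applies the 10-min / 40-s thresholds", {
  ## 15-min dry bout then long wet -> one 15-min event
  ev <- detect_haulouts(wd(c(0, 15, 300), c(1, 0, 0)))
  expect_equal(nrow(ev), 1L)
  expect_equal(as.numeric(ev$end - ev$start, units = "mins"), 15)
  ## 5-min dry bout only -> no event
  expect_equal(nrow(detect_haulouts(wd(c(0, 5, 300), c(1, 0, 0)))), 0L)
  ## exactly 10 min is not "more than 10 min"
  expect_equal(nrow(detect_haulouts(wd(c(0, 10, 300), c(1, 0, 0)))), 0L)
  ## 20-min dry, 30-s wet blip, 20-min dry -> one merged event
  series <- data.frame(seal = "s1",
                       time = t0 + c(0, 1200, 1230, 2430, 6000),
                       dry = c(1, 0, 1, 0, 0))
  ev3 <- detect_haulouts(series)
  expect_equal(nrow(ev3), 1L)
  expect_equal(as.numeric(ev3$start), as.numeric(t0))
  expect_equal(as.numeric(ev3$end), as.numeric(t0) + 2430)
  ## a 40-s wet run closes the event
  series$time <- t0 + c(0, 1200, 1240, 2440, 6000)
  ev4 <- detect_haulouts(series)
  expect_equal(nrow(ev4), 2L)
  expect_error(detect_haulouts(wd(c(0, 5), c(1, 2))), "binary")
})

test_that("automaton results concatenate across well-separated traces", {
  a <- wd(c(0, 20, 100), c(1, 0, 0))
  b <- wd(c(200, 230, 400), c(1, 0, 0))
  joint <- detect_haulouts(rbind(a, b))
  expect_equal(nrow(joint), 2L)
  expect_equal(joint, rbind(detect_haulouts(a), detect_haulouts(b)))
})

test_that("colony assignment picks the nearest site within the radius", {
  sites <- data.frame(site = c("A", "B", "C"), x = c(0, 10, 100),
                      y = c(0, 0, 0), colony = c("C1", "C1", "C2"))
  fixes <- data.frame(seal = "s1", time = t0 + c(0, 100, 200) * 60,
                      x = c(0, 10.4, 60), y = c(0, 0, 0))
  ev <- data.frame(seal = "s1", start = t0 + c(0, 100, 200) * 60,
                   end = t0 + c(10, 110, 210) * 60)
  got <- assign_colony(ev, fixes, sites, tagging_site = "A", radius_km = 50)
  expect_equal(got$site, c("A", "B", "C"))
  expect_equal(got$extra_colony, c(FALSE, FALSE, TRUE))
  ## brute-force nearest-site scan agrees on random events
  withr::local_seed(4)
  rx <- runif(20, 0, 100)
  fx2 <- data.frame(seal = "s1", time = t0 + (1:20) * 3600, x = rx, y = 0)
  ev2 <- data.frame(seal = "s1", start = t0 + (1:20) * 3600,
                    end = t0 + (1:20) * 3600 + 600)
  got2 <- assign_colony(ev2, fx2, sites, tagging_site = "A")
  brute <- sites$site[apply(abs(outer(rx, sites$x, "-")), 1, which.min)]
  expect_equal(got2$site, brute)
})

test_that("trips are segmented between consecutive events with at-sea fixes", {
  ev <- data.frame(seal = "s1", start = t0 + c(0, 200) * 60,
                   end = t0 + c(20, 220) * 60,
                   site = "A", colony = "C1", extra_colony = FALSE)
  ## no intervening fixes -> no trip
  fx0 <- data.frame(seal = "s1", time = t0 + c(10, 210) * 60, x = 0, y = 0)
  expect_equal(nrow(segment_trips(fx0, ev)), 0L)
  ## fixes exactly at the event boundary instants are excluded
  fx1 <- data.frame(seal = "s1", time = t0 + c(20, 60, 120, 200) * 60,
                    x = c(0, 5, 8, 0), y = 0)
  tr <- segment_trips(fx1, ev)
  expect_equal(nrow(tr), 1L)
  expect_equal(nrow(attr(tr, "tracks")[[1]]), 2L)   # boundary fixes dropped
  expect_equal(tr$duration_h, 3)
})

test_that("simulated trips are recovered from the wet/dry record", {
  w <- tiny_world()
  hits <- total <- 0L
  for (seed in c(41, 42, 43)) {
    sim <- simulate_seals(w$seascape, true_preference(), n_seals = 3,
                          n_trips_per_seal = 5, seed = seed)
    ev <- detect_haulouts(sim$wetdry)
    ev <- assign_colony(ev, sim$fixes, w$seascape$haulouts)
    tr <- segment_trips(sim$fixes, ev)
    hits <- hits + nrow(tr); total <- total + 3L * 5L
  }
  expect_gte(hits / total, 0.95)
})

test_that("track regularization interpolates on the 20-min lattice", {
  ## fixes already on the lattice -> reproduced exactly
  tr <- data.frame(time = t0 + c(0, 20, 40) * 60, x = c(0, 1, 3), y = c(0, 2, 4))
  out <- interpolate_track(tr)
  expect_equal(out$x, tr$x); expect_equal(out$y, tr$y)
  ## two fixes 40 min apart -> one interior point at the segment midpoint
  tr2 <- data.frame(time = t0 + c(0, 40) * 60, x = c(0, 4), y = c(0, 0))
  out2 <- interpolate_track(tr2)
  expect_equal(out2$x, c(0, 2, 4))
  ## every regularized point lies on the input polyline
  withr::local_seed(9)
  tr3 <- data.frame(time = t0 + sort(runif(8, 0, 300)) * 60,
                    x = cumsum(rnorm(8)), y = cumsum(rnorm(8)))
  out3 <- interpolate_track(tr3)
  tt <- as.numeric(tr3$time)
  for (i in seq_len(nrow(out3))) {
    g <- as.numeric(out3$time[i])
    j <- max(which(tt <= g))
    if (j == length(tt)) j <- j - 1L
    f <- (g - tt[j]) / (tt[j + 1] - tt[j])
    expect_equal(out3$x[i], tr3$x[j] + f * (tr3$x[j + 1] - tr3$x[j]),
                 tolerance = 1e-9)
  }
  ## single-fix trips dropped
  expect_null(interpolate_track(tr2[1, , drop = FALSE]))
})

test_that("trip filters enforce duration, season and return-to-colony", {
  mk_trip <- function(dur_h, month, dep_col = "C1", arr_col = "C1") {
    dep <- as.POSIXct(sprintf("2012-%02d-10 00:00:00", month), tz = "UTC")
    data.frame(seal = "s1", trip_id = paste0("T", dur_h, month, dep_col, arr_col),
               dep_end = dep, arr_start = dep + dur_h * 3600,
               duration_h = dur_h, dep_site = "A", arr_site = "A",
               dep_colony = dep_col, arr_colony = arr_col,
               dep_extra = FALSE, arr_extra = FALSE, n_fixes = 3L)
  }
  trips <- rbind(mk_trip(2.99, 3), mk_trip(3.0, 3), mk_trip(8, 10),
                 mk_trip(8, 3, arr_col = "C2"), mk_trip(5, 4))
  attr(trips, "tracks") <- setNames(rep(list(NULL), 5), trips$trip_id)
  win <- season_windows("gray")
  got <- filter_trips(trips, win, min_duration_h = 3)
  ## 2.99 h dropped, 3.0 h kept (strict "<"), October (breeding) dropped
  expect_setequal(got$duration_h, c(3.0, 8, 5))
  ## gray-seal return-only mode additionally drops the C2 arrival
  got2 <- filter_trips(trips, win, return_only = TRUE, colony = "C1")
  expect_setequal(got2$duration_h, c(3.0, 5))
  ## enumeration oracle
  keep <- trips$duration_h >= 3 &
    !(as.integer(format(trips$dep_end, "%m")) %in% win$excluded_months)
  expect_equal(nrow(got), sum(keep))
  ## season and duration filters commute
  f1 <- filter_trips(filter_trips(trips, win, min_duration_h = 0),
                     win, min_duration_h = 3)
  expect_equal(f1$trip_id, got$trip_id)
  ## harbor windows differ
  expect_setequal(season_windows("harbor")$excluded_months, 6:9)
})

test_that("trip maximum extent uses at-sea least-cost distance", {
  ## open-water world: a straight offshore transect has extent equal to
  ## the straight-line distance to its farthest point
  land <- matrix(FALSE, 30, 30); land[, 1] <- TRUE
  sg <- build_sea_graph(land, cellsize = 1)
  sites <- data.frame(site = "A", x = 1.5, y = 15.5, colony = "C1")
  sc <- list(land = land, haulouts = sites,
             bathy = sea_grid(matrix(10, 30, 30), 0, 0, 1))
  class(sc) <- "seascape"
  tr <- data.frame(seal = "s1", trip_id = "T1", dep_end = t0,
                   arr_start = t0 + 5 * 3600, duration_h = 5,
                   dep_site = "A", arr_site = "A", dep_colony = "C1",
                   arr_colony = "C1", dep_extra = FALSE, arr_extra = FALSE,
                   n_fixes = 3L)
  attr(tr, "tracks") <- list(T1 = data.frame(
    time = t0 + c(1, 2, 3) * 3600, x = c(5.5, 10.5, 20.5), y = 15.5))
  got <- trip_metrics(tr, sc, sg)
  expect_equal(got$max_extent_km, 19, tolerance = 0.01)
  straight <- trip_metrics(tr, sc, sg, straight_line = TRUE)
  expect_equal(straight$max_extent_km, 19, tolerance = 0.01)
  ## never-leaving track -> extent ~ 0
  attr(tr, "tracks") <- list(T1 = data.frame(
    time = t0 + c(1, 2) * 3600, x = c(1.5, 1.5), y = 15.5))
  expect_lt(trip_metrics(tr, sc, sg)$max_extent_km, 1e-9)
})

test_that("extent around a peninsula matches brute-force Dijkstra", {
  land <- matrix(FALSE, 20, 20)
  land[10, 1:14] <- TRUE                       # west-east peninsula
  sg <- build_sea_graph(land, cellsize = 1)
  sites <- data.frame(site = "A", x = 2.5, y = 5.5, colony = "C1")
  sc <- list(land = land, haulouts = sites,
             bathy = sea_grid(matrix(10, 20, 20), 0, 0, 1))
  class(sc) <- "seascape"
  target <- c(2.5, 15.5)                        # other side of the peninsula
  tr <- data.frame(seal = "s1", trip_id = "T1", dep_end = t0,
                   arr_start = t0 + 4 * 3600, duration_h = 4,
                   dep_site = "A", arr_site = "A", dep_colony = "C1",
                   arr_colony = "C1", dep_extra = FALSE, arr_extra = FALSE,
                   n_fixes = 2L)
  attr(tr, "tracks") <- list(T1 = data.frame(
    time = t0 + c(1, 2) * 3600, x = c(2.5, target[1]), y = c(5.5, target[2])))
  got <- trip_metrics(tr, sc, sg)
  oracle <- dijkstra_oracle(land, 1, c(6, 3))   # row 6, col 3 = (2.5, 5.5)
  expect_equal(got$max_extent_km, oracle[16, 3], tolerance = 1e-9)
  expect_gt(got$max_extent_km, euclid(2.5, 5.5, target[1], target[2]))
})
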