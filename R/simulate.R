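## Synthetic central-place forager simulator.
##
## Each seal alternates haulout bouts (dry) with return trips (wet). A
## trip's foraging-dive locations are drawn from the ground-truth selection
## surface (multinomial over reachable sea cells) and the seal's walk is
## routed through them by least-cost paths over the sea graph, so at-sea
## steps never cross land and the use-availability contrast the selection
## model estimates is induced exactly. Foraging dives are square-profiled
## (U) with moderate descent speeds; transit dives are V-shaped and placed
## along the route. GPS fixes fall on a 20-min lattice with Bernoulli
## dropout; the wet/dry series is emitted as state changepoints.

#' Simulate GPS-tagged seals over a synthetic seascape
#'
#' @param seascape a [make_seascape()] object.
#' @param pref a [true_preference()]; `pref$phi` sets the foraging share
#'   of dives.
#' @param n_seals number of seals (>= 1).
#' @param n_trips_per_seal return trips per seal.
#' @param seed integer seed.
#' @param dives_per_trip mean dives per trip (Poisson, shifted by 1).
#' @param fix_interval_min nominal fix interval (minutes).
#' @param dropout Bernoulli fix-dropout probability (first/last fix of each
#'   bout always kept, as tags transmit reliably at haulout/surfacing).
#' @param wet_blip_prob probability a haulout bout contains a 30-s wet
#'   splash (must not split the detected event).
#' @param start_time POSIXct start of the deployment (default early March,
#'   outside both species' breeding/molt windows).
#' @return list of class `sim_output`: `fixes`, `dives`, `wetdry`,
#'   `true_surface`, `haulout_truth` (simulated bout table), `seascape`
#'   parameters echo.
#' @export
simulate_seals <- function(seascape, pref, n_seals = 4, n_trips_per_seal = 5,
                           seed = 1L, dives_per_trip = 18,
                           fix_interval_min = 20, dropout = 0.2,
                           wet_blip_prob = 0.2,
                           start_time = as.POSIXct("2012-03-05 00:00:00",
                                                   tz = "UTC")) {
  stopifnot(inherits(seascape, "seascape"), inherits(pref, "true_preference"))
  if (n_seals < 1L) stop("n_seals must be >= 1")
  sites <- seascape$haulouts
  if (nrow(sites) < 1L) stop("seascape has no haulout sites")
  sg <- build_sea_graph(seascape)
  ## haulout reachability check
  hv <- snap_to_sea(sg, sites$x, sites$y)
  if (nrow(sites) > 1L) {
    dh <- igraph::distances(sg$graph, v = hv, to = hv)
    bad <- which(!is.finite(dh), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    if (nrow(bad))
      stop(sprintf("haulout sites not connected by sea: %s",
                   paste(apply(bad, 1, function(r)
                     paste(sites$site[r[1]], sites$site[r[2]], sep = "-")),
                     collapse = ", ")))
  }
  surf <- true_selection_surface(seascape, pref, sg)
  cs <- seascape$bathy$cellsize
  ny <- seascape$bathy$ny
  ## sampling pool: sea cells with positive weight
  wv <- surf$values
  pool <- which(!is.na(wv) & wv > 0)        # linear cell indices
  pw <- wv[pool]
  step_s <- fix_interval_min * 60

  cell_xy <- function(lin) {
    row <- (lin - 1L) %% ny + 1L
    col <- (lin - 1L) %/% ny + 1L
    cbind(x = (col - 0.5) * cs, y = (row - 0.5) * cs)
  }
  bathy_at <- function(lin) seascape$bathy$values[lin]

  with_seed(seed, {
    fixes <- list(); dives <- list(); wet <- list(); bouts <- list()
    for (s in seq_len(n_seals)) {
      id <- sprintf("seal%02d", s)
      site <- sites[(s - 1L) %% nrow(sites) + 1L, ]
      hvid <- hv[(s - 1L) %% nrow(sites) + 1L]
      hcell <- sg$sea_idx[hvid]
      t <- start_time + runif(1, 0, 6) * 3600
      sfix <- list(); sdive <- list(); swet <- list(); sbout <- list()
      for (tr in seq_len(n_trips_per_seal)) {
        ## ---- haulout bout (dry) ----
        dur <- runif(1, 30, 180) * 60
        swet[[length(swet) + 1L]] <- data.frame(time = t, dry = 1L)
        if (runif(1) < wet_blip_prob && dur > 1200) {
          tb <- t + runif(1, 300, dur - 600)
          swet[[length(swet) + 1L]] <- data.frame(time = tb, dry = 0L)
          swet[[length(swet) + 1L]] <- data.frame(time = tb + 30, dry = 1L)
        }
        sbout[[length(sbout) + 1L]] <-
          data.frame(seal = id, start = t, end = t + dur, site = site$site)
        ft <- seq(from = t, to = t + dur, by = step_s)
        keep <- runif(length(ft)) > dropout
        keep[c(1L, length(ft))] <- TRUE
        sfix[[length(sfix) + 1L]] <- data.frame(
          seal = id, time = ft[keep], x = site$x, y = site$y)
        t <- t + dur
        ## ---- trip (wet) ----
        trip_t0 <- t
        swet[[length(swet) + 1L]] <- data.frame(time = t, dry = 0L)
        n_dives <- 1L + rpois(1, max(0, dives_per_trip - 1))
        forage <- runif(n_dives) < pref$phi
        n_f <- sum(forage)
        fcells <- if (n_f > 0) pool[sample.int(length(pool), n_f, replace = TRUE,
                                               prob = pw)] else integer(0)
        waypts <- unique(fcells)
        if (length(waypts) == 0L)
          waypts <- pool[sample.int(length(pool), 1L, prob = pw)]
        ## greedy nearest-neighbour ordering from the haulout
        ordered <- integer(0); cur <- cell_xy(hcell)
        rem <- waypts
        while (length(rem)) {
          xy <- cell_xy(rem)
          k <- which.min((xy[, 1] - cur[1])^2 + (xy[, 2] - cur[2])^2)
          ordered <- c(ordered, rem[k]); cur <- xy[k, , drop = FALSE]
          rem <- rem[-k]
        }
        ## route: haulout -> waypoints -> haulout, least-cost over sea
        nodes <- c(hcell, ordered, hcell)
        path <- integer(0)
        for (i in seq_len(length(nodes) - 1L)) {
          vp <- igraph::shortest_paths(
            sg$graph, from = sg$vmap[nodes[i]], to = sg$vmap[nodes[i + 1L]],
            output = "vpath")$vpath[[1]]
          seg <- sg$sea_idx[as.integer(vp)]
          if (length(seg) == 0L)
            stop("no at-sea route between trip waypoints")
          if (length(path)) seg <- seg[-1L]
          path <- c(path, seg)
        }
        ## steps: one 20-min step per path cell; dwell steps host foraging
        step_cells <- integer(0); step_kind <- integer(0)  # 0 travel, 1 dwell
        fc_tab <- table(fcells)
        for (cell in path) {
          step_cells <- c(step_cells, cell); step_kind <- c(step_kind, 0L)
          key <- as.character(cell)
          if (cell %in% ordered && !is.na(fc_tab[key]) && fc_tab[key] > 0) {
            k <- as.integer(fc_tab[key])
            step_cells <- c(step_cells, rep(cell, k))
            step_kind <- c(step_kind, rep(1L, k))
            fc_tab[key] <- 0L
          }
        }
        n_steps <- length(step_cells)
        step_times <- trip_t0 + (seq_len(n_steps) - 0.5) * step_s
        xy <- cell_xy(step_cells)
        jit <- matrix(runif(2 * n_steps, -0.3, 0.3) * cs, ncol = 2)
        sx <- xy[, 1] + jit[, 1]; sy <- xy[, 2] + jit[, 2]
        keep <- runif(n_steps) > dropout
        keep[c(1L, n_steps)] <- TRUE
        sfix[[length(sfix) + 1L]] <- data.frame(
          seal = id, time = step_times[keep], x = sx[keep], y = sy[keep])
        ## foraging dives: one per dwell step
        dwell <- which(step_kind == 1L)
        for (i in dwell) {
          D <- bathy_at(step_cells[i]) * runif(1, 0.80, 0.98)
          prof <- u_profile(D)
          st <- step_times[i] + runif(1, 0, max(1, step_s - prof$T - 10))
          sdive[[length(sdive) + 1L]] <- dive_row(id, st, prof, sx[i], sy[i], TRUE)
        }
        ## transit dives: packed into random travel steps
        n_t <- n_dives - n_f
        travel <- which(step_kind == 0L)
        if (n_t > 0L && length(travel)) {
          at <- sample(travel, n_t, replace = TRUE)
          for (stp in unique(at)) {
            k <- sum(at == stp)
            slot <- step_s / k
            for (q in seq_len(k)) {
              D <- bathy_at(step_cells[stp]) * runif(1, 0.2, 0.5)
              Tmax <- slot * 0.8 - 10
              prof <- v_profile(D, Tmax)
              st <- step_times[stp] + (q - 1) * slot +
                runif(1, 0, max(1, slot - prof$T - 5))
              sdive[[length(sdive) + 1L]] <-
                dive_row(id, st, prof, sx[stp], sy[stp], FALSE)
            }
          }
        }
        t <- trip_t0 + n_steps * step_s + step_s
      }
      ## terminal dry bout
      dur <- runif(1, 30, 120) * 60
      swet[[length(swet) + 1L]] <- data.frame(time = t, dry = 1L)
      sbout[[length(sbout) + 1L]] <-
        data.frame(seal = id, start = t, end = t + dur, site = site$site)
      ft <- seq(from = t, to = t + dur, by = step_s)
      sfix[[length(sfix) + 1L]] <- data.frame(seal = id, time = ft,
                                              x = site$x, y = site$y)
      swet[[length(swet) + 1L]] <- data.frame(time = t + dur, dry = 1L)
      wd <- do.call(rbind, swet); wd$seal <- id
      fixes[[s]] <- do.call(rbind, sfix)
      dives[[s]] <- do.call(rbind, sdive)
      wet[[s]] <- wd[order(wd$time), c("seal", "time", "dry")]
      bouts[[s]] <- do.call(rbind, sbout)
    }
    fixes <- do.call(rbind, fixes); fixes <- fixes[order(fixes$seal, fixes$time), ]
    dives <- do.call(rbind, dives); dives <- dives[order(dives$seal, dives$start), ]
    rownames(fixes) <- rownames(dives) <- NULL
    structure(list(fixes = fixes, dives = dives,
                   wetdry = do.call(rbind, wet),
                   haulout_truth = do.call(rbind, bouts),
                   true_surface = surf, pref = pref,
                   coord_mode = "planar_km"),
              class = "sim_output")
  })
}

## square (U) dive profile: descent/ascent at v m/s, flat bottom phase;
## nine interior points, max depth attained exactly
u_profile <- function(D) {
  v <- runif(1, 0.8, 1.4)
  bottom <- runif(1, 120, 300)
  Tt <- 2 * D / v + bottom
  t_in <- c(D / v, D / v + bottom * (1:7) / 8, Tt - D / v)
  d_in <- D * runif(9, 0.92, 1)
  d_in[5] <- D
  list(T = Tt, D = D, t = t_in, d = d_in)
}

## V dive profile: triangular, apex at mid-dive
v_profile <- function(D, Tmax = 280) {
  Tt <- min(runif(1, 60, 280), Tmax)
  t_in <- (1:9) / 10 * Tt
  tri <- D * (1 - abs((1:9) - 5) / 5)
  d_in <- tri * runif(9, 0.9, 1)
  d_in[5] <- D
  list(T = Tt, D = D, t = t_in, d = d_in)
}

dive_row <- function(id, start, prof, x, y, forage) {
  out <- data.frame(seal = id, start = start, end = start + prof$T,
                    duration = prof$T, max_depth = prof$D,
                    true_x = x, true_y = y, true_forage = forage)
  for (i in 1:9) { out[[paste0("t", i)]] <- prof$t[i]
                   out[[paste0("d", i)]] <- prof$d[i] }
  out
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %d seals, %d fixes, %d dives (%.1f%% foraging), %d wet/dry rows\n",
              length(unique(x$fixes$seal)), nrow(x$fixes), nrow(x$dives),
              100 * mean(x$dives$true_forage), nrow(x$wetdry)))
  invisible(x)
}

#' Write a simulation to disk as plain-text artifacts
#'
#' Fixes, dives, wet/dry and truth labels as CSV; the true selection
#' surface as an ESRI ASCII grid; with `seascape` also the haulout catalog
#' and coastline vertices as GeoJSON.
#'
#' @param sim a [simulate_seals()] output.
#' @param dir output directory (created if needed).
#' @param seascape optional [make_seascape()] object for the vector layers.
#' @return invisibly, the vector of files written.
#' @export
write_sim <- function(sim, dir, seascape = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, c("fixes.csv", "dives.csv", "wetdry.csv",
                        "truth_labels.csv", "true_surface.asc"))
  write.csv(sim$fixes, f[1], row.names = FALSE)
  write.csv(sim$dives[, setdiff(names(sim$dives), "true_forage")], f[2],
            row.names = FALSE)
  write.csv(sim$wetdry, f[3], row.names = FALSE)
  write.csv(sim$dives[, c("seal", "start", "true_x", "true_y", "true_forage")],
            f[4], row.names = FALSE)
  write_asc(sim$true_surface, f[5])
  if (!is.null(seascape)) {
    g <- file.path(dir, c("haulouts.geojson", "coastline.geojson"))
    write_geojson_points(seascape$haulouts, g[1])
    write_geojson_points(as.data.frame(seascape$coastline), g[2])
    f <- c(f, g)
  }
  invisible(f)
}
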