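## Haulout detection from the wet/dry sensor, trip segmentation and
## filtering, track regularization, and trip metrics.
##
## Haulout automaton: an event opens at the start of any maximal dry run
## strictly exceeding `dry_start_min` minutes; once open it closes at the
## first instant a wet run reaches `wet_end_s` seconds, so brief wet
## splashes shorter than that do not split an event. The event's end is
## timestamped at the start of the closing wet run.

#' Detect haulout events from a wet/dry series
#'
#' The series is a changepoint (or sampled) representation: each row's
#' state holds from its timestamp to the next row's.
#'
#' @param wetdry data.frame with columns `time` (ordered) and `dry`
#'   (binary: 1 dry, 0 wet), optionally `seal`.
#' @param dry_start_min minimum continuous dry run to open an event (min,
#'   strict).
#' @param wet_end_s continuous wet run that closes an event (s).
#' @return data.frame of events: `seal`, `start`, `end`.
#' @export
detect_haulouts <- function(wetdry, dry_start_min = 10, wet_end_s = 40) {
  if (!all(wetdry$dry %in% c(0, 1))) stop("wet/dry series must be binary")
  groups <- if (is.null(wetdry$seal)) list(all = wetdry) else
    split(wetdry, wetdry$seal)
  out <- lapply(names(groups), function(id) {
    w <- groups[[id]]
    w <- w[order(w$time), , drop = FALSE]
    tt <- as.numeric(w$time); st <- as.integer(w$dry)
    ## collapse to runs: run i spans [rt[i], rt[i+1])
    chg <- c(TRUE, st[-1] != st[-length(st)])
    rt <- tt[chg]; rs <- st[chg]
    rdur <- c(diff(rt), tt[length(tt)] - rt[length(rt)])
    events <- list()
    open_start <- NA_real_
    for (i in seq_along(rs)) {
      if (is.na(open_start)) {
        if (rs[i] == 1L && rdur[i] > dry_start_min * 60)
          open_start <- rt[i]
      } else {
        if (rs[i] == 0L && rdur[i] >= wet_end_s) {
          events[[length(events) + 1L]] <- c(open_start, rt[i])
          open_start <- NA_real_
          ## the wet run may be followed by a new qualifying dry run,
          ## handled by the next iterations
        }
      }
    }
    if (!is.na(open_start))
      events[[length(events) + 1L]] <- c(open_start, rt[length(rt)] +
                                           rdur[length(rdur)])
    if (!length(events))
      return(data.frame(seal = character(0),
                        start = as.POSIXct(character(0), tz = "UTC"),
                        end = as.POSIXct(character(0), tz = "UTC")))
    ev <- do.call(rbind, events)
    data.frame(seal = id,
               start = as.POSIXct(ev[, 1], origin = "1970-01-01", tz = "UTC"),
               end = as.POSIXct(ev[, 2], origin = "1970-01-01", tz = "UTC"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assign haulout events to sites and to the tagging colony
#'
#' Each event is located at the nearest-in-time fix of its seal and
#' assigned to the nearest haulout site; the colony is the group of sites
#' within `radius_km` of the tagging site, and events landing beyond that
#' radius are flagged extra-colony.
#'
#' @param events output of [detect_haulouts()].
#' @param fixes fix table (`seal`, `time`, `x`, `y`).
#' @param sites haulout catalog (`site`, `x`, `y`, `colony`).
#' @param tagging_site site id of the tagging location (default: first).
#' @param radius_km colony grouping radius.
#' @return events with `x`, `y`, `site`, `colony`, `extra_colony` added.
#' @export
assign_colony <- function(events, fixes, sites, tagging_site = sites$site[1],
                          radius_km = 50) {
  if (nrow(sites) == 0L) stop("site catalog is empty")
  tag <- sites[sites$site == tagging_site, ]
  colony_sites <- sites$site[euclid(sites$x, sites$y, tag$x[1], tag$y[1]) <=
                               radius_km]
  loc <- t(vapply(seq_len(nrow(events)), function(i) {
    fx <- fixes[fixes$seal == events$seal[i], ]
    k <- which.min(abs(as.numeric(fx$time) - as.numeric(events$start[i])))
    c(fx$x[k], fx$y[k])
  }, numeric(2)))
  dd <- outer(loc[, 1], sites$x, "-")^2 + outer(loc[, 2], sites$y, "-")^2
  nearest <- max.col(-dd)
  events$x <- loc[, 1]; events$y <- loc[, 2]
  events$site <- sites$site[nearest]
  events$colony <- sites$colony[nearest]
  events$extra_colony <- !(events$site %in% colony_sites) |
    sqrt(dd[cbind(seq_len(nrow(events)), nearest)]) > radius_km
  events
}

#' Segment trips between consecutive haulout events
#'
#' One trip per consecutive event pair of a seal with at least one strictly
#' at-sea fix between them (fixes at the event boundary instants excluded).
#'
#' @param fixes fix table.
#' @param events (colony-assigned) haulout events.
#' @return data.frame of trips: `seal`, `trip_id`, `dep_end` (departure
#'   haulout end), `arr_start` (arrival haulout start), `duration_h`,
#'   departure/arrival sites, plus a list-column `track` of the at-sea fixes.
#' @export
segment_trips <- function(fixes, events) {
  out <- list()
  for (id in unique(events$seal)) {
    ev <- events[events$seal == id, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    fx <- fixes[fixes$seal == id, , drop = FALSE]
    fx <- fx[order(fx$time), , drop = FALSE]
    if (nrow(ev) < 2L) next
    for (i in seq_len(nrow(ev) - 1L)) {
      t0 <- ev$end[i]; t1 <- ev$start[i + 1L]
      sel <- fx$time > t0 & fx$time < t1
      if (!any(sel)) next
      out[[length(out) + 1L]] <- data.frame(
        seal = id, trip_id = sprintf("%s_T%02d", id, length(out) + 1L),
        dep_end = t0, arr_start = t1,
        duration_h = as.numeric(t1 - t0, units = "hours"),
        dep_site = ev$site[i] %||% NA, arr_site = ev$site[i + 1L] %||% NA,
        dep_colony = ev$colony[i] %||% NA, arr_colony = ev$colony[i + 1L] %||% NA,
        dep_extra = ev$extra_colony[i] %||% NA,
        arr_extra = ev$extra_colony[i + 1L] %||% NA,
        n_fixes = sum(sel))
      attr(out[[length(out)]], "track") <- fx[sel, , drop = FALSE]
    }
  }
  if (!length(out))
    return(structure(data.frame(), tracks = list()))
  trips <- do.call(rbind, out)
  rownames(trips) <- NULL
  attr(trips, "tracks") <- lapply(out, attr, "track")
  names(attr(trips, "tracks")) <- trips$trip_id
  trips
}

#' Straight-line track regularization
#'
#' Positions on a regular `step_min` lattice anchored at the trip
#' departure, linearly interpolated between bracketing fixes; no
#' extrapolation past the last fix. Single-fix tracks are dropped with a
#' log entry. Fixes already on the lattice are reproduced exactly.
#'
#' @param track data.frame of fixes (`time`, `x`, `y`).
#' @param t0 lattice anchor (default first fix time).
#' @param step_min lattice step in minutes.
#' @return data.frame `time`, `x`, `y`, or NULL if the track has < 2 fixes.
#' @export
interpolate_track <- function(track, t0 = NULL, step_min = 20) {
  if (nrow(track) < 2L) {
    ss_log("interpolate_track", "single-fix trip dropped")
    return(NULL)
  }
  track <- track[order(track$time), , drop = FALSE]
  tt <- as.numeric(track$time)
  t0 <- as.numeric(t0 %||% track$time[1])
  grid <- seq(t0 + ceiling(max(0, tt[1] - t0) / (step_min * 60)) * step_min * 60,
              tt[length(tt)], by = step_min * 60)
  grid <- grid[grid >= tt[1]]
  if (!length(grid)) return(NULL)
  data.frame(time = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
             x = stats::approx(tt, track$x, xout = grid)$y,
             y = stats::approx(tt, track$y, xout = grid)$y)
}

#' Species season windows (breeding + early molt exclusion)
#'
#' Gray seals: September-December (breeding) and January-February (molt).
#' Harbor seals: June-July (breeding) and August-September (molt).
#'
#' @param species `"gray"` or `"harbor"`.
#' @return list of class `season_windows` with `species` and
#'   `excluded_months` (integer vector).
#' @export
season_windows <- function(species = c("gray", "harbor")) {
  species <- match.arg(species)
  excluded <- if (species == "gray") c(9:12, 1:2) else 6:9
  structure(list(species = species, excluded_months = excluded),
            class = "season_windows")
}

#' Filter trips by season, duration and return-to-colony
#'
#' Drops trips shorter than `min_duration_h` hours (strict), trips whose
#' departure month falls in the species' excluded window, and - in
#' return-only (gray seal) mode - trips not departing AND arriving at the
#' tagging colony.
#'
#' @param trips output of [segment_trips()].
#' @param windows a [season_windows()].
#' @param min_duration_h minimum trip duration in hours (strict `<` drop).
#' @param return_only keep only within-colony return trips.
#' @param colony tagging colony id (required when `return_only`).
#' @return the retained trips (tracks attribute subset accordingly).
#' @export
filter_trips <- function(trips, windows, min_duration_h = 3,
                         return_only = FALSE, colony = NULL) {
  if (!nrow(trips)) return(trips)
  keep <- trips$duration_h >= min_duration_h
  dep_month <- as.integer(format(trips$dep_end, "%m"))
  keep <- keep & !(dep_month %in% windows$excluded_months)
  if (return_only) {
    if (is.null(colony)) colony <- trips$dep_colony[1]
    keep <- keep & !is.na(trips$dep_colony) & !is.na(trips$arr_colony) &
      trips$dep_colony == colony & trips$arr_colony == colony &
      !(trips$dep_extra %||% FALSE) & !(trips$arr_extra %||% FALSE)
  }
  tracks <- attr(trips, "tracks")
  out <- trips[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tracks") <- tracks[trips$trip_id[keep]]
  ss_log("filter_trips", sprintf("%d of %d trips retained", sum(keep), nrow(trips)))
  out
}

#' Trip duration and maximum at-sea extent
#'
#' Duration is arrival-haulout start minus departure-haulout end. Maximum
#' extent is the largest distance from the departure haulout over the
#' regularized track: least-cost at-sea distance by default (consistent
#' with the geodesic distance covariate), straight-line behind a flag.
#'
#' @param trips output of [segment_trips()] / [filter_trips()].
#' @param seascape a [make_seascape()] (for the sea graph and sites).
#' @param seagraph optional pre-built [build_sea_graph()].
#' @param straight_line use straight-line instead of least-cost distance.
#' @param step_min regularization step in minutes.
#' @return `trips` with `max_extent_km` added (tracks regularized).
#' @export
trip_metrics <- function(trips, seascape, seagraph = NULL,
                         straight_line = FALSE, step_min = 20) {
  if (!nrow(trips)) return(trips)
  seagraph <- seagraph %||% build_sea_graph(seascape)
  tracks <- attr(trips, "tracks")
  sites <- seascape$haulouts
  ext <- rep(NA_real_, nrow(trips))
  for (i in seq_len(nrow(trips))) {
    tr <- interpolate_track(tracks[[trips$trip_id[i]]], t0 = trips$dep_end[i],
                            step_min = step_min)
    if (is.null(tr)) next
    dep <- sites[sites$site == trips$dep_site[i], ]
    if (nrow(dep) == 0L) dep <- sites[1, ]
    org <- c(dep$x[1], dep$y[1])
    d <- if (straight_line) euclid(tr$x, tr$y, org[1], org[2]) else
      least_cost_distance(org, cbind(tr$x, tr$y), seagraph)
    d <- d[is.finite(d)]
    ext[i] <- if (length(d)) max(d) else 0
  }
  trips$max_extent_km <- ext
  trips
}
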