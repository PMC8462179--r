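## Dive-profile scoring and foraging classification.
##
## The tags record, for each dive, its duration T, maximum depth D and nine
## intermediate depth points; the full profile is the piecewise-linear curve
## through (0, 0), the nine interior (time, depth) pairs and (T, 0).
##
## The Time Allocation at Depth (TAD) index rescales the area A under the
## depth profile between the fastest possible V-dive (A_min = D^2/v_max,
## straight down and up at the maximum vertical transit speed v_max) and
## the fastest square dive (A_max = D*T - D^2/v_max):
##
##     TAD = (A - A_min) / (A_max - A_min), clamped into [0, 1].
##
## 0 marks surface-skewed (V) dives, 1 marks square (U) dives in which the
## whole dive is spent at maximum depth. Benthic foraging dives are the
## most U-shaped; among them, very low vertical descent speeds indicate
## resting, hence the two-stage classification below.

#' TAD scoring parameters
#'
#' @param v_max maximum vertical transit speed in m/s (> 0). The default of
#'   2 m/s is configurable; [estimate_v_max()] offers a per-deployment
#'   estimate from observed descent speeds.
#' @param clamp clamp the index into \[0, 1\] (pre-clamp violations are
#'   counted in the package log).
#' @return list of class `tad_params`.
#' @export
tad_params <- function(v_max = 2, clamp = TRUE) {
  if (v_max <= 0) stop("v_max must be > 0")
  structure(list(v_max = v_max, clamp = clamp), class = "tad_params")
}

#' Per-deployment maximum vertical speed estimate
#'
#' The 99th percentile of observed first-segment descent speeds.
#'
#' @param dives scored dive table (see [score_dives()]).
#' @return speed in m/s.
#' @export
estimate_v_max <- function(dives) {
  sp <- descent_speed(dives)
  as.numeric(quantile(sp, 0.99, na.rm = TRUE))
}

## trapezoidal area under one piecewise-linear profile, endpoints added
profile_area <- function(t_in, d_in, duration) {
  tt <- c(0, t_in, duration); dd <- c(0, d_in, 0)
  if (any(diff(tt) <= 0)) stop("profile times must be strictly increasing within (0, T)")
  if (any(dd < 0)) stop("profile depths must be nonnegative")
  sum(diff(tt) * (head(dd, -1) + tail(dd, -1)) / 2)
}

#' Time Allocation at Depth index
#'
#' Computes TAD for each dive of a dive table (columns `duration`,
#' `max_depth`, `t1..t9`, `d1..d9`). Dives for which the maximum depth
#' cannot be reached and left at `v_max` within the dive duration
#' (`2 * D / v_max > T`) are unscorable and get `NA`; at exact equality the
#' V-dive limiting value 0 is returned.
#'
#' @param dives dive data.frame.
#' @param params a [tad_params()].
#' @return numeric vector of TAD values in \[0, 1\] (NA if unscorable).
#' @export
tad_index <- function(dives, params = tad_params()) {
  n <- nrow(dives)
  out <- rep(NA_real_, n)
  tmat <- as.matrix(dives[, paste0("t", 1:9)])
  dmat <- as.matrix(dives[, paste0("d", 1:9)])
  n_preclamp <- 0L
  for (i in seq_len(n)) {
    Tt <- dives$duration[i]; D <- dives$max_depth[i]
    if (!is.finite(Tt) || !is.finite(D) || Tt <= 0 || D <= 0) next
    lim <- 2 * D / params$v_max
    if (lim > Tt + 1e-9) next                      # unscorable
    A <- profile_area(tmat[i, ], dmat[i, ], Tt)
    a_min <- D^2 / params$v_max
    a_max <- D * Tt - a_min
    if (a_max - a_min < 1e-12) { out[i] <- 0; next }  # exact V at v_max
    tad <- (A - a_min) / (a_max - a_min)
    if (tad < 0 || tad > 1) n_preclamp <- n_preclamp + 1L
    out[i] <- if (params$clamp) min(1, max(0, tad)) else tad
  }
  if (n_preclamp > 0)
    ss_log("tad_index", sprintf("%d value(s) clamped into [0,1]", n_preclamp))
  out
}

#' Vertical descent speed
#'
#' Depth of the first interior profile point divided by its time offset
#' from the dive start (the surface-to-first-inflection slope).
#'
#' @param dives dive data.frame with `t1`, `d1`.
#' @return speed in m/s.
#' @export
descent_speed <- function(dives) {
  if (any(dives$t1 <= 0)) stop("first profile point at zero time offset")
  dives$d1 / dives$t1
}

#' Foraging-classification rule
#'
#' @param min_depth prefilter depth threshold in m (dives strictly
#'   shallower are excluded).
#' @param min_duration prefilter duration threshold in s (strictly shorter
#'   excluded).
#' @param tad_quantile fraction of highest-TAD dives kept at stage 1.
#' @param speed_exclusion fraction of the stage-1 selection removed as
#'   lowest descent speeds at stage 2.
#' @return list of class `classification_rule`.
#' @export
classification_rule <- function(min_depth = 3, min_duration = 30,
                                tad_quantile = 0.25, speed_exclusion = 0.10) {
  if (tad_quantile <= 0 || tad_quantile >= 1) stop("tad_quantile must be in (0,1)")
  if (speed_exclusion <= 0 || speed_exclusion >= 1) stop("speed_exclusion must be in (0,1)")
  structure(list(min_depth = min_depth, min_duration = min_duration,
                 tad_quantile = tad_quantile, speed_exclusion = speed_exclusion),
            class = "classification_rule")
}

#' Prefilter very shallow / very short dives
#'
#' Excludes dives with maximum depth < 3 m or duration < 30 s (strict
#' inequalities: boundary dives are retained); these are unlikely to be
#' foraging dives.
#'
#' @param dives dive data.frame.
#' @param rule a [classification_rule()].
#' @return the retained rows.
#' @export
prefilter <- function(dives, rule = classification_rule()) {
  keep <- dives$max_depth >= rule$min_depth & dives$duration >= rule$min_duration
  ss_log("prefilter", sprintf("%d of %d dives removed", sum(!keep), nrow(dives)))
  dives[keep, , drop = FALSE]
}

#' Score a dive table (TAD + descent speed)
#'
#' @param dives dive data.frame.
#' @param params a [tad_params()].
#' @return `dives` with columns `tad` and `desc_speed` added; unscorable
#'   dives (NA TAD) are dropped with a log entry.
#' @export
score_dives <- function(dives, params = tad_params()) {
  dives$tad <- tad_index(dives, params)
  dives$desc_speed <- descent_speed(dives)
  bad <- is.na(dives$tad)
  if (any(bad))
    ss_log("score_dives", sprintf("%d unscorable dive(s) dropped", sum(bad)))
  dives[!bad, , drop = FALSE]
}

## two-stage rule for ONE individual's scored dives
classify_one <- function(dives, rule) {
  n <- nrow(dives)
  dives$foraging <- NA
  if (n < 8L) {
    ss_log("classify_foraging",
           sprintf("individual %s: n = %d < 8, unclassifiable",
                   dives$seal[1] %||% "?", n))
    return(dives)
  }
  dives$foraging <- FALSE
  ## stage 1: ceiling(q * n) highest TAD; ties broken by earlier start
  k1 <- ceiling(rule$tad_quantile * n)
  ord1 <- order(-dives$tad, dives$start)
  sel <- ord1[seq_len(k1)]
  ## stage 2: drop floor(f * k1) lowest descent speeds within the selection
  k2 <- floor(rule$speed_exclusion * k1)
  if (k2 > 0L) {
    ord2 <- order(dives$desc_speed[sel], dives$start[sel])
    sel <- sel[-ord2[seq_len(k2)]]
  }
  dives$foraging[sel] <- TRUE
  dives
}

#' Two-stage foraging classification, per individual
#'
#' Stage 1 keeps the `ceiling(0.25 n)` highest-TAD (most U-shaped) dives of
#' each individual; stage 2 removes the `floor(0.10 k)` lowest-descent-speed
#' dives among those (likely resting), flagging about 22.5% of each
#' individual's prefiltered dives as foraging. Ties are broken toward the
#' earlier start time. Individuals with fewer than 8 scored dives are
#' unclassifiable (NA flags, logged).
#'
#' @param dives scored dive data.frame (columns `seal`, `start`, `tad`,
#'   `desc_speed`).
#' @param rule a [classification_rule()].
#' @return `dives` with a logical `foraging` column.
#' @export
classify_foraging <- function(dives, rule = classification_rule()) {
  out <- lapply(split(dives, dives$seal), classify_one, rule = rule)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$seal, out$start), , drop = FALSE]
}

#' Per-individual classification summary
#'
#' @param dives_raw the unfiltered dive table.
#' @param dives_classified output of [classify_foraging()].
#' @param rule the [classification_rule()] used.
#' @return data.frame with one row per individual: `n`, `n_prefiltered`,
#'   `n_foraging`, thresholds used.
#' @export
classification_summary <- function(dives_raw, dives_classified,
                                   rule = classification_rule()) {
  ids <- sort(unique(dives_raw$seal))
  data.frame(
    seal = ids,
    n = as.integer(table(factor(dives_raw$seal, ids))),
    n_prefiltered = as.integer(table(factor(dives_classified$seal, ids))),
    n_foraging = vapply(ids, function(i)
      sum(dives_classified$foraging[dives_classified$seal == i], na.rm = TRUE),
      integer(1)),
    min_depth = rule$min_depth, min_duration = rule$min_duration,
    tad_quantile = rule$tad_quantile, speed_exclusion = rule$speed_exclusion,
    row.names = NULL)
}

#' Interpolate dive locations from GPS fixes
#'
#' Linear interpolation of coordinates at the dive midpoint time between
#' the bracketing fixes of the same individual. Dives whose bracketing gap
#' exceeds `max_gap_h` (or that lie outside the fix record) are dropped
#' with a count logged.
#'
#' @param dives dive data.frame (`seal`, `start`, `end`).
#' @param fixes fix data.frame (`seal`, `time`, `x`, `y`).
#' @param max_gap_h maximum allowed bracketing gap in hours.
#' @return retained dives with `x` and `y` columns added.
#' @export
interpolate_dive_locations <- function(dives, fixes, max_gap_h = 6) {
  out <- lapply(split(dives, dives$seal), function(dv) {
    fx <- fixes[fixes$seal == dv$seal[1], , drop = FALSE]
    if (is.unsorted(as.numeric(fx$time))) stop("unordered fix times")
    mid <- as.numeric(dv$start) + as.numeric(dv$end - dv$start,
                                             units = "secs") / 2
    ft <- as.numeric(fx$time)
    i2 <- findInterval(mid, ft, left.open = FALSE) # last fix <= mid
    ok <- i2 >= 1L & i2 < nrow(fx)
    ## exact knot coincidence at the last fix is still valid
    at_last <- !ok & i2 == nrow(fx) & mid == ft[length(ft)]
    gap_ok <- rep(FALSE, length(mid))
    gap_ok[ok] <- (ft[i2[ok] + 1L] - ft[i2[ok]]) <= max_gap_h * 3600
    keep <- (ok & gap_ok) | at_last
    dv <- dv[keep, , drop = FALSE]
    if (!nrow(dv)) return(dv)
    m <- mid[keep]; i <- i2[keep]
    frac <- ifelse(at_last[keep], 0,
                   (m - ft[i]) / pmax(ft[pmin(i + 1L, nrow(fx))] - ft[i], 1e-9))
    dv$x <- fx$x[i] + frac * (fx$x[pmin(i + 1L, nrow(fx))] - fx$x[i])
    dv$y <- fx$y[i] + frac * (fx$y[pmin(i + 1L, nrow(fx))] - fx$y[i])
    dv
  })
  n_in <- nrow(dives)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (nrow(out) < n_in)
    ss_log("interpolate_dive_locations",
           sprintf("%d dive(s) without valid bracketing fixes dropped",
                   n_in - nrow(out)))
  out[order(out$seal, out$start), , drop = FALSE]
}
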