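## Synthetic seascape generator: bathymetry, sediment, tidal current, land
## mask, shelf, coastline and haulout sites on a shared planar-km grid.
## The land is a western coastal band whose outline wiggles with the
## coastline-complexity parameter; depth increases monotonically offshore
## with spatially correlated noise, emulating the shelf seas the study
## species forage over.

#' Parameters of a synthetic seascape
#'
#' @param extent_km grid extent, length 1 or 2 (x, y), in km.
#' @param cell_km cell size in km (> 0).
#' @param coast_complexity nonnegative scalar; 0 gives a straight coast.
#' @param max_depth maximum depth in m (positive down).
#' @param n_sediment number of sediment classes (1-6).
#' @param tidal_smoothness correlation length of the tidal field, in cells.
#' @param n_haulouts number of haulout sites (coastal sea cells).
#' @param shelf_cutoff shelf depth cutoff in m; sea cells no deeper than
#'   this form the continental shelf.
#' @return list of class `seascape_params`.
#' @export
seascape_params <- function(extent_km = 100, cell_km = 2,
                            coast_complexity = 1, max_depth = 150,
                            n_sediment = 4, tidal_smoothness = 5,
                            n_haulouts = 2, shelf_cutoff = 120) {
  if (length(extent_km) == 1L) extent_km <- rep(extent_km, 2L)
  if (cell_km <= 0) stop("cell_km must be > 0")
  if (n_sediment < 1L || n_sediment > 6L) stop("n_sediment must be in 1..6")
  nx <- round(extent_km[1] / cell_km); ny <- round(extent_km[2] / cell_km)
  if (nx < 10L || ny < 10L) stop("degenerate grid: need at least 10x10 cells")
  structure(list(extent_km = extent_km, cell_km = cell_km,
                 coast_complexity = coast_complexity, max_depth = max_depth,
                 n_sediment = as.integer(n_sediment),
                 tidal_smoothness = tidal_smoothness,
                 n_haulouts = as.integer(n_haulouts),
                 shelf_cutoff = shelf_cutoff, nx = nx, ny = ny),
            class = "seascape_params")
}

#' Generate a synthetic seascape
#'
#' Deterministic given `(params, seed)`. Produces co-registered rasters of
#' bathymetry (m, positive down, 0 on land), spatially autocorrelated
#' categorical sediment, a nonnegative tidal-current field (m/s), a land
#' mask, the continental-shelf mask (sea cells no deeper than the cutoff),
#' a coastline vertex set (one vertex per land/sea cell edge) and haulout
#' sites placed on sea cells adjacent to land.
#'
#' @param params a [seascape_params()].
#' @param seed integer seed.
#' @return object of class `seascape`.
#' @export
make_seascape <- function(params, seed = 1L) {
  stopifnot(inherits(params, "seascape_params"))
  with_seed(seed, {
    nx <- params$nx; ny <- params$ny; cs <- params$cell_km
    ex <- nx * cs; ey <- ny * cs

    ## coast position x = f(y): base fraction of extent + smooth wiggle
    wig <- as.numeric(smooth_field(matrix(rnorm(ny), ny, 1),
                                   passes = 4L, width = max(3L, ny %/% 8L)))
    if (sd(wig) > 0) wig <- wig / sd(wig)
    coast_x <- ex * pmin(0.45, pmax(0.04,
      0.15 + 0.06 * params$coast_complexity * wig))

    xs <- (seq_len(nx) - 0.5) * cs
    ys <- (seq_len(ny) - 0.5) * cs
    land <- outer(seq_len(ny), seq_len(nx),
                  function(i, j) xs[j] < coast_x[i])

    ## bathymetry: monotone offshore deepening + correlated noise, 0 on land
    off <- outer(seq_len(ny), seq_len(nx),
                 function(i, j) pmax(0, xs[j] - coast_x[i]))
    maxoff <- max(off)
    noise <- random_field(ny, nx, smoothness = max(3L, nx %/% 10L))
    depth <- params$max_depth * (off / maxoff) +
      0.05 * params$max_depth * noise
    depth <- pmax(depth, 2)   # cell centers sit at least half a cell offshore
    ## keep the monotone trend dominant near the coast
    depth[land] <- 0

    ## sediment: quantile bins of a correlated field
    if (params$n_sediment == 1L) {
      sed <- matrix(1L, ny, nx)
    } else {
      f <- random_field(ny, nx, smoothness = max(3L, nx %/% 8L))
      qs <- quantile(f[!land], probs = seq(0, 1, length.out = params$n_sediment + 1L))
      qs[1] <- -Inf; qs[length(qs)] <- Inf
      sed <- matrix(as.integer(cut(f, qs)), ny, nx)
    }
    sed[land] <- NA_integer_

    ## tidal current: nonnegative smooth field (m/s)
    tf <- random_field(ny, nx, smoothness = max(3L, as.integer(params$tidal_smoothness)))
    tidal <- pmax(0.7 + 0.35 * tf, 0)
    tidal[land] <- NA_real_

    bathy <- depth; bathy[land] <- NA_real_
    shelf <- !land & depth <= params$shelf_cutoff & is.finite(bathy)

    ## coastline vertices: midpoints of land/sea cell edges
    coast_pts <- coastline_vertices(land, cs)

    sc <- structure(list(
      bathy = sea_grid(bathy, 0, 0, cs),
      sediment = sea_grid(sed + 0, 0, 0, cs),
      tidal = sea_grid(tidal, 0, 0, cs),
      land = land, shelf = shelf, coastline = coast_pts,
      params = params, coord_mode = "planar_km",
      anchor_lonlat = c(-5.0, 48.5)), class = "seascape")

    ## haulout sites: coastal sea cells (adjacent to land), spread in y,
    ## restricted to the largest connected sea component
    sg <- build_sea_graph(sc)
    main_comp <- which.max(tabulate(sg$component))
    coastal <- which(!land & neighbors_land(land), arr.ind = TRUE)
    lin <- coastal[, 1] + (coastal[, 2] - 1L) * ny
    ok <- sg$vmap[lin] > 0L & sg$component[pmax(sg$vmap[lin], 1L)] == main_comp
    coastal <- coastal[ok, , drop = FALSE]
    if (nrow(coastal) < params$n_haulouts)
      stop("not enough coastal sea cells for the requested haulout sites")
    ord <- order(coastal[, 1])
    pick <- coastal[ord[round(seq(1, nrow(coastal),
                                  length.out = params$n_haulouts + 2L))[
                           2:(params$n_haulouts + 1L)]], , drop = FALSE]
    sc$haulouts <- data.frame(
      site = paste0("S", seq_len(nrow(pick))),
      x = (pick[, 2] - 0.5) * cs, y = (pick[, 1] - 0.5) * cs,
      colony = "C1", stringsAsFactors = FALSE)
    sc
  })
}

## logical matrix: sea cell has a land 4-neighbour
neighbors_land <- function(land) {
  ny <- nrow(land); nx <- ncol(land)
  out <- matrix(FALSE, ny, nx)
  out[-1, ] <- out[-1, ] | land[-ny, ]
  out[-ny, ] <- out[-ny, ] | land[-1, ]
  out[, -1] <- out[, -1] | land[, -nx]
  out[, -nx] <- out[, -nx] | land[, -1]
  out
}

coastline_vertices <- function(land, cs) {
  ny <- nrow(land); nx <- ncol(land)
  pts <- list()
  ## vertical edges between horizontally adjacent land/sea pairs
  h <- which(land[, -nx] != land[, -1], arr.ind = TRUE)
  if (nrow(h)) pts[[1]] <- cbind(x = h[, 2] * cs, y = (h[, 1] - 0.5) * cs)
  v <- which(land[-ny, ] != land[-1, ], arr.ind = TRUE)
  if (nrow(v)) pts[[2]] <- cbind(x = (v[, 2] - 0.5) * cs, y = v[, 1] * cs)
  out <- do.call(rbind, pts)
  if (is.null(out) || nrow(out) == 0L) stop("seascape has no coastline")
  out
}

#' @export
print.seascape <- function(x, ...) {
  cat(sprintf("<seascape> %d x %d cells (%g km), %d%% land, %d haulout site(s), %d sediment class(es)\n",
              x$bathy$nx, x$bathy$ny, x$bathy$cellsize,
              round(100 * mean(x$land)), nrow(x$haulouts),
              x$params$n_sediment))
  invisible(x)
}

#' Ground-truth habitat preference for simulation
#'
#' Log-linear selection weights over the seascape covariates. Weights are
#' `exp(b_bathy * depth + b_tidal * tidal + b_shore * dist_shore +
#' b_haulout * dist_haulout + sediment_logodds[class])`; `phi` is the
#' foraging share of simulated dives.
#'
#' @param b_bathy per-m log-odds on depth (negative = prefer shallow).
#' @param b_tidal per-(m/s) log-odds on tidal current speed.
#' @param b_shore per-km log-odds on distance to shore.
#' @param b_haulout per-km log-odds on least-cost distance to the haulout
#'   (negative = central-place attachment).
#' @param sediment_logodds numeric vector of per-class log-odds (recycled
#'   or zero-padded to the seascape's class count; first class is the
#'   natural reference at 0).
#' @param phi foraging-dive mixture weight in (0, 1).
#' @return list of class `true_preference`.
#' @export
true_preference <- function(b_bathy = 0, b_tidal = 0, b_shore = 0,
                            b_haulout = 0, sediment_logodds = 0,
                            phi = 0.5) {
  if (phi <= 0 || phi >= 1) stop("phi must be in (0, 1)")
  structure(list(b_bathy = b_bathy, b_tidal = b_tidal, b_shore = b_shore,
                 b_haulout = b_haulout, sediment_logodds = sediment_logodds,
                 phi = phi), class = "true_preference")
}

## covariate table over all sea cells of a seascape (cached per seagraph)
sea_cell_covariates <- function(seascape, seagraph = NULL) {
  seagraph <- seagraph %||% build_sea_graph(seascape)
  cc <- grid_centers(seascape$bathy)
  sea <- !seascape$land[cbind(cc$row, cc$col)]
  cc <- cc[sea, , drop = FALSE]
  dh_grid <- lc_distance_grid(seascape, seagraph)
  data.frame(
    row = cc$row, col = cc$col, x = cc$x, y = cc$y,
    bathy = seascape$bathy$values[cbind(cc$row, cc$col)],
    tidal = seascape$tidal$values[cbind(cc$row, cc$col)],
    sediment = seascape$sediment$values[cbind(cc$row, cc$col)],
    dist_shore = distance_to_shore(cbind(cc$x, cc$y), seascape$coastline),
    dist_haulout = dh_grid$values[cbind(cc$row, cc$col)])
}

#' Ground-truth relative selection surface
#'
#' Evaluates the preference's log-linear weight on every sea cell and
#' normalizes to sum one over sea cells reachable from a haulout; land
#' cells are NA. Adding a constant to all log-weights leaves the surface
#' unchanged.
#'
#' @param seascape a [make_seascape()] object.
#' @param pref a [true_preference()].
#' @param seagraph optional pre-built [build_sea_graph()].
#' @return a [sea_grid()] of selection weights summing to 1 over sea.
#' @export
true_selection_surface <- function(seascape, pref, seagraph = NULL) {
  seagraph <- seagraph %||% build_sea_graph(seascape)
  cov <- sea_cell_covariates(seascape, seagraph)
  sl <- pref$sediment_logodds
  nsed <- max(cov$sediment, na.rm = TRUE)
  sl <- rep_len(c(sl, rep(0, nsed)), nsed)
  eta <- pref$b_bathy * cov$bathy + pref$b_tidal * cov$tidal +
    pref$b_shore * cov$dist_shore + sl[cov$sediment]
  reach <- is.finite(cov$dist_haulout)
  eta <- eta + ifelse(reach, pref$b_haulout * cov$dist_haulout, 0)
  eta <- eta - max(eta[reach])          # overflow guard; invariant to offset
  w <- exp(eta)
  w[!reach] <- 0
  w <- w / sum(w)
  m <- matrix(NA_real_, seascape$bathy$ny, seascape$bathy$nx)
  m[cbind(cov$row, cov$col)] <- w
  sea_grid(m, 0, 0, seascape$bathy$cellsize)
}
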