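## Spatial backbone: sea-cell graph, least-cost at-sea distances, distance
## to shore, covariate extraction, MCP, availability regions, pseudo-absences.
##
## All geometry is planar (km). The sea graph connects centers of sea cells
## with 8-connectivity; cardinal edges weigh one cellsize, diagonal edges
## sqrt(2) cellsizes. Least-cost distances therefore never cross land and
## exceed straight-line distance by at most the usual octile-discretization
## factor (~8%).

#' Build the at-sea adjacency graph of a seascape
#'
#' @param seascape a [make_seascape()] object, or a logical land matrix.
#' @param cellsize cell edge length in km (taken from the seascape if given).
#' @param connectivity 8 (default) or 16 neighbours per cell.
#' @return an object of class `sea_graph`: the igraph, the linear indices of
#'   sea cells, and grid geometry.
#' @export
build_sea_graph <- function(seascape, cellsize = NULL, connectivity = 8) {
  if (inherits(seascape, "seascape")) {
    land <- seascape$land
    cellsize <- seascape$bathy$cellsize
    xmin <- seascape$bathy$xmin; ymin <- seascape$bathy$ymin
  } else {
    land <- seascape
    if (is.null(cellsize)) stop("cellsize required when passing a land matrix")
    xmin <- 0; ymin <- 0
  }
  ny <- nrow(land); nx <- ncol(land)
  sea <- !land
  idx <- matrix(seq_len(ny * nx), ny, nx)  # column-major linear index

  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  if (connectivity == 16) {
    offs <- c(offs, list(c(1L, 2L), c(2L, 1L), c(-1L, 2L), c(-2L, 1L)))
  } else if (connectivity != 8) stop("connectivity must be 8 or 16")

  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (o in offs) {
    di <- o[1]; dj <- o[2]
    ii <- seq_len(ny); jj <- seq_len(nx)
    ii1 <- ii[ii + di >= 1L & ii + di <= ny]
    jj1 <- jj[jj + dj >= 1L & jj + dj <= nx]
    if (!length(ii1) || !length(jj1)) next
    a <- idx[ii1, jj1, drop = FALSE]
    b <- idx[ii1 + di, jj1 + dj, drop = FALSE]
    ok <- sea[a] & sea[b]
    from <- c(from, a[ok]); to <- c(to, b[ok])
    w <- c(w, rep(sqrt(di^2 + dj^2) * cellsize, sum(ok)))
  }
  sea_idx <- idx[sea]
  vmap <- integer(ny * nx)          # linear cell index -> vertex id
  vmap[sea_idx] <- seq_along(sea_idx)
  g <- igraph::make_empty_graph(n = length(sea_idx), directed = FALSE)
  g <- igraph::add_edges(g, rbind(vmap[from], vmap[to]))
  igraph::E(g)$weight <- w
  comp <- igraph::components(g)$membership
  structure(list(graph = g, sea_idx = sea_idx, vmap = vmap,
                 component = comp, ny = ny, nx = nx,
                 cellsize = cellsize, xmin = xmin, ymin = ymin),
            class = "sea_graph")
}

#' @export
print.sea_graph <- function(x, ...) {
  cat(sprintf("<sea_graph> %d sea cells, %d edges, %d component(s)\n",
              length(x$sea_idx), igraph::ecount(x$graph),
              max(x$component)))
  invisible(x)
}

## snap a point to the vertex id of its (or the nearest, within tol cells)
## sea cell; returns NA if none within tolerance
snap_to_sea <- function(sg, x, y, tol_cells = 1) {
  col <- floor((x - sg$xmin) / sg$cellsize) + 1L
  row <- floor((y - sg$ymin) / sg$cellsize) + 1L
  n <- length(x)
  out <- rep(NA_integer_, n)
  for (p in seq_len(n)) {
    if (!is.finite(col[p]) || !is.finite(row[p])) next
    best <- NA_integer_; bestd <- Inf
    for (di in -tol_cells:tol_cells) for (dj in -tol_cells:tol_cells) {
      i <- row[p] + di; j <- col[p] + dj
      if (i < 1L || i > sg$ny || j < 1L || j > sg$nx) next
      lin <- i + (j - 1L) * sg$ny
      v <- sg$vmap[lin]
      if (v == 0L) next
      cx <- sg$xmin + (j - 0.5) * sg$cellsize
      cy <- sg$ymin + (i - 0.5) * sg$cellsize
      d <- (cx - x[p])^2 + (cy - y[p])^2
      if (d < bestd) { bestd <- d; best <- v }
    }
    out[p] <- best
  }
  out
}

#' Least-cost at-sea distance from one origin to many targets
#'
#' Single-source shortest-path distance over the sea graph, in km. Origins
#' and targets snap to the nearest sea cell within a one-cell tolerance
#' (haulout sites sit on coastal sea cells). Unreachable targets return
#' `Inf` and are counted in the package log.
#'
#' @param origin length-2 numeric `c(x, y)`.
#' @param targets two-column matrix or data.frame of target points.
#' @param seagraph a [build_sea_graph()] object.
#' @return numeric vector of distances (km), `Inf` where unreachable.
#' @export
least_cost_distance <- function(origin, targets, seagraph) {
  ov <- snap_to_sea(seagraph, origin[1], origin[2])
  if (is.na(ov)) stop("origin does not snap to a sea cell within tolerance")
  targets <- as.matrix(targets)
  tv <- snap_to_sea(seagraph, targets[, 1], targets[, 2])
  d_all <- as.numeric(igraph::distances(seagraph$graph, v = ov,
                                        to = igraph::V(seagraph$graph)))
  out <- rep(Inf, nrow(targets))
  ok <- !is.na(tv)
  out[ok] <- d_all[tv[ok]]
  n_inf <- sum(!is.finite(out))
  if (n_inf > 0)
    ss_log("least_cost_distance",
           sprintf("%d target(s) unreachable or off-sea", n_inf))
  out
}

## distances from a set of origin vertices to every sea cell; returns a
## vector over sea cells (min over origins)
lc_field <- function(seagraph, origin_vids) {
  d <- igraph::distances(seagraph$graph, v = origin_vids,
                         to = igraph::V(seagraph$graph))
  apply(d, 2, min)
}

## least-cost distance to nearest haulout as a sea_grid (NA on land)
lc_distance_grid <- function(seascape, seagraph, sites = NULL) {
  sites <- sites %||% seascape$haulouts
  vids <- snap_to_sea(seagraph, sites$x, sites$y)
  if (anyNA(vids)) stop("haulout site(s) do not snap to sea cells")
  f <- lc_field(seagraph, vids)
  m <- matrix(NA_real_, seagraph$ny, seagraph$nx)
  m[seagraph$sea_idx] <- f
  sea_grid(m, xmin = seagraph$xmin, ymin = seagraph$ymin,
           cellsize = seagraph$cellsize)
}

#' Straight-line distance to the nearest point of the coastline
#'
#' Nearest-vertex distance against the (densely sampled) coastline point
#' set. In planar mode this is Euclidean; the coastline of a synthetic
#' seascape has one vertex per land/sea cell edge, so the discretization
#' error is below half a cell.
#'
#' @param points two-column matrix or data.frame of points (x, y).
#' @param coastline two-column matrix of coastline vertices.
#' @return numeric vector of distances (km).
#' @export
distance_to_shore <- function(points, coastline) {
  coastline <- as.matrix(coastline)
  if (nrow(coastline) == 0L) stop("empty coastline")
  points <- as.matrix(points)
  n <- nrow(points)
  out <- numeric(n)
  chunk <- 2000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    dx <- outer(points[s:e, 1], coastline[, 1], "-")
    dy <- outer(points[s:e, 2], coastline[, 2], "-")
    out[s:e] <- sqrt(apply(dx^2 + dy^2, 1, min))
  }
  out
}

#' Extract model covariates at point locations
#'
#' Nearest-cell lookups of bathymetry, tidal current and sediment class,
#' plus straight-line distance to shore and least-cost distance to the
#' point's last haulout. Rows with any missing covariate are dropped and
#' counted; losing more than half the rows aborts (extent mismatch).
#'
#' @param points data.frame with columns `x`, `y` and optionally `haulout`
#'   (site id of the last haulout visited; defaults to the nearest site).
#' @param seascape a [make_seascape()] object.
#' @param seagraph optional pre-built [build_sea_graph()].
#' @return data.frame `x, y, bathy, tidal, sediment, dist_shore,
#'   dist_haulout` with attribute `n_dropped`.
#' @export
extract_covariates <- function(points, seascape, seagraph = NULL) {
  seagraph <- seagraph %||% build_sea_graph(seascape)
  sites <- seascape$haulouts
  pts <- as.data.frame(points)
  n0 <- nrow(pts)
  if (is.null(pts$haulout)) {
    dd <- outer(pts$x, sites$x, "-")^2 + outer(pts$y, sites$y, "-")^2
    pts$haulout <- sites$site[max.col(-dd)]
  }
  bathy <- grid_lookup(seascape$bathy, pts$x, pts$y)
  tidal <- grid_lookup(seascape$tidal, pts$x, pts$y)
  sedim <- grid_lookup(seascape$sediment, pts$x, pts$y)
  dsh <- distance_to_shore(cbind(pts$x, pts$y), seascape$coastline)
  dha <- rep(NA_real_, n0)
  for (h in unique(pts$haulout)) {
    s <- sites[sites$site == h, ]
    if (nrow(s) == 0L) next
    sel <- which(pts$haulout == h)
    dha[sel] <- least_cost_distance(c(s$x[1], s$y[1]),
                                    cbind(pts$x[sel], pts$y[sel]), seagraph)
  }
  dha[!is.finite(dha)] <- NA_real_
  out <- data.frame(x = pts$x, y = pts$y, bathy = bathy, tidal = tidal,
                    sediment = factor(paste0("sed", sedim)),
                    dist_shore = dsh, dist_haulout = dha)
  keep <- complete.cases(out)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    ss_log("extract_covariates", sprintf("%d row(s) dropped (missing covariates)", n_drop))
  if (n_drop > 0.5 * n0)
    stop(sprintf("extract_covariates: %d of %d rows dropped - extent mismatch?",
                 n_drop, n0))
  out <- out[keep, , drop = FALSE]
  extra <- setdiff(names(pts), c("x", "y"))
  out <- cbind(out, pts[keep, extra, drop = FALSE])
  attr(out, "n_dropped") <- n_drop
  out
}

#' Minimum convex polygon (100% convex hull)
#'
#' @param points two-column matrix or data.frame of locations.
#' @return list of class `mcp`: `vertices` (counter-clockwise open ring)
#'   and `area` (km^2, shoelace formula).
#' @export
mcp <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  pts <- pts[complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3L) stop("MCP needs >= 3 points")
  h <- grDevices::chull(pts)
  verts <- pts[h, , drop = FALSE]
  if (nrow(unique(verts)) < 3L) stop("MCP needs >= 3 non-collinear points")
  a <- polygon_area(verts)
  if (a <= 0) stop("MCP needs >= 3 non-collinear points")
  structure(list(vertices = verts, area = a), class = "mcp")
}

## polygon area centroid (standard signed-area formula)
polygon_centroid <- function(xy) {
  xy <- as.matrix(xy); n <- nrow(xy)
  if (all(xy[1, ] == xy[n, ])) { xy <- xy[-n, , drop = FALSE]; n <- n - 1L }
  x <- xy[, 1]; y <- xy[, 2]; j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Build the availability region around a population MCP
#'
#' Scales the MCP about its centroid so that the scaled polygon's area is
#' `scale_factor` times the MCP area (the default triples the available
#' habitat), then clips to the continental shelf and to sea. The clipped
#' region is represented on the seascape grid.
#'
#' @param mcp_poly an [mcp()] object (or vertex matrix).
#' @param seascape a [make_seascape()] object (provides shelf and land).
#' @param scale_factor area multiple of the buffer (default 3).
#' @param linear_scale if `TRUE`, scale linearly by `scale_factor` instead
#'   (sensitivity option; area then grows by its square).
#' @return list of class `availability_region`: `mcp`, `scaled` (vertices),
#'   `clipped_mask` (logical matrix on the seascape grid), `area_mcp`,
#'   `area_scaled`, `area_clipped` (km^2).
#' @export
availability_region <- function(mcp_poly, seascape, scale_factor = 3,
                                linear_scale = FALSE) {
  verts <- if (inherits(mcp_poly, "mcp")) mcp_poly$vertices else as.matrix(mcp_poly)
  a_mcp <- polygon_area(verts)
  cen <- polygon_centroid(verts)
  s <- if (linear_scale) scale_factor else sqrt(scale_factor)
  scaled <- sweep(sweep(verts, 2, cen, "-") * s, 2, cen, "+")
  a_scaled <- polygon_area(scaled)
  cc <- grid_centers(seascape$bathy)
  inside <- point_in_polygon(scaled, cc$x, cc$y)
  sea <- !seascape$land
  mask <- matrix(FALSE, seascape$bathy$ny, seascape$bathy$nx)
  mask[cbind(cc$row, cc$col)] <- inside
  mask <- mask & sea & seascape$shelf
  if (!any(mask)) stop("availability region is empty after clipping")
  a_clip <- sum(mask) * seascape$bathy$cellsize^2
  structure(list(mcp = verts, scaled = scaled, clipped_mask = mask,
                 area_mcp = a_mcp, area_scaled = a_scaled,
                 area_clipped = a_clip,
                 grid = seascape$bathy[c("xmin", "ymin", "cellsize", "nx", "ny")]),
            class = "availability_region")
}

#' @export
print.availability_region <- function(x, ...) {
  cat(sprintf("<availability_region> MCP %.1f km2, buffer %.1f km2 (x%.2f), clipped %.1f km2\n",
              x$area_mcp, x$area_scaled, x$area_scaled / x$area_mcp, x$area_clipped))
  invisible(x)
}

## membership test for the clipped region
in_region <- function(region, x, y) {
  g <- region$grid
  col <- floor((x - g$xmin) / g$cellsize) + 1L
  row <- floor((y - g$ymin) / g$cellsize) + 1L
  ok <- col >= 1L & col <= g$nx & row >= 1L & row <= g$ny & is.finite(x) & is.finite(y)
  ins <- point_in_polygon(region$scaled, x, y)
  out <- logical(length(x))
  out[ok] <- region$clipped_mask[cbind(row[ok], col[ok])] & ins[ok]
  out
}

#' Sample pseudo-absences inside an availability region
#'
#' Draws, for each individual, `ratio` uniform points per foraging dive
#' inside the clipped availability region, by rejection sampling from the
#' bounding box of the scaled MCP.
#'
#' @param region an [availability_region()].
#' @param foraging_dives data.frame with a column `individual` (one row per
#'   foraging dive), or a named vector of per-individual dive counts.
#' @param ratio pseudo-absences per foraging dive (default 2).
#' @param seed integer seed.
#' @return data.frame `individual, x, y, response = 0`.
#' @export
sample_pseudo_absences <- function(region, foraging_dives, ratio = 2,
                                   seed = NULL) {
  counts <- if (is.data.frame(foraging_dives)) {
    table(foraging_dives$individual)
  } else as.table(foraging_dives)
  bb <- apply(region$scaled, 2, range)
  with_seed(seed, {
    out <- lapply(names(counts), function(id) {
      need <- ratio * as.integer(counts[[id]])
      got <- matrix(numeric(0), 0, 2)
      tried <- 0L
      while (nrow(got) < need) {
        m <- max(1000L, 4L * (need - nrow(got)))
        px <- runif(m, bb[1, 1], bb[2, 1])
        py <- runif(m, bb[1, 2], bb[2, 2])
        acc <- in_region(region, px, py)
        tried <- tried + m
        got <- rbind(got, cbind(px[acc], py[acc]))
        if (tried > 200L * need && nrow(got) < 0.01 * tried)
          stop("pseudo-absence rejection acceptance < 1%: degenerate region")
      }
      got <- got[seq_len(need), , drop = FALSE]
      data.frame(individual = id, x = got[, 1], y = got[, 2], response = 0L)
    })
    do.call(rbind, out)
  })
}
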