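## Kernel utilization distributions of foraging dive locations, 95%
## volume contours, and Bhattacharyya-affinity overlap.
##
## The UD is a product-Gaussian kernel density evaluated on a declared
## grid and normalized over cells; the default bandwidth is the normal
## scale (reference) rule per axis, h = 1.06 * sd * n^(-1/5). The
## Bhattacharyya affinity BA = sum(sqrt(p1 * p2)) over cells of a common
## grid ranges from 0 (complete segregation) to 1 (complete overlap) and
## is applied to the 95%-truncated, renormalized UDs by default.

#' Declare a UD evaluation grid
#'
#' @param xlim,ylim extent.
#' @param n cells per axis (length 1 or 2).
#' @return list of class `ud_grid` with cell-center coordinates.
#' @export
ud_grid <- function(xlim, ylim, n = 100) {
  n <- rep_len(as.integer(n), 2L)
  csx <- diff(xlim) / n[1]; csy <- diff(ylim) / n[2]
  structure(list(x = xlim[1] + (seq_len(n[1]) - 0.5) * csx,
                 y = ylim[1] + (seq_len(n[2]) - 0.5) * csy,
                 nx = n[1], ny = n[2], csx = csx, csy = csy,
                 xlim = xlim, ylim = ylim), class = "ud_grid")
}

## normal-scale rule bandwidth per axis
nrd_bandwidth <- function(v) {
  n <- length(v)
  s <- min(sd(v), stats::IQR(v) / 1.349)
  if (s <= 0) s <- sd(v)
  1.06 * s * n^(-1 / 5)
}

#' Kernel utilization distribution
#'
#' @param points two-column matrix or data.frame of locations (>= 10, not
#'   all identical).
#' @param grid a [ud_grid()]; default spans the points plus 3 bandwidths.
#' @param bandwidth `"auto"` (normal-scale rule) or numeric (length 1 or
#'   2, per axis).
#' @return object of class `ud`: `p` (cell probabilities, rows = y,
#'   summing to 1), `grid`, `bandwidth`, `n`.
#' @export
kde_ud <- function(points, grid = NULL, bandwidth = "auto") {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  pts <- pts[complete.cases(pts), , drop = FALSE]
  n <- nrow(pts)
  if (n < 10L) stop("kde_ud needs >= 10 points")
  if (all(pts[, 1] == pts[1, 1]) && all(pts[, 2] == pts[1, 2]))
    stop("all points identical: no kernel density estimable")
  h <- if (identical(bandwidth, "auto"))
    c(nrd_bandwidth(pts[, 1]), nrd_bandwidth(pts[, 2]))
  else rep_len(as.numeric(bandwidth), 2L)
  if (any(h <= 0)) stop("bandwidth must be positive")
  if (is.null(grid)) {
    grid <- ud_grid(range(pts[, 1]) + c(-3, 3) * h[1],
                    range(pts[, 2]) + c(-3, 3) * h[2], n = 100L)
  }
  ## density(x, y) = mean_i K_h(x - xi) K_h(y - yi), by outer products
  Kx <- dnorm(outer(grid$x, pts[, 1], "-") / h[1]) / h[1]   # nx x n
  Ky <- dnorm(outer(grid$y, pts[, 2], "-") / h[2]) / h[2]   # ny x n
  dens <- (Ky %*% t(Kx)) / n                                 # ny x nx
  p <- dens / sum(dens)
  structure(list(p = p, grid = grid, bandwidth = h, n = n),
            class = "ud")
}

#' @export
print.ud <- function(x, ...) {
  cat(sprintf("<ud> %d x %d grid, n = %d, bandwidth (%.3g, %.3g)%s\n",
              x$grid$nx, x$grid$ny, x$n, x$bandwidth[1], x$bandwidth[2],
              if (!is.null(x$level)) sprintf(", truncated at %g%%",
                                             100 * x$level) else ""))
  invisible(x)
}

#' 95% volume contour and truncated UD
#'
#' Cells sorted by density are accumulated to the smallest set reaching
#' the target probability; the UD is truncated to that set and
#' renormalized. Equal-density cells are admitted in row-major order
#' (documented tie rule; matters only for degenerate UDs).
#'
#' @param ud a [kde_ud()] object.
#' @param level contour probability level (default 0.95).
#' @return a `ud` whose `p` is the truncated-renormalized surface, with
#'   `mask` (logical matrix) and `level` recorded.
#' @export
contour95 <- function(ud, level = 0.95) {
  p <- ud$p
  ## row-major tie order: transpose so that ties resolve along rows
  ordv <- order(t(p), decreasing = TRUE)
  cum <- cumsum(t(p)[ordv])
  k <- which(cum >= level - 1e-12)[1]
  mask_t <- matrix(FALSE, ncol(p), nrow(p))
  mask_t[ordv[seq_len(k)]] <- TRUE
  mask <- t(mask_t)
  q <- p * mask
  q <- q / sum(q)
  out <- ud
  out$p <- q; out$mask <- mask; out$level <- level
  out
}

#' Bhattacharyya affinity of two UDs
#'
#' `BA = sum(sqrt(p1 * p2))` over cells of a shared grid.
#'
#' @param ud1,ud2 [kde_ud()] (or [contour95()]-truncated) objects on the
#'   same grid.
#' @return affinity in \[0, 1\].
#' @export
bhattacharyya <- function(ud1, ud2) {
  g1 <- ud1$grid; g2 <- ud2$grid
  if (g1$nx != g2$nx || g1$ny != g2$ny ||
      max(abs(g1$x - g2$x)) > 1e-9 || max(abs(g1$y - g2$y)) > 1e-9)
    stop("UD grids are not aligned; evaluate both on a common grid")
  sum(sqrt(ud1$p * ud2$p))
}

## common grid for a list of point sets: union bounding box at the finer
## implied cell size
common_ud_grid <- function(point_sets, n = 100L, pad_frac = 0.15) {
  allp <- do.call(rbind, lapply(point_sets, function(p)
    as.matrix(p)[, 1:2, drop = FALSE]))
  rx <- range(allp[, 1]); ry <- range(allp[, 2])
  px <- max(diff(rx), 1e-6) * pad_frac; py <- max(diff(ry), 1e-6) * pad_frac
  ud_grid(rx + c(-px, px), ry + c(-py, py), n = n)
}

#' Pairwise home-range overlap (Bhattacharyya affinity matrix)
#'
#' Estimates each individual's UD of foraging dive locations on a common
#' grid (union bounding box), truncates at the 95% contour (unless
#' `truncate = FALSE`), and computes BA for every unordered pair within
#' the grouping.
#'
#' @param points data.frame of foraging dive locations with columns `x`,
#'   `y` and a grouping id column.
#' @param id name of the id column (default `"individual"`).
#' @param n_grid cells per axis of the common grid.
#' @param truncate apply the 95% truncation-renormalization (default).
#' @param level contour level.
#' @param min_points individuals with fewer points are skipped (logged).
#' @return list of class `overlap_summary`: `ba` (symmetric matrix),
#'   `pairs` (long table), `mean`, `sd`.
#' @export
pairwise_overlap <- function(points, id = "individual", n_grid = 100L,
                             truncate = TRUE, level = 0.95,
                             min_points = 10L) {
  sets <- split(points[, c("x", "y")], points[[id]])
  keep <- vapply(sets, nrow, integer(1)) >= min_points
  if (any(!keep))
    ss_log("pairwise_overlap",
           sprintf("%d individual(s) with < %d points skipped",
                   sum(!keep), min_points))
  sets <- sets[keep]
  ids <- names(sets)
  if (length(sets) < 2L) stop("need >= 2 individuals with enough points")
  grid <- common_ud_grid(sets, n = n_grid)
  uds <- lapply(sets, function(p) {
    u <- kde_ud(p, grid = grid)
    if (truncate) contour95(u, level) else u
  })
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  prs <- combn(seq_along(ids), 2L)
  vals <- apply(prs, 2L, function(ij)
    bhattacharyya(uds[[ij[1]]], uds[[ij[2]]]))
  m[t(prs)] <- vals; m[t(prs)[, 2:1, drop = FALSE]] <- vals
  structure(list(ba = m,
                 pairs = data.frame(a = ids[prs[1, ]], b = ids[prs[2, ]],
                                    ba = vals),
                 mean = mean(vals), sd = sd(vals)),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> %d individuals, %d pairs, BA %.2f +/- %.2f\n",
              nrow(x$ba), nrow(x$pairs), x$mean,
              ifelse(is.na(x$sd), 0, x$sd)))
  invisible(x)
}
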