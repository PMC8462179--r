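# Independent oracles and fixture builders, deliberately implemented with
# different algorithms than the package (brute force / textbook versions).

## plain-R Dijkstra over the 8-connected sea cells of a land matrix;
## returns distances (km) from one cell to all cells (Inf unreachable)
dijkstra_oracle <- function(land, cellsize, from_rc) {
  ny <- nrow(land); nx <- ncol(land)
  dist <- matrix(Inf, ny, nx)
  done <- matrix(FALSE, ny, nx)
  dist[from_rc[1], from_rc[2]] <- 0
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    ui <- (u - 1) %% ny + 1; uj <- (u - 1) %/% ny + 1
    done[ui, uj] <- TRUE
    for (k in seq_len(nrow(offs))) {
      vi <- ui + offs$di[k]; vj <- uj + offs$dj[k]
      if (vi < 1 || vi > ny || vj < 1 || vj > nx) next
      if (land[vi, vj]) next
      w <- sqrt(offs$di[k]^2 + offs$dj[k]^2) * cellsize
      if (dist[ui, uj] + w < dist[vi, vj]) dist[vi, vj] <- dist[ui, uj] + w
    }
  }
  dist
}

## Jarvis-march (gift wrapping) convex hull, counter-clockwise
gift_wrap_hull <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1) 2 else 1
    for (r in seq_len(n)) {
      if (r == p || r == q) next
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_r > d_q)) q <- r
    }
    p <- q
    if (p == start) break
  }
  pts[hull, , drop = FALSE]
}

shoelace <- function(xy) {
  n <- nrow(xy); j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

## dense-grid numerical integration of a piecewise-linear dive profile
profile_area_dense <- function(t_in, d_in, duration, dt = 0.1) {
  tt <- c(0, t_in, duration); dd <- c(0, d_in, 0)
  g <- seq(0, duration, by = dt)
  sum(approx(tt, dd, xout = g)$y) * dt
}

## one-row dive table in the package's column layout
make_dive <- function(duration, max_depth, t_in, d_in, seal = "s1",
                      start = as.POSIXct("2012-03-10 12:00:00", tz = "UTC")) {
  out <- data.frame(seal = seal, start = start, end = start + duration,
                    duration = duration, max_depth = max_depth)
  for (i in 1:9) { out[[paste0("t", i)]] <- t_in[i]
                   out[[paste0("d", i)]] <- d_in[i] }
  out
}

## n random valid dives: duration 60-1200 s, depth 5-200 m, 9 random
## interior points (sorted times, depths in [0, D] with the max forced to D)
random_dives <- function(n, seed = 1, v_max = 2) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      D <- runif(1, 5, 200)
      Tmin <- 2 * D / v_max + 1       # scorable by construction
      Tt <- runif(1, max(60, Tmin), max(1200, Tmin + 60))
      t_in <- sort(runif(9, 0.01 * Tt, 0.99 * Tt))
      while (any(diff(t_in) <= 0)) t_in <- sort(runif(9, 0.01 * Tt, 0.99 * Tt))
      d_in <- runif(9, 0, D)
      d_in[sample(9, 1)] <- D
      make_dive(Tt, D, t_in, d_in, seal = "s1",
                start = as.POSIXct("2012-03-10", tz = "UTC") + i * 3600)
    })
    do.call(rbind, rows)
  })
}

## small shared synthetic world (cached per test run)
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- make_seascape(seascape_params(extent_km = 80, cell_km = 2,
                                          n_sediment = 3, n_haulouts = 2),
                          seed = 99)
      cache <<- list(seascape = sc, seagraph = build_sea_graph(sc))
    }
    cache
  }
})

## logistic use-availability table simulated directly from known effects
sim_ua_table <- function(n = 2000, betas = c(bathy = -0.03, tidal = 1.0,
                                             dist_shore = 0,
                                             dist_haulout = -0.05),
                         n_ind = 12, seed = 1, intercept = 1.5,
                         re_sd = 0.3) {
  withr::with_seed(seed, {
    ids <- factor(sample(sprintf("id%02d", seq_len(n_ind)), n, TRUE))
    tab <- data.frame(
      bathy = runif(n, 0, 150), tidal = runif(n, 0, 1.5),
      dist_shore = runif(n, 0, 60), dist_haulout = runif(n, 0, 80),
      sediment = factor(sample(paste0("sed", 1:4), n, TRUE,
                               prob = c(0.4, 0.3, 0.2, 0.1))),
      individual = ids, site = factor("s1"))
    eta <- intercept + as.matrix(tab[names(betas)]) %*% betas +
      rnorm(n_ind, 0, re_sd)[as.integer(ids)]
    tab$response <- rbinom(n, 1, 1 / (1 + exp(-eta)))
    tab
  })
}

## sparse-ish adjacency matrix of TRUE cells in a logical mask (4-connected)
mask_adjacency <- function(mask) {
  idx <- which(mask)
  ny <- nrow(mask)
  pos <- match(seq_along(mask), idx)
  n <- length(idx)
  A <- matrix(0L, n, n)
  for (k in seq_len(n)) {
    i <- (idx[k] - 1) %% ny + 1; j <- (idx[k] - 1) %/% ny + 1
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > ny || jj < 1 || jj > ncol(mask)) next
      lin <- ii + (jj - 1) * ny
      if (mask[lin]) A[k, pos[lin]] <- 1L
    }
  }
  A
}
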