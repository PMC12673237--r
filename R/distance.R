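#' Distance raster to a landscape feature
#'
#' Computes, for every cell, the Euclidean distance in metres from its
#' centre to the nearest feature cell centre (features `open` and `edge`)
#' or to the nearest access point (`access`, computed point-exact rather
#' than rasterized). Feature cells themselves have distance 0. Grid
#' distances use the exact two-pass Euclidean distance transform of
#' Felzenszwalb & Huttenlocher, so results equal a brute-force
#' minimum-over-feature-cells scan.
#'
#' @param landscape a `landscape_grid`.
#' @param feature one of `"open"`, `"edge"`, `"access"`.
#' @param neighbourhood edge adjacency passed to [edge_cells()].
#' @return A `distance_grid`: list with `dist` (matrix, metres, same
#'   orientation as the landscape), `feature`, `cell_size`, `origin`.
#' @export
distance_raster <- function(landscape, feature = c("open", "edge", "access"),
                            neighbourhood = 4) {
  stopifnot(inherits(landscape, "landscape_grid"))
  feature <- match.arg(feature)
  cs <- landscape$cell_size
  nr <- nrow(landscape$classes); nc <- ncol(landscape$classes)
  if (feature == "access") {
    pts <- landscape$access
    if (nrow(pts) == 0)
      stop("cannot build a distance raster: feature 'access' is empty")
    cx <- landscape$origin[1] + (seq_len(nc) - 0.5) * cs
    cy <- landscape$origin[2] + (seq_len(nr) - 0.5) * cs
    d <- matrix(Inf, nr, nc)
    for (k in seq_len(nrow(pts)))
      d <- pmin(d, sqrt(outer((cy - pts$y[k])^2, (cx - pts$x[k])^2, `+`)))
  } else {
    mask <- if (feature == "open") landscape$classes == 2L
            else edge_cells(landscape, neighbourhood)
    if (!any(mask))
      stop(sprintf("cannot build a distance raster: feature '%s' is empty",
                   feature))
    d <- sqrt(edt_squared(mask)) * cs
  }
  structure(list(dist = d, feature = feature, cell_size = cs,
                 origin = landscape$origin),
            class = "distance_grid")
}

# exact squared Euclidean distance transform (cell units):
# 1D lower-envelope transforms over columns, then rows
edt_squared <- function(mask) {
  BIG <- 1e18
  f <- ifelse(mask, 0, BIG)
  f <- apply(f, 2, dt1d)
  t(apply(f, 1, dt1d))
}

dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Sample a distance grid at point locations
#'
#' Looks up the grid cell containing each point and returns its distance
#' value. Points outside the grid are an error (reported with their
#' coordinates).
#'
#' @param grid a `distance_grid`.
#' @param x,y planar coordinates in metres.
#' @return Numeric vector of distances, metres.
#' @export
sample_distance <- function(grid, x, y) {
  stopifnot(inherits(grid, "distance_grid"))
  cs <- grid$cell_size
  cc <- floor((x - grid$origin[1]) / cs) + 1L
  rr <- floor((y - grid$origin[2]) / cs) + 1L
  # points exactly on the upper/right boundary belong to the last cell
  cc[x == grid$origin[1] + ncol(grid$dist) * cs] <- ncol(grid$dist)
  rr[y == grid$origin[2] + nrow(grid$dist) * cs] <- nrow(grid$dist)
  bad <- cc < 1L | cc > ncol(grid$dist) | rr < 1L | rr > nrow(grid$dist)
  if (any(bad))
    stop(sprintf("fix outside grid at (%.1f, %.1f)",
                 x[which(bad)[1]], y[which(bad)[1]]))
  grid$dist[cbind(rr, cc)]
}
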