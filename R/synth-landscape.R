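#' Generate a synthetic categorical landscape
#'
#' Builds a patchy forest/open landscape on a regular grid by thresholding
#' spatially smoothed Gaussian noise, then overlays straight road corridors
#' and places hunter-access points on road cells. Cell classes are
#' `forest`, `open` and `road`; the default cell size is 30 m, the
#' resolution of common landcover products.
#'
#' @param width,height grid dimensions in cells (each at least 4).
#' @param cell_size cell side length in metres.
#' @param open_fraction proportion of non-road cells classified open.
#' @param n_roads number of straight road corridors (rows or columns).
#' @param n_access number of access points, placed on road cells.
#' @param seed integer seed; the same seed yields the identical landscape.
#' @param smooth_passes smoothing passes applied to the noise field;
#'   more passes give larger patches.
#' @return A `landscape_grid` object: a list with `classes` (integer matrix,
#'   levels `forest`/`open`/`road`; row 1 is the southern edge, column 1 the
#'   western edge, cell `[r, c]` centred at
#'   `origin + cell_size * (c - 0.5, r - 0.5)`), `cell_size`, `origin`, and
#'   `access` (data frame of point coordinates in metres).
#' @export
make_landscape <- function(width, height, cell_size = 30, open_fraction = 0.3,
                           n_roads = 2, n_access = 4, seed = 1,
                           smooth_passes = 3) {
  if (!is.numeric(width) || !is.numeric(height) || width < 4 || height < 4)
    stop("landscape dimensions must be numeric and at least 4x4 cells")
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive number of metres")
  if (open_fraction < 0 || open_fraction > 1)
    stop("open_fraction must lie in [0, 1]")
  if (n_roads < 0 || n_access < 0)
    stop("n_roads and n_access must be non-negative")
  if (n_access > 0 && n_roads == 0)
    stop("access points are placed on roads; n_access > 0 requires n_roads >= 1")
  width <- as.integer(width); height <- as.integer(height)
  if (!is.null(seed)) set.seed(seed)

  noise <- matrix(rnorm(height * width), nrow = height, ncol = width)
  for (k in seq_len(smooth_passes)) noise <- smooth3x3(noise)

  classes <- matrix(1L, nrow = height, ncol = width)  # 1 = forest
  if (open_fraction > 0) {
    thr <- quantile(noise, open_fraction, type = 7)
    classes[noise <= thr] <- 2L                       # 2 = open
  }

  road_cells <- matrix(FALSE, height, width)
  if (n_roads > 0) {
    ori <- sample(c("h", "v"), n_roads, replace = TRUE)
    for (i in seq_len(n_roads)) {
      if (ori[i] == "h") road_cells[sample.int(height, 1L), ] <- TRUE
      else road_cells[, sample.int(width, 1L)] <- TRUE
    }
    classes[road_cells] <- 3L                         # 3 = road
  }

  access <- data.frame(x = numeric(0), y = numeric(0))
  if (n_access > 0) {
    idx <- which(road_cells)
    idx <- idx[sample.int(length(idx), min(n_access, length(idx)))]
    rr <- (idx - 1L) %% height + 1L
    cc <- (idx - 1L) %/% height + 1L
    access <- data.frame(x = (cc - 0.5) * cell_size, y = (rr - 0.5) * cell_size)
  }

  structure(list(classes = classes, cell_size = cell_size,
                 origin = c(0, 0), access = access,
                 levels = c("forest", "open", "road")),
            class = "landscape_grid")
}

# one pass of 3x3 mean smoothing with edge replication
smooth3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + p[dr + seq_len(nr), dc + seq_len(nc)]
  out / 9
}

#' @export
print.landscape_grid <- function(x, ...) {
  tab <- table(factor(x$levels[x$classes], levels = x$levels))
  cat(sprintf("landscape_grid: %d x %d cells of %g m\n",
              nrow(x$classes), ncol(x$classes), x$cell_size))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  access points: %d\n", nrow(x$access)))
  invisible(x)
}

#' Identify edge cells of a landscape
#'
#' Edge habitat is defined as forest cells that border open or road cells.
#' The default border relation is the 4-neighbourhood (rook adjacency);
#' 8-neighbourhood (queen) is available by flag.
#'
#' @param landscape a `landscape_grid`.
#' @param neighbourhood 4 or 8.
#' @return Logical matrix the shape of `landscape$classes`.
#' @export
edge_cells <- function(landscape, neighbourhood = 4) {
  stopifnot(inherits(landscape, "landscape_grid"), neighbourhood %in% c(4, 8))
  cl <- landscape$classes
  nr <- nrow(cl); nc <- ncol(cl)
  openroad <- cl == 2L | cl == 3L
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (neighbourhood == 8)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  near <- matrix(FALSE, nr, nc)
  for (s in shifts) {
    sh <- matrix(FALSE, nr, nc)
    rsrc <- seq_len(nr) - s[1]; csrc <- seq_len(nc) - s[2]
    rok <- rsrc >= 1 & rsrc <= nr; cok <- csrc >= 1 & csrc <= nc
    sh[rok, cok] <- openroad[rsrc[rok], csrc[cok]]
    near <- near | sh
  }
  cl == 1L & near
}

#' Write / read a landscape as plain text
#'
#' The class grid is written in the ESRI ASCII-grid format (integer codes
#' 1 = forest, 2 = open, 3 = road; rows north to south), the access points
#' as a two-column CSV. `read_landscape()` restores the `landscape_grid`.
#'
#' @param landscape a `landscape_grid`.
#' @param grid_file path for the `.asc` grid.
#' @param access_file path for the access-point CSV.
#' @return `write_landscape()` returns the paths invisibly;
#'   `read_landscape()` returns a `landscape_grid`.
#' @export
write_landscape <- function(landscape, grid_file, access_file) {
  stopifnot(inherits(landscape, "landscape_grid"))
  cl <- landscape$classes
  hdr <- c(sprintf("ncols %d", ncol(cl)),
           sprintf("nrows %d", nrow(cl)),
           sprintf("xllcorner %.10g", landscape$origin[1]),
           sprintf("yllcorner %.10g", landscape$origin[2]),
           sprintf("cellsize %.10g", landscape$cell_size),
           "NODATA_value -9999")
  rows <- apply(cl[rev(seq_len(nrow(cl))), , drop = FALSE], 1,
                paste, collapse = " ")
  writeLines(c(hdr, rows), grid_file)
  write.csv(landscape$access, access_file, row.names = FALSE)
  invisible(c(grid = grid_file, access = access_file))
}

#' @rdname write_landscape
#' @export
read_landscape <- function(grid_file, access_file) {
  ln <- readLines(grid_file)
  hdr <- strsplit(trimws(ln[1:6]), "\\s+")
  vals <- setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                   tolower(vapply(hdr, `[`, "", 1)))
  nc <- vals[["ncols"]]; nr <- vals[["nrows"]]
  body <- lapply(strsplit(trimws(ln[-(1:6)]), "\\s+"), as.integer)
  cl <- do.call(rbind, body)
  stopifnot(nrow(cl) == nr, ncol(cl) == nc)
  cl <- cl[rev(seq_len(nr)), , drop = FALSE]  # back to row 1 = south
  access <- read.csv(access_file)
  structure(list(classes = cl, cell_size = vals[["cellsize"]],
                 origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
                 access = access, levels = c("forest", "open", "road")),
            class = "landscape_grid")
}
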