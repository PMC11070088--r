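#' Maximum intensity z-projection
#'
#' Collapses a multichannel stack to 2D by taking, per channel and per pixel,
#' the maximum intensity over z — the standard first step before
#' boundary-referenced quantification.
#'
#' @param stack An [image_stack()].
#' @return An object of class `projection2d`: list with `data` (array
#'   `(y, x, channel)`), `channel_names`, `pixel_size_um`.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  out <- array(0, dim = c(d[1], d[2], d[4]))
  for (c in seq_len(d[4])) {
    m <- stack$data[, , 1, c]
    if (d[3] > 1L) for (z in seq.int(2L, d[3])) m <- pmax(m, stack$data[, , z, c])
    out[, , c] <- m
  }
  structure(
    list(data = out, channel_names = stack$channel_names,
         pixel_size_um = stack$pixel_size_um),
    class = "projection2d"
  )
}

#' @export
print.projection2d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<projection2d> %d x %d px, %d channel(s) [%s], %.3g um/px\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
              x$pixel_size_um))
  invisible(x)
}

# Extract one channel of a projection as a (y, x) matrix.
projection_channel <- function(projection, channel) {
  stopifnot(inherits(projection, "projection2d"))
  projection$data[, , channel_index(projection, channel)]
}

#' Point-in-polygon classification (even-odd rule)
#'
#' Ray-casting (even-odd) test of query points against the boundary polygon.
#' Points lying exactly on an edge or vertex are classified interior, so the
#' interior/exterior partition is exhaustive.
#'
#' @param points Either a length-2 vector `c(x, y)` or a two-column matrix /
#'   data frame of `(x, y)` coordinates.
#' @param roi A [boundary_roi()].
#' @param edge_tol Points within this distance of the boundary are treated as
#'   on-edge (interior). Default 1e-12 pixels.
#' @return Logical vector: `TRUE` for interior.
#' @export
point_in_polygon <- function(points, roi, edge_tol = 1e-12) {
  stopifnot(inherits(roi, "boundary_roi"))
  p <- as_point_matrix(points)
  px <- p[, 1]; py <- p[, 2]
  v <- unclass(roi)
  vx <- v[, 1]; vy <- v[, 2]
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  on_edge <- distance_to_boundary(p, roi) <= edge_tol
  inside | on_edge
}

#' Minimum Euclidean distance from points to the polygon boundary
#'
#' Exact minimum over all boundary segments of the point-to-segment distance
#' (the perpendicular foot clamped to the segment endpoints). Returned in
#' pixel units; multiply by the pixel size for micrometres.
#'
#' @inheritParams point_in_polygon
#' @return Numeric vector of distances (pixels), one per query point.
#' @export
distance_to_boundary <- function(points, roi) {
  stopifnot(inherits(roi, "boundary_roi"))
  p <- as_point_matrix(points)
  min_dist_to_segments(p[, 1], p[, 2], unclass(roi))
}

as_point_matrix <- function(points) {
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 2L) {
    return(matrix(points, ncol = 2L))
  }
  p <- as.matrix(points)
  if (ncol(p) != 2L) abort("`points` must be (x, y) pairs.")
  p
}

# Vectorized min distance from (px, py) to the closed polyline over `v`.
min_dist_to_segments <- function(px, py, v) {
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  best <- rep(Inf, length(px))
  for (s in seq_along(x1)) {
    t <- ((px - x1[s]) * dx[s] + (py - y1[s]) * dy[s]) / len2[s]
    t <- pmin(pmax(t, 0), 1)
    d2 <- (px - (x1[s] + t * dx[s]))^2 + (py - (y1[s] + t * dy[s]))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Per-pixel interior mask and depth-from-boundary field
#'
#' Applies the point-in-polygon test and the exact boundary distance to every
#' pixel center of a `(ny, nx)` grid. Depths are reported in micrometres
#' (`pixel_size_um` times the pixel distance); exterior pixels carry `NA`.
#'
#' @param roi A [boundary_roi()].
#' @param shape Integer `(ny, nx)` grid size in pixels.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @return An object of class `distance_field`: list with `interior_mask`
#'   (`ny x nx` logical), `depth_um` (`ny x nx`, `NA` outside),
#'   `max_depth_um`, `pixel_size_um`, `shape`.
#' @export
interior_distance_field <- function(roi, shape, pixel_size_um = 1) {
  stopifnot(inherits(roi, "boundary_roi"))
  stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
  ny <- as.integer(shape[1]); nx <- as.integer(shape[2])
  # pixel centers: x = col - 1, y = row - 1 (0-based, row-major grid)
  px <- rep(seq_len(nx) - 1, each = ny)
  py <- rep(seq_len(ny) - 1, times = nx)
  dist_px <- min_dist_to_segments(px, py, unclass(roi))
  inside <- point_in_polygon_raw(px, py, unclass(roi)) | dist_px <= 1e-12
  if (!any(inside)) abort("Polygon encloses no pixel centers (empty interior).")
  depth <- matrix(NA_real_, ny, nx)
  depth[cbind(py + 1L, px + 1L)[inside, , drop = FALSE]] <-
    dist_px[inside] * pixel_size_um
  mask <- matrix(FALSE, ny, nx)
  mask[cbind(py + 1L, px + 1L)[inside, , drop = FALSE]] <- TRUE
  # unsigned boundary distance for every pixel (exterior included); used by
  # background estimation, not part of the depth contract
  bdist <- matrix(NA_real_, ny, nx)
  bdist[cbind(py + 1L, px + 1L)] <- dist_px * pixel_size_um
  structure(
    list(interior_mask = mask, depth_um = depth,
         max_depth_um = max(depth, na.rm = TRUE),
         boundary_distance_um = bdist,
         pixel_size_um = pixel_size_um, shape = c(ny, nx)),
    class = "distance_field"
  )
}

# Even-odd test without the on-edge refinement (used where the caller
# already has distances available).
point_in_polygon_raw <- function(px, py, v) {
  vx <- v[, 1]; vy <- v[, 2]
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("<distance_field> %d x %d px, %d interior px, max depth %.2f um\n",
              x$shape[1], x$shape[2], sum(x$interior_mask), x$max_depth_um))
  invisible(x)
}

#' Percent depth towards the organoid center
#'
#' Rescales the depth field to a fraction of the image's maximum depth, so 0
#' is the boundary and 1 the deepest interior pixel.
#'
#' @param field A [interior_distance_field()] result.
#' @return Matrix of fractions in `[0, 1]` (`NA` outside the interior).
#' @export
percent_depth <- function(field) {
  stopifnot(inherits(field, "distance_field"))
  if (field$max_depth_um <= 0) {
    abort("Degenerate distance field: maximum depth is 0; percent depth undefined.")
  }
  field$depth_um / field$max_depth_um
}

#' Bin interior pixels into equally-spaced concentric shells
#'
#' Partitions the organoid interior into `n_shells` equal-width bands of
#' distance from the boundary — escalating "levels" of infiltration towards
#' the center. Edges partition `[0, max_depth_um]` (`absolute_um` mode) or
#' `[0, 1]` (`percent_depth` mode); a pixel with depth `d` falls in shell `i`
#' iff `edges[i] <= d < edges[i+1]`, with the last shell closed on the right
#' so the deepest pixel is always assigned.
#'
#' @param field A [interior_distance_field()] result.
#' @param n_shells Number of shells (>= 1). Default 10.
#' @param mode `"absolute_um"` or `"percent_depth"`.
#' @return An object of class `shell_binning`: list with `mode`, `edges`,
#'   `n_shells`, `shell_label` (`ny x nx` integer, `NA` outside),
#'   `empty_shells` (indices of shells holding no pixel).
#' @export
bin_shells <- function(field, n_shells = 10L, mode = c("absolute_um", "percent_depth")) {
  stopifnot(inherits(field, "distance_field"))
  mode <- match.arg(mode)
  n_shells <- as.integer(n_shells)
  if (n_shells < 1L) abort("`n_shells` must be at least 1.")
  depth <- if (mode == "absolute_um") field$depth_um else percent_depth(field)
  top <- if (mode == "absolute_um") field$max_depth_um else 1
  edges <- seq(0, top, length.out = n_shells + 1L)
  lab <- matrix(NA_integer_, field$shape[1], field$shape[2])
  idx <- which(field$interior_mask)
  lab[idx] <- findInterval(depth[idx], edges, rightmost.closed = TRUE)
  counts <- tabulate(lab[idx], nbins = n_shells)
  empty <- which(counts == 0L)
  if (length(empty)) {
    warn(sprintf("%d of %d shells contain no pixels (shells: %s).",
                 length(empty), n_shells, paste(empty, collapse = ", ")))
  }
  structure(
    list(mode = mode, edges = edges, n_shells = n_shells,
         shell_label = lab, empty_shells = empty),
    class = "shell_binning"
  )
}

#' @export
print.shell_binning <- function(x, ...) {
  cat(sprintf("<shell_binning> %d shells (%s), edges %.3g..%.3g\n",
              x$n_shells, x$mode, x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}
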