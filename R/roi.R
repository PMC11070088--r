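#' Boundary ROI: a closed simple polygon in pixel coordinates
#'
#' The boundary ROI encodes the hand-drawn outline separating the neural
#' organoid interior from the fused tumor spheroid. Vertices are ordered
#' `(x, y)` pairs in 0-based pixel coordinates (x rightward, y downward,
#' vertices at pixel centers); the closing edge from the last vertex back to
#' the first is implicit.
#'
#' @param vertices Two-column matrix or data frame of `(x, y)` vertex
#'   coordinates, at least 3 rows.
#' @return An object of class `boundary_roi`: the vertex matrix with columns
#'   `x` and `y`.
#' @examples
#' roi <- boundary_roi(cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10)))
#' polygon_area(roi)
#' @export
boundary_roi <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) abort("`vertices` must have two columns (x, y).")
  if (nrow(v) < 3L) abort("A boundary ROI needs at least 3 vertices.")
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
    abort("ROI vertices must be finite numbers.")
  }
  storage.mode(v) <- "double"
  colnames(v) <- c("x", "y")
  # drop an explicit closing vertex duplicating the first
  n <- nrow(v)
  if (n > 3L && all(v[n, ] == v[1L, ])) v <- v[-n, , drop = FALSE]
  simple <- polygon_is_simple(v)
  if (!isTRUE(simple)) {
    abort(sprintf(
      "Polygon is self-intersecting: edge %d (vertex %d-%d) crosses edge %d (vertex %d-%d).",
      simple[1], simple[1], simple[1] %% nrow(v) + 1L,
      simple[2], simple[2], simple[2] %% nrow(v) + 1L
    ))
  }
  if (abs(polygon_area(v)) <= 0) abort("Polygon has zero area.")
  structure(v, class = c("boundary_roi", "matrix", "array"))
}

#' @export
print.boundary_roi <- function(x, ...) {
  cat(sprintf(
    "<boundary_roi> %d vertices, area %.1f px^2, bbox [%.1f, %.1f] x [%.1f, %.1f]\n",
    nrow(x), polygon_area(x), min(x[, 1]), max(x[, 1]), min(x[, 2]), max(x[, 2])
  ))
  invisible(x)
}

#' Signed shoelace area of a polygon (absolute value returned)
#'
#' @param vertices A `boundary_roi` or two-column vertex matrix.
#' @return Polygon area in squared pixel units.
#' @export
polygon_area <- function(vertices) {
  v <- unclass(vertices)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# O(n^2) pairwise segment-intersection test. Returns TRUE when simple, or the
# indices of the first pair of crossing edges. Adjacent edges (sharing a
# vertex, including the wrap-around pair) are skipped: they legitimately touch
# at the shared vertex.
polygon_is_simple <- function(vertices) {
  v <- unclass(vertices)
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  if (any(x == x2 & y == y2)) abort("Polygon has a zero-length edge (repeated vertex).")
  cross3 <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  on_seg <- function(ax, ay, bx, by, cx, cy) {
    cx >= pmin(ax, bx) & cx <= pmax(ax, bx) & cy >= pmin(ay, by) & cy <= pmax(ay, by)
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      d1 <- cross3(x[j], y[j], x2[j], y2[j], x[i], y[i])
      d2 <- cross3(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
      d3 <- cross3(x[i], y[i], x2[i], y2[i], x[j], y[j])
      d4 <- cross3(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
      hit <- (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
                ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) ||
        (d1 == 0 && on_seg(x[j], y[j], x2[j], y2[j], x[i], y[i])) ||
        (d2 == 0 && on_seg(x[j], y[j], x2[j], y2[j], x2[i], y2[i])) ||
        (d3 == 0 && on_seg(x[i], y[i], x2[i], y2[i], x[j], y[j])) ||
        (d4 == 0 && on_seg(x[i], y[i], x2[i], y2[i], x2[j], y2[j]))
      if (hit) return(c(i, j))
    }
  }
  TRUE
}

#' Build a jittered-ellipse polygon
#'
#' Convenience recipe for organoid-like outlines: `n_vertices` points on an
#' ellipse with per-vertex radial jitter. Jitter draws from the current RNG
#' stream; seed externally for reproducibility.
#'
#' @param cx,cy Center in pixel coordinates.
#' @param rx,ry Semi-axes in pixels.
#' @param n_vertices Number of polygon vertices.
#' @param jitter Relative radial jitter amplitude in `[0, 1)`; each vertex
#'   radius is scaled by `1 + U(-jitter, jitter)`.
#' @return A `boundary_roi`.
#' @export
ellipse_polygon <- function(cx, cy, rx, ry, n_vertices = 64L, jitter = 0) {
  stopifnot_scalar_positive(rx, "rx"); stopifnot_scalar_positive(ry, "ry")
  if (n_vertices < 3L) abort("`n_vertices` must be at least 3.")
  if (jitter < 0 || jitter >= 1) abort("`jitter` must be in [0, 1).")
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  scale <- if (jitter > 0) 1 + runif(n_vertices, -jitter, jitter) else rep(1, n_vertices)
  boundary_roi(cbind(x = cx + rx * scale * cos(th), y = cy + ry * scale * sin(th)))
}

#' Read a boundary ROI from an ImageJ `.roi` or JSON file
#'
#' Supports polygon-type ImageJ ROIs (binary, integer coordinates) and a JSON
#' dialect `{"type": "polygon", "vertices": [[x, y], ...]}` with decimal
#' coordinates. Other ImageJ ROI types (oval, line, point, ...) are rejected
#' rather than coerced.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"imagej"`, or `"json"`.
#' @return A `boundary_roi`.
#' @export
read_roi <- function(path, format = c("auto", "imagej", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.roi$", path, ignore.case = TRUE)) "imagej" else "json"
  }
  if (!file.exists(path)) abort(sprintf("ROI file not found: %s", path))
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$type, "polygon")) {
      abort(sprintf("JSON ROI type must be 'polygon', got '%s'.", obj$type %||% "<missing>"))
    }
    return(boundary_roi(matrix(as.numeric(obj$vertices), ncol = 2L)))
  }
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, charToRaw("Iout"))) {
    abort(sprintf("Not an ImageJ ROI file: %s", path))
  }
  readBin(con, "integer", 1L, size = 2L, endian = "big")      # version
  type <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
  readBin(con, "integer", 1L, size = 1L, signed = FALSE)      # unused
  if (type != 0L) {
    abort(sprintf("Only polygon-type ImageJ ROIs are supported (type code %d found).", type))
  }
  top <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  left <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  readBin(con, "integer", 2L, size = 2L, endian = "big")      # bottom, right
  n <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  readBin(con, "raw", 64L - 18L)                              # rest of header
  xs <- readBin(con, "integer", n, size = 2L, endian = "big")
  ys <- readBin(con, "integer", n, size = 2L, endian = "big")
  boundary_roi(cbind(x = xs + left, y = ys + top))
}

#' Write a boundary ROI to an ImageJ `.roi` or JSON file
#'
#' The ImageJ dialect stores integer pixel coordinates (non-integer vertices
#' are rejected rather than silently rounded); the JSON dialect preserves
#' full double precision. `read_roi(write_roi(...))` is the identity within
#' the dialect's precision.
#'
#' @param roi A `boundary_roi`.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"imagej"`, or `"json"`.
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path, format = c("auto", "imagej", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.roi$", path, ignore.case = TRUE)) "imagej" else "json"
  }
  if (!inherits(roi, "boundary_roi")) roi <- boundary_roi(roi)
  v <- unclass(roi)
  if (format == "json") {
    jsonlite::write_json(
      list(type = "polygon", vertices = unname(v)),
      path, digits = NA, auto_unbox = TRUE
    )
    return(invisible(path))
  }
  if (any(v != round(v))) {
    abort("ImageJ .roi dialect stores integer coordinates; round vertices first or use the JSON dialect.")
  }
  left <- min(v[, 1]); top <- min(v[, 2])
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("Iout", con, eos = NULL, useBytes = TRUE)
  writeBin(227L, con, size = 2L, endian = "big")                    # version
  writeBin(as.raw(c(0L, 0L)), con)                                  # type=polygon, unused
  writeBin(as.integer(c(top, left, max(v[, 2]), max(v[, 1]))), con,
           size = 2L, endian = "big")
  writeBin(nrow(v), con, size = 2L, endian = "big")
  writeBin(raw(64L - 18L), con)
  writeBin(as.integer(v[, 1] - left), con, size = 2L, endian = "big")
  writeBin(as.integer(v[, 2] - top), con, size = 2L, endian = "big")
  invisible(path)
}
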