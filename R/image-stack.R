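#' Multichannel image stack
#'
#' In-memory container for a multichannel 3D fluorescence stack: a
#' non-negative intensity array ordered `(y, x, z, channel)` plus channel
#' names and the physical pixel size. Lower-dimensional input is promoted:
#' `(y, x)` becomes a single-plane single-channel stack, `(y, x, z)` a
#' single-channel stack.
#'
#' @param data Numeric array: `(y, x)`, `(y, x, z)` or `(y, x, z, channel)`.
#' @param channel_names Character vector naming the channels (unique), e.g.
#'   `c("DAPI", "eGFP")`.
#' @param pixel_size_um Physical pixel size in micrometres per pixel.
#' @return An object of class `image_stack` with elements `data`,
#'   `channel_names`, `pixel_size_um`.
#' @export
image_stack <- function(data, channel_names = NULL, pixel_size_um = 1) {
  if (!is.array(data) && is.matrix(data)) data <- as.array(data)
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) abort("`data` must have 2-4 dimensions (y, x[, z[, channel]]).")
  if (anyNA(data) || any(data < 0)) abort("Stack intensities must be non-negative and non-missing.")
  nc <- dim(data)[4]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    abort(sprintf("%d channel names supplied for %d channels.", length(channel_names), nc))
  }
  if (anyDuplicated(channel_names)) abort("Channel names must be unique.")
  stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
  structure(
    list(data = data, channel_names = as.character(channel_names),
         pixel_size_um = pixel_size_um),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d px, %d z-plane(s), %d channel(s) [%s], %.3g um/px\n",
              d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", "),
              x$pixel_size_um))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

# Index of a named channel, with a helpful error.
channel_index <- function(obj, channel) {
  i <- match(channel, obj$channel_names)
  if (is.na(i)) {
    abort(sprintf("Channel '%s' not found; available: %s.",
                  channel, paste(obj$channel_names, collapse = ", ")))
  }
  i
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Pages are written channel-major (all z-planes of channel 1, then channel
#' 2, ...), each plane as 32-bit float scaled into `[0, 1]` by a per-channel
#' intensity scale. Channel names, pixel size, array shape and the scales go
#' to a JSON sidecar at `<path>.json` so that [read_stack()] reconstructs the
#' stack exactly (to 32-bit float precision).
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  scales <- vapply(seq_len(d[4]), function(c) max(stack$data[, , , c], 1e-12), 0)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (c in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      pages[[k]] <- stack$data[, , z, c] / scales[c]
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(shape = d, channel_names = stack$channel_names,
         pixel_size_um = stack$pixel_size_um, channel_scales = scales,
         page_order = "z-fastest-within-channel"),
    sidecar_path(path), digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' If a JSON sidecar written by [write_stack()] is present, shape, channel
#' names, pixel size and intensity scales are taken from it. Without a
#' sidecar the pages are treated as z-planes of a single channel unless
#' `channel_names` matches the page count, in which case pages are channels.
#' Explicit arguments override sidecar metadata; a missing pixel size with no
#' override is an error (never a silent default).
#'
#' @param path TIFF file.
#' @param channel_names Optional override of channel names.
#' @param pixel_size_um Optional override of the pixel size (um/px).
#' @return An `image_stack`.
#' @export
read_stack <- function(path, channel_names = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) abort(sprintf("Image file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) abort(sprintf("Unreadable TIFF '%s': %s", path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
  if (!is.null(meta)) {
    d <- as.integer(meta$shape)
    if (length(pages) != d[3] * d[4]) {
      abort(sprintf("Channel/plane count mismatch: sidecar says %d pages, file has %d.",
                    d[3] * d[4], length(pages)))
    }
    arr <- array(0, dim = d)
    k <- 1L
    for (c in seq_len(d[4])) {
      for (z in seq_len(d[3])) {
        arr[, , z, c] <- pages[[k]] * meta$channel_scales[c]
        k <- k + 1L
      }
    }
    return(image_stack(arr,
                       channel_names = channel_names %||% meta$channel_names,
                       pixel_size_um = pixel_size_um %||% meta$pixel_size_um))
  }
  if (is.null(pixel_size_um)) {
    abort(sprintf("No pixel size for '%s': supply `pixel_size_um` or a manifest override (no sidecar found).", path))
  }
  np <- length(pages)
  if (!is.null(channel_names) && length(channel_names) == np && np > 1L) {
    arr <- array(0, dim = c(dim(pages[[1]]), 1L, np))
    for (c in seq_len(np)) arr[, , 1L, c] <- pages[[c]]
    return(image_stack(arr, channel_names, pixel_size_um))
  }
  if (!is.null(channel_names) && length(channel_names) != 1L && length(channel_names) != np) {
    abort(sprintf("Channel count mismatch: %d names for %d pages.", length(channel_names), np))
  }
  arr <- array(0, dim = c(dim(pages[[1]]), np, 1L))
  for (z in seq_len(np)) arr[, , z, 1L] <- pages[[z]]
  image_stack(arr, channel_names %||% "ch1", pixel_size_um)
}
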