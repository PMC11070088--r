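#' Per-shell pixel counts and channel mean intensities
#'
#' For each concentric shell of the binning, computes the pixel count and the
#' arithmetic mean intensity of each requested channel over the pixel centers
#' assigned to that shell.
#'
#' @param projection A [max_project()] result.
#' @param binning A [bin_shells()] result computed on the same pixel grid.
#' @param channels Channels to profile; default all channels of the
#'   projection.
#' @return A tibble of class `shell_profile` with one row per shell x
#'   channel: `shell`, `depth_min`, `depth_max`, `n_pixels`, `channel`,
#'   `mean_intensity` (`NA` for empty shells). Binning metadata is carried in
#'   attributes `mode` and `edges`.
#' @export
shell_profile <- function(projection, binning, channels = NULL) {
  stopifnot(inherits(projection, "projection2d"), inherits(binning, "shell_binning"))
  if (!identical(dim(projection$data)[1:2], dim(binning$shell_label))) {
    abort("Projection and shell binning have different pixel grids.")
  }
  channels <- channels %||% projection$channel_names
  lab <- binning$shell_label
  idx <- which(!is.na(lab))
  labs <- lab[idx]
  n_sh <- binning$n_shells
  counts <- tabulate(labs, nbins = n_sh)
  per_channel <- purrr::map(channels, function(ch) {
    vals <- projection_channel(projection, ch)[idx]
    sums <- vapply(seq_len(n_sh), function(s) sum(vals[labs == s]), 0)
    ifelse(counts > 0, sums / counts, NA_real_)
  })
  out <- tidyr::expand_grid(shell = seq_len(n_sh), channel = channels)
  out$depth_min <- binning$edges[out$shell]
  out$depth_max <- binning$edges[out$shell + 1L]
  out$n_pixels <- counts[out$shell]
  out$mean_intensity <- purrr::map2_dbl(
    match(out$channel, channels), out$shell,
    function(ci, s) per_channel[[ci]][s]
  )
  out <- out[, c("shell", "depth_min", "depth_max", "n_pixels", "channel",
                 "mean_intensity")]
  attr(out, "mode") <- binning$mode
  attr(out, "edges") <- binning$edges
  class(out) <- c("shell_profile", class(out))
  out
}

#' Per-shell infiltration metric: mean eGFP over mean DAPI
#'
#' Normalizes the average tumor (eGFP) signal in each shell by the average
#' nuclear (DAPI) signal over the same pixels — a ratio of means, not a mean
#' of ratios. Shells with zero nuclear mean are reported as missing, never 0
#' or infinity.
#'
#' @param profile A [shell_profile()] tibble containing both channels.
#' @param tumor_channel,nuclear_channel Channel names; defaults `"eGFP"` and
#'   `"DAPI"`.
#' @return A tibble with one row per shell: `shell`, `depth_min`,
#'   `depth_max`, `n_pixels`, `tumor_mean`, `nuclear_mean`, `metric`.
#' @export
infiltration_metric <- function(profile, tumor_channel = "eGFP",
                                nuclear_channel = "DAPI") {
  stopifnot(inherits(profile, "shell_profile"))
  for (ch in c(tumor_channel, nuclear_channel)) {
    if (!ch %in% profile$channel) abort(sprintf("Channel '%s' not in profile.", ch))
  }
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(profile[profile$channel %in% c(tumor_channel, nuclear_channel), ]),
    names_from = "channel", values_from = "mean_intensity"
  )
  out <- tibble::tibble(
    shell = wide$shell, depth_min = wide$depth_min, depth_max = wide$depth_max,
    n_pixels = wide$n_pixels,
    tumor_mean = wide[[tumor_channel]], nuclear_mean = wide[[nuclear_channel]]
  )
  out$metric <- dplyr::if_else(
    !is.na(out$nuclear_mean) & out$nuclear_mean > 0,
    out$tumor_mean / out$nuclear_mean, NA_real_
  )
  if (all(is.na(out$metric))) {
    abort("All shells have zero or missing nuclear signal; infiltration metric undefined.")
  }
  out
}

#' Total infiltration past a depth threshold
#'
#' The scalar infiltration metric: mean tumor (eGFP) intensity divided by
#' mean nuclear (DAPI) intensity over all interior pixels at depth at least
#' `threshold` — either an absolute distance from the boundary in
#' micrometres (`past_um`) or a fraction of the maximum depth towards the
#' organoid center (`past_percent`).
#'
#' @param projection A [max_project()] result.
#' @param field The matching [interior_distance_field()].
#' @param threshold Depth threshold: um for `past_um`, fraction in `[0, 1]`
#'   for `past_percent`. Default 0 (whole interior).
#' @param mode `"past_um"` or `"past_percent"`.
#' @param tumor_channel,nuclear_channel Channel names.
#' @return A single number, `mean(tumor) / mean(nuclear)` over qualifying
#'   pixels.
#' @export
total_infiltration <- function(projection, field, threshold = 0,
                               mode = c("past_um", "past_percent"),
                               tumor_channel = "eGFP", nuclear_channel = "DAPI") {
  stopifnot(inherits(projection, "projection2d"), inherits(field, "distance_field"))
  mode <- match.arg(mode)
  depth <- if (mode == "past_um") field$depth_um else percent_depth(field)
  hi <- if (mode == "past_um") field$max_depth_um else 1
  if (threshold < 0 || threshold > hi) {
    abort(sprintf("`threshold` must lie in [0, %.4g] for mode '%s'.", hi, mode))
  }
  qual <- which(field$interior_mask & !is.na(depth) & depth >= threshold)
  if (!length(qual)) {
    abort(sprintf("No interior pixels at depth >= %.4g (%s): empty region.",
                  threshold, mode))
  }
  tum <- mean(projection_channel(projection, tumor_channel)[qual])
  nuc <- mean(projection_channel(projection, nuclear_channel)[qual])
  if (nuc <= 0) abort("Nuclear mean is zero over the qualifying region.")
  tum / nuc
}

#' Marker-to-DAPI total-signal ratio over a region
#'
#' Sum of the marker channel divided by the sum of the nuclear channel over
#' the chosen region: the whole image, the organoid interior, or an
#' interface band of interior pixels within `band_width_um` of the boundary
#' (the fusion interface).
#'
#' @param projection A [max_project()] result.
#' @param marker_channel Marker channel name (e.g. `"CC3"`, `"gH2AX"`,
#'   `"Ki67"`).
#' @param region `"whole_image"`, `"interior"`, or `"interface_band"`.
#' @param field Required [interior_distance_field()] for the interior /
#'   interface regions.
#' @param band_width_um Interface band width in um (default 200).
#' @param nuclear_channel Nuclear channel name.
#' @return A single ratio, `sum(marker) / sum(nuclear)`.
#' @export
marker_ratio <- function(projection, marker_channel,
                         region = c("whole_image", "interior", "interface_band"),
                         field = NULL, band_width_um = 200,
                         nuclear_channel = "DAPI") {
  stopifnot(inherits(projection, "projection2d"))
  region <- match.arg(region)
  mk <- projection_channel(projection, marker_channel)
  nu <- projection_channel(projection, nuclear_channel)
  idx <- switch(region,
    whole_image = seq_along(mk),
    interior = {
      if (is.null(field)) abort("`field` is required for region 'interior'.")
      which(field$interior_mask)
    },
    interface_band = {
      if (is.null(field)) abort("`field` is required for region 'interface_band'.")
      which(field$interior_mask & field$depth_um <= band_width_um)
    }
  )
  if (!length(idx)) abort(sprintf("Region '%s' contains no pixels.", region))
  denom <- sum(nu[idx])
  if (denom <= 0) abort("Total nuclear (DAPI) signal is zero over the region.")
  sum(mk[idx]) / denom
}

#' Normalize per-image marker ratios to each group's untreated control
#'
#' Divides every image's ratio by the mean ratio of the untreated arm of the
#' *same* group, so each group's untreated mean is exactly 1. Normalization
#' is strictly within-group, never across groups.
#'
#' @param data Data frame with one row per image.
#' @param value Column of per-image ratios (unquoted).
#' @param group,treatment Grouping columns (unquoted).
#' @param untreated_label Treatment level identifying the untreated arm.
#' @return The input tibble with an added `relative_value` column.
#' @export
normalize_to_control <- function(data, value, group, treatment,
                                 untreated_label = "untreated") {
  value <- rlang::enquo(value); group <- rlang::enquo(group)
  treatment <- rlang::enquo(treatment)
  data <- tibble::as_tibble(data)
  out <- dplyr::group_by(data, !!group)
  out <- dplyr::mutate(
    out,
    .untreated_mean = mean((!!value)[(!!treatment) == untreated_label])
  )
  out <- dplyr::ungroup(out)
  if (anyNA(out$.untreated_mean) || any(is.nan(out$.untreated_mean))) {
    missing <- unique(dplyr::pull(
      dplyr::filter(out, is.na(.data$.untreated_mean) | is.nan(.data$.untreated_mean)),
      !!group))
    abort(sprintf("Group(s) lacking an untreated arm: %s.",
                  paste(missing, collapse = ", ")))
  }
  out$relative_value <- dplyr::pull(out, !!value) / out$.untreated_mean
  out$.untreated_mean <- NULL
  out
}

#' Per-cell infiltration distances from a tumor-marker channel
#'
#' Detects marker-positive (e.g. H3K27M+) cells by global thresholding (Otsu
#' by default) and connected-component analysis, then reports for each
#' interior cell the minimum Euclidean distance from its intensity-weighted
#' centroid to the organoid boundary — the orthogonal-foot distance for a
#' smooth boundary. Centroids outside the polygon are excluded and counted.
#'
#' @param projection A [max_project()] result containing the marker channel.
#' @param roi The organoid [boundary_roi()].
#' @param channel Marker channel name; default `"H3K27M"`.
#' @param threshold_method `"otsu"` or a numeric threshold.
#' @param min_area_px Minimum component area (pixels) to count as a cell.
#' @return A tibble with one row per interior cell: `cell`, `x`, `y`,
#'   `area_px`, `distance_um`; the number of excluded exterior cells is in
#'   attribute `n_exterior`. No detections give an empty tibble, not an
#'   error.
#' @export
h3k27m_distances <- function(projection, roi, channel = "H3K27M",
                             threshold_method = "otsu", min_area_px = 4L) {
  stopifnot(inherits(projection, "projection2d"), inherits(roi, "boundary_roi"))
  mat <- projection_channel(projection, channel)
  empty_result <- function() {
    out <- tibble::tibble(cell = integer(), x = numeric(), y = numeric(),
                          area_px = integer(), distance_um = numeric())
    attr(out, "n_exterior") <- 0L
    out
  }
  if (diff(range(mat)) == 0) return(empty_result())
  th <- if (identical(threshold_method, "otsu")) otsu_threshold(mat) else {
    if (!is_scalar_number(threshold_method)) abort("`threshold_method` must be 'otsu' or a number.")
    threshold_method
  }
  mask <- mat > th
  if (!any(mask)) return(empty_result())
  lab <- EBImage::bwlabel(mask)
  n_comp <- max(lab)
  areas <- tabulate(lab[lab > 0], nbins = n_comp)
  keep <- which(areas >= min_area_px)
  if (!length(keep)) return(empty_result())
  cent <- t(vapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    w <- mat[idx]
    c(x = sum((idx[, 2] - 1) * w) / sum(w), y = sum((idx[, 1] - 1) * w) / sum(w))
  }, c(x = 0, y = 0)))
  inside <- point_in_polygon(cent, roi)
  out <- tibble::tibble(
    cell = seq_len(sum(inside)),
    x = cent[inside, 1], y = cent[inside, 2],
    area_px = areas[keep][inside],
    distance_um = distance_to_boundary(cent[inside, , drop = FALSE], roi) *
      projection$pixel_size_um
  )
  attr(out, "n_exterior") <- sum(!inside)
  out
}

# Otsu's threshold via EBImage, mapped to the image's own intensity range.
otsu_threshold <- function(mat) {
  rg <- range(mat)
  if (diff(rg) == 0) abort("Cannot threshold a constant image.")
  EBImage::otsu(EBImage::Image(mat), range = rg, levels = 256L)
}

#' Estimate the infiltration decay length from threshold curves
#'
#' Computes [total_infiltration()] on a grid of depth thresholds and fits
#' the exponential depth decay of the infiltrating-cell signal. Multiplying
#' the ratio metric by the qualifying pixel count gives the cumulative
#' (DAPI-normalized) tumor signal past each threshold,
#' `S(t) = A exp(-t / L) + beta N(t)`: an exponential cell term with decay
#' length `L` plus a diffuse-background term proportional to the qualifying
#' area `N(t)`.
#'
#' With `background = "exterior"` (default) the diffuse per-pixel tumor-channel
#' background `beta` is estimated from exterior pixels farther than
#' `exterior_margin_um` from the boundary, and `L` comes from the log-linear
#' regression of the background-subtracted cumulative signal — better
#' conditioned than the joint fit because the exponential and area terms are
#' nearly collinear at large `L`. `background = "profile"` keeps everything
#' interior to the threshold curve and profiles `beta` jointly.
#'
#' @param projection A [max_project()] result.
#' @param field The matching [interior_distance_field()].
#' @param thresholds Depth thresholds (um); default 12 values from 0 to 45%
#'   of the maximum depth. The range deliberately stays in the shallow half
#'   of the organoid: near the center the depth distribution is truncated by
#'   the finite organoid size and the log-survival curve bends away from a
#'   straight line, biasing the slope.
#' @param tumor_channel,nuclear_channel Channel names.
#' @param background `"exterior"` or `"profile"` (see Details).
#' @param exterior_margin_um Exterior pixels closer than this to the boundary
#'   are excluded from background estimation (they catch light from
#'   boundary-adjacent cells).
#' @return A list of class `decay_fit`: `decay_length_um`, `amplitude`,
#'   `background`, `rss`, `curve` (tibble of `threshold_um`, `metric`,
#'   `n_pixels`).
#' @export
estimate_decay_length <- function(projection, field, thresholds = NULL,
                                  tumor_channel = "eGFP",
                                  nuclear_channel = "DAPI",
                                  background = c("exterior", "profile"),
                                  exterior_margin_um = 20) {
  background <- match.arg(background)
  stopifnot(inherits(field, "distance_field"))
  if (is.null(thresholds)) {
    thresholds <- seq(0, 0.45 * field$max_depth_um, length.out = 12L)
  }
  metric <- vapply(thresholds, function(t) {
    total_infiltration(projection, field, t, mode = "past_um",
                       tumor_channel = tumor_channel,
                       nuclear_channel = nuclear_channel)
  }, 0)
  n_px <- vapply(thresholds, function(t) {
    sum(field$interior_mask & !is.na(field$depth_um) & field$depth_um >= t)
  }, 0)
  curve <- tibble::tibble(threshold_um = thresholds, metric = metric,
                          n_pixels = n_px)
  if (background == "exterior") {
    tum <- projection_channel(projection, tumor_channel)
    ext <- !field$interior_mask & field$boundary_distance_um > exterior_margin_um
    if (!any(ext)) abort("No exterior pixels beyond the margin to estimate background from.")
    beta <- mean(tum[ext])
    cum_sum <- vapply(thresholds, function(t) {
      sum(tum[field$interior_mask & !is.na(field$depth_um) & field$depth_um >= t])
    }, 0)
    y <- cum_sum - beta * n_px
    ok <- y > 0
    if (sum(ok) < 4L) abort("Too few thresholds with positive background-subtracted signal.")
    fit <- lm(log(y[ok]) ~ thresholds[ok])
    slope <- coef(fit)[[2]]
    if (slope >= 0) abort("Cumulative signal does not decay with depth; no decay length.")
    return(structure(
      list(decay_length_um = -1 / slope, amplitude = exp(coef(fit)[[1]]),
           background = beta, rss = sum(resid(fit)^2), curve = curve),
      class = "decay_fit"))
  }
  y <- metric * n_px
  if (sum(y > 0) < 4L) abort("Too few thresholds with positive signal to fit a decay length.")
  # profiled least squares: given L, solve y ~ A exp(-t/L) + beta N(t)
  prof_rss <- function(L) {
    X <- cbind(exp(-thresholds / L), n_px)
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  # the profile can be multimodal (the exponential and area columns are
  # nearly collinear at large L): scan a log-spaced grid, then refine locally
  grid <- exp(seq(log(2), log(4 * field$max_depth_um), length.out = 60L))
  rss_grid <- vapply(grid, prof_rss, 0)
  i <- which.min(rss_grid)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(prof_rss, interval = c(lo, hi))
  L <- opt$minimum
  ab <- stats::lm.fit(cbind(exp(-thresholds / L), n_px), y)$coefficients
  if (!is.finite(ab[1]) || ab[1] <= 0) {
    abort("Cumulative signal does not decay with depth; no decay length.")
  }
  structure(list(decay_length_um = L, amplitude = unname(ab[1]),
                 background = unname(ab[2]), rss = opt$objective,
                 curve = curve),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> decay length %.2f um (amplitude %.4g, background %.4g)\n",
              x$decay_length_um, x$amplitude, x$background))
  invisible(x)
}
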