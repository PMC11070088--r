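#' Parameters for a synthetic assembloid scene
#'
#' Bundles everything the generator needs to render a multichannel
#' assembloid stack with known ground truth: image geometry, the organoid
#' outline (explicit vertices or a jittered-ellipse recipe), the infiltrating
#' GFP+ cell population, nuclear density, per-channel gains, marker effect
#' sizes and the Poisson-Gaussian acquisition noise model.
#'
#' Defaults emulate a 10X confocal field of a DIPG-neural assembloid: a
#' roughly elliptical organoid occupying much of a 256 x 256 px frame at
#' 1 um/px, ~150 infiltrating cells whose depth inside the boundary decays
#' exponentially with a 50 um scale, and nuclei filling the organoid at
#' 0.004 nuclei/um^2.
#'
#' @param image_shape Integer `(z, y, x)` stack dimensions.
#' @param pixel_size_um Pixel size, um/px.
#' @param organoid_polygon A [boundary_roi()], a two-column vertex matrix, or
#'   a recipe from [ellipse_recipe()].
#' @param n_cells Number of infiltrating GFP+ cells.
#' @param decay_length_um Exponential scale (um) of the cell-depth
#'   distribution inward from the boundary.
#' @param cell_radius_um Rendered tumor-cell radius (Gaussian blob with
#'   `sigma = cell_radius_um / 2`).
#' @param nuclear_radius_um Rendered nucleus radius for the DAPI channel.
#' @param nuclear_density DAPI+ nuclei per um^2 of organoid interior.
#' @param channel_gains Named per-channel peak intensities; must contain
#'   `DAPI` and `eGFP`. Any additional names become marker channels rendered
#'   at the tumor-cell positions.
#' @param marker_effect Named multiplicative marker level per marker channel
#'   (e.g. `c(CC3 = 2.5)`); defaults to 1 for every marker in
#'   `channel_gains`.
#' @param noise Length-3 numeric `(poisson_scale, gaussian_sd,
#'   background_offset)`: per-pixel variance of the signal-dependent
#'   (Poisson) term is `poisson_scale * signal`, plus additive Gaussian read
#'   noise and a constant background.
#' @param z_weights Relative signal weight of each z-plane (length
#'   `image_shape[1]`); the maximum projection is dominated by plane 1.
#' @param min_separation_um Minimum center-to-center distance between
#'   rendered tumor cells (0 disables the constraint).
#' @param seed RNG seed fixing the scene bit-for-bit.
#' @return A `scene_params` list.
#' @export
scene_params <- function(image_shape = c(3L, 256L, 256L),
                         pixel_size_um = 1,
                         organoid_polygon = ellipse_recipe(128, 128, 100, 90,
                                                           n_vertices = 64L,
                                                           jitter = 0.03),
                         n_cells = 150L,
                         decay_length_um = 50,
                         cell_radius_um = 6,
                         nuclear_radius_um = 5,
                         nuclear_density = 0.004,
                         channel_gains = c(DAPI = 100, eGFP = 120),
                         marker_effect = NULL,
                         noise = c(poisson_scale = 0.05, gaussian_sd = 2,
                                   background_offset = 5),
                         z_weights = NULL,
                         min_separation_um = 0,
                         seed = 1L) {
  stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_positive(decay_length_um, "decay_length_um")
  stopifnot_scalar_positive(cell_radius_um, "cell_radius_um")
  stopifnot_scalar_positive(nuclear_radius_um, "nuclear_radius_um")
  if (length(image_shape) != 3L || any(image_shape < 1)) {
    abort("`image_shape` must be (z, y, x) positive counts.")
  }
  if (n_cells < 0) abort("`n_cells` must be non-negative.")
  if (nuclear_density < 0) abort("`nuclear_density` must be non-negative.")
  if (!all(c("DAPI", "eGFP") %in% names(channel_gains))) {
    abort("`channel_gains` must name at least DAPI and eGFP.")
  }
  if (any(channel_gains < 0)) abort("Channel gains must be non-negative.")
  markers <- setdiff(names(channel_gains), c("DAPI", "eGFP"))
  eff <- setNames(rep(1, length(markers)), markers)
  if (!is.null(marker_effect)) {
    bad <- setdiff(names(marker_effect), markers)
    if (length(bad)) {
      abort(sprintf("`marker_effect` names not in channel_gains markers: %s.",
                    paste(bad, collapse = ", ")))
    }
    eff[names(marker_effect)] <- marker_effect
  }
  if (length(noise) != 3L || any(noise < 0)) {
    abort("`noise` must be (poisson_scale, gaussian_sd, background_offset), all >= 0.")
  }
  names(noise) <- c("poisson_scale", "gaussian_sd", "background_offset")
  if (is.null(z_weights)) {
    z_weights <- seq(1, 0.5, length.out = image_shape[1])
  }
  if (length(z_weights) != image_shape[1]) {
    abort("`z_weights` must have one weight per z-plane.")
  }
  structure(
    list(image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
         organoid_polygon = organoid_polygon, n_cells = as.integer(n_cells),
         decay_length_um = decay_length_um, cell_radius_um = cell_radius_um,
         nuclear_radius_um = nuclear_radius_um, nuclear_density = nuclear_density,
         channel_gains = channel_gains, marker_effect = eff, noise = noise,
         z_weights = z_weights, min_separation_um = min_separation_um,
         seed = as.integer(seed)),
    class = "scene_params"
  )
}

#' Jittered-ellipse polygon recipe (resolved at generation time)
#'
#' @param cx,cy Center (pixels).
#' @param rx,ry Semi-axes (pixels).
#' @param n_vertices Number of vertices.
#' @param jitter Relative radial jitter in `[0, 1)`.
#' @return A recipe understood by [scene_params()].
#' @export
ellipse_recipe <- function(cx, cy, rx, ry, n_vertices = 64L, jitter = 0) {
  structure(list(cx = cx, cy = cy, rx = rx, ry = ry,
                 n_vertices = as.integer(n_vertices), jitter = jitter),
            class = "ellipse_recipe")
}

resolve_polygon <- function(spec) {
  if (inherits(spec, "boundary_roi")) return(spec)
  if (inherits(spec, "ellipse_recipe")) {
    return(ellipse_polygon(spec$cx, spec$cy, spec$rx, spec$ry,
                           spec$n_vertices, spec$jitter))
  }
  boundary_roi(spec)
}

# Add a Gaussian blob of peak `amp` and s.d. `sigma` (px) at (x0, y0) into
# `img` (modified in place via return). Window clipped at +-3.5 sigma.
add_blob <- function(img, x0, y0, sigma, amp) {
  ny <- nrow(img); nx <- ncol(img)
  w <- ceiling(3.5 * sigma)
  cx <- round(x0) + 1L; cy <- round(y0) + 1L
  xr <- max(1L, cx - w):min(nx, cx + w)
  yr <- max(1L, cy - w):min(ny, cy + w)
  if (!length(xr) || !length(yr)) return(img)
  gx <- exp(-((xr - 1L - x0)^2) / (2 * sigma^2))
  gy <- exp(-((yr - 1L - y0)^2) / (2 * sigma^2))
  img[yr, xr] <- img[yr, xr] + amp * outer(gy, gx)
  img
}

render_blobs <- function(shape_yx, xs, ys, sigma, amp = 1) {
  img <- matrix(0, shape_yx[1], shape_yx[2])
  for (i in seq_along(xs)) img <- add_blob(img, xs[i], ys[i], sigma, amp)
  img
}

# Sample `n` points uniformly inside a polygon by bounding-box rejection.
sample_in_polygon <- function(n, roi, shape_yx) {
  v <- unclass(roi)
  xlo <- max(min(v[, 1]), 0); xhi <- min(max(v[, 1]), shape_yx[2] - 1)
  ylo <- max(min(v[, 2]), 0); yhi <- min(max(v[, 2]), shape_yx[1] - 1)
  xs <- numeric(0); ys <- numeric(0)
  guard <- 0L
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 32L)
    cx <- runif(m, xlo, xhi); cy <- runif(m, ylo, yhi)
    keep <- point_in_polygon_raw(cx, cy, v)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
    guard <- guard + 1L
    if (guard > 1000L) abort("Failed to sample points inside the polygon.")
  }
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# Place infiltrating cells: depth ~ Exp(decay_length), position uniform along
# the boundary, stepped inward along the local edge normal; resampled until
# the placed center is interior, inside the frame, and separated.
place_cells <- function(n, roi, shape_yx, decay_px, min_sep_px) {
  v <- unclass(roi)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  seg_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  cum <- cumsum(seg_len)
  # inward normal: rotate the edge direction so the normal points towards the
  # polygon interior (sign from the shoelace orientation)
  sgn <- sign(sum(x1 * y2 - x2 * y1))
  nxs <- -(y2 - y1) / seg_len * sgn
  nys <- (x2 - x1) / seg_len * sgn
  px <- numeric(n); py <- numeric(n); d_drawn <- numeric(n)
  placed <- 0L; tries <- 0L
  max_tries <- 400L * max(n, 1L)
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf(
        "Could not place %d cells inside the organoid (placed %d): organoid area too small for n_cells at this cell size/separation.",
        n, placed))
    }
    d <- rexp(1L, rate = 1 / decay_px)
    u <- runif(1L, 0, cum[length(cum)])
    s <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
    t <- (u - c(0, cum)[s]) / seg_len[s]
    bx <- x1[s] + t * (x2[s] - x1[s]); by <- y1[s] + t * (y2[s] - y1[s])
    qx <- bx + d * nxs[s]; qy <- by + d * nys[s]
    if (qx < 0 || qy < 0 || qx > shape_yx[2] - 1 || qy > shape_yx[1] - 1) next
    if (!point_in_polygon_raw(qx, qy, v)) next
    if (min_sep_px > 0 && placed > 0L) {
      if (min((px[seq_len(placed)] - qx)^2 + (py[seq_len(placed)] - qy)^2) <
          min_sep_px^2) next
    }
    placed <- placed + 1L
    px[placed] <- qx; py[placed] <- qy; d_drawn[placed] <- d
  }
  list(x = px, y = py, depth_drawn_px = d_drawn)
}

# noise = (poisson_scale, gaussian_sd, background_offset), by position
apply_noise <- function(signal, noise) {
  out <- signal
  p <- noise[[1]]
  if (p > 0) {
    lam <- p * signal
    out <- out + (rpois(length(signal), lam) - lam)
  }
  if (noise[[2]] > 0) {
    out <- out + rnorm(length(signal), 0, noise[[2]])
  }
  out <- out + noise[[3]]
  pmax(matrix(out, nrow(signal), ncol(signal)), 0)
}

#' Generate a synthetic assembloid scene with ground truth
#'
#' Renders a multichannel stack emulating a confocal section of a
#' DIPG-neural assembloid: DAPI+ nuclei filling the organoid interior,
#' infiltrating GFP+ tumor cells whose depth inward from the boundary is
#' exponentially distributed with scale `decay_length_um`, and optional
#' marker channels (CC3, gH2AX, Ki67, H3K27M, ...) rendered at the tumor
#' cell positions with intensity proportional to `marker_effect`. Acquisition
#' noise is signal-dependent Poisson plus Gaussian read noise plus a constant
#' background, clipped at zero.
#'
#' @param params A [scene_params()] object.
#' @return A list of class `assembloid_scene` with elements `stack`
#'   ([image_stack()]), `roi` ([boundary_roi()]) and `truth` (a
#'   `scene_ground_truth` list: `polygon`, `cell_positions` tibble with
#'   columns `x`, `y`, `depth_drawn_um`, `depth_um`, `decay_length_um`,
#'   `marker_effect`, `n_nuclei`, `pixel_size_um`, `seed`).
#' @export
generate_assembloid_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_preserved_seed(params$seed, {
    shp <- params$image_shape                 # (z, y, x)
    yx <- shp[c(2L, 3L)]
    psz <- params$pixel_size_um
    roi <- resolve_polygon(params$organoid_polygon)
    v <- unclass(roi)
    if (any(v[, 1] < 0 | v[, 1] > yx[2] - 1 | v[, 2] < 0 | v[, 2] > yx[1] - 1)) {
      abort("Organoid polygon extends outside the image frame.")
    }
    area_px <- polygon_area(roi)
    cell_r_px <- params$cell_radius_um / psz
    # cells are rendered blobs and may overlap; the hard capacity limits are
    # one center per pixel, or disjoint disks when a separation is enforced
    sep_px <- params$min_separation_um / psz
    capacity <- if (sep_px > 0) 0.7 * area_px / (pi * (sep_px / 2)^2) else area_px
    if (params$n_cells > 0 && params$n_cells > capacity) {
      abort(sprintf(
        "Organoid area (%.0f px^2) too small to hold %d cells of radius %.1f px%s.",
        area_px, params$n_cells, cell_r_px,
        if (sep_px > 0) sprintf(" at %.1f px separation", sep_px) else ""))
    }

    # nuclei filling the organoid interior
    n_nuc <- round(params$nuclear_density * area_px * psz^2)
    nuc <- if (n_nuc > 0) sample_in_polygon(n_nuc, roi, yx) else
      cbind(x = numeric(0), y = numeric(0))

    # infiltrating tumor cells
    cells <- place_cells(params$n_cells, roi, yx,
                         decay_px = params$decay_length_um / psz,
                         min_sep_px = params$min_separation_um / psz)
    depth_true_px <- if (params$n_cells > 0) {
      distance_to_boundary(cbind(cells$x, cells$y), roi)
    } else numeric(0)

    nuc_sigma <- params$nuclear_radius_um / psz / 2
    cell_sigma <- cell_r_px / 2
    nuc_render <- render_blobs(yx, nuc[, 1], nuc[, 2], nuc_sigma)
    cell_nuc_render <- render_blobs(yx, cells$x, cells$y, nuc_sigma)
    cell_render <- render_blobs(yx, cells$x, cells$y, cell_sigma)

    gains <- params$channel_gains
    base <- list(DAPI = gains[["DAPI"]] * (nuc_render + cell_nuc_render),
                 eGFP = gains[["eGFP"]] * cell_render)
    for (m in setdiff(names(gains), c("DAPI", "eGFP"))) {
      base[[m]] <- gains[[m]] * params$marker_effect[[m]] * cell_render
    }

    arr <- array(0, dim = c(yx[1], yx[2], shp[1], length(base)))
    for (c in seq_along(base)) {
      for (z in seq_len(shp[1])) {
        arr[, , z, c] <- apply_noise(params$z_weights[z] * base[[c]], params$noise)
      }
    }
    stack <- image_stack(arr, channel_names = names(base), pixel_size_um = psz)

    truth <- structure(
      list(polygon = roi,
           cell_positions = tibble::tibble(
             x = cells$x, y = cells$y,
             depth_drawn_um = cells$depth_drawn_px * psz,
             depth_um = depth_true_px * psz),
           decay_length_um = params$decay_length_um,
           marker_effect = params$marker_effect,
           n_nuclei = n_nuc, pixel_size_um = psz, seed = params$seed),
      class = "scene_ground_truth"
    )
    structure(list(stack = stack, roi = roi, truth = truth),
              class = "assembloid_scene")
  })
}

#' Write a generated scene to disk (TIFF stack + ROI + ground-truth JSON)
#'
#' @param scene An `assembloid_scene`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the files.
#' @return Named character vector of the written paths.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stack_path <- file.path(dir, paste0(name, ".tif"))
  write_stack(scene$stack, stack_path)
  roi_json <- file.path(dir, paste0(name, "_roi.json"))
  write_roi(scene$roi, roi_json, format = "json")
  roi_ij <- file.path(dir, paste0(name, ".roi"))
  v <- unclass(scene$roi)
  ij_ok <- all(v == round(v))
  if (ij_ok) write_roi(scene$roi, roi_ij, format = "imagej")
  truth_path <- file.path(dir, paste0(name, "_truth.json"))
  tr <- scene$truth
  jsonlite::write_json(
    list(polygon = unname(unclass(tr$polygon)),
         cell_positions = tr$cell_positions,
         decay_length_um = tr$decay_length_um,
         marker_effect = as.list(tr$marker_effect),
         n_nuclei = tr$n_nuclei, pixel_size_um = tr$pixel_size_um,
         seed = tr$seed),
    truth_path, digits = NA, auto_unbox = TRUE
  )
  c(stack = stack_path, roi_json = roi_json,
    roi_imagej = if (ij_ok) roi_ij else NA_character_, truth = truth_path)
}

#' Generate a 2D spheroid-migration frame pair with known areas
#'
#' Renders one bright disk per time point (spheroid body plus migration halo)
#' of radius `r0_um` at 0 h and `r24_um` at 24 h, with Gaussian noise and a
#' constant background. The ground-truth spread areas are `pi r^2`.
#'
#' @param r0_um,r24_um Disk radii (um) at 0 h and 24 h; `r24_um >= r0_um > 0`.
#' @param frame_shape `(ny, nx)` frame size in pixels.
#' @param pixel_size_um Pixel size (um/px).
#' @param intensity Disk foreground intensity.
#' @param noise `(gaussian_sd, background_offset)`.
#' @param seed RNG seed.
#' @return List of class `migration_series`: `frame_0h`, `frame_24h` (y, x
#'   matrices), `pixel_size_um`, `truth` (list with `true_area_0h_um2`,
#'   `true_area_24h_um2`, `true_ratio`).
#' @export
generate_migration_series <- function(r0_um, r24_um, frame_shape = c(300L, 300L),
                                      pixel_size_um = 1, intensity = 100,
                                      noise = c(gaussian_sd = 2,
                                                background_offset = 5),
                                      seed = 1L) {
  stopifnot_scalar_positive(r0_um, "r0_um")
  if (r24_um < r0_um) abort("`r24_um` must be >= `r0_um`.")
  ny <- frame_shape[1]; nx <- frame_shape[2]
  r24_px <- r24_um / pixel_size_um
  if (2 * r24_px + 4 > min(ny, nx)) {
    abort(sprintf("Disk of radius %.0f px does not fit in a %d x %d frame.",
                  r24_px, ny, nx))
  }
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  dist <- sqrt(outer((seq_len(ny) - 1 - cy)^2, (seq_len(nx) - 1 - cx)^2, "+"))
  render <- function(r_px) {
    # 1-px anti-aliased edge: coverage ramp of the pixel across the rim
    cov <- pmin(pmax(r_px - dist + 0.5, 0), 1)
    intensity * cov
  }
  with_preserved_seed(seed, {
    noisy <- function(img) {
      img <- img + matrix(rnorm(length(img), 0, noise[[1]]), nrow(img))
      pmax(img + noise[[2]], 0)
    }
    f0 <- noisy(render(r0_um / pixel_size_um))
    f24 <- noisy(render(r24_px))
    structure(
      list(frame_0h = f0, frame_24h = f24, pixel_size_um = pixel_size_um,
           truth = list(true_area_0h_um2 = pi * r0_um^2,
                        true_area_24h_um2 = pi * r24_um^2,
                        true_ratio = (r24_um / r0_um)^2)),
      class = "migration_series"
    )
  })
}

#' Generate a synthetic dose-viability table from a 4PL ground truth
#'
#' Viability at dose `d` follows the four-parameter logistic
#' `bottom + (top - bottom) / (1 + (d / ic50)^hill)`, multiplied by
#' `1 + N(0, cv)` noise and floored at zero.
#'
#' @param true_ic50 Ground-truth IC50 (same units as `doses`).
#' @param hill Hill slope (> 0 for a decreasing viability curve).
#' @param top,bottom Upper/lower asymptotes, `0 <= bottom < top`.
#' @param doses Positive dose vector.
#' @param cv Coefficient of variation of multiplicative noise.
#' @param replicates Replicates per dose.
#' @param seed RNG seed.
#' @return A tibble with columns `dose`, `replicate`, `viability`, and the
#'   ground truth in attribute `truth`.
#' @export
generate_dose_response <- function(true_ic50, hill = 1, top = 1, bottom = 0,
                                   doses = 10^seq(-1, 5, length.out = 8),
                                   cv = 0, replicates = 3L, seed = 1L) {
  stopifnot_scalar_positive(true_ic50, "true_ic50")
  if (any(doses <= 0)) abort("All doses must be positive.")
  if (bottom < 0 || bottom >= top) abort("Require 0 <= bottom < top.")
  mu <- four_pl(doses, top, bottom, true_ic50, hill)
  with_preserved_seed(seed, {
    out <- tidyr::expand_grid(dose = doses, replicate = seq_len(replicates))
    mu_rep <- rep(mu, each = replicates)
    eps <- if (cv > 0) rnorm(nrow(out), 0, cv) else 0
    out$viability <- pmax(mu_rep * (1 + eps), 0)
    attr(out, "truth") <- list(ic50 = true_ic50, hill = hill, top = top,
                               bottom = bottom, cv = cv)
    out
  })
}

#' Generate a grouped assembloid dataset with per-group effects
#'
#' Emulates a multi-arm infiltration experiment (e.g. nontarget control vs
#' integrin knockdowns): for each group, `n_images` replicate scenes are
#' generated from `base_params` with a per-group multiplicative effect
#' applied either to the number of infiltrating cells (`effect_on =
#' "n_cells"`) or to all marker effect sizes (`effect_on = "marker"`). Scene
#' seeds are a deterministic function of `(seed, group index, replicate)`.
#'
#' @param effects Named numeric: per-group effect multiplier; names are the
#'   group labels and must include `control`.
#' @param n_images Scenes per group.
#' @param base_params [scene_params()] shared by all groups.
#' @param control Name of the control group.
#' @param effect_on `"n_cells"` or `"marker"`.
#' @param seed Base RNG seed.
#' @return A tibble with columns `group`, `replicate`, `effect`, `scene`
#'   (list column of `assembloid_scene`), with attribute `control`.
#' @export
generate_group_dataset <- function(effects, n_images = 5L,
                                   base_params = scene_params(),
                                   control = "NT",
                                   effect_on = c("n_cells", "marker"),
                                   seed = 1L) {
  effect_on <- match.arg(effect_on)
  if (length(effects) < 2L || is.null(names(effects))) {
    abort("`effects` must be a named vector with at least 2 groups.")
  }
  if (!control %in% names(effects)) {
    abort(sprintf("No control group designated: '%s' is not among the groups (%s).",
                  control, paste(names(effects), collapse = ", ")))
  }
  grid <- tidyr::expand_grid(group = names(effects),
                             replicate = seq_len(n_images))
  grid$effect <- effects[grid$group]
  grid$scene <- purrr::pmap(grid, function(group, replicate, effect) {
    p <- base_params
    gi <- match(group, names(effects))
    p$seed <- as.integer((seed * 1000 + gi * 100 + replicate) %% 2147483647)
    if (effect_on == "n_cells") {
      p$n_cells <- as.integer(round(p$n_cells * effect))
    } else {
      p$marker_effect <- p$marker_effect * effect
    }
    generate_assembloid_scene(p)
  })
  attr(grid, "control") <- control
  grid
}

#' Write a grouped dataset to disk with a loadable manifest
#'
#' Writes every scene (TIFF + ROI + truth JSON) plus a `manifest.csv` that
#' [load_manifest()] accepts unchanged, closing the generator-loader
#' contract.
#'
#' @param dataset Output of [generate_group_dataset()].
#' @param dir Output directory.
#' @param treatment Treatment label recorded for every image (single-arm
#'   datasets); default `"untreated"`.
#' @return Path of the written manifest.
#' @export
write_group_dataset <- function(dataset, dir, treatment = "untreated") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  control <- attr(dataset, "control")
  rows <- purrr::pmap(dataset, function(group, replicate, effect, scene) {
    name <- sprintf("%s_rep%02d", group, replicate)
    paths <- write_scene(scene, dir, name)
    tibble::tibble(
      image = basename(paths[["stack"]]), roi = basename(paths[["roi_json"]]),
      group = group, treatment = treatment, replicate = replicate,
      channels = paste(scene$stack$channel_names, collapse = ";"),
      control = group == control, untreated = treatment == "untreated"
    )
  })
  manifest <- dplyr::bind_rows(rows)
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path)
  path
}

# 4PL mean response (decreasing in dose for hill > 0)
four_pl <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}
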