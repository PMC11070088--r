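# Shared fixtures and independent oracles, all built in code.

# Axis-aligned square ROI with corners at (lo, lo) and (hi, hi).
square_roi <- function(lo = 0, hi = 10) {
  boundary_roi(cbind(x = c(lo, hi, hi, lo), y = c(lo, lo, hi, hi)))
}

# Random star-shaped polygon around a center: strictly increasing angles with
# random radii, hence always simple.
random_star_polygon <- function(n_vertices, cx = 0, cy = 0,
                                r_min = 5, r_max = 15) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  # guard against duplicate angles (zero-length edges)
  while (any(diff(th) < 1e-6)) th <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_min, r_max)
  boundary_roi(cbind(x = cx + r * cos(th), y = cy + r * sin(th)))
}

# Winding-number point-in-polygon oracle: sum of signed angle increments.
winding_number_oracle <- function(px, py, roi) {
  v <- unclass(roi)
  n <- nrow(v)
  total <- rep(0, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(v[i, 2] - py, v[i, 1] - px)
    a2 <- atan2(v[j, 2] - py, v[j, 1] - px)
    d <- a2 - a1
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    total <- total + d
  }
  abs(total) > pi   # ~2*pi inside, ~0 outside
}
# Dense boundary-sampling distance oracle, hierarchically refined: a coarse
# pass over the whole boundary picks candidate segments (all within two
# coarse spacings of the best), then each candidate is re-sampled at
# 1e-4-px spacing around its own best coarse sample.
dense_distance_oracle <- function(px, py, roi, coarse = 0.05, fine = 1e-4) {
  v <- unclass(roi)
  n <- nrow(v)
  x2 <- c(v[-1, 1], v[1, 1]); y2 <- c(v[-1, 2], v[1, 2])
  seg_len <- sqrt((x2 - v[, 1])^2 + (y2 - v[, 2])^2)
  counts <- pmax(ceiling(seg_len / coarse), 2)
  bx <- by <- seg_id <- t_of <- vector("list", n)
  for (s in seq_len(n)) {
    t <- seq(0, 1, length.out = counts[s])
    bx[[s]] <- v[s, 1] + t * (x2[s] - v[s, 1])
    by[[s]] <- v[s, 2] + t * (y2[s] - v[s, 2])
    seg_id[[s]] <- rep(s, counts[s]); t_of[[s]] <- t
  }
  bx <- unlist(bx); by <- unlist(by)
  seg_id <- unlist(seg_id); t_of <- unlist(t_of)
  out <- numeric(length(px))
  for (q in seq_along(px)) {
    d2 <- (bx - px[q])^2 + (by - py[q])^2
    best_d <- sqrt(min(d2))
    near <- d2 <= (best_d + 2 * coarse)^2
    cand <- unique(seg_id[near])
    best <- Inf
    for (s in cand) {
      in_seg <- which(seg_id == s & near)
      b <- in_seg[which.min(d2[in_seg])]
      halfwin <- (coarse * 1.5) / seg_len[s]
      tt <- seq(max(t_of[b] - halfwin, 0), min(t_of[b] + halfwin, 1),
                by = fine / seg_len[s])
      fx <- v[s, 1] + tt * (x2[s] - v[s, 1])
      fy <- v[s, 2] + tt * (y2[s] - v[s, 2])
      d2f <- (fx - px[q])^2 + (fy - py[q])^2
      best <- min(best, min(d2f))
      # d^2 is exactly quadratic in t on a segment: one parabolic step
      # through the best sample and its neighbors lands on the true vertex
      j <- which.min(d2f)
      if (j > 1L && j < length(tt)) {
        denom <- d2f[j + 1L] - 2 * d2f[j] + d2f[j - 1L]
        if (denom > 0) {
          tstar <- tt[j] - 0.5 * (tt[j + 1L] - tt[j]) *
            (d2f[j + 1L] - d2f[j - 1L]) / denom
          tstar <- min(max(tstar, 0), 1)
          best <- min(best, (v[s, 1] + tstar * (x2[s] - v[s, 1]) - px[q])^2 +
                        (v[s, 2] + tstar * (y2[s] - v[s, 2]) - py[q])^2)
        }
      }
    }
    out[q] <- sqrt(best)
  }
  out
}

# Uniform random interior points of a polygon via bounding-box rejection.
random_interior_points <- function(n, roi) {
  v <- unclass(roi)
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    cx <- runif(4L * n, min(v[, 1]), max(v[, 1]))
    cy <- runif(4L * n, min(v[, 2]), max(v[, 2]))
    keep <- point_in_polygon(cbind(cx, cy), roi)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# Small fast scene for pipeline tests; ... overrides any default.
small_scene_params <- function(seed = 1L, ...) {
  defaults <- list(
    image_shape = c(2L, 128L, 128L),
    organoid_polygon = ellipse_recipe(64, 64, 48, 42, n_vertices = 40L, jitter = 0.02),
    n_cells = 60L, decay_length_um = 20, nuclear_density = 0.004,
    seed = seed
  )
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

# A projection2d built directly from per-channel matrices (single z-plane).
projection_from_matrices <- function(..., pixel_size_um = 1) {
  mats <- list(...)
  arr <- array(0, dim = c(dim(mats[[1]]), 1L, length(mats)))
  for (i in seq_along(mats)) arr[, , 1L, i] <- mats[[i]]
  max_project(image_stack(arr, channel_names = names(mats),
                          pixel_size_um = pixel_size_um))
}
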