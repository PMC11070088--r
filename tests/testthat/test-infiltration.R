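make_square_setup <- function(side = 16, shape = c(20, 20)) {
  roi <- square_roi(0, side)
  field <- interior_distance_field(roi, shape)
  list(roi = roi, field = field)
}

test_that("shell means: constants, indicators, and a pixel-loop oracle", {
  s <- make_square_setup()
  b <- bin_shells(s$field, 4)
  const <- matrix(3.7, 20, 20)
  proj <- projection_from_matrices(DAPI = const, eGFP = 2 * const)
  pr <- shell_profile(proj, b)
  expect_true(all(pr$mean_intensity[pr$channel == "DAPI"] == 3.7))
  expect_true(all(pr$mean_intensity[pr$channel == "eGFP"] == 7.4))

  # indicator of shell 3
  ind <- matrix(0, 20, 20)
  ind[b$shell_label == 3L & !is.na(b$shell_label)] <- 1
  proj_i <- projection_from_matrices(DAPI = const, mark = ind)
  pr_i <- shell_profile(proj_i, b, channels = "mark")
  expect_equal(pr_i$mean_intensity, c(0, 0, 1, 0))

  # random image vs explicit per-pixel loop
  set.seed(8)
  img <- matrix(runif(400), 20, 20)
  pr_r <- shell_profile(projection_from_matrices(DAPI = img), b, "DAPI")
  for (sh in 1:4) {
    vals <- c()
    for (r in 1:20) for (cc in 1:20) {
      if (!is.na(b$shell_label[r, cc]) && b$shell_label[r, cc] == sh) {
        vals <- c(vals, img[r, cc])
      }
    }
    expect_equal(pr_r$mean_intensity[pr_r$shell == sh], mean(vals))
  }
  expect_error(shell_profile(proj, b, channels = "absent"), "not found")
})

test_that("per-shell infiltration metric is a ratio of means with NA on empty nuclei", {
  s <- make_square_setup()
  b <- bin_shells(s$field, 4)
  dapi <- matrix(runif(400, 1, 2), 20, 20)
  proj <- projection_from_matrices(DAPI = dapi, eGFP = 2 * dapi)
  m <- infiltration_metric(shell_profile(proj, b))
  expect_equal(m$metric, rep(2, 4))
  proj0 <- projection_from_matrices(DAPI = dapi, eGFP = 0 * dapi)
  expect_equal(infiltration_metric(shell_profile(proj0, b))$metric, rep(0, 4))
  # joint positive rescaling leaves the metric unchanged
  projc <- projection_from_matrices(DAPI = 13.5 * dapi, eGFP = 13.5 * 2 * dapi)
  expect_equal(infiltration_metric(shell_profile(projc, b))$metric, rep(2, 4))
  # zero nuclear mean in one shell -> NA, not 0 or Inf
  dapi2 <- dapi
  dapi2[b$shell_label == 2L & !is.na(b$shell_label)] <- 0
  proj2 <- projection_from_matrices(DAPI = dapi2, eGFP = matrix(1, 20, 20))
  m2 <- infiltration_metric(shell_profile(proj2, b))
  expect_true(is.na(m2$metric[2]))
  expect_false(anyNA(m2$metric[-2]))
  projz <- projection_from_matrices(DAPI = matrix(0, 20, 20), eGFP = dapi)
  expect_error(infiltration_metric(shell_profile(projz, b)), "nuclear")
})

test_that("total infiltration: thresholds, uniform ratio, and shell consistency", {
  s <- make_square_setup()
  proj <- projection_from_matrices(DAPI = matrix(4, 20, 20),
                                   eGFP = matrix(6, 20, 20))
  for (th in c(0, 2, 5)) {
    expect_equal(total_infiltration(proj, s$field, th), 1.5)
  }
  expect_equal(total_infiltration(proj, s$field, 0.5, mode = "past_percent"), 1.5)
  expect_error(total_infiltration(proj, s$field, 1e5), "threshold")
  # threshold 0 equals the count-weighted combination of shell means
  set.seed(3)
  dapi <- matrix(runif(400, 1, 2), 20, 20)
  egfp <- matrix(runif(400, 0, 3), 20, 20)
  projr <- projection_from_matrices(DAPI = dapi, eGFP = egfp)
  b <- bin_shells(s$field, 5)
  pr <- infiltration_metric(shell_profile(projr, b))
  whole <- total_infiltration(projr, s$field, 0)
  expect_equal(whole,
               sum(pr$n_pixels * pr$tumor_mean) / sum(pr$n_pixels * pr$nuclear_mean))
})

test_that("marker ratios: trivials, loop oracle, and region selection", {
  s <- make_square_setup()
  set.seed(12)
  dapi <- matrix(runif(400, 0.5, 2), 20, 20)
  proj <- projection_from_matrices(DAPI = dapi, CC3 = dapi)
  expect_equal(marker_ratio(proj, "CC3"), 1)
  proj0 <- projection_from_matrices(DAPI = dapi, CC3 = 0 * dapi)
  expect_equal(marker_ratio(proj0, "CC3"), 0)
  cc3 <- matrix(runif(400, 0, 5), 20, 20)
  projr <- projection_from_matrices(DAPI = dapi, CC3 = cc3)
  num <- 0; den <- 0
  for (r in 1:20) for (cc in 1:20) { num <- num + cc3[r, cc]; den <- den + dapi[r, cc] }
  expect_equal(marker_ratio(projr, "CC3"), num / den)
  # interface band: only pixels within the band width contribute
  band <- marker_ratio(projr, "CC3", region = "interface_band",
                       field = s$field, band_width_um = 3)
  idx <- which(s$field$interior_mask & s$field$depth_um <= 3)
  expect_equal(band, sum(cc3[idx]) / sum(dapi[idx]))
  interior <- marker_ratio(projr, "CC3", region = "interior", field = s$field)
  idx2 <- which(s$field$interior_mask)
  expect_equal(interior, sum(cc3[idx2]) / sum(dapi[idx2]))
  expect_error(marker_ratio(projr, "CC3", region = "interior"), "field")
  projz <- projection_from_matrices(DAPI = 0 * dapi, CC3 = cc3)
  expect_error(marker_ratio(projz, "CC3"), "zero")
})

test_that("ratio metrics scale linearly under numerator-only rescaling", {
  s <- make_square_setup()
  set.seed(4)
  dapi <- matrix(runif(400, 1, 2), 20, 20)
  egfp <- matrix(runif(400, 0, 2), 20, 20)
  p1 <- projection_from_matrices(DAPI = dapi, eGFP = egfp)
  p3 <- projection_from_matrices(DAPI = dapi, eGFP = 3 * egfp)
  expect_equal(total_infiltration(p3, s$field, 0),
               3 * total_infiltration(p1, s$field, 0))
  expect_equal(marker_ratio(p3, "eGFP"), 3 * marker_ratio(p1, "eGFP"))
})

test_that("normalization to untreated control is exact and within-group", {
  df <- tidyr::expand_grid(group = c("NT", "KD1", "KD2"),
                           treatment = c("untreated", "5Gy"),
                           replicate = 1:3)
  set.seed(6)
  df$ratio <- runif(nrow(df), 0.5, 2)
  out <- normalize_to_control(df, ratio, group, treatment)
  means <- tapply(out$relative_value[out$treatment == "untreated"],
                  out$group[out$treatment == "untreated"], mean)
  expect_equal(as.numeric(means), rep(1, 3))
  # treated ratio 3x the untreated mean -> relative value 3
  un_mean <- mean(df$ratio[df$group == "NT" & df$treatment == "untreated"])
  df2 <- rbind(df, data.frame(group = "NT", treatment = "5Gy", replicate = 9,
                              ratio = 3 * un_mean))
  out2 <- normalize_to_control(df2, ratio, group, treatment)
  expect_equal(out2$relative_value[nrow(out2)], 3)
  # group lacking an untreated arm is rejected by name
  df3 <- df[!(df$group == "KD2" & df$treatment == "untreated"), ]
  expect_error(normalize_to_control(df3, ratio, group, treatment), "KD2")
})

test_that("marker effect is recovered through the ratio + normalization chain", {
  gains <- c(DAPI = 100, eGFP = 120, CC3 = 100)
  make_arm <- function(effect, seed_base) {
    vapply(1:4, function(r) {
      p <- small_scene_params(seed = seed_base + r,
                              channel_gains = gains,
                              marker_effect = c(CC3 = effect),
                              noise = c(0.05, 1, 0.5))
      sc <- generate_assembloid_scene(p)
      marker_ratio(max_project(sc$stack), "CC3")
    }, 0)
  }
  untreated <- make_arm(1, 100)
  treated <- make_arm(2.5, 200)
  df <- tibble::tibble(
    group = "NT",
    treatment = rep(c("untreated", "panobinostat"), each = 4),
    ratio = c(untreated, treated)
  )
  out <- normalize_to_control(df, ratio, group, treatment)
  rel <- mean(out$relative_value[out$treatment == "panobinostat"])
  expect_equal(rel, 2.5, tolerance = 0.1)
})

test_that("per-cell marker distances recover known depths", {
  p <- scene_params(
    image_shape = c(1L, 200L, 200L),
    organoid_polygon = ellipse_recipe(100, 100, 80, 72, n_vertices = 56L),
    n_cells = 1L, decay_length_um = 30, nuclear_density = 0.001,
    channel_gains = c(DAPI = 100, eGFP = 120, H3K27M = 150),
    noise = c(0, 0.5, 2), min_separation_um = 15, seed = 21L
  )
  sc <- generate_assembloid_scene(p)
  det <- h3k27m_distances(max_project(sc$stack), sc$roi)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$distance_um - sc$truth$cell_positions$depth_um), 1)
})

test_that("exterior marker-positive cells are excluded and counted", {
  # one synthetic blob outside the polygon
  img <- matrix(0, 60, 60)
  img <- assembloidq:::add_blob(img, 50, 8, 2, 100)   # (x=50, y=8)
  roi <- square_roi(5, 35)
  proj <- projection_from_matrices(DAPI = matrix(1, 60, 60), H3K27M = img)
  det <- h3k27m_distances(proj, roi)
  expect_equal(nrow(det), 0L)
  expect_equal(attr(det, "n_exterior"), 1L)
  # no detections: sub-threshold-size blob and constant channel both give
  # an empty result, not an error
  tiny <- assembloidq:::add_blob(matrix(0, 60, 60), 20, 20, 0.8, 50)
  det2 <- h3k27m_distances(
    projection_from_matrices(DAPI = matrix(1, 60, 60), H3K27M = tiny),
    roi, min_area_px = 50L)
  expect_equal(nrow(det2), 0L)
  det3 <- h3k27m_distances(
    projection_from_matrices(DAPI = matrix(1, 60, 60),
                             H3K27M = matrix(0, 60, 60)), roi)
  expect_equal(nrow(det3), 0L)
})
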