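test_that("spot detection finds isolated phantom spots with voxel accuracy", {
  geo <- voxel_geometry(3.25, 10)
  heart <- array(TRUE, c(90, 90, 30))
  set.seed(21)
  placed <- place_spots(heart, geo, n_spots = 50, min_sep_um = 28,
                        peak_range = c(18000, 22000))
  ch <- volume_image(cardioclear3d:::add_noise(placed$channel$voxels, 20, 100),
                     "Ly6G", geo)
  det <- detect_spots(ch)
  expect_equal(nrow(det), 50)
  truth <- as.matrix(placed$spots[, c("x_um", "y_um", "z_um")])
  found <- as.matrix(det[, c("x_um", "y_um", "z_um")])
  nn <- vapply(seq_len(nrow(truth)), function(i)
    min(sqrt(rowSums(sweep(found, 2, truth[i, ])^2))), numeric(1))
  expect_true(all(nn <= sqrt(2 * 3.25^2 + 10^2)))  # within one voxel diagonal
  # lateral localization within one pixel
  nn_xy <- vapply(seq_len(nrow(truth)), function(i)
    min(sqrt(rowSums(sweep(found[, 1:2], 2, truth[i, 1:2])^2))), numeric(1))
  expect_lt(median(nn_xy), 3.25)
})

test_that("the intensity band is inclusive and rejects out-of-band peaks", {
  geo <- voxel_geometry(3.25, 10)
  heart <- array(TRUE, c(40, 40, 16))
  set.seed(4)
  bright <- place_spots(heart, geo, n_spots = 1, peak_range = c(52000, 52000))
  det <- detect_spots(bright$channel, band = c(4500, 35000), geometry = geo)
  expect_equal(nrow(det), 0)
  det2 <- detect_spots(bright$channel, band = c(4500, 65535), geometry = geo)
  expect_equal(nrow(det2), 1)
  expect_error(detect_spots(bright$channel, band = c(100, 10), geometry = geo),
               "inverted")
  empty <- detect_spots(array(0, c(20, 20, 10)), geometry = geo)
  expect_equal(nrow(empty), 0)
})

test_that("spots are labeled by containment with infarct precedence", {
  geo <- voxel_geometry(3.25, 10)
  d <- c(40, 40, 20)
  aar <- array(FALSE, d); aar[5:35, 5:35, 3:17] <- TRUE
  infarct <- array(FALSE, d); infarct[15:25, 15:25, 8:12] <- TRUE
  spots <- data.frame(x_um = c(60, 40, 125),  # inside infarct / aar-only / out
                      y_um = c(60, 40, 125),
                      z_um = c(95, 80, 185))
  lab <- classify_spots_by_region(spots, list(aar = aar, infarct = infarct), geo)
  expect_equal(lab$region, c("infarct", "aar", "outside"))
})

test_that("signed border distances match the analytic sphere profile", {
  geo <- voxel_geometry(2, 2)
  d <- c(50, 50, 50)
  centre <- c(49, 49, 49)
  ball <- ellipsoid_mask(d, geo, centre, c(30, 30, 30))
  sdist <- cardioclear3d:::signed_border_distance(ball, voxel_spacing(geo))
  diag_um <- sqrt(sum(voxel_spacing(geo)^2))
  probes <- rbind(c(25, 25, 25), c(40, 25, 25), c(25, 10, 25), c(5, 25, 25))
  for (i in seq_len(nrow(probes))) {
    p <- probes[i, ]
    r <- sqrt(sum(((p - 1) * 2 - centre)^2))
    expected <- r - 30
    expect_lt(abs(sdist[p[1], p[2], p[3]] - expected), 1.5 * diag_um)
  }
})

test_that("uniform spots give relative shell density 1, shell-bound gives the ratio", {
  geo <- voxel_geometry(3.25, 10)
  d <- c(80, 80, 30)
  heart <- array(FALSE, d); heart[5:76, 5:76, 3:28] <- TRUE
  border <- array(FALSE, d); border[30:50, 30:50, 10:20] <- TRUE
  rels <- vapply(1:6, function(s) {
    set.seed(100 + s)
    sp <- place_spots(heart, geo, n_spots = 250, shell_enrichment = 1)
    border_shell_density(sp$spots, border, heart, geo, 30)$relative_density
  }, numeric(1))
  # binomial sampling error on the mean over 6 seeds
  expect_lt(abs(mean(rels) - 1), 0.15)

  set.seed(77)
  sp_in <- place_spots(heart, geo, n_spots = 200, border_mask = border,
                       shell_enrichment = Inf, shell_halfwidth_um = 30)
  bd <- border_shell_density(sp_in$spots, border, heart, geo, 30)
  expect_rel_error(bd$relative_density,
                   bd$heart_volume_mm3 / bd$shell_volume_mm3, 0.05)

  # no spots near the border -> 0
  far <- data.frame(x_um = 10, y_um = 10, z_um = 40)
  expect_equal(border_shell_density(far, border, heart, geo, 30)$relative_density, 0)
})

test_that("relative density is invariant to uniform thinning of spots", {
  geo <- voxel_geometry(3.25, 10)
  d <- c(60, 60, 24)
  heart <- array(TRUE, d)
  border <- array(FALSE, d); border[20:40, 20:40, 8:16] <- TRUE
  set.seed(31)
  sp <- place_spots(heart, geo, n_spots = 400, shell_enrichment = 1)
  full <- border_shell_density(sp$spots, border, heart, geo, 30)$relative_density
  thin <- sp$spots[sample.int(400, 200), ]
  half <- border_shell_density(thin, border, heart, geo, 30)$relative_density
  expect_lt(abs(full - half), 0.35)
})
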