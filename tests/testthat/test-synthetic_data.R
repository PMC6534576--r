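test_that("generated network hits the length budget (bookkeeping oracle)", {
  geo <- voxel_geometry(2, 2)
  d <- c(100, 100, 100)  # (200 µm)^3
  mask <- array(TRUE, d)
  set.seed(5)
  net <- generate_vessel_network(mask, geo, target_vld = 100, ibd_um = 65)
  total_mm <- graph_total_length(net) / 1000
  # independent oracle: re-sum polyline segment lengths
  oracle_mm <- sum(vapply(net$paths, function(p)
    sum(sqrt(rowSums(diff(p)^2))), numeric(1))) / 1000
  expect_equal(total_mm, oracle_mm, tolerance = 1e-10)
  expect_rel_error(total_mm, 0.8, 0.10)
})

test_that("zero target yields an empty network, same seed identical output", {
  geo <- voxel_geometry(3.25, 10)
  mask <- array(TRUE, c(30, 30, 10))
  empty <- generate_vessel_network(mask, geo, target_vld = 0)
  expect_equal(nrow(empty$edges), 0)

  set.seed(11); a <- generate_vessel_network(mask, geo, 800, 65)
  set.seed(11); b <- generate_vessel_network(mask, geo, 800, 65)
  expect_identical(a$paths, b$paths)
})

test_that("rasterized straight tube matches the analytic cylinder volume", {
  fx <- tube_fixture(radius_um = 6, len_um = 200, spacing = c(2, 2, 2))
  mask <- as.array(fx$volume$voxels >= 5000)  # half peak
  analytic_vox <- pi * fx$radius_um^2 * fx$len_um / prod(voxel_spacing(fx$geometry))
  expect_rel_error(sum(mask), analytic_vox, 0.20)
})

test_that("empty graphs rasterize to zero and voids are zeroed", {
  geo <- voxel_geometry(2, 2)
  g0 <- vessel_graph(matrix(numeric(), ncol = 3), list(),
                     matrix(integer(), ncol = 2))
  v0 <- rasterize_vessels(g0, geo, c(10, 10, 10))
  expect_true(all(v0$voxels == 0))

  fx <- tube_fixture()
  void <- array(FALSE, fx$dim)
  void[seq_len(fx$dim[1] / 2), , ] <- TRUE
  vv <- rasterize_vessels(fx$graph, fx$geometry, fx$dim, radius_um = 6,
                          void_mask = void)
  expect_true(all(vv$voxels[void] == 0))
  expect_gt(sum(vv$voxels[!void]), 0)
})

test_that("spot placement respects counts, bounds and the shell-bound limit", {
  geo <- voxel_geometry(3.25, 10)
  heart <- array(FALSE, c(60, 60, 24))
  heart[10:50, 10:50, 5:20] <- TRUE
  none <- place_spots(heart, geo, n_spots = 0)
  expect_equal(nrow(none$spots), 0)
  expect_true(all(none$channel$voxels == 0))

  set.seed(3)
  border <- array(FALSE, dim(heart)); border[25:35, 25:35, 10:14] <- TRUE
  sp_all <- place_spots(heart, geo, n_spots = 120, border_mask = border,
                        shell_enrichment = Inf, shell_halfwidth_um = 30)
  bd <- border_shell_density(sp_all$spots, border, heart, geo, 30)
  # closed form: all spots in the shell -> ratio = V_heart / V_shell
  expect_rel_error(bd$relative_density,
                   bd$heart_volume_mm3 / bd$shell_volume_mm3, 0.05)
})

test_that("full phantom is deterministic and truth masks are nested", {
  ph <- small_phantom()
  ph2 <- generate_phantom(phantom_config(seed = 42, dim = c(96, 96, 32),
                                         n_spots = 60))
  expect_identical(ph$channels$CD31$voxels, ph2$channels$CD31$voxels)
  expect_identical(ph$channels$Ly6G$voxels, ph2$channels$Ly6G$voxels)

  m <- ph$truth$masks
  expect_true(all(!m$infarct | m$aar))   # infarct inside AAR
  expect_true(all(!m$aar | m$heart))     # AAR inside heart
  expect_true(all(!m$curly | m$heart))

  # every spot lies inside the heart mask
  sp <- voxel_spacing(ph$config$geometry)
  idx <- cbind(round(ph$truth$spots$x_um / sp[1]) + 1,
               round(ph$truth$spots$y_um / sp[2]) + 1,
               round(ph$truth$spots$z_um / sp[3]) + 1)
  expect_true(all(m$heart[idx]))
})

test_that("configured AAR wedge fraction is honoured within one point", {
  ph <- small_phantom()
  frac <- sum(ph$truth$masks$aar) / sum(ph$truth$masks$heart)
  expect_lt(abs(frac - 0.29), 0.01)
})

test_that("edge rim raises the autofluorescence edge-homogeneity ratio", {
  base <- phantom_config(seed = 9, dim = c(64, 64, 24), aar_fraction = 0,
                         n_spots = 0, target_vld = 0)
  rim <- phantom_config(seed = 9, dim = c(64, 64, 24), aar_fraction = 0,
                        n_spots = 0, target_vld = 0,
                        rim_amplitude = 12000, rim_width_um = 12)
  ph0 <- generate_phantom(base)
  ph1 <- generate_phantom(rim)
  mid <- (dim(ph0$channels$autofluorescence$voxels) / 2) *
    voxel_spacing(base$geometry)
  args <- list(start_um = c(0, mid[2], mid[3]), end_um = c(mid[1], mid[2], mid[3]),
               n_samples = 80)
  r0 <- do.call(edge_homogeneity_ratio,
                c(list(ph0$channels$autofluorescence), args))
  r1 <- do.call(edge_homogeneity_ratio,
                c(list(ph1$channels$autofluorescence), args))
  expect_lt(abs(r0 - 1), 0.35)
  expect_gt(r1, r0)
})
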