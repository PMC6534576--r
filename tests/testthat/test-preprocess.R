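test_that("Gaussian smoothing preserves constants and interior mass", {
  geo <- voxel_geometry(3.25, 10)
  const <- volume_image(array(1234, c(12, 12, 8)), "other", geo)
  out <- gaussian_smooth(const, 2)
  expect_equal(max(abs(out$voxels - 1234)), 0, tolerance = 1e-9)

  # impulse far from the border: total intensity conserved to < 0.1%
  imp <- array(0, c(21, 21, 15))
  imp[11, 11, 8] <- 1
  sm <- gaussian_smooth(imp, 2, geometry = geo)
  expect_lt(abs(sum(sm) - 1), 1e-3)
})

test_that("impulse response matches the separable Gaussian closed form", {
  geo <- voxel_geometry(3.25, 10)
  imp <- array(0, c(21, 21, 15))
  imp[11, 11, 8] <- 1
  sm <- gaussian_smooth(imp, 2, geometry = geo)
  sig <- physical_to_voxel_sigma(2, geo)  # (0.615, 0.615, 0.2) voxels
  gk <- function(d, s) {
    h <- max(1L, ceiling(3 * s))
    k <- exp(-(-h:h)^2 / (2 * s^2)); k <- k / sum(k)
    ifelse(abs(d) <= h, k[d + h + 1], 0)
  }
  for (probe in list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 1), c(2, 1, 1))) {
    expected <- gk(probe[1], sig[1]) * gk(probe[2], sig[2]) * gk(probe[3], sig[3])
    expect_equal(sm[11 + probe[1], 11 + probe[2], 8 + probe[3]], expected,
                 tolerance = 1e-10)
  }
})

test_that("rolling ball removes background and preserves small peaks", {
  geo <- voxel_geometry(2, 2)
  expect_equal(max(abs(as_vox <- rolling_ball_subtract(
    array(500, c(16, 16, 16)), 20, geometry = geo))), 0)

  # ramp background + bright 5 µm spot
  d <- c(40, 40, 20)
  ramp <- array(rep(seq(100, 500, length.out = d[1]), times = prod(d[2:3])),
                dim = d)
  spot <- array(0, d)
  xs <- ((seq_len(d[1]) - 1) * 2 - 40)
  ys <- ((seq_len(d[2]) - 1) * 2 - 40)
  zs <- ((seq_len(d[3]) - 1) * 2 - 20)
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  spot[r2 <= 2.5^2] <- 4000
  out <- rolling_ball_subtract(ramp + spot, 20, geometry = geo)
  peak_in <- max((ramp + spot)[spot > 0]) - max(ramp[spot > 0])
  peak_out <- max(out[spot > 0])
  expect_gt(peak_out, 0.9 * peak_in)
  # background suppressed in the interior (boundary artifacts of the opening
  # are expected and removed by later thresholding)
  interior <- array(FALSE, d); interior[12:28, 12:28, 6:15] <- TRUE
  expect_lt(max(out[spot == 0 & interior]), 0.05 * max(ramp))

  # oracle: output must equal input minus its own grayscale opening
  sp <- voxel_spacing(geo)
  off <- cardioclear3d:::ball_offsets(20, sp)
  er <- array(cardioclear3d:::cc_gray_morph(ramp + spot, d, off, FALSE), d)
  op <- array(cardioclear3d:::cc_gray_morph(er, d, off, TRUE), d)
  expect_equal(max(abs(out - pmax(ramp + spot - op, 0))), 0, tolerance = 1e-9)

  expect_warning(rolling_ball_subtract(array(1, c(4, 4, 4)), 0.5, geometry = geo),
                 "smaller than one voxel")
})

test_that("Frangi vesselness prefers tubes over plates and blobs", {
  geo <- voxel_geometry(2, 2)
  d <- c(40, 40, 40)
  zeros <- frangi_vesselness(array(7, d), geometry = geo)
  expect_true(all(zeros == 0))

  coords <- (seq_len(40) - 1) * 2 - 39
  tube <- array(0, d); plate <- array(0, d); sphere <- array(0, d)
  for (x in 1:40) tube[x, , ] <- 1000 * (outer(coords^2, coords^2, "+") <= 36)
  for (x in 1:40) for (y in 1:40) plate[x, y, ] <- 1000 * (coords^2 <= 36)
  r2 <- outer(outer(coords^2, coords^2, "+"), coords^2, "+")
  sphere[r2 <= 36] <- 1000

  vt <- frangi_vesselness(tube, scales_um = c(4, 6), geometry = geo)
  vp <- frangi_vesselness(plate, scales_um = c(4, 6), geometry = geo)
  vs <- frangi_vesselness(sphere, scales_um = c(4, 6), geometry = geo)
  expect_gt(vt[20, 20, 20], vp[20, 20, 20])
  expect_gt(vt[20, 20, 20], vs[20, 20, 20])
  expect_true(all(vt >= 0 & vt <= 1))

  # invariance to a constant offset
  vt2 <- frangi_vesselness(tube + 500, scales_um = c(4, 6), geometry = geo)
  expect_equal(vt2[20, 20, 20], vt[20, 20, 20], tolerance = 1e-8)
})

test_that("in-plane rotation changes the tube axis response by < 5%", {
  geo <- voxel_geometry(2, 2)
  d <- c(50, 50, 24)
  mk_tube <- function(theta) {
    ctr <- c(48, 48, 22)
    dir <- c(cos(theta), sin(theta), 0)
    p1 <- ctr - 60 * dir; p2 <- ctr + 60 * dir
    g <- vessel_graph(rbind(p1, p2), list(rbind(p1, p2)), matrix(c(1, 2), 1))
    rasterize_vessels(g, geo, d, radius_um = 5, peak = 10000, nsub = 3)
  }
  v0 <- frangi_vesselness(mk_tube(0)$voxels, scales_um = c(4, 6), geometry = geo)
  v45 <- frangi_vesselness(mk_tube(pi / 4)$voxels, scales_um = c(4, 6),
                           geometry = geo)
  r0 <- v0[25, 25, 12]
  r45 <- v45[25, 25, 12]
  expect_lt(abs(r45 - r0) / r0, 0.05)
})

test_that("edge-homogeneity ratio follows its defining arithmetic", {
  expect_equal(edge_homogeneity_ratio(rep(800, 50), threshold = 100), 1.0)
  profile <- c(rep(10, 10), 1600, 1600, rep(800, 38))
  expect_equal(edge_homogeneity_ratio(profile, threshold = 400, edge_frac = 0.05),
               2.0)
  expect_error(edge_homogeneity_ratio(rep(0, 50), threshold = 10), "tissue")
})
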