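make_lv <- function(d = c(60, 60, 100), lumen_z = 30:90, heart_z = 30:100,
                    geo = voxel_geometry(10, 10)) {
  heart <- array(FALSE, d)
  lumen <- array(FALSE, d)
  sp <- voxel_spacing(geo)
  centre <- c(30, 30) * sp[1:2]
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  r2 <- outer((xs - centre[1])^2, (ys - centre[2])^2, "+")
  wall <- r2 <= 250^2
  cavity <- r2 <= 120^2
  for (z in intersect(heart_z, seq_len(d[3]))) heart[, , z] <- wall
  for (z in intersect(lumen_z, seq_len(d[3]))) lumen[, , z] <- cavity
  lumen <- lumen & heart
  heart_solid <- heart & !lumen
  list(heart = heart_solid, lumen = lumen, geo = geo, centre = centre)
}

test_that("slabs split the lumen range into equal thirds plus an apex", {
  lv <- make_lv()
  slabs <- define_slabs(lv$heart, lv$lumen)
  expect_equal(slabs$apex_side, "high")
  expect_equal(slabs$apex, c(91, 100))
  width <- function(r) r[2] - r[1] + 1
  expect_equal(width(slabs$apical), width(slabs$mid), tolerance = 1)
  expect_equal(width(slabs$mid), width(slabs$basal), tolerance = 1)
  expect_equal(slabs$basal[1], 30)
  expect_equal(slabs$apical[2], 90)

  # lumen spanning the whole heart: empty apex, flagged
  lv2 <- make_lv(lumen_z = 30:100)
  expect_warning(s2 <- define_slabs(lv2$heart, lv2$lumen), "apex slab is empty")
  expect_true(s2$apex_empty)

  expect_error(define_slabs(lv$heart, array(FALSE, dim(lv$heart))), "empty")
})

test_that("axis reversal yields mirrored but equivalent slabs", {
  lv <- make_lv()
  rev_z <- function(m) m[, , rev(seq_len(dim(m)[3]))]
  s_fwd <- define_slabs(lv$heart, lv$lumen)
  s_rev <- define_slabs(rev_z(lv$heart), rev_z(lv$lumen))
  expect_equal(s_rev$apex_side, "low")
  nz <- dim(lv$heart)[3]
  expect_lte(max(abs(sort(nz + 1 - s_rev$apex) - s_fwd$apex)), 1)
  expect_lte(max(abs(sort(nz + 1 - s_rev$basal) - s_fwd$basal)), 1)
})

test_that("segment labels partition the LV and number by the AHA convention", {
  lv <- make_lv()
  slabs <- define_slabs(lv$heart, lv$lumen)
  seg <- assign_segments(lv$heart, lv$lumen, slabs, reference_angle_deg = 0)

  # partition: every LV voxel in a slab has exactly one label
  zs <- slabs$basal[1]:slabs$apex[2]
  lv_vox <- (lv$heart & !lv$lumen)[, , zs]
  expect_true(all(seg[, , zs][lv_vox] >= 1))
  expect_true(all(seg[, , zs][lv_vox] <= 17))
  expect_equal(sort(unique(as.vector(seg))), 0:17)

  # apex slab entirely labeled 17
  apex_lab <- seg[, , slabs$apex[1]:slabs$apex[2]]
  expect_true(all(apex_lab[lv$heart[, , slabs$apex[1]:slabs$apex[2]]] == 17))

  # a thin anterior wedge in the basal slab gets label 1 (angle oracle)
  z0 <- slabs$basal[1] + 1
  sl <- seg[, , z0]
  idx <- which(lv$heart[, , z0], arr.ind = TRUE)
  sp <- voxel_spacing(lv$geo)
  theta <- atan2((idx[, 2] - 1) * sp[2] - lv$centre[2],
                 (idx[, 1] - 1) * sp[1] - lv$centre[1]) * 180 / pi
  anterior <- abs(theta) < 25
  expect_true(all(sl[idx[anterior, , drop = FALSE]] == 1))
  # a voxel 180 deg away is inferior (segment 4)
  inferior <- abs(abs(theta) - 180) < 25
  expect_true(all(sl[idx[inferior, , drop = FALSE]] == 4))

  # per-slab labels land in their legal ranges
  expect_true(all(seg[, , slabs$mid[1]:slabs$mid[2]] %in% c(0, 7:12)))
  expect_true(all(seg[, , slabs$apical[1]:slabs$apical[2]] %in% c(0, 13:16)))
})

test_that("positivity rating matches a voxel-wise overlap oracle", {
  lv <- make_lv()
  slabs <- define_slabs(lv$heart, lv$lumen)
  seg <- assign_segments(lv$heart, lv$lumen, slabs, reference_angle_deg = 0)

  expect_equal(rate_positivity(seg, array(FALSE, dim(seg))), rep(FALSE, 17))

  apex_feature <- array(FALSE, dim(seg))
  apex_feature[, , slabs$apex[1]:slabs$apex[2]] <- lv$heart[, , slabs$apex[1]:slabs$apex[2]]
  r <- rate_positivity(seg, apex_feature)
  expect_equal(which(r), 17L)

  # arbitrary wedge: rating must equal the brute-force per-voxel check
  set.seed(6)
  wedge <- array(FALSE, dim(seg))
  wedge[1:30, 1:25, 40:70] <- TRUE
  wedge <- wedge & lv$heart
  r2 <- rate_positivity(seg, wedge)
  oracle <- vapply(1:17, function(s) any(seg == s & wedge), logical(1))
  expect_equal(r2, oracle)
})

test_that("rotating specimen and reference together leaves ratings unchanged", {
  lv <- make_lv()
  slabs <- define_slabs(lv$heart, lv$lumen)
  wedge <- array(FALSE, dim(lv$heart))
  wedge[31:60, 20:40, 35:85] <- TRUE
  wedge <- wedge & lv$heart
  seg0 <- assign_segments(lv$heart, lv$lumen, slabs, reference_angle_deg = 0)
  r0 <- rate_positivity(seg0, wedge)
  # rotate everything by 90 deg about the lumen axis (x,y) -> (-y,x)
  rot <- function(m) aperm(m, c(2, 1, 3))[dim(m)[2]:1, , ]
  heart_r <- rot(lv$heart); lumen_r <- rot(lv$lumen); wedge_r <- rot(wedge)
  seg_r <- assign_segments(heart_r, lumen_r, define_slabs(heart_r, lumen_r),
                           reference_angle_deg = 90)
  r_r <- rate_positivity(seg_r, wedge_r)
  expect_equal(r_r, r0)
})

test_that("heat maps sum ratings across hearts", {
  r12 <- rep(FALSE, 17); r12[12] <- TRUE
  hm <- aggregate_heatmap(rep(list(r12), 5))
  expect_equal(hm$count[hm$segment == 12], 5)
  expect_equal(sum(hm$count), 5)

  expect_equal(aggregate_heatmap(list())$count, rep(0L, 17))
  one <- runif(17) > 0.5
  expect_equal(aggregate_heatmap(list(one))$count, as.integer(one))
  expect_error(aggregate_heatmap(list(rep(TRUE, 16))), "length")
})
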