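test_that("a straight tube skeletonizes to two endpoints with correct length", {
  fx <- tube_fixture(radius_um = 6, len_um = 200)
  mask <- segment_vessels(fx$volume, 5000)
  gr <- skeletonize_and_graph(mask, fx$geometry)
  expect_equal(sum(gr$nodes$type == "endpoint"), 2)
  expect_equal(sum(gr$nodes$type == "branch"), 0)
  diag_um <- sqrt(sum(voxel_spacing(fx$geometry)^2))
  expect_lt(abs(graph_total_length(gr) - fx$len_um), 3 * diag_um)
})

test_that("a symmetric Y yields one degree-3 branch node and three endpoints", {
  geo <- voxel_geometry(2, 2)
  stem <- c(150, 40, 40)
  gy <- vessel_graph(rbind(c(30, 40, 40), stem, c(230, 100, 40), c(230, -20 + 40, 40)),
                     list(rbind(c(30, 40, 40), stem),
                          rbind(stem, c(230, 100, 40)),
                          rbind(stem, c(230, 20, 40))),
                     rbind(c(1, 2), c(2, 3), c(2, 4)))
  vol <- rasterize_vessels(gy, geo, c(140, 80, 40), radius_um = 5, peak = 10000)
  gr <- skeletonize_and_graph(segment_vessels(vol, 5000), geo)
  expect_equal(sum(gr$nodes$type == "branch"), 1)
  expect_equal(gr$nodes$degree[gr$nodes$type == "branch"], 3)
  expect_equal(sum(gr$nodes$type == "endpoint"), 3)
})

test_that("empty and over-thresholded masks produce empty results", {
  geo <- voxel_geometry(2, 2)
  gr <- skeletonize_and_graph(array(FALSE, c(8, 8, 8)), geo)
  expect_equal(nrow(gr$edges), 0)
  fx <- tube_fixture()
  expect_warning(m <- segment_vessels(fx$volume, 1e6), "empty")
  expect_false(any(m))
  expect_false(any(segment_vessels(array(0, c(8, 8, 8)), 1) |> suppressWarnings()))
})

test_that("interbranch distance uses only branch-to-branch path lengths", {
  # two degree-3 nodes joined by a 67 µm path, plus terminal whiskers
  n <- rbind(c(0, 0, 0), c(67, 0, 0),
             c(-20, 20, 0), c(-20, -20, 0), c(87, 20, 0), c(87, -20, 0))
  paths <- list(rbind(n[1, ], n[2, ]),
                rbind(n[1, ], n[3, ]), rbind(n[1, ], n[4, ]),
                rbind(n[2, ], n[5, ]), rbind(n[2, ], n[6, ]))
  g <- vessel_graph(n, paths, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 5), c(2, 6)))
  ib <- interbranch_distance(g)
  expect_equal(ib$ibd_median_um, 67)
  expect_equal(length(ib$ibd_um), 1)
  expect_false(ib$empty)

  # single tube: no branch-to-branch edge, flagged empty
  g1 <- vessel_graph(rbind(c(0, 0, 0), c(100, 0, 0)),
                     list(rbind(c(0, 0, 0), c(100, 0, 0))), matrix(c(1, 2), 1))
  expect_true(interbranch_distance(g1)$empty)
})

test_that("a rasterized ladder recovers its 50 µm rung spacing", {
  geo <- voxel_geometry(2, 2)
  d <- c(130, 50, 24)
  rail_y <- c(20, 76)
  xs <- seq(24, 224, by = 50)
  nodes <- rbind(do.call(rbind, lapply(xs, function(x) c(x, rail_y[1], 22))),
                 do.call(rbind, lapply(xs, function(x) c(x, rail_y[2], 22))))
  n_x <- length(xs)
  paths <- list(); ends <- NULL
  for (i in seq_len(n_x - 1)) {
    paths <- c(paths, list(rbind(nodes[i, ], nodes[i + 1, ])),
               list(rbind(nodes[n_x + i, ], nodes[n_x + i + 1, ])))
    ends <- rbind(ends, c(i, i + 1), c(n_x + i, n_x + i + 1))
  }
  for (i in seq_len(n_x)) {
    paths <- c(paths, list(rbind(nodes[i, ], nodes[n_x + i, ])))
    ends <- rbind(ends, c(i, n_x + i))
  }
  g <- vessel_graph(nodes, paths, ends)
  vol <- rasterize_vessels(g, geo, d, radius_um = 4, peak = 10000)
  gr <- skeletonize_and_graph(segment_vessels(vol, 5000), geo)
  ib <- interbranch_distance(gr)
  expect_lt(abs(ib$ibd_median_um - 50), sqrt(sum(voxel_spacing(geo)^2)))
})

test_that("VLD arithmetic, empty graphs and linear scaling behave", {
  geo <- voxel_geometry(2, 2)
  mask <- array(TRUE, c(50, 50, 50))  # (100 µm)^3
  g <- vessel_graph(rbind(c(0, 50, 50), c(100, 50, 50)),
                    list(rbind(c(0, 50, 50), c(100, 50, 50))), matrix(c(1, 2), 1))
  out <- vessel_length_density(g, mask, geo)
  expect_equal(out$vld, 100, tolerance = 1e-9)

  g0 <- vessel_graph(matrix(numeric(), ncol = 3), list(), matrix(integer(), ncol = 2))
  expect_equal(vessel_length_density(g0, mask, geo)$vld, 0)
  expect_error(vessel_length_density(g, array(FALSE, c(4, 4, 4)), geo), "empty")

  # doubling every linear dimension: length x2, volume x8 -> VLD / 4
  geo2 <- voxel_geometry(4, 4)
  g2 <- vessel_graph(rbind(c(0, 100, 100), c(200, 100, 100)),
                     list(rbind(c(0, 100, 100), c(200, 100, 100))),
                     matrix(c(1, 2), 1))
  out2 <- vessel_length_density(g2, mask, geo2)
  expect_equal(out2$vld, out$vld / 4, tolerance = 1e-9)
})

test_that("total length is invariant to edge re-orientation and reindexing", {
  fx <- tube_fixture()
  g <- fx$graph
  flipped <- vessel_graph(as.matrix(g$nodes[, c("x", "y", "z")])[2:1, ],
                          lapply(g$paths, function(p) p[rev(seq_len(nrow(p))), ]),
                          matrix(c(2, 1), 1))
  expect_equal(graph_total_length(flipped), graph_total_length(g))
})

test_that("realignment recenters offset centerlines and recovers radii", {
  geo <- voxel_geometry(2, 2)
  d <- c(80, 40, 40)
  axis_y <- 39
  p1 <- c(20, axis_y, 39); p2 <- c(130, axis_y, 39)
  g_true <- vessel_graph(rbind(p1, p2), list(rbind(p1, p2)), matrix(c(1, 2), 1))
  ref <- gaussian_smooth(rasterize_vessels(g_true, geo, d, radius_um = 4,
                                           peak = 10000, nsub = 3), 1.5)
  # centerline offset by one voxel in y
  off <- rbind(p1 + c(0, 2, 0), p2 + c(0, 2, 0))
  path_off <- cbind(seq(p1[1], p2[1], by = 2), axis_y + 2, 39)
  g_off <- vessel_graph(off, list(path_off), matrix(c(1, 2), 1))
  re <- realign_and_measure_diameters(g_off, ref, search_vox = 2)
  interior <- 3:(nrow(path_off) - 2)
  before <- mean(abs(path_off[interior, 2] - axis_y))
  after <- mean(abs(re$paths[[1]][interior, 2] - axis_y))
  expect_lt(after, 0.5 * before)
  expect_lt(abs(median(re$radii[[1]][interior], na.rm = TRUE) - 4), 1)

  # flat reference: radii unknown, centerline untouched
  flat <- array(100, d)
  re_flat <- realign_and_measure_diameters(g_off, flat, geometry = geo)
  expect_true(all(is.na(re_flat$radii[[1]])))
  expect_equal(re_flat$paths[[1]], path_off, ignore_attr = TRUE)
})

test_that("2D capillary counts extrapolate to density per mm2", {
  expect_equal(capillary_count_2d(0), 0)
  expect_equal(capillary_count_2d(5, 251.49), 5 / (251.49 / 1000)^2,
               tolerance = 1e-9)
  expect_equal(capillary_count_2d(5, 251.49), 79.06, tolerance = 1e-3)
  expect_equal(capillary_count_2d(1, 1000), 1)
  m <- matrix(FALSE, 30, 30)
  m[3:5, 3:5] <- TRUE; m[20:22, 8:9] <- TRUE; m[10, 25] <- TRUE
  expect_equal(capillary_count_2d(m, 1000), 3)
  expect_error(capillary_count_2d(3, 0), "positive")
})

test_that("crossing resolution rejoins an X into two through-paths", {
  # X: four arms meeting at a single degree-4 node
  c0 <- c(0, 0, 0)
  arms <- rbind(c(-40, -40, 0), c(40, 40, 0), c(-40, 40, 0), c(40, -40, 0))
  nodes <- rbind(c0, arms)
  paths <- lapply(1:4, function(i) rbind(c0, arms[i, ]))
  g <- vessel_graph(nodes, paths, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  gs <- simplify_vessel_graph(g, merge_um = 0, crossing_dot = -0.5)
  expect_equal(sum(gs$nodes$degree >= 3), 0)
  expect_equal(nrow(gs$edges), 2)
  expect_equal(sort(gs$edges$length_um), c(sqrt(2) * 80, sqrt(2) * 80),
               tolerance = 1e-9)
})
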