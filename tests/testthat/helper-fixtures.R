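# Shared fixtures, built in code and memoised for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small full-featured phantom (AAR wedge, infarct void, curly rim, spots)
small_phantom <- function() {
  cached("small_phantom", function() {
    generate_phantom(phantom_config(seed = 42, dim = c(96, 96, 32),
                                    n_spots = 60))
  })
}

# rasterized straight tube along x plus its segmentation-ready geometry
tube_fixture <- function(radius_um = 6, len_um = 200, spacing = c(2, 2, 2)) {
  geo <- voxel_geometry(spacing[1], spacing[3])
  d <- c(ceiling(len_um / spacing[1]) + 40, 40, 40)
  mid <- (d[2:3] / 2 - 1) * spacing[2:3]
  p1 <- c(35, mid[1], mid[2])
  p2 <- c(35 + len_um, mid[1], mid[2])
  g <- vessel_graph(rbind(p1, p2), list(rbind(p1, p2)), matrix(c(1, 2), 1))
  vol <- rasterize_vessels(g, geo, d, radius_um = radius_um, peak = 10000)
  list(geometry = geo, dim = d, graph = g, volume = vol,
       p1 = p1, p2 = p2, len_um = len_um, radius_um = radius_um)
}

expect_rel_error <- function(value, expected, tol) {
  expect_lt(abs(value - expected) / abs(expected), tol)
}
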