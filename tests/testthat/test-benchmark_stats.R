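test_that("Pearson fit recovers exact linear relations and fails degenerate ones", {
  x <- c(1, 2, 3, 4, 5)
  out <- pearson_fit(x, 2 * x + 1)
  expect_equal(out$r, 1)
  expect_equal(out$slope, 2)
  expect_equal(out$intercept, 1)

  expect_error(pearson_fit(x, rep(3, 5)), "zero variance")
  expect_error(pearson_fit(1:2, 1:2), "at least 3")

  out2 <- pearson_fit(c(1, 2, 3), c(2, 3, 5))
  expect_equal(out2$r, 0.9820, tolerance = 1e-4)
})

test_that("Pearson and Bland-Altman agree with textbook closed forms to 1e-10", {
  set.seed(12)
  x <- rnorm(40, 10, 3)
  y <- 1.2 * x + rnorm(40, 0, 1)
  out <- pearson_fit(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r_manual * sqrt((40 - 2) / (1 - r_manual^2))
  p_manual <- 2 * pt(-abs(t_stat), df = 38)
  b_manual <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(out$r, r_manual, tolerance = 1e-10)
  expect_equal(out$p_value, p_manual, tolerance = 1e-10)
  expect_equal(out$slope, b_manual, tolerance = 1e-10)
  expect_equal(out$intercept, mean(y) - b_manual * mean(x), tolerance = 1e-10)

  ba <- bland_altman(x, y)
  d <- y - x
  expect_equal(ba$mean_difference, mean(d), tolerance = 1e-10)
  expect_equal(ba$sd, sqrt(sum((d - mean(d))^2) / 39), tolerance = 1e-10)
  expect_equal(unname(ba$limits),
               c(mean(d) - 1.96 * sd(d), mean(d) + 1.96 * sd(d)),
               tolerance = 1e-10)
})

test_that("Bland-Altman hand examples and translation property hold", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$mean_difference, 0)
  expect_equal(unname(ident$limits), c(0, 0))

  ab <- bland_altman(c(1, 2, 3), c(2, 2, 5))
  expect_equal(ab$table$difference, c(1, 0, 2))
  expect_equal(ab$mean_difference, 1.0)
  expect_equal(ab$sd, 1.0)
  expect_equal(unname(ab$limits), c(-0.96, 2.96))

  shifted <- bland_altman(c(1, 2, 3), c(2, 2, 5) + 7)
  expect_equal(shifted$mean_difference, ab$mean_difference + 7)
})

test_that("Bland-Altman limits contain ~95% of Gaussian differences", {
  set.seed(99)
  a <- rnorm(10000, 50, 5)
  b <- a + rnorm(10000, 1, 2)
  ba <- bland_altman(a, b)
  inside <- mean(ba$table$difference >= ba$limits[1] &
                   ba$table$difference <= ba$limits[2])
  expect_lt(abs(inside - 0.95), 0.01)
})

test_that("inter-operator spread is expressed relative to the item average", {
  eq <- interoperator_spread(matrix(7, nrow = 4, ncol = 3))
  expect_true(all(eq$percent == 100))
  expect_equal(eq$max_deviation_pct, 0)

  one <- interoperator_spread(matrix(c(90, 100, 110), nrow = 1))
  expect_equal(as.vector(one$percent), c(90, 100, 110))
  expect_equal(one$max_deviation_pct, 10)

  vals <- rbind(c(10, 12, 14), c(0, 0, 0), c(5, 5, 5))
  expect_message(out <- interoperator_spread(vals), "excluding")
  expect_equal(out$excluded_items, 2L)
  expect_equal(nrow(out$percent), 2)
  expect_error(interoperator_spread(matrix(0, 2, 2)), "zero average")
})

test_that("TTC planimetry counts label areas correctly", {
  lab <- matrix(0L, 40, 40)
  lab[5:35, 5:20] <- 1L          # viable
  lab[5:35, 21:28] <- 3L         # AAR, viable
  lab[5:35, 29:36] <- 2L         # TTC-negative
  out <- ttc_planimetry(lab)
  expect_equal(out$ttc_neg_pct_of_aar, 50)
  aar_px <- sum(lab %in% c(2, 3)); slice_px <- sum(lab != 0)
  expect_equal(out$aar_pct_of_slice, 100 * aar_px / slice_px)

  expect_error(ttc_planimetry(matrix(1L, 4, 4)), "AAR")

  # checkerboard TTC-neg over a quarter of the AAR
  lab2 <- matrix(0L, 20, 20)
  lab2[1:20, 1:20] <- 3L
  chk <- outer(1:20, 1:20, function(i, j) (i + j) %% 2 == 0) & (row(lab2) <= 10)
  lab2[chk] <- 2L
  out2 <- ttc_planimetry(lab2)
  expect_equal(out2$ttc_neg_pct_of_aar, 100 * sum(chk) / 400)
})
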