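test_that("grid weights normalise and scale with cos(latitude)", {
  g <- build_grid(18, 36, ocean_mask = NULL)
  expect_equal(sum(g$weights), 1)
  # equator vs 60N cell at equal spacing: weight ratio cos(0)/cos(60) = 2
  g2 <- build_grid(18, 36)
  i_eq <- which.min(abs(g2$lat - 5))   # no centre at exactly 0; use ratio of cos
  expect_equal(g2$weights[which.min(abs(g2$lat - 55)), 1] /
                 g2$weights[i_eq, 1],
               cos(55 * pi / 180) / cos(5 * pi / 180))
  expect_identical(dim(g2$weights), c(18L, 36L))
  expect_length(g2$z_centers, 10)
  expect_error(build_grid(4, 8), "n_lat")
  expect_error(build_grid(18, 36, z_interfaces = c(0, 50, 100)), "107")
  # a mask emptying one band is a configuration error
  m <- matrix(TRUE, 18, 36); m[regionalize(build_grid(18, 36)$lat) == "SO", ] <- FALSE
  expect_error(build_grid(18, 36, ocean_mask = m), "zero ocean cells")
})

test_that("latitudinal bands are half-open and poleward-inclusive", {
  # band boundaries follow the stated interval contract: poleward-inclusive
  # at +50 (NH), equatorward-inclusive at -30 (LL) and -50 (SI)
  expect_equal(as.character(regionalize(c(60, 50, 40, 30, 0, -30, -40, -50, -60))),
               c("NH", "NH", "NI", "NI", "LL", "LL", "SI", "SI", "SO"))
  # every latitude belongs to exactly one band
  expect_false(anyNA(regionalize(seq(-89.9, 89.9, by = 0.37))))
})

test_that("depth reduction is trapezoid-exact and interpolates boundaries", {
  expect_equal(depth_reduce(rep(3, 5), c(10, 30, 50, 80, 105),
                            layer = c(0, 100)), 300)
  expect_equal(depth_reduce(rep(3, 5), c(10, 30, 50, 80, 105), "average",
                            layer = c(0, 100)), 3)
  expect_equal(depth_reduce(2 + 0.04 * c(0, 50, 100), c(0, 50, 100),
                            layer = c(0, 100)), 400)
  # exact for arbitrary linear profiles, boundary interpolation included
  set.seed(7)
  for (i in 1:20) {
    a <- runif(1, -1, 1); b <- runif(1, 0, 5)
    lay <- c(5, 107)
    # keep the layer inside the sampled range (and populated) so the
    # piecewise-linear reduction is analytically exact
    zc <- sort(c(0, runif(3, 1, 100), runif(3, 110, 240), 250))
    got <- depth_reduce(a * zc + b, zc, layer = lay)
    want <- a / 2 * (lay[2]^2 - lay[1]^2) + b * (lay[2] - lay[1])
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(depth_reduce(c(1, 2), c(10, 200), layer = c(0, 107)),
               "fewer than 2")
  # matrix input reduces column-wise
  m <- cbind(rep(1, 3), c(2, 4, 6))
  expect_equal(depth_reduce(m, c(0, 50, 100), layer = c(0, 100)), c(100, 400))
})

test_that("composites are area-weighted with spatial standard errors", {
  g <- mk_grid_small()
  x <- matrix(5, length(g$lat), length(g$lon))
  cs <- composite_stats(x, g)
  expect_equal(cs$mean, rep(5, 6))
  expect_equal(cs$se, rep(0, 6))
  expect_equal(cs$n[cs$region == "global"], sum(g$ocean))
  # band counts sum to global
  expect_equal(sum(cs$n[cs$region != "global"]), cs$n[cs$region == "global"])
  # hand cos-weighting of three cells via a 1-column comparison
  v <- matrix(rnorm(length(g$lat) * length(g$lon)), length(g$lat))
  csg <- composite_stats(v, g, "global")
  expect_equal(csg$mean, sum(g$weights * v))
  expect_gte(csg$mean, min(v)); expect_lte(csg$mean, max(v))
  expect_error(composite_stats(v * NA, g), "NaN|NA")
})

test_that("change metrics: identity, hand percent, trend", {
  s <- data.frame(year = 1990:2099, mean = 57)
  cm <- change_metrics(s)
  expect_equal(cm$difference, 0)
  expect_equal(cm$percent_change, 0)
  expect_equal(cm$trend_per_decade, 0)
  # Southern-Ocean-like biomass change: 57 -> 60 is +5.26%
  s2 <- data.frame(year = 1990:2099,
                   mean = c(rep(57, 24), rep(NA, 62), rep(60, 24)))
  s2$mean[25:86] <- seq(57, 60, length.out = 62)
  cm2 <- change_metrics(s2)
  expect_equal(cm2$difference, 3)
  expect_equal(cm2$percent_change, 100 * (60 / 57 - 1), tolerance = 1e-12)
  # temperature-like difference
  s3 <- data.frame(year = 1990:2099,
                   mean = seq(13, by = 2 / 109, length.out = 110))
  cm3 <- change_metrics(s3, baseline = c(1990, 1990), scenario = c(2099, 2099))
  expect_equal(cm3$difference, 2, tolerance = 1e-12)
  expect_equal(cm3$trend_per_decade, 10 * 2 / 109, tolerance = 1e-9)
  expect_error(change_metrics(s, baseline = c(1800, 1810)), "outside")
  # percent/difference consistency
  expect_equal(cm2$difference, cm2$baseline_mean * cm2$percent_change / 100,
               tolerance = 1e-12)
})
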