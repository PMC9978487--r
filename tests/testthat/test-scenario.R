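test_that("generator recovers prescribed regional moments", {
  g <- mk_grid_small()
  nz <- length(g$z_centers)
  # zero noise, zero anomaly: composites equal spec values to 1e-10 relative
  sp <- scenario_spec("ssp585", sigma_frac = 0, anomaly_frac = 0)
  fs <- generate_fields(sp, g, c(1990:1992, 2076:2078), seed = 1)
  red <- function(t, v, mode = "integrate", layer = c(0, 107))
    matrix(depth_reduce(matrix(fs$vars[[v]][t, , , ], nrow = nz),
                        g$z_centers, mode, layer),
           length(g$lat), length(g$lon))
  so_doc <- composite_stats(red(1, "DOC"), g, "SO")$mean
  expect_equal(so_doc, 318, tolerance = 1e-10)
  t_ll <- composite_stats(red(1, "T", "average", c(10, 107)), g, "LL")$mean
  expect_equal(t_ll, 24, tolerance = 1e-10)
  # historical years carry zero trend: 1990 equals 1992 exactly
  expect_identical(fs$vars$DOC[1, , , ], fs$vars$DOC[3, , , ])
  # end-century window mean recovers the target (ramp normalisation)
  so_end <- mean(sapply(4:6, function(t) composite_stats(red(t, "DOC"), g, "SO")$mean))
  mid <- mean(2076:2078)
  want <- 318 + (mid - 2015) / (2087.5 - 2015) * (451 - 318)
  expect_equal(so_end, want, tolerance = 1e-10)

  # default anomaly is regionally demeaned: composites still exact
  sp2 <- scenario_spec("ssp585", sigma_frac = 0)
  fs2 <- generate_fields(sp2, g, 1990, seed = 1)
  v <- matrix(depth_reduce(matrix(fs2$vars$DOC[1, , , ], nrow = nz),
                           g$z_centers, "integrate", c(0, 107)),
              length(g$lat), length(g$lon))
  expect_equal(composite_stats(v, g, "SO")$mean, 318, tolerance = 1e-8)
  # ... but the field itself varies in space
  expect_gt(stats::sd(v), 0)
})

test_that("generator is bit-deterministic and validates ids", {
  g <- mk_grid_small()
  sp <- scenario_spec("ssp245")
  a <- generate_fields(sp, g, 2000:2010, seed = 9)
  b <- generate_fields(sp, g, 2000:2010, seed = 9)
  expect_identical(a$vars, b$vars)
  d <- generate_fields(sp, g, 2000:2010, seed = 10)
  expect_false(identical(a$vars, d$vars))
  expect_error(scenario_spec("rcp85"), "arg")
  expect_error(scenario_spec("ssp126", rho = 1), "rho")
})

test_that("noisy composites stay within sampling error of the spec values", {
  g <- mk_grid_small()
  nz <- length(g$z_centers)
  sp <- scenario_spec("historical")   # default noise
  means <- sapply(1:6, function(s) {
    fs <- generate_fields(sp, g, 1990:1999, seed = 100 + s)
    mean(sapply(1:10, function(t)
      composite_stats(matrix(depth_reduce(matrix(fs$vars$DOC[t, , , ], nrow = nz),
                                          g$z_centers, "integrate", c(0, 107)),
                             length(g$lat), length(g$lon)), g, "LL")$mean))
  })
  # 3% AR(1) noise, regionally averaged over many cells/years: tight
  expect_lt(abs(mean(means) - 2350) / 2350, 0.01)
})

test_that("station observations round-trip, thin binomially and repeat", {
  g <- mk_grid_small()
  fs <- generate_fields(scenario_spec("historical", sigma_frac = 0,
                                      anomaly_frac = 0), g, 2001:2010, seed = 2)
  # fabricate a simulated biomass field: constant 0.5 mmol C m^-3
  fs$vars$B <- array(0.5, dim(fs$vars$T))
  stn <- data.frame(station = "s1", lat = 20, lon = 100)
  # sigma 0, no gaps, no harmonic: converting back recovers truth exactly
  obs <- generate_station_obs(fs, stn, "abundance", sigma_ln = 0,
                              missing_frac = 0, harm_amp = 0, seed = 5)
  expect_equal(nrow(obs), 10 * 12)
  expect_equal(convert_abundance(obs$value, 10), rep(0.5, 120),
               tolerance = 1e-10)
  # missingness 0.3 over 120 months: ~84 records within binomial spread
  obs2 <- generate_station_obs(fs, stn, "abundance", sigma_ln = 0,
                               missing_frac = 0.3, seed = 6)
  expect_lt(abs(nrow(obs2) - 84), 4 * sqrt(120 * 0.3 * 0.7))
  expect_identical(generate_station_obs(fs, stn, "abundance", seed = 7),
                   generate_station_obs(fs, stn, "abundance", seed = 7))
  expect_error(generate_station_obs(fs, data.frame(station = "x", lat = 120,
                                                   lon = 0), "abundance"),
               "outside")
  # thymidine route uses BP and the thymidine factor
  fs$vars$BP <- array(convert_thymidine(5), dim(fs$vars$T))
  tob <- generate_station_obs(fs, stn, "thymidine", sigma_ln = 0,
                              missing_frac = 0, harm_amp = 0, seed = 5)
  expect_equal(unique(tob$value), 5, tolerance = 1e-10) # 5 pmol/L/h
})

test_that("gridded observations respect coverage and determinism", {
  g <- mk_grid_small()
  fs <- generate_fields(scenario_spec("historical", sigma_frac = 0,
                                      anomaly_frac = 0), g, 2001:2003, seed = 2)
  fs$vars$B <- array(0.5, dim(fs$vars$T))
  full <- generate_gridded_obs(fs, coverage = 1, sigma_ln = 0, harm_amp = 0,
                               seed = 3)
  expect_equal(nrow(full), sum(g$ocean) * 12)
  expect_equal(convert_abundance(full$value, 9.1), rep(0.5, nrow(full)),
               tolerance = 1e-10)
  part <- generate_gridded_obs(fs, coverage = 0.1, seed = 3)
  frac <- nrow(part) / (sum(g$ocean) * 12)
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / (sum(g$ocean) * 12)))
  expect_identical(generate_gridded_obs(fs, coverage = 0.3, seed = 8),
                   generate_gridded_obs(fs, coverage = 0.3, seed = 8))
})
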