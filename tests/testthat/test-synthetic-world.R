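# Synthetic world generator: layout, determinism, latent mapping, footprints,
# airborne samples.

test_that("world generation is deterministic and hosts all 19 strata", {
  cfg <- world_config()
  w1 <- generate_world(cfg, seed = 1)
  w2 <- generate_world(cfg, seed = 1)
  expect_identical(w1$biome$values, w2$biome$values)
  expect_identical(w1$stratum$values, w2$stratum$values)
  present <- sort(unique(na.omit(as.vector(w1$stratum$values))))
  expect_equal(present, 1:19)
})

test_that("a northern-hemisphere-only extent hosts no southern strata", {
  w <- generate_world(world_config(extent = c(-2, 2, 0, 1)), seed = 1)
  present <- unique(na.omit(as.vector(w$stratum$values)))
  expect_length(intersect(present, c(2, 7, 9, 11, 13)), 0)
  expect_true(all(c(1, 6, 8, 10, 12, 3, 14) %in% present))
})

test_that("an extent too small for the layout errors naming missing strata", {
  expect_error(generate_world(world_config(extent = c(0, 0.4, 0, 0.2)),
                              seed = 1),
               "missing strata")
})

test_that("reflectance is clamped, deterministic without noise, seasonal", {
  w <- generate_world(world_config(sigma_refl = 0), seed = 3)
  d <- as.Date("2021-07-01")
  r1 <- simulate_reflectance(w, d)
  r2 <- simulate_reflectance(w, d)
  expect_identical(r1$bands, r2$bands)
  expect_true(all(r1$bands >= 0 & r1$bands <= 1))
  expect_error(simulate_reflectance(w, as.Date("2019-07-01")),
               "outside the simulated years")

  # band-2 seasonal maximum lands at the stratum phase (within 15 days)
  cell <- which(w$stratum$values == 1, arr.ind = TRUE)[1, ]
  phase <- w$config$coef$phase[w$config$coef$stratum == 1]
  series <- vapply(1:365, function(d)
    simulate_reflectance(w, as.Date("2021-01-01") + d - 1)$bands[cell[1], cell[2], 2],
    numeric(1))
  expect_lte(min(abs(which.max(series) - phase), 365 - abs(which.max(series) - phase)),
             15)
})

test_that("latent SIF follows the configured linear mapping with clamping", {
  # a1 = 0 everywhere: truth is the (clamped) intercept, constant per stratum
  coef0 <- default_latent_coefficients()
  coef0$a1_base <- 0; coef0$a1_amp <- 0; coef0$a0_amp <- 0
  w <- generate_world(world_config(coef = coef0, sigma_refl = 0), seed = 1)
  d <- as.Date("2021-06-01")
  tr <- simulate_true_sif(w, simulate_reflectance(w, d), d)
  for (s in c(1, 10, 19)) {
    vals <- tr$values[w$stratum$values == s]
    expect_equal(unique(na.omit(vals)), coef0$a0_base[coef0$stratum == s])
  }
  # negative intercept clamps to zero
  coefn <- coef0; coefn$a0_base <- -1
  wn <- generate_world(world_config(coef = coefn, sigma_refl = 0), seed = 1)
  trn <- simulate_true_sif(wn, simulate_reflectance(wn, d), d)
  expect_equal(unique(na.omit(as.vector(trn$values))), 0)

  # identical reflectance, different slopes -> different SIF (heterogeneity)
  w2 <- generate_world(world_config(sigma_refl = 0), seed = 1)
  bands <- array(0.2, c(40, 80, 7)); bands[, , 2] <- 0.5
  flat <- refl_stack(bands, w2$config$extent, w2$config$cellsize, date = d)
  tr2 <- simulate_true_sif(w2, flat, d)
  co <- latent_coefficients(w2, c(1, 19), doy365(d))
  expect_false(isTRUE(all.equal(co$a1[1], co$a1[2])))
  v1 <- unique(na.omit(tr2$values[w2$stratum$values == 1]))
  v19 <- unique(na.omit(tr2$values[w2$stratum$values == 19]))
  expect_equal(v1, max(0, co$a0[1] + co$a1[1] * 0.3))
  expect_equal(v19, max(0, co$a0[2] + co$a1[2] * 0.3))
  expect_false(isTRUE(all.equal(v1, v19)))
})

test_that("noise-free footprints are exactly inverted by the band combination", {
  w <- generate_world(world_config(sigma_band = 0, sigma_refl = 0), seed = 5)
  d <- as.Date("2021-08-01")
  tr <- simulate_true_sif(w, simulate_reflectance(w, d), d)
  fp <- sample_footprints(w, tr, d)
  expect_gt(nrow(fp), 100)
  rc <- sifrecon:::cell_rowcol(tr, fp$lat, fp$lon)
  truth <- tr$values[rc]
  expect_equal(combine_bands(fp$sif_757, fp$sif_771), truth, tolerance = 1e-12)
  # determinism
  fp2 <- sample_footprints(w, tr, d)
  expect_identical(fp, fp2)
})

test_that("swaths tile the grid within one revisit period", {
  w <- generate_world(world_config(), seed = 1)
  dates <- as.Date("2021-03-01") + 0:(w$config$revisit_days - 1)
  covered <- sort(unique(unlist(lapply(dates, function(d)
    sifrecon:::swath_columns(w, d)))))
  expect_equal(covered, seq_len(ncol(w$biome$values)))
})

test_that("airborne samples carry the 1.12 scaling and aggregate to truth", {
  w <- generate_world(world_config(airborne_sigma = 0, sigma_refl = 0),
                      seed = 2)
  d <- as.Date("2021-07-10")
  tr <- simulate_true_sif(w, simulate_reflectance(w, d), d)
  air <- simulate_airborne(w, tr, region = c(-2, 0, -1, 1), date = d)
  rc <- sifrecon:::cell_rowcol(tr, air$lat, air$lon)
  truth <- tr$values[rc]
  expect_equal(air$sif_755, 1.12 * truth, tolerance = 1e-12)
  # inverse scaling recovers truth exactly
  expect_equal(air$sif_755 / 1.12, truth, tolerance = 1e-12)
  # per-cell aggregation of fine samples reproduces the cell value
  agg <- tapply(air$sif_755 / 1.12, paste(rc[, 1], rc[, 2]), mean)
  key <- do.call(rbind, strsplit(names(agg), " "))
  cellv <- tr$values[cbind(as.integer(key[, 1]), as.integer(key[, 2]))]
  expect_equal(as.vector(agg), cellv, tolerance = 1e-12)
  expect_error(simulate_airborne(w, tr, region = c(-3, 0, -1, 1), date = d),
               "outside the world extent")
})

test_that("day-of-year mapping folds leap days onto the 365-day circle", {
  expect_equal(doy365(as.Date("2021-01-01")), 1)
  expect_equal(doy365(as.Date("2021-12-31")), 365)
  expect_equal(doy365(as.Date("2020-02-29")), 60)
  expect_equal(doy365(as.Date("2020-12-31")), 365)
  expect_equal(doy365(as.Date("2020-03-01")), doy365(as.Date("2021-03-01")))
})
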