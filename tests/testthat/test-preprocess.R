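# Footprint screening: quality filter, cross-band combination, neighbour
# smoothing, feature matching, training-table assembly.

test_that("qc_filter keeps exactly the allowed flags, preserving order", {
  set.seed(11)
  fp <- line_footprints(runif(100))
  fp$qc_flag <- 1L
  fp$qc_flag[sample.int(100, 17)] <- 0L
  expect_identical(qc_filter(fp, c(0L, 1L)), fp)
  expect_equal(nrow(qc_filter(fp, 2L)), 0)
  kept <- qc_filter(fp, 0L)
  expect_equal(nrow(kept), 17)
  expect_identical(kept$id, fp$id[fp$qc_flag == 0L])
  expect_error(qc_filter(fp, integer(0)), "non-empty")
})

test_that("combine_bands implements the cross-band formula", {
  expect_equal(combine_bands(0, 0), 0)
  expect_equal(combine_bands(1.0, 0.8), 1.1)
  # exact inverse of the synthetic two-band decomposition
  s <- c(0.01, 0.5, 2.3, 7)
  expect_equal(combine_bands(s, (2 / 3) * s), s)
  # linearity
  x <- runif(5); y <- runif(5)
  expect_equal(combine_bands(3 * x, 3 * y), 3 * combine_bands(x, y))
  expect_error(combine_bands(NA_real_, 1), "finite")
  expect_error(combine_bands(1, Inf), "finite")
})

test_that("knn_smooth averages the k nearest neighbours, excluding the target", {
  # six collinear, equally spaced footprints: everyone's neighbours are the
  # other five, so each smoothed value is the mean of the others
  fp <- line_footprints(c(1, 2, 3, 4, 5, 6), spacing_deg = 0.01)
  sm <- knn_smooth(fp, k = 5, max_radius = 0.1)
  expect_equal(nrow(sm), 6)
  expect_equal(sm$sif_smoothed, (21 - fp$sif_daily) / 5)
  # the middle footprint's smoothed value is the mean of {1,2,4,5,6}... and
  # for values {1..5} around a target the mean is 3
  fp5 <- line_footprints(c(9, 1, 2, 3, 4, 5), spacing_deg = 0.001)
  fp5$sif_daily[1] <- 9   # target value must not enter its own average
  sm5 <- knn_smooth(fp5, k = 5, max_radius = 0.1)
  expect_equal(sm5$sif_smoothed[1], 3)
  # constants are a fixed point
  fpc <- line_footprints(rep(2.5, 8))
  expect_equal(knn_smooth(fpc)$sif_smoothed, rep(2.5, 8))
})

test_that("under-populated neighbourhoods are dropped or renormalized", {
  fp <- line_footprints(c(1, 2, 3), spacing_deg = 0.01)
  dropped <- knn_smooth(fp, k = 5, max_radius = 0.1)
  expect_equal(nrow(dropped), 0)
  expect_setequal(attr(dropped, "dropped"), fp$id)
  ren <- knn_smooth(fp, k = 5, max_radius = 0.1, partial = "renormalize")
  expect_equal(ren$sif_smoothed, c(2.5, 2, 1.5))
  expect_error(knn_smooth(fp, k = 0), "at least 1")
})

test_that("knn_smooth matches a brute-force all-pairs oracle", {
  set.seed(99)
  n <- 200
  fp <- data.frame(id = sprintf("f%03d", sample.int(n)),
                   date = as.Date("2021-05-01") + sample(0:1, n, TRUE),
                   lat = runif(n, -0.1, 0.1), lon = runif(n, -0.1, 0.1),
                   sif_757 = runif(n), sif_771 = runif(n), qc_flag = 0L)
  fp$sif_daily <- combine_bands(fp$sif_757, fp$sif_771)
  oracle <- brute_knn_smooth(fp, k = 5, max_radius = 0.05)
  sm <- knn_smooth(fp, k = 5, max_radius = 0.05)
  expect_equal(nrow(sm), sum(!is.na(oracle)))
  expect_equal(sm$sif_smoothed, oracle[match(sm$id, fp$id)])
  expect_setequal(attr(sm, "dropped"), fp$id[is.na(oracle)])
})

test_that("match_reflectance averages the covered cell centres", {
  bands <- array(NA_real_, c(3, 3, 7))
  for (b in 1:7) bands[, , b] <- matrix(1:9 / 10 + b, 3, 3, byrow = TRUE)
  st <- refl_stack(bands, extent = c(0, 0.15, 0, 0.15), cellsize = 0.05,
                   date = as.Date("2021-06-01"))
  src <- list("2021-06-01" = st)
  centre <- data.frame(id = "c", date = as.Date("2021-06-01"),
                       lat = 0.075, lon = 0.075, sif_757 = 1, sif_771 = 1,
                       qc_flag = 0L, sif_daily = 1, sif_smoothed = 1)
  # radius below half a cell: only the centre cell
  one <- match_reflectance(centre, src, radius = 0.02)
  expect_equal(one$b1, bands[2, 2, 1])
  # radius covering exactly the 3x3 block of centres
  block <- match_reflectance(centre, src, radius = 0.08)
  expect_equal(unlist(block[paste0("b", 1:7)], use.names = FALSE),
               vapply(1:7, function(b) mean(bands[, , b]), numeric(1)))
  # two-cell mean
  two <- centre; two$lat <- 0.125; two$lon <- 0.05
  got <- match_reflectance(two, src, radius = 0.03)
  expect_equal(got$b1, mean(bands[1, 1:2, 1]))
  # missing date errors naming the date
  bad <- centre; bad$date <- as.Date("2021-06-02")
  expect_error(match_reflectance(bad, src), "2021-06-02")
})

test_that("build_training_table labels strata and excludes non-vegetated cells", {
  # 2 x 2 world in southern Asia: northern-hemisphere needleleaf (stratum 1),
  # water, northern grassland (stratum 12), Asian cropland (stratum 18)
  biome <- sif_grid(matrix(c(1, 0, 10, 12), 2, 2, byrow = TRUE),
                    extent = c(140, 140.1, 10, 10.1), cellsize = 0.05)
  sm <- assign_model_ids(biome)
  fp <- data.frame(id = c("a", "b", "c", "d"),
                   date = as.Date("2021-02-03"),
                   lat = c(10.075, 10.075, 10.025, 10.025),
                   lon = c(140.025, 140.075, 140.025, 140.075),
                   sif_757 = 1, sif_771 = 1, qc_flag = 0L,
                   sif_daily = 1, sif_smoothed = 1,
                   b1 = 0.1, b2 = 0.3, b3 = 0.1, b4 = 0.1, b5 = 0.1,
                   b6 = 0.1, b7 = 0.1)
  tab <- build_training_table(fp, sm)
  expect_equal(nrow(tab), 3)                       # water footprint excluded
  expect_equal(attr(tab, "excluded"), 1)
  expect_equal(tab$stratum[tab$id == "a"], 1L)     # needleleaf, lat >= 0
  expect_equal(tab$stratum[tab$id == "c"], 12L)    # grassland, NH
  expect_equal(tab$stratum[tab$id == "d"], 18L)    # cropland, Asia
  expect_equal(tab$doy, rep(34L, 3))
  expect_equal(tab$year, rep(2021L, 3))
})

test_that("noise-variance reductions follow the band-combination and smoothing laws", {
  # quick sanity versions of the Monte-Carlo laws (full runs in acceptance)
  set.seed(123)
  sigma <- 0.2; n <- 5000
  s <- runif(n, 0.5, 1.5)
  combined <- combine_bands(s + rnorm(n, 0, sigma),
                            (2 / 3) * s + rnorm(n, 0, sigma))
  expect_equal(var(combined - s) / sigma^2, 0.8125, tolerance = 0.08)
})
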