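# Evaluation: metrics, cross-biome report, strategy comparison, cross-sensor
# validation.

test_that("regression metrics match closed-form oracles", {
  obs <- c(0.2, 0.5, 0.9, 1.4, 2.0)
  # identity
  m <- regression_metrics(obs, obs)
  expect_equal(m$r2, 1); expect_equal(m$rmse, 0); expect_equal(m$slope, 1)
  # constant shift keeps the slope, costs RMSE and R2
  m1 <- regression_metrics(obs + 1, obs)
  expect_equal(m1$rmse, 1); expect_equal(m1$slope, 1)
  expect_equal(m1$r2, 1 - 5 / sum((obs - mean(obs))^2))
  # arbitrary fixture against independent arithmetic (lm for the slope)
  pred <- c(0.25, 0.4, 1.1, 1.2, 2.2)
  m2 <- regression_metrics(pred, obs)
  expect_equal(m2$slope, unname(coef(lm(pred ~ obs))[2]), tolerance = 1e-12)
  expect_equal(m2$rmse, sqrt(mean((pred - obs)^2)), tolerance = 1e-12)
  expect_equal(m2$r2, 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-12)
  # Pearson variant
  expect_equal(regression_metrics(pred, obs, r2_method = "pearson")$r2,
               cor(pred, obs)^2, tolerance = 1e-12)
  expect_error(regression_metrics(rep(1, 3), rep(1, 3)), "zero variance")
  expect_error(regression_metrics(1:3, 1:4), "equal length")
})

test_that("the cross-biome report marks absent strata instead of scoring them", {
  tab <- make_fleet_table(strata = c(1L, 4L), n_per = 150L)
  cfg <- registry_config(cap = 200L, min_n = 50L, folds = 3,
                         param_grid = fast_gbt_grid(30L), seed = 1)
  reg <- train_registry(tab, doys = 150L, config = cfg)
  val <- make_fleet_table(strata = c(1L, 4L), n_per = 40L, seed = 77)
  rep <- cross_biome_report(reg, val, strata = c(1, 4, 9))
  expect_equal(rep$status, c("ok", "ok", "absent"))
  expect_true(is.na(rep$r2[rep$stratum == 9]))
  expect_equal(sum(rep$n), nrow(val))
  expect_true(all(rep$algorithm == "gbt"))
})

test_that("strategy comparison shares one validation set and sees no edge on a homogeneous world", {
  # identical mapping for every stratum and day: pooling loses nothing
  set.seed(10)
  tabs <- lapply(1:6, function(s)
    linear_training_table(500, a0 = 0.3, a1 = 2, noise = 0.05, strata = s,
                          doys = c(100L, 220L), seed = s))
  tab <- do.call(rbind, tabs)
  tab$id <- sprintf("r%05d", seq_len(nrow(tab)))
  cfg <- registry_config(cap = 3000L, min_n = 50L, folds = 3,
                         param_grid = fast_gbt_grid(80L), seed = 4)
  cmp <- compare_strategies(tab, doys = c(100L, 220L), config = cfg, seed = 4)
  expect_equal(cmp$mstws$n, cmp$universal$n)
  expect_false(is.null(cmp$val_hash))
  expect_lt(abs(cmp$diff$r2), 0.05)
  # the same call reproduces the identical held-out set
  cmp2 <- compare_strategies(tab, doys = c(100L, 220L), config = cfg, seed = 4)
  expect_identical(cmp2$val_hash, cmp$val_hash)
  expect_equal(cmp2$mstws$r2, cmp$mstws$r2)
})

test_that("cross-sensor validation scales, aggregates and pairs airborne data", {
  set.seed(31)
  v <- matrix(runif(20 * 30, 0.3, 1.5), 20, 30)
  v[1, ] <- NA                      # a nodata stripe
  g <- sif_grid(v, extent = c(0, 1.5, 0, 1), cellsize = 0.05,
                date = as.Date("2021-06-01"))
  # airborne truth = grid values scaled by 1.12, 4 samples per covered cell
  cells <- which(!is.na(v), arr.ind = TRUE)
  air <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    r <- cells[i, 1]; c <- cells[i, 2]
    data.frame(lat = 1 - (r - runif(4)) * 0.05,
               lon = (c - runif(4)) * 0.05,
               date = g$date, sif_755 = 1.12 * v[r, c])
  }))
  res <- cross_sensor_validate(g, air)
  expect_equal(res$metrics$slope, 1, tolerance = 1e-9)
  expect_equal(res$metrics$r2, 1, tolerance = 1e-9)
  expect_equal(nrow(res$pairs), sum(!is.na(v)))   # one pair per covered cell
  # omitting the scaling correction inflates the slope by exactly the ratio
  raw <- cross_sensor_validate(g, air, apply_scaling = FALSE)
  expect_equal(raw$metrics$slope / res$metrics$slope, 1 / 1.12,
               tolerance = 1e-9)
  # note: predicted on y, observed on x; uncorrected *observations* are
  # larger, so the fitted slope of predictions on them shrinks by 1.12
  expect_error(cross_sensor_validate(g, air[0, ]), "no overlap")
  # scaling invariance: feeding 1.12 x truth with correction equals truth
  air2 <- air; air2$sif_755 <- air$sif_755 / 1.12
  res2 <- cross_sensor_validate(g, air2, apply_scaling = FALSE)
  expect_equal(res2$metrics$r2, res$metrics$r2, tolerance = 1e-12)
  # minimum sample count filter (every cell holds exactly 4 samples)
  res3 <- cross_sensor_validate(g, air, min_samples = 4)
  expect_equal(nrow(res3$pairs), nrow(res$pairs))
  expect_error(cross_sensor_validate(g, air, min_samples = 5), "no overlap")
})
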