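# Regressor fleet: CV training, algorithm selection, registry, fallback
# resolution, gridded prediction, persistence.

test_that("cross-validated training recovers a noiseless linear mapping", {
  tab <- linear_training_table(2000, noise = 0, seed = 3)
  parts <- split_train_val(tab, seed = 1)
  for (alg in c("gbt", "rf")) {
    grid <- if (alg == "gbt") fast_gbt_grid(200L)
            else data.frame(num_trees = 300L, mtry = 3L, min_node_size = 2L)
    m <- train_model_cv(parts$train, alg, grid, seed = 9)
    val <- regression_metrics(predict(m, parts$val), parts$val$sif_smoothed)
    expect_gte(val$r2, 0.99)
  }
})

test_that("training is deterministic and invariant to row order", {
  tab <- linear_training_table(400, noise = 0.05, seed = 4)
  newx <- as.matrix(linear_training_table(50, seed = 5)[paste0("b", 1:7)])
  for (alg in c("gbt", "rf", "nn")) {
    grid <- switch(alg, gbt = fast_gbt_grid(50L),
                   rf = data.frame(num_trees = 100L, mtry = 3L, min_node_size = 5L),
                   nn = data.frame(size = 4L, decay = 1e-3, maxit = 100L))
    m1 <- train_model_cv(tab, alg, grid, seed = 2)
    m2 <- train_model_cv(tab[sample.int(nrow(tab)), ], alg, grid, seed = 2)
    expect_identical(m1$params, m2$params)
    expect_equal(predict(m1, newx), predict(m2, newx), tolerance = 1e-12)
  }
})

test_that("grid search returns the single configuration when there is one", {
  tab <- linear_training_table(300, noise = 0.02, seed = 6)
  grid <- fast_gbt_grid(40L)
  m <- train_model_cv(tab, "gbt", grid, seed = 1)
  expect_equal(m$params$nrounds, 40L)
  expect_equal(nrow(m$cv_table), 1)
  expect_error(train_model_cv(transform(tab, sif_smoothed = 1), "gbt", grid),
               "zero variance")
})

test_that("algorithm selection scores candidates and breaks ties by order", {
  tabs <- list(linear_training_table(400, noise = 0.05, seed = 1),
               linear_training_table(400, noise = 0.05, seed = 2))
  grids <- list(gbt = fast_gbt_grid(60L),
                nn = data.frame(size = 2L, decay = 0.1, maxit = 30L))
  one <- select_algorithm(tabs, candidates = "gbt", param_grids = grids,
                          folds = 3, seed = 1)
  expect_equal(as.character(one), "gbt")
  # identical candidates tie; the declared order wins
  tie <- select_algorithm(tabs, candidates = c("gbt", "gbt"),
                          param_grids = grids, folds = 3, seed = 1)
  expect_equal(as.character(tie), "gbt")
  both <- select_algorithm(tabs, candidates = c("gbt", "nn"),
                           param_grids = grids, folds = 3, seed = 1)
  comp <- attr(both, "comparison")
  expect_equal(nrow(comp), 2)
  expect_equal(as.character(both),
               comp$algorithm[which.max(comp$mean_cv_r2)])
})

test_that("the registry trains per-stratum models plus a per-DOY universal", {
  tab <- make_fleet_table()
  cfg <- registry_config(cap = 200L, min_n = 50L, folds = 3,
                         param_grid = fast_gbt_grid(40L), seed = 3)
  reg <- train_registry(tab, doys = 150L, config = cfg)
  expect_length(reg$models, 19)
  expect_length(reg$universal, 1)
  expect_length(reg$skipped, 0)
  expect_equal(sum(reg$audit$n_found), nrow(tab) + nrow(tab))  # 19 keys + universal
  # dropping one stratum below the floor yields 18 models + a skip marker
  tab2 <- tab[!(tab$stratum == 7 & seq_len(nrow(tab)) %% 3 > 0), ]
  reg2 <- train_registry(tab2, doys = 150L, config = cfg)
  expect_length(reg2$models, 18)
  expect_equal(reg2$skipped, "d150:s07")
  expect_length(reg2$universal, 1)
})

test_that("auto selection picks one algorithm for the whole fleet", {
  tab <- make_fleet_table(strata = c(3L, 9L), n_per = 80L)
  cfg <- registry_config(cap = 200L, min_n = 40L, folds = 2L,
                         algorithm = "auto", n_select_keys = 2L, seed = 11)
  reg <- train_registry(tab, doys = 150L, strata = c(3L, 9L), config = cfg)
  expect_true(reg$algorithm %in% c("gbt", "rf", "nn"))
  expect_length(reg$models, 2)
  expect_true(all(vapply(reg$models, `[[`, character(1), "algorithm") ==
                    reg$algorithm))
})

test_that("fallback resolution prefers exact, then nearest date, then universal", {
  tab <- make_fleet_table(strata = c(5L, 6L), n_per = 150L)
  cfg <- registry_config(cap = 200L, min_n = 50L, folds = 3,
                         param_grid = fast_gbt_grid(30L), seed = 1)
  reg <- train_registry(tab, doys = c(150L), config = cfg)
  # exact
  expect_equal(resolve_model(reg, 150, 5)$path, "exact")
  # synthetic registry with models at DOYs 198 and 203 for stratum 5
  fake <- reg
  fake$models <- list(`d198:s05` = reg$models[["d150:s05"]],
                      `d203:s05` = reg$models[["d150:s05"]])
  r <- resolve_model(fake, 200, 5)
  expect_equal(r$key, "d198:s05")        # distance 2 beats 3
  expect_equal(r$path, "nearest_date")
  # equal distances resolve toward the earlier day
  fake$models <- list(`d198:s05` = reg$models[["d150:s05"]],
                      `d202:s05` = reg$models[["d150:s05"]])
  expect_equal(resolve_model(fake, 200, 5)$key, "d198:s05")
  # circular distance across the year boundary
  fake$models <- list(`d003:s05` = reg$models[["d150:s05"]],
                      `d330:s05` = reg$models[["d150:s05"]])
  expect_equal(resolve_model(fake, 360, 5)$key, "d003:s05")  # 8 < 30
  # never-trained stratum falls back to the per-DOY universal model
  u <- resolve_model(reg, 150, 11)
  expect_equal(u$path, "universal")
  expect_equal(u$key, "d150:universal")
  # horizon limits the nearest-date search
  fake$universal <- reg$universal
  lim <- resolve_model(fake, 150, 5, horizon = 3)
  expect_equal(lim$path, "universal")
  # exhaustive-search oracle over random registries
  set.seed(42)
  for (i in 1:20) {
    doys <- sample(1:365, 6)
    fake$models <- setNames(rep(list(reg$models[["d150:s05"]]), 6),
                            sprintf("d%03d:s05", doys))
    q <- sample(1:365, 1)
    got <- resolve_model(fake, q, 5)
    dist <- pmin(abs(doys - q) %% 365, 365 - abs(doys - q) %% 365)
    expect_equal(sifrecon:::circular_doy_distance(
      sifrecon:::parse_key_doy(got$key), q), min(dist))
  }
  expect_error(resolve_model(structure(list(models = list(),
                                            universal = list()),
                                       class = "model_registry"), 1, 1),
               "no model resolvable")
})

test_that("registry persistence round trips models and manifest", {
  tab <- make_fleet_table(strata = c(1L, 2L), n_per = 120L)
  cfg <- registry_config(cap = 200L, min_n = 50L, folds = 3,
                         param_grid = fast_gbt_grid(30L), seed = 5)
  reg <- train_registry(tab, doys = 150L, config = cfg)
  dir <- withr::local_tempdir()
  save_registry(reg, dir)
  back <- load_registry(dir)
  expect_setequal(names(back$models), names(reg$models))
  expect_equal(back$algorithm, reg$algorithm)
  newx <- as.matrix(linear_training_table(30, seed = 9)[paste0("b", 1:7)])
  for (k in names(reg$models))
    expect_equal(predict(back$models[[k]], newx),
                 predict(reg$models[[k]], newx), tolerance = 1e-12)
})

test_that("gridded prediction respects mask, geometry and provenance", {
  w <- generate_world(tiny_world_config(), seed = 2)
  tab <- world_training_table(w, 150)
  cfg <- registry_config(cap = 2000L, min_n = 40L, folds = 3,
                         param_grid = fast_gbt_grid(60L), seed = 2)
  reg <- train_registry(tab, doys = 150L, config = cfg)
  d <- as.Date("2021-05-30")
  refl <- simulate_reflectance(w, d)
  g <- predict_grid(reg, refl, w$stratum, d)
  expect_equal(g$extent, w$stratum$extent)
  expect_identical(is.finite(g$values), !is.na(w$stratum$values))
  prov <- attr(g, "provenance")
  expect_true(all(!is.na(prov[!is.na(w$stratum$values)])))
  # all-nodata stratum map -> all-nodata output
  empty <- w$stratum
  empty$values[] <- NA_real_
  g0 <- predict_grid(reg, refl, empty, d)
  expect_true(all(is.na(g0$values)))
})
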