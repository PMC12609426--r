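# The regressor fleet: per-(day-of-year, stratum) models with 5-fold
# cross-validated hyperparameter selection, a registry with skip-markers and
# per-DOY universal models, nearest-date / universal fallback resolution and
# gridded prediction.
#
# Three algorithm families are supported behind one fit/predict surface:
#   gbt -- gradient-boosted regression trees (xgboost)
#   rf  -- random forest (ranger)
#   nn  -- single-hidden-layer feed-forward network (nnet)

feature_cols_default <- paste0("b", 1:7)

#' Default hyperparameter grids
#'
#' Small grids over the parameters that matter for each family: boosting
#' iterations / learning rate / depth / L2 for the gradient-boosted trees,
#' number of trees / mtry / node size for the random forest, hidden-layer
#' width / weight decay for the network.
#'
#' @param algorithm `"gbt"`, `"rf"` or `"nn"`.
#' @return A `data.frame`, one row per candidate configuration.
#' @export
default_param_grid <- function(algorithm = c("gbt", "rf", "nn")) {
  switch(match.arg(algorithm),
    gbt = expand.grid(nrounds = c(150L, 300L), max_depth = c(4L, 6L),
                      eta = c(0.1, 0.3), lambda = 1),
    rf  = expand.grid(num_trees = c(200L, 500L), mtry = c(2L, 4L),
                      min_node_size = c(2L, 5L)),
    nn  = expand.grid(size = c(8L, 16L), decay = c(1e-4, 1e-2),
                      maxit = 300L))
}

# deterministic single fit of one (algorithm, params) configuration
fit_one <- function(x, y, algorithm, params, seed) {
  x <- as.matrix(x)
  if (algorithm == "gbt") {
    dm <- xgboost::xgb.DMatrix(x, label = y)
    booster <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    max_depth = params$max_depth, eta = params$eta,
                    lambda = params$lambda, nthread = 1,
                    seed = seed %% 2147483647),
      data = dm, nrounds = params$nrounds, verbose = 0)
    list(algorithm = "gbt", raw = xgboost::xgb.save.raw(booster),
         env = new.env(parent = emptyenv()))
  } else if (algorithm == "rf") {
    fit <- ranger::ranger(y = y, x = as.data.frame(x),
                          num.trees = params$num_trees,
                          mtry = min(params$mtry, ncol(x)),
                          min.node.size = params$min_node_size,
                          seed = seed, num.threads = 1)
    list(algorithm = "rf", fit = fit)
  } else if (algorithm == "nn") {
    set.seed(seed)
    fit <- nnet::nnet(x, y, size = params$size, decay = params$decay,
                      maxit = params$maxit, linout = TRUE, trace = FALSE,
                      MaxNWts = 5000)
    list(algorithm = "nn", fit = fit)
  } else stop("unknown algorithm: ", algorithm)
}

predict_one <- function(fit, x) {
  x <- as.matrix(x)
  if (fit$algorithm == "gbt") {
    if (is.null(fit$env$booster))
      fit$env$booster <- xgboost::xgb.load.raw(fit$raw)
    predict(fit$env$booster, xgboost::xgb.DMatrix(x))
  } else if (fit$algorithm == "rf") {
    predict(fit$fit, as.data.frame(x))$predictions
  } else {
    as.numeric(predict(fit$fit, x))
  }
}

# R^2 used to score CV folds (1 - SS_res / SS_tot); -Inf on degenerate folds
score_r2 <- function(pred, obs) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(-Inf)
  1 - sum((obs - pred)^2) / sst
}

#' Train one model with cross-validated hyperparameter selection
#'
#' Runs k-fold cross-validation (default 5 folds) over the configuration
#' grid, scores each configuration by mean held-out R-squared, refits the
#' best configuration on the full table and records training metrics.
#' Rows are put into a canonical order (by `id` when present) before fold
#' assignment, so the result is invariant to the row order of the input at a
#' fixed seed.
#'
#' @param table Training rows with feature columns and a target column.
#' @param algorithm `"gbt"`, `"rf"` or `"nn"`.
#' @param param_grid Configuration grid (default [default_param_grid()]).
#' @param folds Number of CV folds (default 5, minimum 2).
#' @param seed Integer seed (folds and stochastic fitters).
#' @param feature_cols,target_col Column names (defaults `b1`..`b7`,
#'   `sif_smoothed`).
#' @return A `sif_model`: list with the fitted regressor, `algorithm`,
#'   `params`, `cv_score`, the full `cv_table`, `n_train` and training
#'   `metrics`.
#' @export
train_model_cv <- function(table, algorithm = "gbt",
                           param_grid = default_param_grid(algorithm),
                           folds = 5L, seed = 1L,
                           feature_cols = feature_cols_default,
                           target_col = "sif_smoothed") {
  stopifnot(folds >= 2, nrow(param_grid) >= 1)
  if ("id" %in% names(table))
    table <- table[order(table$id), , drop = FALSE]
  y <- table[[target_col]]
  if (stats::var(y) == 0)
    stop("degenerate target: zero variance in ", target_col)
  x <- as.matrix(table[, feature_cols, drop = FALSE])
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  cv_scores <- numeric(nrow(param_grid))
  for (p in seq_len(nrow(param_grid))) {
    sc <- numeric(0)
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (sum(tr) < 2 || sum(!tr) < 1) next
      fit <- fit_one(x[tr, , drop = FALSE], y[tr], algorithm,
                     param_grid[p, , drop = FALSE], seed)
      s <- score_r2(predict_one(fit, x[!tr, , drop = FALSE]), y[!tr])
      if (is.finite(s)) sc <- c(sc, s)
    }
    cv_scores[p] <- if (length(sc)) mean(sc) else -Inf
  }
  best <- which.max(cv_scores)        # ties resolve to the earlier grid row
  fit <- fit_one(x, y, algorithm, param_grid[best, , drop = FALSE], seed)
  pred <- predict_one(fit, x)
  structure(list(
    key = NULL, algorithm = algorithm,
    params = as.list(param_grid[best, , drop = FALSE]),
    cv_score = cv_scores[best],
    cv_table = cbind(param_grid, cv_score = cv_scores),
    fit = fit, n_train = n, seed = seed,
    feature_cols = feature_cols, target_col = target_col,
    metrics = list(train = regression_metrics(pred, y))),
    class = "sif_model")
}

#' Predict from a fitted model
#'
#' @param object A `sif_model`.
#' @param newdata Matrix or data frame carrying the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.sif_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  predict_one(object$fit, newdata)
}

#' @export
print.sif_model <- function(x, ...) {
  cat("<sif_model> ", x$algorithm,
      if (!is.null(x$key)) paste0(" [", x$key, "]"),
      ", n_train ", x$n_train,
      ", cv R2 ", formatC(x$cv_score, digits = 4, format = "f"), "\n",
      sep = "")
  invisible(x)
}

#' Select the modelling algorithm by cross-validation
#'
#' Trains every candidate on a representative sample of model keys and
#' returns the candidate with the best mean cross-validation score; ties are
#' broken by the declared candidate order.  The full comparison is kept in
#' the `"comparison"` attribute for cross-biome reporting.
#'
#' @param tables List of training tables (one per representative key).
#' @param candidates Character vector of algorithm tags, in preference order.
#' @param folds,seed As in [train_model_cv()].
#' @param param_grids Optional named list of grids per candidate.
#' @return The winning algorithm tag (character), with attribute
#'   `comparison` (a `data.frame` of per-candidate mean scores).
#' @export
select_algorithm <- function(tables, candidates = c("gbt", "rf", "nn"),
                             folds = 5L, seed = 1L, param_grids = NULL) {
  stopifnot(length(candidates) >= 1, length(tables) >= 1)
  scores <- sapply(candidates, function(alg) {
    grid <- if (!is.null(param_grids)) param_grids[[alg]]
            else default_param_grid(alg)
    mean(vapply(tables, function(tb)
      train_model_cv(tb, alg, grid, folds = folds, seed = seed)$cv_score,
      numeric(1)))
  })
  if (all(!is.finite(scores))) stop("all candidate algorithms failed")
  winner <- candidates[which.max(scores)]
  attr(winner, "comparison") <- data.frame(algorithm = candidates,
                                           mean_cv_r2 = unname(scores))
  winner
}

model_key <- function(doy, stratum) {
  if (identical(stratum, "universal")) sprintf("d%03d:universal", doy)
  else sprintf("d%03d:s%02d", doy, stratum)
}

#' Registry training configuration
#'
#' @param cap,min_n,ratio,folds As in the sampling and CV stages.
#' @param algorithm `"gbt"`, `"rf"`, `"nn"` or `"auto"` (cross-validated
#'   selection on a sample of keys before fleet training).
#' @param param_grid Optional grid override (single-algorithm case).
#' @param seed Master seed; per-key seeds are derived from it.
#' @param n_select_keys Number of representative keys used when
#'   `algorithm = "auto"`.
#' @return A list of settings for [train_registry()].
#' @export
registry_config <- function(cap = 5000L, min_n = 1000L, ratio = 0.7,
                            folds = 5L, algorithm = "gbt",
                            param_grid = NULL, seed = 1L,
                            n_select_keys = 3L) {
  list(cap = cap, min_n = min_n, ratio = ratio, folds = folds,
       algorithm = algorithm, param_grid = param_grid, seed = seed,
       n_select_keys = n_select_keys)
}

key_seed <- function(seed, doy, stratum) {
  s <- if (identical(stratum, "universal")) 20L else as.integer(stratum)
  ((seed %% 49999L) * 40009L + doy * 101L + s * 13L) %% 2147483629L
}

#' Train the model registry
#'
#' For each requested day of year: trains up to 19 stratum models (one per
#' sub-biome domain with enough samples in the 16-day window pooled across
#' years) plus one per-DOY universal model on the combined vegetated data of
#' that window.  Keys failing the sample floor get skip-markers; a DOY whose
#' universal pool is itself below the floor is recorded as a DOY-level gap.
#' Each model keeps validation metrics from its 70:30 held-out part.
#'
#' @param table Labelled training table (see [build_training_table()]).
#' @param doys Integer vector of target days of year.
#' @param strata Model IDs to attempt (default 1:19).
#' @param config A [registry_config()].
#' @return A `model_registry`: lists `models` and `universal` keyed by
#'   [model_key()] strings, `skipped` markers, `gaps`, an `audit` table
#'   (per key: `n_found`, `n_used`, `skipped`), the algorithm used, the
#'   config and seed.
#' @export
train_registry <- function(table, doys, strata = 1:19,
                           config = registry_config()) {
  algorithm <- config$algorithm
  if (identical(algorithm, "auto")) {
    # representative keys: the largest pools among requested (doy, stratum)
    pools <- list()
    for (d in doys) for (s in strata) {
      rows <- collect_window_samples(table, d, s)
      if (nrow(rows) > config$min_n) pools[[model_key(d, s)]] <- rows
    }
    if (!length(pools)) stop("no key has enough samples to select an algorithm")
    sizes <- vapply(pools, nrow, integer(1))
    pick <- names(sort(sizes, decreasing = TRUE))[
      seq_len(min(config$n_select_keys, length(pools)))]
    algorithm <- select_algorithm(pools[pick], folds = config$folds,
                                  seed = config$seed)
  }
  grid <- if (!is.null(config$param_grid)) config$param_grid
          else default_param_grid(algorithm)

  models <- list(); universal <- list()
  skipped <- character(0); gaps <- integer(0)
  audit <- list()
  train_key <- function(rows, d, s) {
    ks <- key_seed(config$seed, d, s)
    ruled <- apply_sampling_rules(rows, cap = config$cap,
                                  min_n = config$min_n, seed = ks)
    audit[[length(audit) + 1]] <<- data.frame(
      key = model_key(d, s), doy = d, stratum = as.character(s),
      n_found = ruled$n_found, n_used = ruled$n_used,
      skipped = ruled$skipped)
    if (ruled$skipped) return(NULL)
    parts <- split_train_val(ruled$table, ratio = config$ratio, seed = ks)
    m <- train_model_cv(parts$train, algorithm, grid,
                        folds = config$folds, seed = ks)
    m$key <- model_key(d, s)
    m$metrics$validation <- regression_metrics(
      predict(m, parts$val), parts$val[[m$target_col]])
    m
  }
  for (d in doys) {
    for (s in strata) {
      m <- train_key(collect_window_samples(table, d, s), d, s)
      if (is.null(m)) skipped <- c(skipped, model_key(d, s))
      else models[[m$key]] <- m
    }
    mu <- train_key(collect_window_samples(table, d, "universal"),
                    d, "universal")
    if (is.null(mu)) gaps <- c(gaps, d)
    else universal[[mu$key]] <- mu
  }
  structure(list(models = models, universal = universal, skipped = skipped,
                 gaps = gaps, audit = do.call(rbind, audit),
                 algorithm = algorithm, config = config,
                 seed = config$seed), class = "model_registry")
}

#' @export
print.model_registry <- function(x, ...) {
  cat("<model_registry> ", length(x$models), " stratum models, ",
      length(x$universal), " universal models, ", length(x$skipped),
      " skipped, algorithm ", x$algorithm, "\n", sep = "")
  invisible(x)
}

parse_key_doy <- function(keys) as.integer(substr(keys, 2, 4))
parse_key_stratum <- function(keys) as.integer(substr(keys, 7, 8))

#' Resolve the model serving a (day of year, stratum) query
#'
#' Resolution order: the exact (doy, stratum) model if trained; otherwise
#' the same-stratum model at minimal circular DOY distance within
#' `horizon` (ties broken toward the earlier day); otherwise the universal
#' model for the query DOY, or failing that the nearest-DOY universal model.
#' The path taken is recorded in the result.
#'
#' @param registry A `model_registry`.
#' @param doy,stratum Query key.
#' @param horizon Maximum circular DOY distance searched for a same-stratum
#'   substitute (default `Inf`).
#' @return A list with `model` (a `sif_model`), `key` and `path` (one of
#'   `"exact"`, `"nearest_date"`, `"universal"`, `"nearest_universal"`).
#' @export
resolve_model <- function(registry, doy, stratum, horizon = Inf) {
  k <- model_key(doy, stratum)
  if (!is.null(registry$models[[k]]))
    return(list(model = registry$models[[k]], key = k, path = "exact"))

  nearest <- function(keys, target) {
    # minimal circular distance; ties toward the earlier (backward) DOY
    kd <- parse_key_doy(keys)
    d <- circular_doy_distance(kd, target)
    cand <- which(d == min(d))
    if (length(cand) > 1) {
      back <- ((target - kd[cand] - 1) %% 365 + 1)   # small if kd is earlier
      cand <- cand[which.min(back)]
    }
    list(key = keys[cand[1]], dist = min(d))
  }

  if (!identical(stratum, "universal")) {
    keys <- names(registry$models)
    same <- keys[parse_key_stratum(keys) == as.integer(stratum)]
    if (length(same)) {
      nd <- nearest(same, doy)
      if (nd$dist <= horizon)
        return(list(model = registry$models[[nd$key]], key = nd$key,
                    path = "nearest_date"))
    }
  }
  uk <- model_key(doy, "universal")
  if (!is.null(registry$universal[[uk]]))
    return(list(model = registry$universal[[uk]], key = uk,
                path = "universal"))
  if (length(registry$universal)) {
    nd <- nearest(names(registry$universal), doy)
    return(list(model = registry$universal[[nd$key]], key = nd$key,
                path = "nearest_universal"))
  }
  stop("no model resolvable for key ", k)
}

#' Predict a daily SIF grid
#'
#' Per vegetated cell: features are the cell's 7 reflectance bands and the
#' prediction comes from the model resolved for (day of year of `date`,
#' stratum of the cell).  Non-vegetated cells are nodata.  A provenance
#' layer records which model key served each cell.
#'
#' @param registry A `model_registry`.
#' @param refl A [refl_stack()] for the prediction date.
#' @param stratum_map [sif_grid()] of model IDs aligned with `refl`.
#' @param date Prediction date.
#' @param horizon Fallback search horizon, see [resolve_model()].
#' @return A [sif_grid()] of predicted SIF with attribute `provenance`
#'   (character matrix of model keys).
#' @export
predict_grid <- function(registry, refl, stratum_map, date, horizon = Inf) {
  check_same_geometry(stratum_map, refl, "stratum map and reflectance")
  d <- doy365(as.Date(date))
  nr <- dim(refl$bands)[1]; nc <- dim(refl$bands)[2]
  out <- matrix(NA_real_, nr, nc)
  prov <- matrix(NA_character_, nr, nc)
  feats <- matrix(as.vector(refl$bands), nr * nc, 7)
  colnames(feats) <- feature_cols_default
  st <- as.vector(stratum_map$values)
  for (s in sort(unique(stats::na.omit(st)))) {
    res <- resolve_model(registry, d, s, horizon = horizon)
    idx <- which(!is.na(st) & st == s)
    out[idx] <- predict(res$model, feats[idx, , drop = FALSE])
    prov[idx] <- res$key
  }
  g <- sif_grid(out, stratum_map$extent, stratum_map$cellsize,
                date = as.Date(date))
  attr(g, "provenance") <- prov
  g
}

#' Save / load a model registry
#'
#' The registry is persisted as a plain-text manifest
#' (`manifest.tsv`: key, kind, algorithm, n_found/n_used bookkeeping) plus
#' one serialized model file per key under `models/`, so large fleets can be
#' inspected without loading every regressor.
#'
#' @param registry A `model_registry`.
#' @param dir Directory to create/use.
#' @return For the writer, `dir` invisibly; for the reader, the registry.
#' @export
save_registry <- function(registry, dir) {
  dir.create(file.path(dir, "models"), recursive = TRUE, showWarnings = FALSE)
  all <- c(registry$models, registry$universal)
  kind <- c(rep("stratum", length(registry$models)),
            rep("universal", length(registry$universal)))
  manifest <- data.frame(
    key = names(all), kind = kind,
    algorithm = vapply(all, `[[`, character(1), "algorithm"),
    n_train = vapply(all, `[[`, integer(1), "n_train"),
    cv_score = vapply(all, `[[`, numeric(1), "cv_score"),
    file = file.path("models", paste0(gsub(":", "_", names(all)), ".rds")))
  write_delim_table(manifest, file.path(dir, "manifest.tsv"))
  write_delim_table(data.frame(key = registry$skipped),
                    file.path(dir, "skipped.tsv"))
  writeLines(yaml::as.yaml(list(algorithm = registry$algorithm,
                                seed = registry$seed,
                                gaps = registry$gaps)),
             file.path(dir, "registry.yaml"))
  if (!is.null(registry$audit))
    write_delim_table(registry$audit, file.path(dir, "audit.tsv"))
  for (i in seq_along(all)) {
    m <- all[[i]]
    if (m$fit$algorithm == "gbt") m$fit$env <- NULL  # cache is rebuildable
    saveRDS(m, file.path(dir, manifest$file[i]))
  }
  invisible(dir)
}

#' @rdname save_registry
#' @export
load_registry <- function(dir) {
  manifest <- read_delim_table(file.path(dir, "manifest.tsv"))
  meta <- yaml::read_yaml(file.path(dir, "registry.yaml"))
  sk <- read_delim_table(file.path(dir, "skipped.tsv"))
  audit_path <- file.path(dir, "audit.tsv")
  models <- list(); universal <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- readRDS(file.path(dir, manifest$file[i]))
    if (m$fit$algorithm == "gbt" && is.null(m$fit$env))
      m$fit$env <- new.env(parent = emptyenv())
    if (manifest$kind[i] == "universal") universal[[manifest$key[i]]] <- m
    else models[[manifest$key[i]]] <- m
  }
  structure(list(models = models, universal = universal,
                 skipped = as.character(sk$key),
                 gaps = as.integer(unlist(meta$gaps)),
                 audit = if (file.exists(audit_path))
                   read_delim_table(audit_path) else NULL,
                 algorithm = meta$algorithm, config = NULL,
                 seed = meta$seed), class = "model_registry")
}
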