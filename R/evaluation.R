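# Evaluation surfaces: R^2 / RMSE / regression slope, per-stratum
# cross-biome reports, moving-window-vs-universal strategy comparison and
# cross-sensor validation against airborne SIF.

#' Regression evaluation metrics
#'
#' With observations as truth on the x-axis:
#' \eqn{R^2 = 1 - SS_{res} / SS_{tot}} (coefficient of determination, not
#' squared Pearson correlation -- the two diverge when the slope differs
#' from 1; set `r2_method = "pearson"` for the other convention),
#' \eqn{RMSE = \sqrt{\mathrm{mean}((pred - obs)^2)}}, and the ordinary
#' least-squares slope of predicted on observed.
#'
#' @param predicted,observed Equal-length finite numeric vectors, `n >= 2`.
#' @param r2_method `"ss"` (default) or `"pearson"`.
#' @return A list of class `eval_metrics` with `r2`, `rmse`, `slope`, `n`.
#' @export
regression_metrics <- function(predicted, observed,
                               r2_method = c("ss", "pearson")) {
  r2_method <- match.arg(r2_method)
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (length(observed) < 2) stop("need at least 2 pairs")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop("non-finite values in predicted or observed")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("zero variance in observations")
  r2 <- if (r2_method == "ss")
    1 - sum((observed - predicted)^2) / sst
  else suppressWarnings(stats::cor(predicted, observed))^2
  slope <- sum((observed - mean(observed)) *
                 (predicted - mean(predicted))) / sst
  structure(list(r2 = r2,
                 rmse = sqrt(mean((predicted - observed)^2)),
                 slope = slope, n = length(observed)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.4f, RMSE = %.4f, slope = %.4f (n = %d)\n",
              x$r2, x$rmse, x$slope, x$n))
  invisible(x)
}

# predictions for labelled validation rows via the registry fallback chain
predict_rows <- function(registry, rows, horizon = Inf) {
  pred <- rep(NA_real_, nrow(rows))
  groups <- split(seq_len(nrow(rows)),
                  paste(rows$doy, rows$stratum, sep = ":"))
  for (idx in groups) {
    res <- resolve_model(registry, rows$doy[idx[1]], rows$stratum[idx[1]],
                         horizon = horizon)
    pred[idx] <- predict(res$model, rows[idx, , drop = FALSE])
  }
  pred
}

#' Cross-biome stratified performance report
#'
#' Evaluates one or more registries (e.g. one per candidate algorithm) on a
#' validation table stratified by the 19 sub-biome model domains.  Strata
#' absent from the validation data are marked `"absent"`, not scored as
#' zero.
#'
#' @param registries A single `model_registry` or a named list of them
#'   (names become the `algorithm` column).
#' @param validation Validation rows labelled with `doy` and `stratum`.
#' @param strata Strata to report on (default 1:19).
#' @param target_col Observation column (default `"sif_smoothed"`).
#' @return A `data.frame` with columns `stratum`, `algorithm`, `status`,
#'   `n`, `r2`, `rmse`, `slope`.
#' @export
cross_biome_report <- function(registries, validation, strata = 1:19,
                               target_col = "sif_smoothed") {
  if (inherits(registries, "model_registry"))
    registries <- stats::setNames(list(registries), registries$algorithm)
  rows <- list()
  for (alg in names(registries)) {
    reg <- registries[[alg]]
    for (s in strata) {
      sub <- validation[!is.na(validation$stratum) &
                          validation$stratum == s, , drop = FALSE]
      if (nrow(sub) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          stratum = s, algorithm = alg, status = "absent", n = nrow(sub),
          r2 = NA_real_, rmse = NA_real_, slope = NA_real_)
        next
      }
      m <- regression_metrics(predict_rows(reg, sub), sub[[target_col]])
      rows[[length(rows) + 1]] <- data.frame(
        stratum = s, algorithm = alg, status = "ok", n = m$n, r2 = m$r2,
        rmse = m$rmse, slope = m$slope)
    }
  }
  do.call(rbind, rows)
}

#' Compare the moving-window strategy against a universal model
#'
#' Holds out a seeded validation fraction of the labelled table, trains (a)
#' one universal model on the remaining rows pooled across all dates and
#' strata and (b) the per-(day-of-year, stratum) fleet on the same remaining
#' rows, and evaluates both on the byte-identical held-out rows.  Identical
#' data, algorithm, hyperparameter search and validation set -- the only
#' difference is the sampling strategy.
#'
#' @param table Labelled training table.
#' @param doys Days of year to evaluate (validation rows are restricted to
#'   these DOYs so every row is served by an in-window fleet model).
#' @param config A [registry_config()]; `config$cap` also caps the universal
#'   pool.
#' @param seed Seed for the holdout split.
#' @param ratio Training fraction of the holdout split (default 0.7).
#' @return A list with `mstws` and `universal` ([regression_metrics()]),
#'   `diff` (mstws minus universal for r2/rmse/slope), `n_val` and
#'   `val_hash` (hash of the shared validation rows).
#' @export
compare_strategies <- function(table, doys, config = registry_config(),
                               seed = 1L, ratio = 0.7) {
  eval_rows <- table[table$doy %in% doys & !is.na(table$stratum), ,
                     drop = FALSE]
  parts <- split_train_val(eval_rows, ratio = ratio, seed = seed)
  train <- parts$train; val <- parts$val
  # remaining rows outside the evaluated DOYs still inform the fleet windows
  # and the universal pool equally
  rest <- table[!(rownames(table) %in% rownames(eval_rows)) &
                  !is.na(table$stratum), , drop = FALSE]
  pool <- rbind(train, rest)

  grid <- if (!is.null(config$param_grid)) config$param_grid
          else default_param_grid(config$algorithm)
  uni_pool <- apply_sampling_rules(pool, cap = config$cap,
                                   min_n = config$min_n,
                                   seed = seed)$table
  if (is.null(uni_pool)) stop("universal pool below the sample floor")
  universal <- train_model_cv(uni_pool, config$algorithm, grid,
                              folds = config$folds, seed = seed)
  registry <- train_registry(pool, doys = doys, config = config)

  obs <- val$sif_smoothed
  m_uni <- regression_metrics(predict(universal, val), obs)
  m_mst <- regression_metrics(predict_rows(registry, val), obs)
  list(mstws = m_mst, universal = m_uni,
       diff = list(r2 = m_mst$r2 - m_uni$r2,
                   rmse = m_mst$rmse - m_uni$rmse,
                   slope = m_mst$slope - m_uni$slope),
       n_val = nrow(val), val_hash = rlang::hash(val))
}

#' Cross-sensor validation against airborne SIF
#'
#' Scales airborne 755 nm samples to the satellite band
#' (\eqn{SIF_{corrected} = SIF_{755} / 1.12} by default), averages them per
#' 0.05 degree cell and date, pairs each covered cell with the predicted
#' grid and computes regression metrics.
#'
#' @param grids A [sif_grid()] or a list of them; each must carry a `date`.
#' @param airborne Samples with columns `lat`, `lon`, `date`, `sif_755`.
#' @param scale Magnitude ratio removed from the airborne values
#'   (default 1.12).
#' @param apply_scaling Set `FALSE` to skip the correction (e.g. to measure
#'   the slope inflation it prevents).
#' @param min_samples Minimum airborne points per cell (default 1).
#' @return A list with `metrics` ([regression_metrics()]) and `pairs` (a
#'   `data.frame` of cell-level predicted/observed pairs).
#' @export
cross_sensor_validate <- function(grids, airborne, scale = 1.12,
                                  apply_scaling = TRUE, min_samples = 1L) {
  if (inherits(grids, "sif_grid")) grids <- list(grids)
  value <- if (apply_scaling) airborne$sif_755 / scale else airborne$sif_755
  pairs <- list()
  for (g in grids) {
    if (is.null(g$date)) stop("every grid must carry a date")
    sub <- airborne[as.Date(airborne$date) == as.Date(g$date), , drop = FALSE]
    if (nrow(sub) == 0) next
    v <- value[as.Date(airborne$date) == as.Date(g$date)]
    rc <- cell_rowcol(g, sub$lat, sub$lon)
    ok <- !is.na(rc[, 1])
    cell <- paste(rc[ok, 1], rc[ok, 2])
    agg <- tapply(v[ok], cell, mean)
    cnt <- tapply(v[ok], cell, length)
    keep <- cnt >= min_samples
    if (!any(keep)) next
    rcu <- do.call(rbind, strsplit(names(agg)[keep], " "))
    idx <- cbind(as.integer(rcu[, 1]), as.integer(rcu[, 2]))
    pred <- g$values[idx]
    fin <- is.finite(pred)
    pairs[[length(pairs) + 1]] <- data.frame(
      date = g$date, row = idx[fin, 1], col = idx[fin, 2],
      predicted = pred[fin], observed = unname(agg[keep])[fin],
      n_samples = unname(cnt[keep])[fin])
  }
  if (!length(pairs))
    stop("no overlap between airborne samples and predicted grids")
  pairs <- do.call(rbind, pairs)
  list(metrics = regression_metrics(pairs$predicted, pairs$observed),
       pairs = pairs)
}
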