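# Footprint screening and preparation: quality filter, cross-band noise
# reduction, five-nearest-neighbour smoothing, reflectance feature matching
# and assembly of the training table.

#' Quality-control filter
#'
#' Keeps exactly the soundings whose `qc_flag` is in `allowed_flags`; row
#' order is preserved.  An empty result is permitted (the sampling rules
#' downstream handle small samples).
#'
#' @param footprints Footprint table (see [read_footprint_table()]).
#' @param allowed_flags Non-empty vector of acceptable flag values
#'   (default `0`, the highest-quality retrievals).
#' @return The filtered table.
#' @export
qc_filter <- function(footprints, allowed_flags = 0L) {
  if (length(allowed_flags) == 0) stop("allowed_flags must be non-empty")
  footprints[footprints$qc_flag %in% allowed_flags, , drop = FALSE]
}

#' Cross-band combination of the two SIF bands
#'
#' Combines the 757 nm and 771 nm daily SIF retrievals into a single value,
#' \deqn{SIF_{daily} = 0.5 (SIF_{757} + 1.5 \, SIF_{771}),}
#' which suppresses independent band noise: for band noise of variance
#' \eqn{\sigma^2} the combined value has noise variance
#' \eqn{(0.5^2 + 0.75^2)\sigma^2 = 0.8125\,\sigma^2}, and when the 771 nm
#' band carries \eqn{2/3} of the signal the combination is exactly unbiased.
#'
#' @param sif_757,sif_771 Numeric vectors of band values (finite).
#' @return Numeric vector of combined daily SIF.
#' @export
combine_bands <- function(sif_757, sif_771) {
  if (any(!is.finite(sif_757)) || any(!is.finite(sif_771)))
    stop("combine_bands requires finite band values")
  0.5 * (sif_757 + 1.5 * sif_771)
}

# metres per degree of latitude (mean), used to express the degree-valued
# radii against haversine distances
M_PER_DEG <- 111194.9

# pairwise haversine distances for one date group, in metres
pairwise_dist_m <- function(lat, lon) {
  geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine)
}

#' Five-nearest-neighbour smoothing of daily SIF
#'
#' For each sounding, averages the combined daily SIF of its `k` nearest
#' same-date neighbours (great-circle distance, target excluded, ties broken
#' by sounding `id`):
#' \deqn{SIF_{smoothed} = \tfrac{1}{k} \sum_{i=1}^{k} SIF_{daily,i}.}
#' With the default `k = 5` each neighbour carries weight 0.2.  Soundings
#' with fewer than `k` same-date neighbours within `max_radius` are dropped
#' (default) or averaged over the neighbours found
#' (`partial = "renormalize"`); dropped ids are reported in the `"dropped"`
#' attribute.
#'
#' @param footprints Footprint table carrying a `sif_daily` column (add one
#'   with [combine_bands()]).
#' @param k Number of neighbours (default 5).
#' @param max_radius Neighbourhood radius in degrees (default 0.1).
#' @param include_self If `TRUE` the target sounding is counted among its own
#'   neighbours (default `FALSE`: the formula averages the *neighbouring*
#'   footprints).
#' @param partial `"drop"` (default) or `"renormalize"` for under-populated
#'   neighbourhoods.
#' @return The surviving rows with a `sif_smoothed` column appended;
#'   attribute `dropped` holds the ids of removed soundings.
#' @export
knn_smooth <- function(footprints, k = 5L, max_radius = 0.1,
                       include_self = FALSE,
                       partial = c("drop", "renormalize")) {
  partial <- match.arg(partial)
  if (k < 1) stop("k must be at least 1")
  if (!"sif_daily" %in% names(footprints))
    stop("footprints must carry a sif_daily column; see combine_bands()")
  if (nrow(footprints) == 0) {
    footprints$sif_smoothed <- numeric(0)
    attr(footprints, "dropped") <- character(0)
    return(footprints)
  }
  radius_m <- max_radius * M_PER_DEG
  out <- vector("list", 0)
  dropped <- character(0)
  for (d in split(seq_len(nrow(footprints)), as.character(footprints$date))) {
    grp <- footprints[d, , drop = FALSE]
    n <- nrow(grp)
    sm <- rep(NA_real_, n)
    if (n > 1 || include_self) {
      dm <- pairwise_dist_m(grp$lat, grp$lon)
      if (!include_self) diag(dm) <- Inf
      for (i in seq_len(n)) {
        cand <- which(dm[i, ] <= radius_m)
        # order by distance, ties by id for reproducibility
        cand <- cand[order(dm[i, cand], grp$id[cand])]
        if (length(cand) >= k) {
          sm[i] <- mean(grp$sif_daily[cand[seq_len(k)]])
        } else if (partial == "renormalize" && length(cand) > 0) {
          sm[i] <- mean(grp$sif_daily[cand])
        }
      }
    }
    keep <- !is.na(sm)
    dropped <- c(dropped, grp$id[!keep])
    grp <- grp[keep, , drop = FALSE]
    grp$sif_smoothed <- sm[keep]
    out[[length(out) + 1]] <- grp
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$id, footprints$id)), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Match footprint features from fine-resolution reflectance
#'
#' Each sounding's feature vector `b1`..`b7` is the unweighted mean of all
#' reflectance cells whose centres fall within `radius` degrees of the
#' footprint centre (the synthetic analogue of averaging all fine pixels
#' inside the footprint polygon).  Distances use an equirectangular
#' approximation (longitude scaled by `cos(lat)`), adequate at footprint
#' scale.  Soundings covering no cell are dropped and reported.
#'
#' @param footprints Footprint table.
#' @param refl_source Either a function `function(date) -> refl_stack` or a
#'   named list of [refl_stack()]s keyed by `as.character(date)`.  A missing
#'   date is an error naming the date.
#' @param radius Footprint radius in degrees (default 0.05).
#' @return The surviving rows with `b1`..`b7` appended; attribute `dropped`
#'   holds removed ids.
#' @export
match_reflectance <- function(footprints, refl_source, radius = 0.05) {
  get_stack <- function(date) {
    key <- as.character(date)
    st <- if (is.function(refl_source)) refl_source(as.Date(date))
          else refl_source[[key]]
    if (is.null(st) || !inherits(st, "refl_stack"))
      stop("no reflectance available for date ", key)
    st
  }
  if (nrow(footprints) == 0) {
    for (b in 1:7) footprints[[paste0("b", b)]] <- numeric(0)
    attr(footprints, "dropped") <- character(0)
    return(footprints)
  }
  out <- vector("list", 0)
  dropped <- character(0)
  for (d in split(seq_len(nrow(footprints)), as.character(footprints$date))) {
    grp <- footprints[d, , drop = FALSE]
    stack <- get_stack(grp$date[1])
    nr <- dim(stack$bands)[1]; nc <- dim(stack$bands)[2]
    g <- band_grid(stack, 1)
    lats <- grid_lats(g); lons <- grid_lons(g)
    win <- ceiling(radius / stack$cellsize) + 1L
    feats <- matrix(NA_real_, nrow(grp), 7)
    for (i in seq_len(nrow(grp))) {
      rc <- cell_rowcol(g, grp$lat[i], grp$lon[i])
      if (is.na(rc[1])) next
      rows <- max(1L, rc[1] - win):min(nr, rc[1] + win)
      cols <- max(1L, rc[2] - win):min(nc, rc[2] + win)
      cl <- expand.grid(row = rows, col = cols)
      dy <- lats[cl$row] - grp$lat[i]
      dx <- (lons[cl$col] - grp$lon[i]) * cos(grp$lat[i] * pi / 180)
      cov <- sqrt(dx^2 + dy^2) <= radius
      if (!any(cov)) next
      sel <- cbind(cl$row[cov], cl$col[cov])
      for (b in 1:7) feats[i, b] <- mean(stack$bands[, , b][sel])
    }
    keep <- is.finite(feats[, 1])
    dropped <- c(dropped, grp$id[!keep])
    grp <- grp[keep, , drop = FALSE]
    for (b in 1:7) grp[[paste0("b", b)]] <- feats[keep, b]
    out[[length(out) + 1]] <- grp
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$id, footprints$id)), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Assemble the training table
#'
#' Labels each processed sounding with its day of year, year and sub-biome
#' model ID (from the stratum map cell containing the footprint centre) and
#' drops rows falling on non-vegetated or unassigned cells.
#'
#' @param footprints Processed footprint table (must carry `sif_smoothed` and
#'   `b1`..`b7`).
#' @param stratum_map [sif_grid()] of model IDs (see [assign_model_ids()]).
#' @return Training table with `doy`, `year`, `stratum` appended; attribute
#'   `excluded` counts the dropped rows.
#' @export
build_training_table <- function(footprints, stratum_map) {
  need <- c("sif_smoothed", paste0("b", 1:7), "date")
  miss <- setdiff(need, names(footprints))
  if (length(miss))
    stop("footprints are missing column(s): ", paste(miss, collapse = ", "))
  rc <- cell_rowcol(stratum_map, footprints$lat, footprints$lon)
  stratum <- rep(NA_real_, nrow(footprints))
  ok <- !is.na(rc[, 1])
  stratum[ok] <- stratum_map$values[rc[ok, , drop = FALSE]]
  out <- footprints
  out$doy <- doy365(out$date)
  out$year <- as.integer(format(as.Date(out$date), "%Y"))
  out$stratum <- as.integer(stratum)
  keep <- !is.na(out$stratum)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- sum(!keep)
  res
}
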