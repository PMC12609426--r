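# Shared fixtures, built in code.

# small world for fast end-to-end checks (20 x 40 cells, one year)
tiny_world_config <- function(...) {
  world_config(extent = c(-1, 1, -0.5, 0.5), years = 2021L,
               fp_per_cell = 4, ...)
}

# footprint table with ids, one date, positions on a line of given spacing
line_footprints <- function(values, spacing_deg = 0.01, lat0 = 0, lon0 = 0,
                            date = as.Date("2021-06-01")) {
  n <- length(values)
  data.frame(id = sprintf("fp-%03d", seq_len(n)), date = date,
             lat = lat0, lon = lon0 + (seq_len(n) - 1) * spacing_deg,
             sif_757 = values, sif_771 = (2 / 3) * values,
             qc_flag = 0L, sif_daily = values, stringsAsFactors = FALSE)
}

# independent brute-force k-nearest-neighbour smoothing oracle
brute_knn_smooth <- function(fp, k = 5, max_radius = 0.1) {
  out <- rep(NA_real_, nrow(fp))
  for (i in seq_len(nrow(fp))) {
    same <- which(fp$date == fp$date[i])
    same <- setdiff(same, i)
    d <- geosphere::distHaversine(cbind(fp$lon[i], fp$lat[i]),
                                  cbind(fp$lon[same], fp$lat[same]))
    keep <- same[d <= max_radius * 111194.9]
    dk <- d[d <= max_radius * 111194.9]
    keep <- keep[order(dk, fp$id[keep])]
    if (length(keep) >= k) out[i] <- mean(fp$sif_daily[keep[seq_len(k)]])
  }
  out
}

# labelled training table drawn from a known linear mapping; bands 3..7 are
# uninformative
linear_training_table <- function(n, a0 = 0.3, a1 = 2, noise = 0,
                                  strata = 1L, doys = 100L, seed = 1) {
  set.seed(seed)
  b1 <- runif(n, 0.02, 0.12); b2 <- runif(n, 0.2, 0.5)
  tab <- data.frame(id = sprintf("r%05d", seq_len(n)),
                    b1 = b1, b2 = b2, b3 = runif(n), b4 = runif(n),
                    b5 = runif(n), b6 = runif(n), b7 = runif(n))
  tab$sif_smoothed <- a0 + a1 * (b2 - b1) + rnorm(n, 0, noise)
  tab$doy <- sample(rep_len(doys, n))
  tab$stratum <- sample(rep_len(strata, n))
  tab$year <- 2021L
  tab$date <- as.Date("2021-01-01") + tab$doy - 1
  tab
}

# per-stratum tables around one DOY, each with its own linear mapping
make_fleet_table <- function(strata = 1:19, n_per = 120L, doy = 150L,
                             seed = 1) {
  tabs <- lapply(strata, function(s)
    linear_training_table(n_per, a0 = 0.1 * s, a1 = 0.5 + 0.1 * s,
                          noise = 0.02, strata = s,
                          doys = (doy - 3):(doy + 3), seed = seed + s))
  tab <- do.call(rbind, tabs)
  tab$id <- sprintf("r%05d", seq_len(nrow(tab)))
  tab
}

# fast single-configuration boosting grid for tests
fast_gbt_grid <- function(nrounds = 100L)
  data.frame(nrounds = nrounds, max_depth = 5L, eta = 0.3, lambda = 1)

# build the processed training table for a world over the windows of `doys`
world_training_table <- function(w, doys, years = w$config$years,
                                 qc = 0L, max_radius = 0.1, radius = 0.05) {
  alld <- sort(unique(unlist(lapply(doys, doy_window))))
  dates <- as.Date(unlist(lapply(years, function(y)
    as.character(as.Date(paste0(y, "-01-01")) + alld - 1))))
  tabs <- lapply(dates, function(d) {
    refl <- simulate_reflectance(w, d)
    tr <- simulate_true_sif(w, refl, d)
    fp <- qc_filter(sample_footprints(w, tr, d), qc)
    if (nrow(fp) == 0) return(NULL)
    fp$sif_daily <- combine_bands(fp$sif_757, fp$sif_771)
    fp <- knn_smooth(fp, max_radius = max_radius)
    fp <- match_reflectance(fp, function(dd) simulate_reflectance(w, dd),
                            radius = radius)
    build_training_table(fp, w$stratum)
  })
  do.call(rbind, tabs)
}
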