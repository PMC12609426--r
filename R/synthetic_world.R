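# Synthetic world: a self-contained toy earth with the statistical structure
# the moving-window stratified method assumes -- a reflectance->SIF mapping
# that is linear in a vegetation band contrast but whose coefficients drift
# with season and differ between sub-biome strata, observed through noisy
# two-band soundings confined to a moving swath.

#' Configure a synthetic world
#'
#' The world is laid out in three longitudinal panels so that all 19 model
#' domains are realisable on a small grid: a hemispheric panel with
#' latitudinal bands of needleleaf forest, deciduous broadleaf forest,
#' shrubland, savanna and grassland (mirrored across the equator), an
#' evergreen-broadleaf panel with three region columns (Amazon, Congo,
#' Southeast Asia) and a cropland panel with six continent columns.  A small
#' fraction of cells is replaced by non-vegetated classes (water, urban,
#' snow/ice, barren) to exercise masking.
#'
#' The latent truth is \eqn{S = \max(0, a_0(s, d) + a_1(s, d) \, g)} where
#' \eqn{g = b_2 - b_1} is a near-infrared-minus-red band contrast, \eqn{s}
#' the stratum and \eqn{d} the day of year; both coefficients follow a
#' stratum-specific annual sinusoid with phase `phase(s)`.  Soundings carry
#' two bands, \eqn{757\,\mathrm{nm} = S + e_1} and
#' \eqn{771\,\mathrm{nm} = \tfrac{2}{3} S + e_2} with independent
#' \eqn{N(0, \sigma_{band}^2)} noise, so the cross-band combination
#' \eqn{0.5 (S_{757} + 1.5\, S_{771})} recovers \eqn{S} exactly when
#' \eqn{\sigma_{band} = 0}.  Airborne-style samples are scaled by
#' `airborne_scale` (default 1.12, the 755 nm vs 757 nm magnitude offset).
#'
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)` degrees; the default
#'   `c(-2, 2, -1, 1)` with 0.05 degree cells gives a 40 x 80 grid straddling
#'   the equator.
#' @param cellsize Cell size in degrees (default 0.05, the target product
#'   resolution).
#' @param years Integer vector of simulated years.
#' @param coef Per-stratum latent coefficients, a `data.frame` with columns
#'   `stratum`, `a0_base`, `a0_amp`, `a1_base`, `a1_amp`, `phase`
#'   (default [default_latent_coefficients()]).
#' @param sigma_band Sounding band-noise standard deviation, SIF units
#'   (default 0.1, a realistic single-sounding retrieval noise).
#' @param sigma_refl Reflectance noise standard deviation (default 0.01).
#' @param spatial_amp Amplitude of the deterministic within-stratum spatial
#'   reflectance gradient (default 0.05); gives the latent field spatial
#'   texture without randomness.
#' @param swath_cells Swath width in grid columns; `NULL` (default) chooses
#'   the smallest width whose swaths tile the grid within one revisit period.
#' @param revisit_days Revisit period in days (default 16).
#' @param fp_per_cell Mean soundings per swath cell per day (default 2).
#' @param sam_per_day Snapshot-area acquisitions per day (default 2): dense
#'   footprint patches dropped at seeded random vegetated locations,
#'   emulating the instrument's target/snapshot mode, so every region is
#'   sampled at scattered days of year in addition to its swath overpasses.
#' @param sam_radius Snapshot patch radius in degrees (default 0.1).
#' @param qc_fail_rate Fraction of soundings flagged as low quality
#'   (default 0.1).
#' @param nonveg_fraction Fraction of cells replaced by non-vegetated classes
#'   (default 0.03).
#' @param footprint_radius Footprint radius in degrees used when matching
#'   reflectance (default 0.05).
#' @param airborne_scale Airborne-to-sounding magnitude ratio (default 1.12).
#' @param airborne_sigma Airborne sample noise sd (default 0.02).
#' @param airborne_per_cell Airborne samples per cell (default 25).
#' @return A `world_config` list, validated.
#' @export
world_config <- function(extent = c(-2, 2, -1, 1), cellsize = 0.05,
                         years = c(2021L, 2022L),
                         coef = default_latent_coefficients(),
                         sigma_band = 0.1, sigma_refl = 0.01,
                         spatial_amp = 0.05, swath_cells = NULL,
                         revisit_days = 16L, fp_per_cell = 2,
                         sam_per_day = 2L, sam_radius = 0.1,
                         qc_fail_rate = 0.1, nonveg_fraction = 0.03,
                         footprint_radius = 0.05, airborne_scale = 1.12,
                         airborne_sigma = 0.02, airborne_per_cell = 25L) {
  grid_dims(extent, cellsize)  # validates divisibility
  stopifnot(sigma_band >= 0, sigma_refl >= 0, revisit_days >= 1,
            fp_per_cell > 0, qc_fail_rate >= 0, qc_fail_rate < 1,
            length(years) >= 1, airborne_scale > 0)
  if (!is.null(swath_cells) && swath_cells < 1)
    stop("swath width must be at least one cell")
  need <- c("stratum", "a0_base", "a0_amp", "a1_base", "a1_amp", "phase")
  if (!all(need %in% names(coef)))
    stop("coef must have columns ", paste(need, collapse = ", "))
  structure(list(extent = as.numeric(extent), cellsize = cellsize,
                 years = as.integer(years), coef = coef,
                 sigma_band = sigma_band, sigma_refl = sigma_refl,
                 spatial_amp = spatial_amp, swath_cells = swath_cells,
                 revisit_days = as.integer(revisit_days),
                 fp_per_cell = fp_per_cell,
                 sam_per_day = as.integer(sam_per_day),
                 sam_radius = sam_radius, qc_fail_rate = qc_fail_rate,
                 nonveg_fraction = nonveg_fraction,
                 footprint_radius = footprint_radius,
                 airborne_scale = airborne_scale,
                 airborne_sigma = airborne_sigma,
                 airborne_per_cell = as.integer(airborne_per_cell)),
            class = "world_config")
}

#' Default latent reflectance-to-SIF coefficients
#'
#' One row per model domain (1-19).  Phases put the seasonal peak of the
#' northern-hemisphere strata in boreal summer, the southern ones in austral
#' summer and the tropical evergreen regions in between; slopes `a1` differ
#' across strata so that a single pooled model cannot represent all domains.
#'
#' @return A `data.frame` with columns `stratum`, `a0_base`, `a0_amp`,
#'   `a1_base`, `a1_amp`, `phase` (phase in day-of-year units).
#' @export
default_latent_coefficients <- function() {
  s <- 1:19
  nh <- c(1, 6, 8, 10, 12)          # hemispheric NH strata
  sh <- c(2, 7, 9, 11, 13)          # hemispheric SH strata
  ebf <- 3:5
  cro <- 14:19
  phase <- numeric(19)
  phase[nh] <- 185 + 6 * seq_along(nh)
  phase[sh] <- 10 + 6 * seq_along(sh)
  phase[ebf] <- c(95, 130, 165)
  phase[cro] <- c(195, 25, 190, 70, 205, 20)
  data.frame(
    stratum = s,
    a0_base = 0.25 + 0.015 * s,
    a0_amp  = 0.10 + 0.005 * s,
    a1_base = 1.0 + 0.12 * s,
    a1_amp  = 0.25 + 0.01 * s,
    phase   = phase)
}

# seasonal factor: peaks at doy == phase, period 365
season_factor <- function(doy, phase) cos(2 * pi * (doy - phase) / 365)

#' Latent coefficients at a given day of year
#'
#' Retrieval oracle for parameter-recovery tests: returns the exact `a0`,
#' `a1` used by the generator for each requested (stratum, doy).
#'
#' @param world A `sif_world` (or a `world_config`).
#' @param stratum Model ID vector (1-19).
#' @param doy Day-of-year vector (recycled against `stratum`).
#' @return A `data.frame` with columns `stratum`, `doy`, `a0`, `a1`.
#' @export
latent_coefficients <- function(world, stratum, doy) {
  cfg <- if (inherits(world, "sif_world")) world$config else world
  co <- cfg$coef[match(stratum, cfg$coef$stratum), ]
  f <- season_factor(doy, co$phase)
  data.frame(stratum = stratum, doy = doy,
             a0 = co$a0_base + co$a0_amp * f,
             a1 = co$a1_base + co$a1_amp * f)
}

# small deterministic integer for per-(seed, date, channel) RNG streams
derive_seed <- function(seed, date, channel = 0L) {
  d <- as.integer(as.Date(date)) %% 100000L
  ((seed %% 49999L) * 40009L + d * 17L + channel * 7919L) %% 2147483629L
}

# band-level reflectance parameters: base level and seasonal amplitude per
# band; band 2 (NIR-like) carries the strongest seasonal signal
refl_band_base <- c(0.06, 0.30, 0.04, 0.08, 0.22, 0.16, 0.10)
refl_band_amp  <- c(0.02, 0.22, 0.01, 0.02, 0.09, 0.05, 0.03)

#' Generate a synthetic world
#'
#' Lays out the biome raster (IGBP codes) and region raster, assigns the
#' sub-biome model IDs through the same stratification code used for real
#' land cover, and prepares the latent-truth skeleton.  Deterministic for a
#' fixed `(config, seed)`.
#'
#' @param config A [world_config()].
#' @param seed Integer seed controlling the non-vegetated sprinkle and all
#'   downstream per-date noise streams.
#' @return A `sif_world`: list with `config`, `seed`, `biome` ([sif_grid()]
#'   of IGBP codes), `region` (`sif_grid` of region codes), `stratum`
#'   (`sif_grid` of model IDs), `mask` (vegetated mask).
#' @export
generate_world <- function(config, seed = 1L) {
  stopifnot(inherits(config, "world_config"))
  dims <- grid_dims(config$extent, config$cellsize)
  nr <- dims[1]; nc <- dims[2]
  lat <- matrix(config$extent[4] - config$cellsize / 2 -
                  (seq_len(nr) - 1) * config$cellsize, nr, nc)
  biome <- matrix(NA_real_, nr, nc)
  region <- matrix(NA_real_, nr, nc)

  # Blocks are separated by one-cell water strips (a coast/river analogue) so
  # that spatial neighbourhoods -- footprint smoothing, feature averaging --
  # do not straddle two model domains, which at this toy scale would couple
  # strata that in reality are separated by vast distances.
  split_blocks <- function(idx, k) {
    # k blocks separated by single-strip gaps; NULL when idx is too short
    if (length(idx) < 2 * k - 1) return(NULL)
    w <- (length(idx) - (k - 1)) %/% k
    blocks <- vector("list", k)
    at <- 1L
    for (i in seq_len(k)) {
      extra <- if (i <= (length(idx) - (k - 1)) %% k) 1L else 0L
      blocks[[i]] <- idx[at:(at + w + extra - 1L)]
      at <- at + w + extra + 1L             # +1 skips the strip
    }
    blocks
  }

  # longitudinal panels: hemispheric bands / EBF regions / CRO regions
  panels <- split_blocks(seq_len(nc), 3L)
  if (is.null(panels)) panels <- list(integer(0), integer(0), integer(0))
  colsA <- panels[[1]]; colsB <- panels[[2]]; colsC <- panels[[3]]

  # panel A: five latitudinal bands per hemisphere, strip-separated (the
  # hemisphere boundary row(s) also fall on a strip)
  groupsA <- c(igbp_classes[["enf"]], igbp_classes[["dbf"]],
               igbp_classes[["closed_shrubland"]], igbp_classes[["savanna"]],
               igbp_classes[["grassland"]])
  for (h in c("NH", "SH")) {
    rows <- which(if (h == "NH") lat[, 1] >= 0 else lat[, 1] < 0)
    if (!length(rows)) next
    rows <- if (h == "NH") rows[-length(rows)] else rows[-1]  # equator strip
    bands <- split_blocks(rows, 5L)
    if (is.null(bands)) next
    for (k in 1:5) biome[bands[[k]], colsA] <- groupsA[k]
  }

  # panel B: evergreen broadleaf forest in 3 region columns; panel C:
  # cropland in 6 continent columns (left as water when too narrow -- the
  # missing-stratum check below reports exactly what could not be hosted)
  subB <- split_blocks(colsB, 3L)
  if (!is.null(subB)) for (k in 1:3) {
    biome[, subB[[k]]] <- igbp_classes[["ebf"]]
    region[, subB[[k]]] <- region_codes[[ebf_regions[k]]]
  }
  subC <- split_blocks(colsC, 6L)
  if (!is.null(subC)) for (k in 1:6) {
    biome[, subC[[k]]] <- igbp_classes[["cropland"]]
    region[, subC[[k]]] <- region_codes[[cro_regions[k]]]
  }
  biome[is.na(biome)] <- igbp_classes[["water"]]   # separator strips

  # sprinkle non-vegetated cells (seeded)
  if (config$nonveg_fraction > 0) {
    set.seed(derive_seed(seed, "2000-01-01", 1L))
    n_nv <- round(config$nonveg_fraction * nr * nc)
    idx <- sample.int(nr * nc, n_nv)
    nv_class <- sample(c(igbp_classes[["water"]], igbp_classes[["urban"]],
                         igbp_classes[["snow_ice"]], igbp_classes[["barren"]]),
                       n_nv, replace = TRUE,
                       prob = c(0.55, 0.15, 0.15, 0.15))
    biome[idx] <- nv_class
    region[idx] <- NA_real_
  }

  biome_grid <- sif_grid(biome, config$extent, config$cellsize,
                         units = "IGBP class")
  region_grid <- sif_grid(region, config$extent, config$cellsize,
                          units = "region code")
  stratum <- assign_model_ids(biome_grid, regions = region_grid)

  # every stratum the extent can host must actually be present
  required <- c(3:5, 14:19,
                if (any(lat >= 0)) c(1, 6, 8, 10, 12),
                if (any(lat < 0)) c(2, 7, 9, 11, 13))
  present <- sort(unique(stats::na.omit(as.vector(stratum$values))))
  missing <- setdiff(required, present)
  if (length(missing)) {
    tab <- stratum_table()
    stop("extent too small to host all configured biomes; missing strata: ",
         paste(sprintf("%d (%s/%s)", missing, tab$group[missing],
                       tab$region[missing]), collapse = ", "))
  }

  structure(list(config = config, seed = as.integer(seed),
                 biome = biome_grid, region = region_grid,
                 stratum = stratum, mask = vegetated_mask(biome_grid)),
            class = "sif_world")
}

#' @export
print.sif_world <- function(x, ...) {
  cat("<sif_world> ", nrow(x$biome$values), "x", ncol(x$biome$values),
      " cells, years ", paste(x$config$years, collapse = ","),
      ", seed ", x$seed, "\n", sep = "")
  cat("  strata present: ",
      paste(sort(unique(stats::na.omit(as.vector(x$stratum$values)))),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

check_world_date <- function(world, date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  if (!yr %in% world$config$years)
    stop("date ", format(date), " is outside the simulated years (",
         paste(world$config$years, collapse = ", "), ")")
  date
}

# deterministic within-stratum spatial texture in [-1, 1]
spatial_field <- function(nr, nc) {
  fr <- (row(matrix(0, nr, nc)) - 1) / max(1, nr - 1)
  fc <- (col(matrix(0, nr, nc)) - 1) / max(1, nc - 1)
  0.6 * sin(2 * pi * 2 * fc) + 0.4 * cos(2 * pi * 3 * fr)
}

#' Simulate a day of 7-band surface reflectance
#'
#' Every band follows a stratum-specific annual sinusoid (peak at the
#' stratum's phase) around a band-specific base level, plus a deterministic
#' spatial gradient and optional Gaussian noise, clamped to \[0, 1\].  Band 2
#' (NIR-like) has the largest seasonal amplitude and therefore co-varies with
#' the latent SIF signal.  Deterministic for fixed (world, date).
#'
#' @param world A `sif_world`.
#' @param date Date within the configured years.
#' @return A [refl_stack()].
#' @export
simulate_reflectance <- function(world, date) {
  date <- check_world_date(world, date)
  cfg <- world$config
  nr <- nrow(world$biome$values); nc <- ncol(world$biome$values)
  d <- doy365(date)
  st <- world$stratum$values
  co <- cfg$coef[match(st, cfg$coef$stratum), ]
  f <- matrix(season_factor(d, co$phase), nr, nc)
  f[is.na(f)] <- 0                       # non-vegetated: flat season
  scale_s <- matrix(0.7 + 0.015 * co$stratum, nr, nc)
  scale_s[is.na(scale_s)] <- 0.7
  off_s <- matrix(0.01 * (((co$stratum * 7) %% 11) - 5) / 5, nr, nc)
  off_s[is.na(off_s)] <- 0
  sp <- spatial_field(nr, nc)

  if (cfg$sigma_refl > 0) set.seed(derive_seed(world$seed, date, 2L))
  bands <- array(NA_real_, c(nr, nc, 7))
  for (b in 1:7) {
    v <- refl_band_base[b] + off_s + refl_band_amp[b] * scale_s * f
    # spatial gradient, strongest on the NIR band so the contrast g = b2 - b1
    # varies within a stratum
    gain <- c(0.3, 1, 0.1, 0.1, 0.4, 0.2, 0.1)[b]
    v <- v + cfg$spatial_amp * gain * sp
    if (cfg$sigma_refl > 0)
      v <- v + matrix(stats::rnorm(nr * nc, 0, cfg$sigma_refl), nr, nc)
    bands[, , b] <- pmin(1, pmax(0, v))
  }
  refl_stack(bands, cfg$extent, cfg$cellsize, date = date)
}

# scalar vegetation contrast the latent mapping is linear in
band_contrast <- function(bands) bands[, , 2] - bands[, , 1]

#' Latent true SIF for one date
#'
#' \eqn{S = \max(0, a_0(s, d) + a_1(s, d) (b_2 - b_1))} per vegetated cell;
#' `NA` elsewhere.  The coefficients are those returned by
#' [latent_coefficients()], so the truth is fully recoverable.
#'
#' @param world A `sif_world`.
#' @param refl A [refl_stack()] aligned to the world grid.
#' @param date Date of the slice.
#' @return A [sif_grid()] of true SIF.
#' @export
simulate_true_sif <- function(world, refl, date) {
  date <- check_world_date(world, date)
  check_same_geometry(world$biome, refl, "world and reflectance")
  d <- doy365(date)
  nr <- nrow(world$biome$values); nc <- ncol(world$biome$values)
  st <- as.vector(world$stratum$values)
  co <- latent_coefficients(world, st, d)
  g <- as.vector(band_contrast(refl$bands))
  s <- pmax(0, co$a0 + co$a1 * g)
  s[is.na(st)] <- NA_real_
  sif_grid(matrix(s, nr, nc), world$config$extent, world$config$cellsize,
           date = date)
}

# swath columns for a date: strips that shift so the union over one revisit
# period tiles the whole grid
swath_columns <- function(world, date) {
  cfg <- world$config
  nc <- ncol(world$biome$values)
  w <- cfg$swath_cells
  if (is.null(w)) w <- ceiling(nc / cfg$revisit_days)
  w <- min(nc, max(1L, as.integer(w)))
  pos <- as.integer(as.Date(date)) %% cfg$revisit_days
  c0 <- 1L + floor(pos / cfg$revisit_days * nc)
  (((c0 - 1L) + seq_len(w) - 1L) %% nc) + 1L
}

#' Sample satellite footprints for one date
#'
#' Soundings fall at uniform random positions within the date's pseudo-orbital
#' swath, restricted to cells with finite truth.  Each sounding over true
#' value \eqn{S} reports `sif_757 =` \eqn{S + e_1} and
#' `sif_771 =` \eqn{\tfrac{2}{3} S + e_2} with independent
#' \eqn{N(0, \sigma_{band}^2)} errors; a configured fraction receives a
#' failing quality flag (`qc_flag = 1`).
#'
#' @param world A `sif_world`.
#' @param truth [sif_grid()] of true SIF for `date` (from
#'   [simulate_true_sif()]).
#' @param date Date.
#' @param seed Optional override of the world seed for the noise stream.
#' @return A footprint `data.frame` with columns `id`, `date`, `lat`, `lon`,
#'   `sif_757`, `sif_771`, `qc_flag`.
#' @export
sample_footprints <- function(world, truth, date, seed = world$seed) {
  date <- check_world_date(world, date)
  check_same_geometry(world$biome, truth, "world and truth")
  cfg <- world$config
  nr <- nrow(truth$values)
  cols <- swath_columns(world, date)
  nc <- ncol(truth$values)
  cells <- expand.grid(row = seq_len(nr), col = cols)
  cells <- cells[is.finite(truth$values[cbind(cells$row, cells$col)]), ,
                 drop = FALSE]
  set.seed(derive_seed(seed, date, 3L))
  n_sw <- stats::rpois(1, cfg$fp_per_cell * nrow(cells))
  pick <- if (n_sw > 0 && nrow(cells) > 0)
    cells[sample.int(nrow(cells), n_sw, replace = TRUE), , drop = FALSE]
  else cells[integer(0), , drop = FALSE]
  # snapshot-area acquisitions: dense patches at random vegetated locations
  if (cfg$sam_per_day > 0) {
    veg <- which(is.finite(truth$values), arr.ind = TRUE)
    rad <- max(1L, round(cfg$sam_radius / cfg$cellsize))
    for (k in seq_len(cfg$sam_per_day)) {
      if (nrow(veg) == 0) break
      ctr <- veg[sample.int(nrow(veg), 1), ]
      patch <- expand.grid(
        row = max(1L, ctr[1] - rad):min(nr, ctr[1] + rad),
        col = max(1L, ctr[2] - rad):min(nc, ctr[2] + rad))
      patch <- patch[is.finite(truth$values[cbind(patch$row, patch$col)]), ,
                     drop = FALSE]
      n_p <- stats::rpois(1, cfg$fp_per_cell * nrow(patch))
      if (n_p > 0 && nrow(patch) > 0)
        pick <- rbind(pick,
                      patch[sample.int(nrow(patch), n_p, replace = TRUE), ,
                            drop = FALSE])
    }
  }
  n <- nrow(pick)
  if (n == 0)
    return(data.frame(id = character(), date = as.Date(character()),
                      lat = numeric(), lon = numeric(), sif_757 = numeric(),
                      sif_771 = numeric(), qc_flag = integer()))
  lat <- cfg$extent[4] - (pick$row - stats::runif(n)) * cfg$cellsize
  lon <- cfg$extent[1] + (pick$col - stats::runif(n)) * cfg$cellsize
  s <- truth$values[cbind(pick$row, pick$col)]
  e1 <- if (cfg$sigma_band > 0) stats::rnorm(n, 0, cfg$sigma_band) else 0
  e2 <- if (cfg$sigma_band > 0) stats::rnorm(n, 0, cfg$sigma_band) else 0
  qc <- as.integer(stats::runif(n) < cfg$qc_fail_rate)
  data.frame(id = sprintf("fp-%s-%06d", format(date, "%Y%m%d"), seq_len(n)),
             date = date, lat = lat, lon = lon,
             sif_757 = s + e1, sif_771 = (2 / 3) * s + e2, qc_flag = qc,
             stringsAsFactors = FALSE)
}

#' Simulate airborne-style fine-resolution SIF
#'
#' Dense sub-cell samples over a region, valued `airborne_scale` (default
#' 1.12) times the cell truth plus small noise -- emulating an airborne
#' 755 nm retrieval whose magnitude sits about 12% above the satellite
#' 757 nm band.
#'
#' @param world A `sif_world`.
#' @param truth [sif_grid()] of true SIF for `date`.
#' @param region `c(lon_min, lon_max, lat_min, lat_max)`; must lie within the
#'   world extent.
#' @param date Date.
#' @param seed Optional seed override.
#' @return A `data.frame` with columns `lat`, `lon`, `date`, `sif_755`.
#' @export
simulate_airborne <- function(world, truth, region, date, seed = world$seed) {
  date <- check_world_date(world, date)
  ex <- world$config$extent
  if (region[1] < ex[1] || region[2] > ex[2] ||
      region[3] < ex[3] || region[4] > ex[4])
    stop("airborne region [", paste(format(region), collapse = ", "),
         "] extends outside the world extent [",
         paste(format(ex), collapse = ", "), "]")
  cfg <- world$config
  lats <- grid_lats(truth); lons <- grid_lons(truth)
  rows <- which(lats <= region[4] & lats >= region[3])
  cols <- which(lons >= region[1] & lons <= region[2])
  cells <- expand.grid(row = rows, col = cols)
  cells <- cells[is.finite(truth$values[cbind(cells$row, cells$col)]), ,
                 drop = FALSE]
  if (nrow(cells) == 0)
    return(data.frame(lat = numeric(), lon = numeric(),
                      date = as.Date(character()), sif_755 = numeric()))
  set.seed(derive_seed(seed, date, 4L))
  m <- cfg$airborne_per_cell
  idx <- cells[rep(seq_len(nrow(cells)), each = m), ]
  n <- nrow(idx)
  lat <- cfg$extent[4] - (idx$row - stats::runif(n)) * cfg$cellsize
  lon <- cfg$extent[1] + (idx$col - stats::runif(n)) * cfg$cellsize
  s <- truth$values[cbind(idx$row, idx$col)]
  noise <- if (cfg$airborne_sigma > 0)
    stats::rnorm(n, 0, cfg$airborne_sigma) else 0
  data.frame(lat = lat, lon = lon, date = date,
             sif_755 = cfg$airborne_scale * s + noise)
}

#' Day of year on a 365-day circle
#'
#' Dates are mapped to 1..365; in leap years February 29 maps to 60 and later
#' dates are shifted back one so each calendar day keeps its non-leap DOY
#' (one model per DOY, no 366th).
#'
#' @param date A `Date` vector.
#' @return Integer vector in 1..365.
#' @export
doy365 <- function(date) {
  date <- as.Date(date)
  d <- as.POSIXlt(date)$yday + 1L
  yr <- as.POSIXlt(date)$year + 1900L
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  d[leap & d > 60L] <- d[leap & d > 60L] - 1L
  d
}
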