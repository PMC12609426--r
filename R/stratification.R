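# Sub-biome stratification: IGBP land-cover classes -> 19 model domains.
# Biome groups are split by hemisphere (needleleaf/deciduous forest,
# shrubland, savanna, grassland), by tropical region (evergreen broadleaf),
# or by continent (cropland).

#' IGBP class codes
#'
#' Integer codes of the IGBP land-cover legend as used by the MODIS 0.05
#' degree land-cover product: 0 water, 1 ENF, 2 EBF, 3 DNF, 4 DBF, 5 mixed
#' forest, 6 closed shrubland, 7 open shrubland, 8 woody savanna, 9 savanna,
#' 10 grassland, 11 permanent wetland, 12 cropland, 13 urban, 14
#' cropland/natural mosaic, 15 snow and ice, 16 barren.
#'
#' @format Named integer vector.
#' @export
igbp_classes <- c(
  water = 0L, enf = 1L, ebf = 2L, dnf = 3L, dbf = 4L, mixed_forest = 5L,
  closed_shrubland = 6L, open_shrubland = 7L, woody_savanna = 8L,
  savanna = 9L, grassland = 10L, wetland = 11L, cropland = 12L, urban = 13L,
  cropland_mosaic = 14L, snow_ice = 15L, barren = 16L)

# IGBP code -> biome group used for stratification.  Mixed forest is folded
# into the deciduous broadleaf group (closest structural analogue; there is
# no mixed-forest model domain); wetlands are treated as non-vegetated for
# modelling purposes.  Both choices are overridable.
biome_group <- function(codes, mf_group = "DBF", mosaic_group = "CRO",
                        wetland_group = NA_character_) {
  map <- c(`0` = NA, `1` = "NF", `2` = "EBF", `3` = "NF", `4` = "DBF",
           `5` = mf_group, `6` = "SHR", `7` = "SHR", `8` = "SAV",
           `9` = "SAV", `10` = "GRA", `11` = wetland_group, `12` = "CRO",
           `13` = NA, `14` = mosaic_group, `15` = NA, `16` = NA)
  bad <- !is.na(codes) & !(codes %in% 0:16)
  if (any(bad))
    stop("unknown IGBP class code(s): ",
         paste(sort(unique(codes[bad])), collapse = ", "))
  out <- unname(map[as.character(codes)])
  out[is.na(codes)] <- NA_character_
  out
}

#' Vegetated-area mask
#'
#' Marks the cells on which modelling and prediction are performed.  Water,
#' urban, snow/ice and barren cells are excluded, as are wetlands (no model
#' domain is defined for them) and any class whose biome group is unset.
#'
#' @param biome_grid A [sif_grid()] of IGBP class codes (see [igbp_classes]).
#' @param ... Passed to the internal class-to-group mapping
#'   (`mf_group`, `mosaic_group`, `wetland_group`) to override the defaults.
#' @return A `sif_grid` of 0/1 values (1 = vegetated); `NA` input cells stay
#'   `NA`.
#' @export
vegetated_mask <- function(biome_grid, ...) {
  grp <- biome_group(as.vector(biome_grid$values), ...)
  v <- matrix(as.numeric(!is.na(grp)), nrow(biome_grid$values))
  v[is.na(biome_grid$values)] <- NA_real_
  sif_grid(v, biome_grid$extent, biome_grid$cellsize, units = "mask")
}

#' Default region bounding polygons
#'
#' Editable bounding boxes (lon_min, lon_max, lat_min, lat_max) for the
#' tropical evergreen-broadleaf regions (Amazon, Congo, Southeast Asia) and
#' the six cropland continents.  These are deliberately coarse; supply your
#' own list (same names) for serious regional work, or a region-code raster
#' (see [assign_model_ids()]) to bypass polygons entirely.
#'
#' @return Named list of length-4 numeric vectors.
#' @export
default_region_polygons <- function() {
  list(
    amazon        = c(-82, -44, -20, 12),
    congo         = c(5, 35, -12, 8),
    se_asia       = c(90, 160, -12, 28),
    north_america = c(-170, -50, 15, 75),
    south_america = c(-82, -34, -56, 15),
    europe        = c(-11, 60, 35, 72),
    africa        = c(-18, 52, -35, 35),
    asia          = c(60, 180, 5, 77),
    australia     = c(110, 180, -50, -10))
}

# ordered region names per group; order is the tie-break when boxes overlap
ebf_regions <- c("amazon", "congo", "se_asia")
cro_regions <- c("north_america", "south_america", "europe", "africa",
                 "asia", "australia")

# model-ID lookup: group x subdivision -> 1..19
stratum_id_table <- function() {
  data.frame(
    group  = c("NF", "NF", "EBF", "EBF", "EBF", "DBF", "DBF", "SHR", "SHR",
               "SAV", "SAV", "GRA", "GRA", rep("CRO", 6)),
    region = c("NH", "SH", "amazon", "congo", "se_asia", "NH", "SH", "NH",
               "SH", "NH", "SH", "NH", "SH", cro_regions),
    id     = 1:19,
    stringsAsFactors = FALSE)
}

#' Names of the 19 sub-biome model domains
#'
#' @return A `data.frame` with columns `id`, `group`, `region`.
#' @export
stratum_table <- function() {
  t <- stratum_id_table()
  t[, c("id", "group", "region")]
}

in_bbox <- function(lat, lon, box) {
  lon >= box[1] & lon <= box[2] & lat >= box[3] & lat <= box[4]
}

region_codes <- c(amazon = 1L, congo = 2L, se_asia = 3L, north_america = 4L,
                  south_america = 5L, europe = 6L, africa = 7L, asia = 8L,
                  australia = 9L)

#' Assign sub-biome model IDs
#'
#' Maps every vegetated cell of an IGBP land-cover raster to one of the 19
#' sub-biome model domains: needleleaf forest, deciduous broadleaf forest,
#' shrubland, savanna and grassland are split by hemisphere (cell-centre
#' latitude >= 0 is "northern"); evergreen broadleaf forest by the Amazon,
#' Congo and Southeast-Asia regions; cropland by six continents.
#'
#' @param biome_grid A [sif_grid()] of IGBP class codes.
#' @param regions Either a named list of bounding boxes (see
#'   [default_region_polygons()]) or a `sif_grid` of region codes
#'   (1 amazon, 2 congo, 3 se_asia, 4 north_america, 5 south_america,
#'   6 europe, 7 africa, 8 asia, 9 australia) as produced by the synthetic
#'   world generator, which bypasses polygon lookup.
#' @param unmatched What to do with an evergreen-broadleaf or cropland cell
#'   falling outside every region: `"none"` leaves it unassigned (reported),
#'   `"nearest"` assigns the region whose box centre is closest.
#' @param ... Class-to-group overrides, as in [vegetated_mask()].
#' @return A `sif_grid` of model IDs (1-19, `NA` for non-vegetated or
#'   unassigned cells) with an `"unmatched"` attribute giving the count of
#'   region-less vegetated cells.
#' @export
assign_model_ids <- function(biome_grid, regions = default_region_polygons(),
                             unmatched = c("none", "nearest"), ...) {
  unmatched <- match.arg(unmatched)
  nr <- nrow(biome_grid$values); nc <- ncol(biome_grid$values)
  grp <- matrix(biome_group(as.vector(biome_grid$values), ...), nr)
  lat <- matrix(grid_lats(biome_grid), nr, nc)
  lon <- matrix(grid_lons(biome_grid), nr, nc, byrow = TRUE)
  ids <- stratum_id_table()
  out <- matrix(NA_real_, nr, nc)
  n_unmatched <- 0L

  hemi <- ifelse(lat >= 0, "NH", "SH")
  for (g in c("NF", "DBF", "SHR", "SAV", "GRA")) {
    for (h in c("NH", "SH")) {
      sel <- !is.na(grp) & grp == g & hemi == h
      out[sel] <- ids$id[ids$group == g & ids$region == h]
    }
  }

  region_of <- function(sel, region_names) {
    # returns region name per selected cell, NA when outside all boxes
    res <- rep(NA_character_, sum(sel))
    if (inherits(regions, "sif_grid")) {
      code <- regions$values[sel]
      nm <- names(region_codes)[match(code, region_codes)]
      res <- ifelse(nm %in% region_names, nm, NA_character_)
    } else {
      la <- lat[sel]; lo <- lon[sel]
      for (rn in region_names) {
        hit <- is.na(res) & in_bbox(la, lo, regions[[rn]])
        res[hit] <- rn
      }
      if (unmatched == "nearest" && anyNA(res)) {
        centres <- vapply(region_names, function(rn)
          c(mean(regions[[rn]][3:4]), mean(regions[[rn]][1:2])), numeric(2))
        for (i in which(is.na(res))) {
          d <- (centres[1, ] - la[i])^2 + (centres[2, ] - lo[i])^2
          res[i] <- region_names[which.min(d)]
        }
      }
    }
    res
  }

  for (g in c("EBF", "CRO")) {
    rn <- if (g == "EBF") ebf_regions else cro_regions
    sel <- !is.na(grp) & grp == g
    if (!any(sel)) next
    reg <- region_of(sel, rn)
    n_unmatched <- n_unmatched + sum(is.na(reg))
    id <- ids$id[match(paste(g, reg), paste(ids$group, ids$region))]
    out[sel] <- id
  }

  res <- sif_grid(out, biome_grid$extent, biome_grid$cellsize,
                  units = "model id")
  attr(res, "unmatched") <- n_unmatched
  res
}
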