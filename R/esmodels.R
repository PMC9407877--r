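# The four ecosystem-service models. NPP follows the CASA light-use
# efficiency scheme (NPP = APAR x eps, summed over months); food production
# allocates a zone's reported total yield to cropland cells in proportion to
# NDVI; soil conservation is RUSLE potential-minus-actual erosion
# (SC = R K LS (1 - C P)); water yield is annual precipitation minus actual
# evapotranspiration from the one-parameter Budyko (Fu) curve used by the
# InVEST water-yield model.

#' Construct an ecosystem-service layer
#' @param service One of `"NPP", "FP", "SC", "WY"`.
#' @param year Calendar year.
#' @param values Numeric matrix of cell values.
#' @param units Unit string (`"t ha-1"` for NPP/FP/SC, `"mm"` for WY).
#' @param grid The shared [grid_spec()].
#' @return An `es_layer` object.
#' @export
es_layer <- function(service, year, values, units, grid) {
  structure(list(service = service, year = year, values = values,
                 units = units, grid = grid), class = "es_layer")
}

#' @export
print.es_layer <- function(x, ...) {
  cat(sprintf("<es_layer> %s %s  mean %.3f %s (%d x %d)\n", x$service,
              format(x$year), mean(x$values, na.rm = TRUE), x$units,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# ---- NPP (CASA) ----------------------------------------------------------

#' CASA parameter set
#'
#' Closure constants for the light-use-efficiency NPP model. `eps_max` is
#' the maximum light-use efficiency (g C per MJ APAR) per land-use class;
#' water and urban cells fix NPP at zero. FPAR rises linearly with NDVI
#' between `ndvi_min` and `ndvi_max` up to `fpar_max`. The temperature
#' stress is a Gaussian around `t_opt` with scale `t_width`; the water
#' stress is `0.5 + 0.5 * min(1, ppt_m / pet_m)` with a simple
#' temperature-proportional monthly PET proxy (`pet_coef` mm per deg C), so
#' the efficiency term never depends on solar radiation and NPP stays
#' linear in it. `phenology` scales the annual NDVI surface into months.
#'
#' @param eps_max Named vector of class-wise maximum efficiencies (g C/MJ).
#' @param ndvi_min,ndvi_max NDVI at bare soil / full canopy.
#' @param fpar_max Upper FPAR bound.
#' @param t_opt,t_width Temperature-stress optimum and scale (deg C).
#' @param pet_coef Monthly PET proxy slope (mm per deg C).
#' @param use_stress Disable both stress terms when `FALSE` (testing aid).
#' @param phenology 12 monthly NDVI multipliers (mean 1).
#' @return List of class `casa_params`.
#' @export
casa_params <- function(eps_max = c(cropland = 0.56, forest = 0.69,
                                    grassland = 0.54, water = 0, urban = 0,
                                    unused = 0.40),
                        ndvi_min = 0.05, ndvi_max = 0.95, fpar_max = 0.95,
                        t_opt = 20, t_width = 15, pet_coef = 3,
                        use_stress = TRUE,
                        phenology = NULL) {
  if (is.null(phenology)) {
    ph <- 1 + 0.45 * cos(2 * pi * ((1:12) - 7.5) / 12)
    phenology <- ph / mean(ph)
  }
  structure(list(eps_max = eps_max, ndvi_min = ndvi_min, ndvi_max = ndvi_max,
                 fpar_max = fpar_max, t_opt = t_opt, t_width = t_width,
                 pet_coef = pet_coef, use_stress = use_stress,
                 phenology = phenology), class = "casa_params")
}

#' Annual net primary productivity (CASA)
#'
#' Sums monthly `APAR x eps` where `APAR = SOL_m x FPAR x 0.5` (half of
#' shortwave is photosynthetically active) and `eps` is the class-wise
#' maximum light-use efficiency damped by temperature and water stress.
#' Internal units are g C m-2; the returned layer is converted to t ha-1
#' (x 0.01). Water and urban cells return 0.
#'
#' @param forcing A `forcing_stack` with 12 monthly solar and precipitation
#'   layers.
#' @param landuse A `landuse_map` on the same grid.
#' @param params A [casa_params()] set.
#' @return An `es_layer` (service `"NPP"`, units t ha-1).
#' @export
compute_npp <- function(forcing, landuse, params = casa_params()) {
  for (nm in c("sol_monthly", "ppt_monthly", "tem_monthly"))
    if (length(forcing[[nm]]) != 12L)
      stop_with(paste0("forcing$", nm, " must hold 12 months"),
                "eslines_incomplete_forcing")
  cls <- landuse$classes
  epsm <- matrix(params$eps_max[names(LANDUSE_CODES)[cls]],
                 nrow(cls), ncol(cls))
  veg_mask <- !(cls %in% LANDUSE_CODES[c("water", "urban")])
  npp <- matrix(0, nrow(cls), ncol(cls))
  for (m in 1:12) {
    ndvi_m <- clamp(forcing$ndvi * params$phenology[m], -1, 1)
    fpar <- clamp((ndvi_m - params$ndvi_min) /
                    (params$ndvi_max - params$ndvi_min), 0, 1) * params$fpar_max
    fpar[!veg_mask] <- 0
    apar <- forcing$sol_monthly[[m]] * fpar * 0.5
    if (params$use_stress) {
      tem_m <- forcing$tem_monthly[[m]]
      t_stress <- exp(-0.5 * ((tem_m - params$t_opt) / params$t_width)^2)
      pet_m <- pmax(1, params$pet_coef * pmax(tem_m, 0))
      w_stress <- 0.5 + 0.5 * pmin(1, forcing$ppt_monthly[[m]] / pet_m)
      eps <- epsm * t_stress * w_stress
    } else eps <- epsm
    npp <- npp + apar * eps
  }
  es_layer("NPP", forcing$year, npp * 0.01, "t ha-1", forcing$grid)
}

# ---- food production ------------------------------------------------------

#' Food production allocated to cropland cells by NDVI share
#'
#' Within each administrative zone, the zone's total yield `gsum_t` is
#' split over cropland cells in proportion to their NDVI:
#' `FP_i = NDVI_i / sum(NDVI over zone cropland) * Gsum`. Cells outside
#' cropland get 0. A zone whose cropland NDVI sums to zero (or that has no
#' cropland) is skipped with a warning and contributes 0.
#'
#' @param ndvi NDVI matrix.
#' @param landuse A `landuse_map`.
#' @param zones A `zone_map`; its `yield_table` must carry one `gsum_t`
#'   row per zone (pre-filtered to the year of interest).
#' @param year Year recorded on the output layer.
#' @param per_ha Divide the per-cell tonnage by cell area to report t ha-1.
#' @return An `es_layer` (service `"FP"`; units `"t"` per cell, or
#'   `"t ha-1"` when `per_ha`). Conservation: the summed tonnage per zone
#'   equals `gsum_t` exactly (up to float tolerance).
#' @export
compute_fp <- function(ndvi, landuse, zones, year = NA_integer_,
                       per_ha = FALSE) {
  yt <- zones$yield_table
  if (!is.null(yt$year) && length(unique(yt$year)) > 1)
    stop_invalid("yield_table must be filtered to a single year")
  zid <- sort(unique(as.vector(zones$zones)))
  if (!all(zid %in% yt$zone_id))
    stop_invalid("every zone in the raster needs a yield_table row")
  crop <- landuse$classes == LANDUSE_CODES[["cropland"]]
  fp <- matrix(0, nrow(ndvi), ncol(ndvi))
  skipped <- integer(0)
  for (z in zid) {
    inz <- zones$zones == z & crop
    s <- sum(pmax(ndvi[inz], 0))
    if (!any(inz) || s <= 0) {
      skipped <- c(skipped, z)
      next
    }
    gsum <- yt$gsum_t[match(z, yt$zone_id)]
    fp[inz] <- pmax(ndvi[inz], 0) / s * gsum
  }
  if (length(skipped) > 0)
    warning(sprintf("FP: %d zone(s) without positive cropland NDVI skipped: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  units <- "t"
  if (per_ha) {
    fp <- fp / cell_area_ha(landuse$grid)
    units <- "t ha-1"
  }
  out <- es_layer("FP", year, fp, units, landuse$grid)
  out$skipped_zones <- skipped
  out
}

# ---- RUSLE factors and soil conservation ---------------------------------

#' RUSLE closure parameters
#'
#' @param c_floor Cover factor at full fractional vegetation cover
#'   (C decays exponentially from 1 at bare soil to this floor).
#' @param ndvi_soil,ndvi_veg NDVI of bare soil / full canopy used for the
#'   fractional-cover transform.
#' @param p_table Support-practice factor per land-use class (0 on water
#'   and urban: no erodible surface).
#' @param slope_length Slope length lambda (m); defaults to the cell size
#'   at run time when `NULL`.
#' @return List of class `rusle_params`.
#' @export
rusle_params <- function(c_floor = 0.01, ndvi_soil = 0.05, ndvi_veg = 0.9,
                         p_table = c(cropland = 0.35, forest = 1,
                                     grassland = 1, water = 0, urban = 0,
                                     unused = 1),
                         slope_length = NULL) {
  structure(list(c_floor = c_floor, ndvi_soil = ndvi_soil,
                 ndvi_veg = ndvi_veg, p_table = p_table,
                 slope_length = slope_length), class = "rusle_params")
}

#' Compute the five RUSLE factor rasters
#'
#' R: monthly Wischmeier rainfall erosivity
#' `sum_m 1.735 * 10^(1.5 log10(p_m^2 / P) - 0.8188)` (MJ mm hm-2 h-1).
#' K: EPIC soil-erodibility from sand/silt/clay/organic-carbon fractions,
#' converted to SI (t h MJ-1 mm-1) with the 0.1317 factor.
#' LS: slope from the steepest of the eight DEM neighbours (D8), steepness
#' factor S by the two-piece McCool relation (`10.8 sin t + 0.03` under 9%
#' slope, `16.8 sin t - 0.5` above), length factor `(lambda/22.13)^m` with
#' the exponent stepping 0.2/0.3/0.4/0.5 by slope class.
#' C: `exp(log(c_floor) * fc)` with fractional cover fc from NDVI, so C = 1
#' on bare soil and `c_floor` under full canopy.
#' P: class lookup.
#'
#' @param forcing A `forcing_stack` (monthly precipitation, NDVI, soil).
#' @param landuse A `landuse_map`.
#' @param dem Elevation matrix (m); defaults to `forcing$dem`.
#' @param params A [rusle_params()] set.
#' @return A `rusle_factors` list with matrices `R, K, LS, C, P`.
#' @export
compute_rusle_factors <- function(forcing, landuse, dem = forcing$dem,
                                  params = rusle_params()) {
  if (length(forcing$ppt_monthly) != 12L)
    stop_with("monthly precipitation required", "eslines_incomplete_forcing")
  grid <- forcing$grid

  P_ann <- Reduce(`+`, forcing$ppt_monthly)
  R <- matrix(0, grid$n_rows, grid$n_cols)
  pos <- P_ann > 0
  for (m in 1:12) {
    pm <- forcing$ppt_monthly[[m]]
    term <- matrix(0, grid$n_rows, grid$n_cols)
    ok <- pos & pm > 0
    term[ok] <- 1.735 * 10^(1.5 * log10(pm[ok]^2 / P_ann[ok]) - 0.8188)
    R <- R + term
  }

  K <- epic_k(forcing$soil$sand, forcing$soil$silt, forcing$soil$clay,
              forcing$soil$oc)
  LS <- ls_factor(dem, grid$cell_size,
                  slope_length = params$slope_length %||% grid$cell_size)

  fc <- clamp((forcing$ndvi - params$ndvi_soil) /
                (params$ndvi_veg - params$ndvi_soil), 0, 1)
  C <- exp(log(params$c_floor) * fc)

  P <- matrix(params$p_table[names(LANDUSE_CODES)[landuse$classes]],
              grid$n_rows, grid$n_cols)

  structure(list(R = R, K = K, LS = LS, C = C, P = P, grid = grid,
                 year = forcing$year), class = "rusle_factors")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# EPIC erodibility; texture fractions and organic carbon in percent.
epic_k <- function(sand, silt, clay, oc) {
  sn1 <- 1 - sand / 100
  k <- (0.2 + 0.3 * exp(-0.0256 * sand * (1 - silt / 100))) *
    (silt / pmax(clay + silt, 1e-9))^0.3 *
    (1 - 0.25 * oc / (oc + exp(3.72 - 2.95 * oc))) *
    (1 - 0.7 * sn1 / (sn1 + exp(-5.51 + 22.9 * sn1)))
  0.1317 * k
}

# D8 slope + McCool LS. Flat cells fall back to the minimum S of 0.03.
ls_factor <- function(dem, cell_size, slope_length) {
  if (length(dem) == 1L) {
    message("LS: single flat cell; factor set to its minimum")
    return(matrix((slope_length / 22.13)^0.2 * 0.03, 1, 1))
  }
  grad <- matrix(0, nrow(dem), ncol(dem))
  for (j in seq_len(nrow(offsets8))) {
    d <- sqrt(sum(offsets8[j, ]^2)) * cell_size
    nb <- shift_mat(dem, offsets8[j, 1], offsets8[j, 2])
    g <- (dem - nb) / d       # positive downhill gradient toward neighbour
    g[is.na(g)] <- 0
    grad <- pmax(grad, g)
  }
  theta <- atan(grad)
  slope_pct <- grad * 100
  S <- ifelse(slope_pct < 9, 10.8 * sin(theta) + 0.03,
              16.8 * sin(theta) - 0.5)
  m <- ifelse(slope_pct < 1, 0.2,
              ifelse(slope_pct < 3.5, 0.3,
                     ifelse(slope_pct < 5, 0.4, 0.5)))
  L <- (slope_length / 22.13)^m
  L * S
}

#' Soil conservation from RUSLE factors
#'
#' `SC = Ap - Ar = R K LS - R K LS C P = R K LS (1 - C P)`, in t ha-1.
#' Non-negative because C and P never exceed 1.
#'
#' @param factors A `rusle_factors` object.
#' @return An `es_layer` (service `"SC"`, units t ha-1).
#' @export
compute_sc <- function(factors) {
  for (nm in c("R", "K", "LS", "C", "P")) {
    v <- factors[[nm]]
    if (any(v < 0, na.rm = TRUE))
      stop_with(paste("negative values in factor", nm), "eslines_invalid_input")
  }
  if (any(factors$C > 1 + 1e-12, na.rm = TRUE) ||
      any(factors$P > 1 + 1e-12, na.rm = TRUE))
    stop_with("C and P must not exceed 1", "eslines_invalid_input")
  sc <- factors$R * factors$K * factors$LS * (1 - factors$C * factors$P)
  es_layer("SC", factors$year, sc, "t ha-1", factors$grid)
}

# ---- water yield (Budyko / InVEST) ---------------------------------------

#' Water-yield parameter set
#'
#' @param kc_table Per-class evapotranspiration coefficient Kc (scales
#'   reference ET into potential ET).
#' @param z Seasonal constant Z of the Budyko parameter
#'   `w = AWC * Z / PPT + 1.25`. Default 7.5 (the source never states it).
#' @param awc Available water capacity raster (mm); built from soil texture
#'   via [awc_from_soil()] when `NULL`.
#' @param et0 Reference evapotranspiration raster (mm/yr); built from
#'   annual temperature via [et0_from_temperature()] when `NULL`.
#' @return List of class `wy_params`.
#' @export
wy_params <- function(kc_table = c(cropland = 0.85, forest = 1, grassland = 0.75,
                                   water = 1.1, urban = 0.3, unused = 0.5),
                      z = 7.5, awc = NULL, et0 = NULL) {
  if (z <= 0) stop_invalid("Z must be > 0")
  if (any(kc_table < 0)) stop_invalid("Kc must be >= 0")
  structure(list(kc_table = kc_table, z = z, awc = awc, et0 = et0),
            class = "wy_params")
}

#' Available water capacity from soil texture
#'
#' Simple pedotransfer: plant-available water fraction
#' `0.05 + 0.004 clay + 0.002 silt + 0.01 oc` (clamped to `[0.05, 0.45]`)
#' times an effective root depth.
#'
#' @param soil List with `clay`, `silt`, `oc` percent rasters.
#' @param root_depth_mm Effective rooting depth (mm).
#' @return AWC matrix (mm).
#' @export
awc_from_soil <- function(soil, root_depth_mm = 1000) {
  frac <- clamp(0.05 + 0.004 * soil$clay + 0.002 * soil$silt +
                  0.01 * soil$oc, 0.05, 0.45)
  frac * root_depth_mm
}

#' Reference evapotranspiration from annual mean temperature
#'
#' Linear proxy `ET0 = 66 * max(T, 0)` mm/yr (about 1000 mm at 15 deg C),
#' adequate for synthetic landscapes; replace with a measured raster via
#' [wy_params()] for real inputs.
#'
#' @param tem Annual mean temperature matrix (deg C).
#' @return ET0 matrix (mm/yr).
#' @export
et0_from_temperature <- function(tem) pmax(tem, 0) * 66

#' Annual water yield (Budyko-Fu curve, InVEST convention)
#'
#' `WY = (1 - AET/PPT) * PPT` with
#' `AET/PPT = 1 + PET/PPT - (1 + (PET/PPT)^w)^(1/w)`,
#' `PET = Kc(class) * ET0`, and `w = AWC * Z / PPT + 1.25`. Cells with
#' zero precipitation return 0 by convention.
#'
#' @param forcing A `forcing_stack`.
#' @param landuse A `landuse_map`.
#' @param params A [wy_params()] set.
#' @return An `es_layer` (service `"WY"`, units mm), bounded by
#'   `0 <= WY <= PPT`.
#' @export
compute_wy <- function(forcing, landuse, params = wy_params()) {
  ppt <- forcing$ppt
  awc <- params$awc %||% awc_from_soil(forcing$soil)
  et0 <- params$et0 %||% et0_from_temperature(forcing$tem)
  kc <- matrix(params$kc_table[names(LANDUSE_CODES)[landuse$classes]],
               nrow(ppt), ncol(ppt))
  pet <- kc * et0

  wy <- matrix(0, nrow(ppt), ncol(ppt))
  pos <- ppt > 0
  if (any(!pos)) message(sprintf("WY: %d cell(s) with PPT = 0 set to 0",
                                 sum(!pos)))
  r <- pet[pos] / ppt[pos]
  w <- awc[pos] * params$z / ppt[pos] + 1.25
  # (1 + r^w)^(1/w) computed in log space so large w neither under- nor
  # overflows: log term = (max(t,0) + log1p(exp(-|t|)))/w with t = w log r
  t <- w * log(r)
  t[r == 0] <- -Inf
  root <- exp((pmax(t, 0) + log1p(exp(-abs(t)))) / w)
  aet_ratio <- 1 + r - root
  wy[pos] <- pmax(0, (1 - aet_ratio)) * ppt[pos]
  es_layer("WY", forcing$year, wy, "mm", forcing$grid)
}

#' Spatial-mean table of a set of ES layers
#'
#' @param layers_by_year List (one element per year) of named lists of
#'   `es_layer` objects.
#' @return data.frame with `year` and one `<service>_mean` column each.
#' @export
es_means <- function(layers_by_year) {
  do.call(rbind, lapply(layers_by_year, function(ly) {
    row <- lapply(ly, function(l) mean(l$values, na.rm = TRUE))
    names(row) <- paste0(tolower(names(ly)), "_mean")
    cbind(data.frame(year = ly[[1]]$year), as.data.frame(row))
  }))
}
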