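# Synthetic input generator: land-use mosaics, climate/vegetation forcing
# stacks, administrative zones with yield tables, and scatter clouds with a
# known upper boundary. Every generator is a pure function of its arguments
# and a seed, so downstream stages have ground-truth recovery tests.

LANDUSE_CODES <- c(cropland = 1L, forest = 2L, grassland = 3L,
                   water = 4L, urban = 5L, unused = 6L)

landuse_code <- function(name) {
  code <- LANDUSE_CODES[name]
  if (anyNA(code)) stop_invalid(paste0("unknown land-use class: ",
                                       paste(name[is.na(code)], collapse = ", ")))
  unname(code)
}

#' Generate a six-class land-use mosaic
#'
#' Modified-random-clusters landscape: class nuclei are scattered over the
#' grid (their number shrinks as `clumping` grows), then grown outward in
#' quota-limited breadth-first rounds until every class reaches its target
#' cell count. Realized class counts equal the largest-remainder rounding
#' of `class_proportions`, so composition is exact up to one cell per class.
#'
#' @param spec A [grid_spec()].
#' @param class_proportions Named numeric vector/list (names among
#'   `cropland, forest, grassland, water, urban, unused`) summing to 1.
#' @param clumping Spatial aggregation in `[0, 1]`: 0 gives salt-and-pepper
#'   maps, values near 1 give few large patches.
#' @param seed Integer seed; same seed, same map.
#' @return A `landuse_map`: list with `grid` and integer matrix `classes`
#'   (codes 1 cropland, 2 forest, 3 grassland, 4 water, 5 urban, 6 unused).
#' @export
generate_landscape <- function(spec, class_proportions, clumping = 0.5,
                               seed = 1L) {
  p <- unlist(class_proportions)
  if (abs(sum(p) - 1) > 1e-9)
    stop_invalid("class proportions must sum to 1")
  if (clumping < 0 || clumping > 1)
    stop_invalid("clumping must be in [0, 1]")
  p <- p[p > 0]
  codes <- landuse_code(names(p))
  N <- n_cells(spec)

  target <- apportion(N, as.numeric(p))
  classes <- with_seed(seed, grow_clusters(spec, codes, target, clumping))
  structure(list(grid = spec, classes = classes), class = "landuse_map")
}

# Largest-remainder apportionment of `total` cells among shares `p`.
apportion <- function(total, p) {
  raw <- p / sum(p) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# sample() treats a length-1 numeric first argument as 1:x; never do that
resample <- function(x, size = length(x), ...) {
  x[sample.int(length(x), size, ...)]
}

grow_clusters <- function(spec, codes, target, clumping) {
  nr <- spec$n_rows; nc <- spec$n_cols; N <- nr * nc
  k <- length(codes)
  n_nuclei <- max(k, min(N, ceiling(N * (1 - clumping)^2)))
  nuc_per_class <- pmin(apportion(n_nuclei, target), target)
  nuc_per_class <- pmax(nuc_per_class, ifelse(target > 0L, 1L, 0L))

  lab <- matrix(NA_integer_, nr, nc)
  cells <- sample.int(N, sum(nuc_per_class))
  lab[cells] <- resample(rep(codes, times = nuc_per_class))
  remaining <- target - tabulate_codes(lab, codes)

  repeat {
    un <- which(is.na(lab))
    if (length(un) == 0L || all(remaining <= 0L)) break
    # candidate class per unassigned cell: a random assigned 4-neighbour
    ord <- sample.int(4L)
    cand <- rep(NA_integer_, N)
    for (j in ord) {
      nb <- shift_mat(lab, offsets4[j, 1], offsets4[j, 2])
      take <- is.na(lab) & is.na(cand) & !is.na(nb)
      cand[take] <- nb[take]
    }
    claim <- which(!is.na(cand))
    if (length(claim) == 0L) break
    assigned_any <- FALSE
    for (i in seq_along(codes)) {
      if (remaining[i] <= 0L) next
      mine <- claim[cand[claim] == codes[i]]
      if (length(mine) == 0L) next
      if (length(mine) > remaining[i])
        mine <- resample(mine, remaining[i])
      lab[mine] <- codes[i]
      remaining[i] <- remaining[i] - length(mine)
      assigned_any <- TRUE
    }
    if (!assigned_any) break
  }
  # stalled frontier or exhausted neighbours: fill leftovers at random from
  # the remaining quota so the composition stays exact
  un <- which(is.na(lab))
  if (length(un) > 0L) {
    pool <- rep(codes, times = pmax(remaining, 0L))
    lab[un] <- if (length(pool) == length(un)) resample(pool) else
      resample(codes, length(un), replace = TRUE,
               prob = pmax(remaining, 0L) + 1e-9)
  }
  lab
}

tabulate_codes <- function(lab, codes) {
  vapply(codes, function(cd) sum(lab == cd, na.rm = TRUE), integer(1))
}

#' Class composition of a land-use map
#' @param landuse A `landuse_map`.
#' @return Named numeric vector of class fractions (sums to 1).
#' @export
class_fractions <- function(landuse) {
  v <- table(factor(landuse$classes, levels = LANDUSE_CODES))
  out <- as.numeric(v) / sum(v)
  names(out) <- names(LANDUSE_CODES)
  out
}

# ---- digital elevation model -------------------------------------------

#' Generate a DEM with a central mountain ridge
#'
#' Smoothed random relief plus a Gaussian bump centred on the grid, so the
#' topographic (LS) factor of the erosion model has realistic contrast
#' between a mountainous core and surrounding plains.
#'
#' @param spec A [grid_spec()].
#' @param base Plain elevation (m). @param relief SD of the random relief (m).
#' @param ridge_height Peak height of the central mountain above base (m).
#' @param ridge_frac Ridge footprint as a fraction of the smaller grid
#'   dimension.
#' @param seed Integer seed.
#' @return Elevation matrix (m), non-negative.
#' @export
generate_dem <- function(spec, base = 60, relief = 25, ridge_height = 900,
                         ridge_frac = 0.18, seed = 1L) {
  with_seed(seed, {
    f <- gaussian_field(spec$n_rows, spec$n_cols,
                        range_cells = max(2, round(min(spec$n_rows,
                                                       spec$n_cols) / 20)))
    r <- (row(f) - (spec$n_rows + 1) / 2)
    c <- (col(f) - (spec$n_cols + 1) / 2)
    sigma <- ridge_frac * min(spec$n_rows, spec$n_cols)
    ridge <- ridge_height * exp(-(r^2 + c^2) / (2 * sigma^2))
    pmax(base + relief * f + ridge, 0)
  })
}

# ---- forcing stacks -----------------------------------------------------

# Monthly share of annual precipitation; June-August carry 70% of the year.
PPT_MONTH_WEIGHTS <- c(0.02, 0.02, 0.03, 0.04, 0.05, 0.20,
                       0.25, 0.25, 0.06, 0.04, 0.02, 0.02)

# Monthly share of annual shortwave radiation (summer-peaked, sums to 1).
SOL_MONTH_WEIGHTS <- local({
  w <- 1 + 0.55 * cos(2 * pi * ((1:12) - 7) / 12)
  w / sum(w)
})

#' Generate multi-year climate, vegetation, soil and socioeconomic forcing
#'
#' One `forcing_stack` per year. Annual precipitation follows
#' `mean + trend * (year - years[1])` plus a west-east gradient and a
#' spatially autocorrelated anomaly with the configured `sd`. The anomaly
#' fields keep their natural grid-mean fluctuation (smooth fields have few
#' effective degrees of freedom), which plays the role of yearly regional
#' climate anomalies around the configured path. NDVI is generated as a
#' mixture of the standardized precipitation field (weight
#' `ndvi_coupling`) and independent noise, so the cell-wise correlation
#' between NDVI and precipitation matches the coupling coefficient. Temperature and radiation follow the same
#' gradient-plus-anomaly scheme. Soil texture (sand/silt/clay summing to
#' 100%) and the DEM are fixed across years; population and GDP grow
#' geometrically.
#'
#' @param spec A [grid_spec()].
#' @param years Integer vector of calendar years (non-empty).
#' @param ppt_params,tem_params,sol_params Lists with `mean`, `sd`,
#'   `spatial_gradient`, `trend` (units: mm/yr, deg C, MJ m-2 yr-1).
#' @param ndvi_coupling Correlation between NDVI and the precipitation
#'   anomaly across cells, in `[-1, 1]`.
#' @param ndvi_params List with `base` and `sd` of NDVI.
#' @param socio_params List with `pop0`, `pop_growth`, `gdp0`, `gdp_growth`.
#' @param seed Integer seed.
#' @return List of `forcing_stack` objects (one per year), each holding
#'   `year`, `ppt` (annual, mm), `ppt_monthly` (list of 12), `tem` (deg C),
#'   `tem_monthly`, `sol` (annual MJ m-2), `sol_monthly`, `ndvi`, `dem`,
#'   `soil` (sand/silt/clay/oc percent), `pop`, `gdp`, and the `grid`.
#' @export
generate_forcing <- function(spec, years,
                             ppt_params = list(mean = 700, sd = 60,
                                               spatial_gradient = 0.3,
                                               trend = 0),
                             tem_params = list(mean = 12, sd = 0.8,
                                               spatial_gradient = 0.25,
                                               trend = 0),
                             sol_params = list(mean = 5200, sd = 150,
                                               spatial_gradient = 0.1,
                                               trend = 0),
                             ndvi_coupling = 0.6,
                             ndvi_params = list(base = 0.55, sd = 0.12),
                             socio_params = list(pop0 = 120, pop_growth = 0.01,
                                                 gdp0 = 8e5, gdp_growth = 0.11),
                             seed = 1L) {
  if (length(years) == 0) stop_invalid("years must be non-empty")
  if (ppt_params$mean <= 0) stop_invalid("ppt mean must be > 0")
  for (p in list(ppt_params, tem_params, sol_params))
    if (p$sd < 0) stop_invalid("sd parameters must be non-negative")
  if (ndvi_params$sd < 0) stop_invalid("ndvi sd must be non-negative")

  nr <- spec$n_rows; nc <- spec$n_cols
  xg <- (col(matrix(0, nr, nc)) - 0.5) / nc - 0.5   # -0.5..0.5 west-east
  yg <- (row(matrix(0, nr, nc)) - 0.5) / nr - 0.5
  rng <- max(2, round(min(nr, nc) / 12))

  with_seed(seed, {
    dem <- generate_dem(spec, seed = NULL)
    f1 <- gaussian_field(nr, nc, rng); f2 <- gaussian_field(nr, nc, rng)
    s1 <- exp(0.8 * f1); s2 <- exp(0.8 * f2)
    tot <- s1 + s2 + 1
    soil <- list(sand = 100 * s1 / tot, silt = 100 * s2 / tot,
                 clay = 100 * 1 / tot,
                 oc = clamp(1.2 + 0.5 * gaussian_field(nr, nc, rng), 0.1, 4))
    pop_field <- exp(0.6 * gaussian_field(nr, nc, rng))
    gdp_field <- exp(0.8 * gaussian_field(nr, nc, rng))

    lapply(seq_along(years), function(i) {
      yr <- years[i]; dt <- yr - years[1]
      ppt_level <- ppt_params$mean + ppt_params$trend * dt
      z_ppt <- gaussian_field(nr, nc, rng)
      ppt <- pmax(ppt_level * (1 + ppt_params$spatial_gradient * xg) +
                    ppt_params$sd * z_ppt, 0)

      rho <- ndvi_coupling
      z_ind <- gaussian_field(nr, nc, rng)
      # couple to the full precipitation field (gradient + anomaly) so the
      # cell-wise correlation equals the coupling coefficient
      z_full <- if (stats::sd(ppt) > 0) (ppt - mean(ppt)) / stats::sd(ppt)
                else matrix(0, nr, nc)
      z_mix <- rho * z_full + sqrt(max(0, 1 - rho^2)) * z_ind
      ndvi <- clamp(ndvi_params$base + ndvi_params$sd * z_mix, -1, 1)

      tem <- tem_params$mean + tem_params$trend * dt +
        tem_params$spatial_gradient * 10 * (-yg) +
        tem_params$sd * gaussian_field(nr, nc, rng)
      sol <- pmax(
        (sol_params$mean + sol_params$trend * dt) *
          (1 + sol_params$spatial_gradient * xg) +
          sol_params$sd * gaussian_field(nr, nc, rng), 0)

      noise_p <- stats::rnorm(1, 0, 0.02)
      noise_g <- stats::rnorm(1, 0, 0.04)
      structure(list(
        year = yr, grid = spec,
        ppt = ppt,
        ppt_monthly = lapply(PPT_MONTH_WEIGHTS, function(w) ppt * w),
        tem = tem,
        tem_monthly = lapply(1:12, function(m)
          tem + 12 * cos(2 * pi * (m - 7) / 12)),
        sol = sol,
        sol_monthly = lapply(SOL_MONTH_WEIGHTS, function(w) sol * w),
        ndvi = ndvi, dem = dem, soil = soil,
        pop = socio_params$pop0 * (1 + socio_params$pop_growth)^dt *
          pop_field * (1 + noise_p),
        gdp = socio_params$gdp0 * (1 + socio_params$gdp_growth)^dt *
          gdp_field * (1 + noise_g)
      ), class = "forcing_stack")
    })
  })
}

# ---- administrative zones ----------------------------------------------

#' Generate an administrative-zone map with a per-zone yield table
#'
#' Zones are the nearest-nucleus (Voronoi) regions of `n_zones` seeded
#' points. The yield table carries the total food production `gsum_t`
#' (tonnes) of each zone for each year, proportional to zone area and a
#' geometric per-hectare yield path.
#'
#' @param spec A [grid_spec()].
#' @param n_zones Number of zones (>= 1).
#' @param years Calendar years covered by the table.
#' @param yield_params List with `fp0` (t/ha in `years[1]`) and `trend`
#'   (relative annual growth).
#' @param seed Integer seed.
#' @return A `zone_map`: list with `grid`, integer matrix `zones`, and
#'   data.frame `yield_table` (zone_id, year, gsum_t).
#' @export
generate_zones <- function(spec, n_zones = 9, years = 2000L,
                           yield_params = list(fp0 = 3.5, trend = 0.025),
                           seed = 1L) {
  if (n_zones < 1) stop_invalid("n_zones must be >= 1")
  nr <- spec$n_rows; nc <- spec$n_cols
  with_seed(seed, {
    cells <- sample.int(nr * nc, n_zones)
    cr <- (cells - 1) %% nr + 1; cc <- (cells - 1) %/% nr + 1
    rr <- row(matrix(0, nr, nc)); cc2 <- col(matrix(0, nr, nc))
    d2 <- array(Inf, dim = c(nr, nc))
    zones <- matrix(1L, nr, nc)
    for (z in seq_len(n_zones)) {
      dz <- (rr - cr[z])^2 + (cc2 - cc[z])^2
      upd <- dz < d2
      zones[upd] <- z
      d2[upd] <- dz[upd]
    }
    area_ha <- cell_area_ha(spec)
    counts <- tabulate(zones, nbins = n_zones)
    yt <- do.call(rbind, lapply(seq_along(years), function(i) {
      data.frame(zone_id = seq_len(n_zones), year = years[i],
                 gsum_t = counts * area_ha * yield_params$fp0 *
                   (1 + yield_params$trend)^(i - 1))
    }))
    structure(list(grid = spec, zones = zones, yield_table = yt),
              class = "zone_map")
  })
}

# ---- scatter clouds with a known upper boundary ------------------------

#' Generate a scatter cloud bounded above by a known curve
#'
#' Draws `x ~ Uniform(x_range)` and sets `y = f(x) * U^gamma` with
#' `U ~ Uniform(0, 1)`, so `f` is the exact upper boundary of the cloud and
#' `gamma` (`noise_exponent`) controls how densely points crowd the
#' boundary (small gamma = dense).
#'
#' Forms: `hump` with `params = list(x_star, y_star, width)` giving
#' `f(x) = y_star - ((x - x_star)/width)^2`, and `exponential` with
#' `params = list(k, b)` giving `f(x) = b * k^x`.
#'
#' @param n Number of points (>= 100).
#' @param form `"hump"` or `"exponential"`.
#' @param params Boundary parameters (see Details).
#' @param noise_exponent Positive real gamma.
#' @param x_range Length-2 numeric range of x.
#' @param seed Integer seed.
#' @param pair_label Label `"A_B"` attached to the cloud.
#' @param year Calendar year attached to the cloud.
#' @return A `scatter_cloud`: list with `pair_label`, `x`, `y`, `year`, and
#'   `truth` (the boundary used).
#' @export
generate_constrained_cloud <- function(n, form = c("hump", "exponential"),
                                       params, noise_exponent = 1,
                                       x_range = c(0, 10), seed = 1L,
                                       pair_label = "A_B", year = NA_integer_) {
  form <- match.arg(form)
  if (n < 100) stop_invalid("n must be >= 100")
  if (noise_exponent <= 0) stop_invalid("noise_exponent must be > 0")
  f <- boundary_fun(form, params)
  if (min(f(seq(x_range[1], x_range[2], length.out = 512))) <= 0)
    stop_invalid("boundary must be strictly positive over x_range")
  with_seed(seed, {
    x <- stats::runif(n, x_range[1], x_range[2])
    u <- stats::runif(n)
    y <- f(x) * u^noise_exponent
    structure(list(pair_label = pair_label, x = x, y = y, year = year,
                   truth = list(form = form, params = params,
                                x_range = x_range, f = f)),
              class = "scatter_cloud")
  })
}

boundary_fun <- function(form, params) {
  if (form == "hump") {
    for (k in c("x_star", "y_star", "width"))
      if (is.null(params[[k]])) stop_invalid(paste("hump params need", k))
    if (params$width <= 0) stop_invalid("hump width must be > 0")
    function(x) params$y_star - ((x - params$x_star) / params$width)^2
  } else {
    for (k in c("k", "b"))
      if (is.null(params[[k]])) stop_invalid(paste("exponential params need", k))
    if (params$k <= 0) stop_invalid("exponential k must be > 0")
    if (params$b <= 0) stop_invalid("exponential b must be > 0")
    function(x) params$b * params$k^x
  }
}
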