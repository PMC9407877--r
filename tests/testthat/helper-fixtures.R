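# Shared builders for hand-constructed inputs. Everything is created in
# code; no binary fixtures.

# A forcing_stack with spatially constant layers, for exact ES-model
# arithmetic. Monthly solar defaults to the annual value split evenly.
make_forcing <- function(spec, ppt = 700, tem = 15, sol = 4800, ndvi = 0.6,
                         year = 2000L,
                         sol_monthly = NULL, ppt_monthly = NULL,
                         soil = NULL, dem = NULL) {
  m <- function(v) matrix(v, spec$n_rows, spec$n_cols)
  if (is.null(sol_monthly)) sol_monthly <- lapply(rep(sol / 12, 12), m)
  if (is.null(ppt_monthly)) ppt_monthly <- lapply(rep(ppt / 12, 12), m)
  if (is.null(soil)) soil <- list(sand = m(40), silt = m(40), clay = m(20),
                                  oc = m(1.5))
  if (is.null(dem)) dem <- m(100)
  structure(list(
    year = year, grid = spec, ppt = m(ppt), ppt_monthly = ppt_monthly,
    tem = m(tem), tem_monthly = lapply(rep(tem, 12), m),
    sol = m(sol), sol_monthly = sol_monthly,
    ndvi = m(ndvi), dem = dem, soil = soil,
    pop = m(100), gdp = m(1e5)
  ), class = "forcing_stack")
}

# A landuse_map with every cell the same class (default cropland).
make_landuse <- function(spec, class = "cropland") {
  structure(list(grid = spec,
                 classes = matrix(eslines:::landuse_code(class),
                                  spec$n_rows, spec$n_cols)),
            class = "landuse_map")
}

# A landuse_map from an explicit code matrix.
landuse_from <- function(classes, cell_size = 250) {
  spec <- grid_spec(nrow(classes), ncol(classes), cell_size)
  structure(list(grid = spec, classes = classes), class = "landuse_map")
}

# A zone_map with a single zone covering the grid.
make_zones <- function(spec, gsum, zones = NULL) {
  if (is.null(zones)) zones <- matrix(1L, spec$n_rows, spec$n_cols)
  structure(list(grid = spec, zones = zones,
                 yield_table = data.frame(zone_id = sort(unique(as.vector(zones))),
                                          gsum_t = gsum)),
            class = "zone_map")
}

# Boundary points placed exactly on a curve (for exact-fit tests).
exact_boundary <- function(x, y, label = "test") {
  structure(list(pair_label = label,
                 points = data.frame(x_mid = x, y_q = y),
                 bins_dropped = 0L, edges = NULL, quantile = 1,
                 min_points = 1L),
            class = "boundary_points")
}

# Independent type-7 quantile oracle: sort and linearly interpolate.
quantile7_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
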