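test_that("NPP follows the light-use-efficiency product and its limits", {
  spec <- grid_spec(4, 4)
  lu <- make_landuse(spec, "cropland")
  p <- casa_params(eps_max = c(cropland = 0.5, forest = 0.5, grassland = 0.5,
                               water = 0, urban = 0, unused = 0.5),
                   fpar_max = 1, ndvi_min = 0.05, ndvi_max = 0.95,
                   use_stress = FALSE, phenology = rep(1, 12))

  # one productive month, APAR = 200 * 1 * 0.5 = 100 MJ m-2, eps = 0.5
  sol_m <- c(list(matrix(200, 4, 4)), lapply(1:11, function(i) matrix(0, 4, 4)))
  f <- make_forcing(spec, ndvi = 0.95, sol_monthly = sol_m)
  npp <- compute_npp(f, lu, p)
  expect_equal(npp$values, matrix(0.5, 4, 4), tolerance = 1e-12)
  expect_equal(npp$units, "t ha-1")

  # NDVI at the configured floor: FPAR = 0 everywhere
  f0 <- make_forcing(spec, ndvi = 0.05)
  expect_true(all(compute_npp(f0, lu, p)$values == 0))

  # doubling solar radiation doubles NPP even with stress terms active
  ps <- casa_params()
  f1 <- make_forcing(spec, sol = 4000, ndvi = 0.6, tem = 18, ppt = 800)
  f2 <- make_forcing(spec, sol = 8000, ndvi = 0.6, tem = 18, ppt = 800)
  n1 <- compute_npp(f1, lu, ps)$values
  n2 <- compute_npp(f2, lu, ps)$values
  expect_equal(n2 / n1, matrix(2, 4, 4), tolerance = 1e-9)

  # water and urban cells produce nothing
  lw <- make_landuse(spec, "water")
  expect_true(all(compute_npp(f1, lw, ps)$values == 0))

  # missing month
  fbad <- f1
  fbad$sol_monthly <- fbad$sol_monthly[1:11]
  expect_error(compute_npp(fbad, lu, ps),
               class = "eslines_incomplete_forcing")
})

test_that("FP allocation is NDVI-proportional and conserves zone totals", {
  spec <- grid_spec(1, 2)
  lu <- make_landuse(spec, "cropland")
  z <- make_zones(spec, gsum = 8)
  ndvi <- matrix(c(0.2, 0.6), 1, 2)
  fp <- compute_fp(ndvi, lu, z)
  expect_equal(as.vector(fp$values), c(2, 6), tolerance = 1e-12)

  # symmetry: equal NDVI shares the total evenly
  spec4 <- grid_spec(2, 2)
  fp4 <- compute_fp(matrix(0.4, 2, 2), make_landuse(spec4, "cropland"),
                    make_zones(spec4, gsum = 10))
  expect_true(all(abs(fp4$values - 2.5) < 1e-12))

  # conservation on a random multi-zone landscape
  set.seed(31)
  specr <- grid_spec(30, 30)
  lur <- generate_landscape(specr, c(cropland = 0.6, forest = 0.2,
                                     urban = 0.2), seed = 3)
  zones <- matrix(rep(1:3, each = 300), 30, 30)
  zr <- make_zones(specr, gsum = c(50, 70, 90), zones = zones)
  fpr <- compute_fp(matrix(runif(900, 0.2, 0.9), 30, 30), lur, zr)
  for (z_id in 1:3) {
    got <- sum(fpr$values[zones == z_id])
    expect_equal(got, c(50, 70, 90)[z_id], tolerance = 1e-6)
  }
  # non-cropland cells stay at zero
  expect_true(all(fpr$values[lur$classes != 1] == 0))

  # a zone without cropland is skipped with a warning, FP = 0 there
  lu_half <- landuse_from(matrix(c(1L, 1L, 5L, 5L), 2, 2))
  zhw <- make_zones(lu_half$grid, gsum = c(4, 4),
                    zones = matrix(c(1L, 1L, 2L, 2L), 2, 2))
  expect_warning(fph <- compute_fp(matrix(0.5, 2, 2), lu_half, zhw),
                 "skipped")
  expect_equal(sum(fph$values[, 2]), 0)
  expect_equal(sum(fph$values[, 1]), 4, tolerance = 1e-12)
})

test_that("RUSLE factors behave at their analytic endpoints", {
  spec <- grid_spec(5, 5)
  lu <- make_landuse(spec, "cropland")

  # no rain, no erosivity
  fdry <- make_forcing(spec, ppt = 0,
                       ppt_monthly = lapply(1:12, function(i) matrix(0, 5, 5)))
  expect_true(all(compute_rusle_factors(fdry, lu)$R == 0))

  # flat terrain keeps LS at its minimum; a slope raises it
  f <- make_forcing(spec)
  flat <- compute_rusle_factors(f, lu)$LS
  fslope <- make_forcing(spec, dem = matrix(seq(0, 400, length.out = 5),
                                            5, 5, byrow = TRUE))
  sloped <- compute_rusle_factors(fslope, lu)$LS
  expect_true(all(sloped >= flat - 1e-12))
  expect_gt(max(sloped), max(flat))

  # C endpoints: bare soil 1, full canopy at the floor
  p <- rusle_params(c_floor = 0.01, ndvi_soil = 0.05, ndvi_veg = 0.9)
  fbare <- make_forcing(spec, ndvi = 0.05)
  ffull <- make_forcing(spec, ndvi = 0.9)
  expect_true(all(compute_rusle_factors(fbare, lu, params = p)$C == 1))
  expect_equal(compute_rusle_factors(ffull, lu, params = p)$C,
               matrix(0.01, 5, 5), tolerance = 1e-12)

  # P lookup: water and urban fully non-erodible
  lw <- make_landuse(spec, "water")
  expect_true(all(compute_rusle_factors(f, lw)$P == 0))
})

test_that("soil conservation follows SC = R K LS (1 - C P)", {
  mk <- function(R, K, LS, C, P)
    structure(list(R = matrix(R, 2, 2), K = matrix(K, 2, 2),
                   LS = matrix(LS, 2, 2), C = matrix(C, 2, 2),
                   P = matrix(P, 2, 2), grid = grid_spec(2, 2), year = 2000L),
              class = "rusle_factors")
  sc <- compute_sc(mk(100, 0.3, 2, 0.2, 1))
  expect_equal(sc$values, matrix(48, 2, 2))        # Ap = 60, Ar = 12
  expect_true(all(compute_sc(mk(100, 0.3, 2, 1, 1))$values == 0))
  expect_equal(compute_sc(mk(100, 0.3, 2, 0, 1))$values, matrix(60, 2, 2))
  expect_error(compute_sc(mk(-1, 0.3, 2, 0.2, 1)),
               class = "eslines_invalid_input")
  # monotone decrease in C and in P
  expect_true(all(compute_sc(mk(100, 0.3, 2, 0.5, 0.8))$values <=
                    compute_sc(mk(100, 0.3, 2, 0.4, 0.8))$values))
  expect_true(all(compute_sc(mk(100, 0.3, 2, 0.5, 0.9))$values <=
                    compute_sc(mk(100, 0.3, 2, 0.5, 0.8))$values))
})

test_that("water yield matches the Budyko-curve analytic cases", {
  spec <- grid_spec(3, 3)
  lu <- make_landuse(spec, "forest")   # Kc = 1
  f <- make_forcing(spec, ppt = 1000)
  m <- function(v) matrix(v, 3, 3)

  # zero demand: WY = PPT
  wy0 <- compute_wy(f, lu, wy_params(et0 = m(0), awc = m(100)))
  expect_equal(wy0$values, m(1000), tolerance = 1e-6)

  # PPT = 1000, PET = 500, w = 2  (AWC Z / PPT = 0.75 with AWC = 100, Z = 7.5)
  wy <- compute_wy(f, lu, wy_params(z = 7.5, awc = m(100), et0 = m(500)))
  expected <- (1 - (1.5 - sqrt(1.25))) * 1000
  expect_equal(wy$values, m(expected), tolerance = 1e-6)

  # large w, energy-limited: WY -> PPT - PET
  wyl <- compute_wy(f, lu, wy_params(z = 7.5, awc = m(1e6), et0 = m(500)))
  expect_equal(wyl$values, m(500), tolerance = 1e-6)

  # zero precipitation returns 0 by convention
  fz <- make_forcing(spec, ppt = 0,
                     ppt_monthly = lapply(1:12, function(i) m(0)))
  expect_message(wyz <- compute_wy(fz, lu, wy_params(et0 = m(500),
                                                     awc = m(100))),
                 "PPT = 0")
  expect_true(all(wyz$values == 0))
})

test_that("water yield is bounded by PPT and non-increasing in PET", {
  spec <- grid_spec(20, 20)
  lu <- generate_landscape(spec, c(cropland = 0.5, forest = 0.3,
                                   grassland = 0.2), seed = 8)
  f <- generate_forcing(spec, 2000, seed = 8)[[1]]
  base <- compute_wy(f, lu)
  expect_true(all(base$values >= 0))
  expect_true(all(base$values <= f$ppt + 1e-9))
  hot <- compute_wy(f, lu, wy_params(et0 = et0_from_temperature(f$tem) * 1.5))
  expect_true(all(hot$values <= base$values + 1e-9))
})
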