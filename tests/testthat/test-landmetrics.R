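test_that("patch labelling respects class and connectivity", {
  # uniform raster: one patch covering everything
  lu1 <- make_landuse(grid_spec(6, 6, 100))
  ps1 <- label_patches(lu1)
  expect_equal(nrow(ps1$patches), 1)
  expect_equal(ps1$patches$area_m2, 36 * 100^2)

  # 2x2 checkerboard: 4 patches under rook, 2 under queen adjacency
  chk <- landuse_from(matrix(c(1L, 2L, 2L, 1L), 2, 2), cell_size = 100)
  expect_equal(nrow(label_patches(chk, connectivity = 4)$patches), 4)
  expect_equal(nrow(label_patches(chk, connectivity = 8)$patches), 2)

  # partition property on a random map
  lur <- generate_landscape(grid_spec(40, 40, 250),
                            c(cropland = 0.5, forest = 0.3, water = 0.2),
                            clumping = 0.4, seed = 5)
  psr <- label_patches(lur)
  expect_equal(sum(psr$patches$area_m2), 40 * 40 * 250^2)
  expect_gte(nrow(psr$patches), 3)
})

test_that("composition percentages match brute-force cell counts", {
  lu <- generate_landscape(grid_spec(50, 50),
                           c(cropland = 0.4, forest = 0.3, urban = 0.3),
                           seed = 11)
  comp <- compute_composition(lu)
  expect_equal(sum(comp), 100)
  brute <- 100 * vapply(1:6, function(cd) mean(lu$classes == cd), numeric(1))
  expect_equal(unname(comp), brute)

  lu1 <- make_landuse(grid_spec(10, 10))
  c1 <- compute_composition(lu1)
  expect_equal(unname(c1["cropland"]), 100)
})

test_that("configuration metrics reproduce their closed-form cases", {
  # single-class square: SHDI 0, LSI 1, CONTAG undefined
  lu1 <- make_landuse(grid_spec(8, 8, 100))
  m1 <- compute_configuration(label_patches(lu1), lu1)
  expect_equal(m1$shdi, 0)
  expect_equal(m1$lsi, 1)
  expect_true(is.na(m1$contag))

  # two classes at 50/50: SHDI = ln 2
  halves <- landuse_from(cbind(matrix(1L, 10, 5), matrix(2L, 10, 5)))
  mh <- compute_configuration(label_patches(halves), halves)
  expect_equal(mh$shdi, log(2), tolerance = 1e-12)

  # PD unit arithmetic: 4 patches on 100 ha -> 4 per 100 ha
  quad <- landuse_from(rbind(cbind(matrix(1L, 10, 10), matrix(2L, 10, 10)),
                             cbind(matrix(2L, 10, 10), matrix(1L, 10, 10))),
                       cell_size = 50)   # 20x20 cells of 50 m = 100 ha
  mq <- compute_configuration(label_patches(quad, connectivity = 4), quad)
  expect_equal(mq$n_patches, 4)
  expect_equal(mq$pd, 4)

  # aggregation monotonicity: clumped beats randomly interspersed at the
  # same composition. (A pure 2-class checkerboard is NOT a low-CONTAG
  # reference: its adjacencies are perfectly predictable, so the FRAGSTATS
  # formula scores it 50, above solid halves on a finite grid.)
  props <- c(cropland = 0.5, forest = 0.5)
  clumped <- generate_landscape(grid_spec(60, 60), props, clumping = 0.9,
                                seed = 21)
  random <- generate_landscape(grid_spec(60, 60), props, clumping = 0,
                               seed = 21)
  c_cl <- compute_configuration(label_patches(clumped), clumped)$contag
  c_rn <- compute_configuration(label_patches(random), random)$contag
  expect_gt(c_cl, c_rn)
  expect_true(c_rn >= 0 && c_cl <= 100)

  # checkerboard reference value: entropy ln 2 of the adjacency
  # distribution gives exactly 50%
  n <- 12
  board <- landuse_from(matrix(ifelse((row(diag(n)) + col(diag(n))) %% 2 == 0,
                                      1L, 2L), n, n))
  cb <- compute_configuration(label_patches(board), board)$contag
  expect_equal(cb, 50, tolerance = 1e-9)
})

test_that("PAFRAC is 1 for square patches and NA when undersampled", {
  # synthetic patch set: 12 solid squares, sides 2..16 cells of 250 m
  sides <- rep(c(2, 4, 8, 16), 3)
  ps <- structure(list(
    labels = NULL,
    patches = data.frame(id = seq_along(sides), class = 1L,
                         area_m2 = (sides * 250)^2,
                         perim_m = 4 * sides * 250),
    grid = grid_spec(100, 100), connectivity = 8), class = "patch_set")
  lu <- make_landuse(grid_spec(100, 100))
  m <- compute_configuration(ps, lu)
  expect_equal(m$pafrac, 1, tolerance = 1e-9)

  # below the patch-count floor the metric is explicit missing, never 0
  ps$patches <- ps$patches[1:5, ]
  expect_true(is.na(compute_configuration(ps, lu)$pafrac))
})

test_that("SHDI is relabel-invariant and maximal at equal shares", {
  lu <- generate_landscape(grid_spec(40, 40),
                           c(cropland = 0.5, forest = 0.3, water = 0.2),
                           seed = 2)
  relab <- lu
  relab$classes <- matrix(c(3L, 1L, 2L, 4L, 5L, 6L)[lu$classes], 40, 40)
  s1 <- compute_configuration(label_patches(lu), lu)$shdi
  s2 <- compute_configuration(label_patches(relab), relab)$shdi
  expect_equal(s1, s2, tolerance = 1e-12)

  eq3 <- generate_landscape(grid_spec(60, 60),
                            c(cropland = 1/3, forest = 1/3, water = 1/3),
                            seed = 3)
  s_eq <- compute_configuration(label_patches(eq3), eq3)$shdi
  expect_lt(abs(s_eq - log(3)), 1e-3)   # shares exact up to one cell
  expect_lte(s_eq, log(3) + 1e-12)
})

test_that("PD falls as the landscape aggregates at fixed composition", {
  props <- c(cropland = 0.5, forest = 0.5)
  fine <- generate_landscape(grid_spec(60, 60), props, clumping = 0,
                             seed = 4)
  coarse <- generate_landscape(grid_spec(60, 60), props, clumping = 0.9,
                               seed = 4)
  pd_f <- compute_configuration(label_patches(fine), fine)$pd
  pd_c <- compute_configuration(label_patches(coarse), coarse)$pd
  expect_gt(pd_f, pd_c)
})
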