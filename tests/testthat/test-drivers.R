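# Shared small driver matrix built once: 21 years of forcing + landscape
# metrics on a 30 x 30 grid.
make_dm <- function(seed = 42) {
  spec <- grid_spec(30, 30)
  years <- 2000:2020
  forcings <- generate_forcing(spec, years,
                               ppt_params = list(mean = 700, sd = 60,
                                                 spatial_gradient = 0.3,
                                                 trend = 2),
                               seed = seed)
  set.seed(seed)
  jit <- matrix(runif(21 * 6, -0.01, 0.01), 21, 6)  # yearly composition noise
  metrics <- do.call(rbind, lapply(seq_along(years), function(i) {
    p <- c(cropland = 0.6 - 0.002 * (i - 1), forest = 0.1, grassland = 0.1,
           water = 0.05, urban = 0.1 + 0.002 * (i - 1), unused = 0.05)
    p <- pmax(p + jit[i, ], 0.01)
    lu <- generate_landscape(spec, p / sum(p), clumping = 0.5,
                             seed = seed + i)
    landscape_metrics(lu, year = years[i])
  }))
  build_driver_matrix(forcings, metrics)
}

dm <- make_dm()

test_that("driver matrix has one standardized row per year", {
  expect_equal(length(dm$year), 21)
  expect_equal(ncol(dm$std), 16)   # 15 drivers from the design + pop/gdp split
  expect_true(all(abs(colMeans(dm$std)) < 1e-9))
  expect_true(all(abs(apply(dm$std, 2, sd) - 1) < 1e-9))
  expect_setequal(colnames(dm$std),
                  c("ppt", "tem", "ndvi", "cropland", "forest", "grassland",
                    "water", "urban", "unused", "pafrac", "lsi", "contag",
                    "shdi", "pd", "gdp", "pop"))
})

test_that("near-constant columns are dropped with a message and year
           mismatches are typed errors", {
  spec <- grid_spec(10, 10)
  years <- 2000:2009
  f <- generate_forcing(spec, years,
                        ppt_params = list(mean = 600, sd = 0,
                                          spatial_gradient = 0, trend = 0),
                        seed = 1)
  met <- do.call(rbind, lapply(seq_along(years), function(i)
    landscape_metrics(generate_landscape(
      spec, c(cropland = 0.6, forest = 0.4), seed = i), year = years[i])))
  expect_message(d0 <- build_driver_matrix(f, met), "near-constant")
  expect_false("ppt" %in% colnames(d0$std))

  expect_error(build_driver_matrix(f, met[met$year != 2005, ]),
               class = "eslines_alignment_error")
})

test_that("a single exact predictor earns importance 1 and accuracy 100", {
  y <- 2 + 3 * dm$std$ppt
  X1 <- dm
  X1$std <- dm$std[, "ppt", drop = FALSE]
  res <- fit_model0(y, X1)
  expect_equal(res$terms$term, "ppt")
  expect_equal(res$terms$importance, 1)
  expect_equal(res$accuracy, 100, tolerance = 1e-6)
  expect_equal(res$terms$star, "**")
})

test_that("the VIF guard keeps one of a duplicated predictor pair", {
  set.seed(3)
  y <- dm$std$ppt + rnorm(21, 0, 0.1)
  X2 <- dm
  X2$std$ppt_copy <- dm$std$ppt
  res <- fit_model0(y, X2)
  got <- res$terms$term
  expect_equal(sum(got %in% c("ppt", "ppt_copy")), 1)
})

test_that("main-effect recovery: the true driver dominates importance", {
  set.seed(11)
  y <- dm$std$ppt + rnorm(21, 0, 0.1)
  res <- fit_model0(y, dm)
  expect_true("ppt" %in% res$terms$term)
  expect_gt(res$terms$importance[res$terms$term == "ppt"], 0.8)
  expect_gt(res$accuracy, 80)
  expect_true(all(abs(sum(res$terms$importance) - 1) < 1e-9))
})

test_that("interaction recovery and the no-residual guard", {
  set.seed(19)
  y <- dm$std$gdp * dm$std$pafrac + rnorm(21, 0, 0.1)
  res <- fit_model1(y, dm)
  expect_true("gdp:pafrac" %in% res$terms$term)
  co <- res$terms$coefficient[res$terms$term == "gdp:pafrac"]
  expect_gt(co, 0)

  # a perfectly explained main-effect response admits no interaction
  y2 <- dm$std$ppt
  res2 <- fit_model1(y2, dm)
  expect_false(any(res2$terms$interaction))
})

test_that("results are invariant to affine rescaling of raw drivers", {
  set.seed(23)
  yv <- dm$std$ndvi + rnorm(21, 0, 0.2)
  res_a <- fit_model0(yv, dm)

  dm_b <- dm
  dm_b$raw$ndvi <- 1000 * dm$raw$ndvi + 5
  ctr <- vapply(dm_b$raw, mean, numeric(1))
  scl <- vapply(dm_b$raw, sd, numeric(1))
  dm_b$std <- as.data.frame(scale(dm_b$raw, ctr, scl))
  res_b <- fit_model0(yv, dm_b)
  expect_equal(res_a$terms$term, res_b$terms$term)
  expect_equal(res_a$terms$importance, res_b$terms$importance,
               tolerance = 1e-9)
  expect_equal(res_a$accuracy, res_b$accuracy, tolerance = 1e-9)
})

test_that("attribution needs enough usable years", {
  short <- feature_series("p", "f", 2000:2004, rnorm(5))
  expect_error(fit_model0(short, dm), class = "eslines_alignment_error")
  partial <- feature_series("p", "f", 2000:2020,
                            c(rnorm(6), rep(NA, 15)))
  expect_error(fit_model0(partial, dm), class = "eslines_insufficient_data")
})

test_that("attribute_all stacks both models per response", {
  set.seed(29)
  sl <- list(
    a = feature_series("NPP_FP", "fp_threshold", 2000:2020,
                       dm$std$ppt + rnorm(21, 0, 0.3)),
    b = feature_series("SC_FP", "b", 2000:2020, rnorm(21))
  )
  tab <- attribute_all(sl, dm)
  expect_true(all(c(0, 1) %in% tab$model))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 100))
  sums <- tapply(tab$importance[!is.na(tab$importance)],
                 paste(tab$response, tab$model)[!is.na(tab$importance)], sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
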