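# Constraint-line extraction by quantile segmentation: bin the constraining
# service on the x-axis, take a high empirical quantile of the response per
# bin, and fit a parametric curve (quadratic hump or exponential decay) to
# the boundary points. The hump threshold is the vertex of the fitted
# quadratic; the exponential is characterised by the decay base k and the
# intercept b of y = b * k^x (b is the bound as x approaches zero).

#' Extract boundary points from a scatter cloud
#'
#' Splits the x-range into `n_bins` equal-width bins and takes the
#' `quantile` empirical quantile (linear-interpolation, type 7) of y in
#' each bin holding at least `min_points` observations; sparser bins are
#' dropped and counted.
#'
#' @param cloud A `scatter_cloud` (or any list with numeric `x`, `y`).
#' @param n_bins Number of equal-width bins (default 50).
#' @param quantile Upper quantile level per bin (default 0.99).
#' @param min_points Minimum observations a bin needs to emit a point.
#' @return A `boundary_points` object: data.frame `points` with `x_mid`
#'   (bin centre) and `y_q`, plus `bins_dropped`, the bin `edges`, and the
#'   settings used.
#' @export
extract_boundary <- function(cloud, n_bins = 50, quantile = 0.99,
                             min_points = 10) {
  x <- cloud$x; y <- cloud$y
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (n_bins < 1) stop_invalid("n_bins must be >= 1")
  if (quantile <= 0 || quantile > 1) stop_invalid("quantile must be in (0, 1]")
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  counts <- tabulate(bin, nbins = n_bins)
  kept <- which(counts >= min_points)
  if (length(kept) < 5)
    stop_with(sprintf("only %d bin(s) with >= %d points; need at least 5",
                      length(kept), min_points), "eslines_insufficient_data")
  yq <- vapply(kept, function(b)
    stats::quantile(y[bin == b], quantile, names = FALSE, type = 7),
    numeric(1))
  structure(list(
    pair_label = cloud$pair_label %||% NA_character_,
    points = data.frame(x_mid = mids[kept], y_q = yq),
    bins_dropped = n_bins - length(kept),
    edges = edges, quantile = quantile, min_points = min_points
  ), class = "boundary_points")
}

#' Fit a constraint curve to boundary points
#'
#' Hump form: least-squares quadratic `y = a2 x^2 + a1 x + a0` requiring a
#' concave fit (`a2 < 0`); the characteristic threshold is the vertex
#' `threshold_x = -a1 / (2 a2)` with height `threshold_y`. Exponential
#' form: `y = b * k^x` fitted by regressing `ln y` on `x` (`k` = exp of
#' the slope, `b` = exp of the intercept); `b` is the bound at `x = 0` and
#' `k` the per-unit decay base. `"auto"` fits both and keeps the higher
#' R-squared. R-squared is always computed on the boundary points, on the
#' original y scale.
#'
#' @param points A `boundary_points` object.
#' @param form `"hump"`, `"exponential"`, or `"auto"`.
#' @return A `constraint_curve`: list with `form`, `params`, `r2`,
#'   `threshold_x`/`threshold_y` (hump only, `NA` otherwise), `k`/`b`
#'   (exponential only), `n_points`, `pair_label`.
#' @export
fit_constraint <- function(points, form = c("hump", "exponential", "auto")) {
  form <- match.arg(form)
  df <- points$points
  if (nrow(df) < 5)
    stop_with("need at least 5 boundary points", "eslines_insufficient_data")
  if (form == "auto") {
    hump <- tryCatch(fit_constraint(points, "hump"), error = function(e) NULL)
    expo <- tryCatch(fit_constraint(points, "exponential"),
                     error = function(e) NULL)
    if (is.null(hump) && is.null(expo))
      stop_with("neither form could be fitted", "eslines_form_mismatch")
    if (is.null(expo) || (!is.null(hump) && hump$r2 >= expo$r2)) return(hump)
    return(expo)
  }
  x <- df$x_mid; y <- df$y_q
  if (form == "hump") {
    fit <- stats::lm(y ~ x + I(x^2))
    a <- stats::coef(fit)                  # a0, a1, a2
    if (!is.finite(a[3]) || a[3] >= -1e-12)
      stop_with("hump form rejected: quadratic coefficient not negative",
                "eslines_form_mismatch")
    tx <- -a[2] / (2 * a[3])
    ty <- a[1] + a[2] * tx + a[3] * tx^2
    yhat <- stats::fitted(fit)
    curve <- new_curve(points, "hump",
                       params = c(a2 = unname(a[3]), a1 = unname(a[2]),
                                  a0 = unname(a[1])),
                       r2 = r_squared(y, yhat),
                       threshold_x = unname(tx), threshold_y = unname(ty))
  } else {
    if (any(y <= 0))
      stop_with("exponential form needs positive boundary y",
                "eslines_invalid_input")
    fit <- stats::lm(log(y) ~ x)
    co <- stats::coef(fit)
    k <- exp(unname(co[2])); b <- exp(unname(co[1]))
    yhat <- b * k^x
    curve <- new_curve(points, "exponential",
                       params = c(k = k, b = b),
                       r2 = r_squared(y, yhat), k = k, b = b)
  }
  curve
}

new_curve <- function(points, form, params, r2, threshold_x = NA_real_,
                      threshold_y = NA_real_, k = NA_real_, b = NA_real_) {
  structure(list(pair_label = points$pair_label, form = form, params = params,
                 r2 = r2, threshold_x = threshold_x, threshold_y = threshold_y,
                 k = k, b = b, n_points = nrow(points$points),
                 x_range = range(points$points$x_mid)),
            class = "constraint_curve")
}

r_squared <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  max(0, min(1, 1 - sum((y - yhat)^2) / ss_tot))
}

#' @export
print.constraint_curve <- function(x, ...) {
  if (x$form == "hump")
    cat(sprintf("<constraint_curve> %s hump: threshold (%.3f, %.3f), R2 %.3f\n",
                x$pair_label, x$threshold_x, x$threshold_y, x$r2))
  else
    cat(sprintf("<constraint_curve> %s exponential: k %.5f, b %.3f, R2 %.3f\n",
                x$pair_label, x$k, x$b, x$r2))
  invisible(x)
}

#' Evaluate a fitted constraint curve
#' @param curve A `constraint_curve`.
#' @param x Numeric vector.
#' @return Fitted boundary values at `x`.
#' @export
predict_constraint <- function(curve, x) {
  p <- curve$params
  if (curve$form == "hump") p[["a0"]] + p[["a1"]] * x + p[["a2"]] * x^2
  else p[["b"]] * p[["k"]]^x
}

#' Plot a cloud, its boundary points and the fitted curve
#' @param cloud A `scatter_cloud`. @param boundary A `boundary_points`.
#' @param curve A `constraint_curve`.
#' @param ... Passed to `plot()`.
#' @export
plot_constraint <- function(cloud, boundary, curve, ...) {
  graphics::plot(cloud$x, cloud$y, pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("steelblue", 0.35),
                 xlab = "constraining ES", ylab = "response ES", ...)
  graphics::points(boundary$points$x_mid, boundary$points$y_q, pch = 19)
  xs <- seq(min(cloud$x), max(cloud$x), length.out = 200)
  graphics::lines(xs, predict_constraint(curve, xs), col = "red", lwd = 2)
  if (curve$form == "hump" && is.finite(curve$threshold_x))
    graphics::points(curve$threshold_x, curve$threshold_y, pch = 17, cex = 1.4)
  invisible(NULL)
}

# default functional form per ES pair: SC_FP decays exponentially, the
# other five pairs are hump-shaped
DEFAULT_PAIR_FORMS <- c(NPP_SC = "hump", NPP_WY = "hump", NPP_FP = "hump",
                        WY_FP = "hump", WY_SC = "hump", SC_FP = "exponential")

#' Fit constraint curves for all ES pairs and years
#'
#' For every year and pair label `"A_B"` (A the constraining service on
#' the x-axis, B the response): co-locate the two layers, drop cells with
#' missing values, restrict FP-involving pairs to cropland cells (FP is
#' defined only there), draw a seeded sample of up to `sample_n` cells,
#' extract boundary points and fit the pair's configured form. Pairs that
#' fail (insufficient cells or a form mismatch) are recorded as missing
#' and the run continues.
#'
#' @param es_layers List (one element per year) of named lists of
#'   `es_layer` objects (`NPP`, `FP`, `SC`, `WY`).
#' @param pairs Character vector of pair labels; defaults to the six
#'   standard pairs.
#' @param sample_n Cells sampled per pair and year (default 10000).
#' @param landuse_by_year List of `landuse_map` per year (needed for the
#'   cropland mask of FP pairs).
#' @param n_bins,quantile,min_points Passed to [extract_boundary()].
#' @param forms Named character vector pair -> form, defaulting to
#'   `DEFAULT_PAIR_FORMS`.
#' @param seed Integer seed for cell sampling.
#' @return data.frame with one row per year x pair: form, fitted
#'   parameters, `r2`, `threshold_x`, `threshold_y`, `k`, `b`,
#'   `n_points`, `status`.
#' @export
run_pairs <- function(es_layers, pairs = names(DEFAULT_PAIR_FORMS),
                      sample_n = 10000, landuse_by_year = NULL,
                      n_bins = 50, quantile = 0.99, min_points = 10,
                      forms = DEFAULT_PAIR_FORMS, seed = 1L) {
  rows <- list()
  for (iy in seq_along(es_layers)) {
    layers <- es_layers[[iy]]
    yr <- layers[[1]]$year
    for (pair in pairs) {
      ab <- strsplit(pair, "_", fixed = TRUE)[[1]]
      form <- forms[[pair]] %||% "auto"
      res <- tryCatch({
        la <- layers[[ab[1]]]; lb <- layers[[ab[2]]]
        if (is.null(la) || is.null(lb))
          stop_with(paste("missing layer for", pair), "eslines_insufficient_data")
        xv <- as.vector(la$values); yv <- as.vector(lb$values)
        ok <- is.finite(xv) & is.finite(yv)
        if (any(ab %in% "FP") && !is.null(landuse_by_year)) {
          crop <- as.vector(landuse_by_year[[iy]]$classes ==
                              LANDUSE_CODES[["cropland"]])
          ok <- ok & crop
        }
        idx <- which(ok)
        if (length(idx) < 5 * min_points)
          stop_with("insufficient valid cells", "eslines_insufficient_data")
        if (length(idx) > sample_n)
          idx <- with_seed(seed + iy, sample(idx, sample_n))
        cloud <- list(pair_label = pair, x = xv[idx], y = yv[idx], year = yr)
        bp <- extract_boundary(cloud, n_bins = n_bins, quantile = quantile,
                               min_points = min_points)
        fit_constraint(bp, form)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          year = yr, pair = pair, form = form, r2 = NA_real_,
          threshold_x = NA_real_, threshold_y = NA_real_,
          k = NA_real_, b = NA_real_, n_points = NA_integer_,
          status = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          year = yr, pair = pair, form = res$form, r2 = res$r2,
          threshold_x = res$threshold_x, threshold_y = res$threshold_y,
          k = res$k, b = res$b, n_points = res$n_points, status = "ok")
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(n_bins = n_bins, quantile = quantile,
                              min_points = min_points, sample_n = sample_n,
                              forms = forms, seed = seed)
  out
}
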