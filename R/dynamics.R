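# Interannual dynamics of constraint-line characteristic values: OLS trend
# tests with the two-star significance convention, type-7 box statistics
# with 1.5 IQR fences, series extrema, and the per-service annual summary.

#' Construct a characteristic-value series
#' @param pair_label Pair the feature belongs to (e.g. `"NPP_FP"`).
#' @param feature Feature name (e.g. `"fp_threshold"`, `"k"`, `"b"`).
#' @param years Integer years. @param values Numeric values (same length).
#' @param units Unit string.
#' @return A `feature_series` object.
#' @export
feature_series <- function(pair_label, feature, years, values, units = "") {
  stopifnot(length(years) == length(values))
  structure(list(pair_label = pair_label, feature = feature,
                 years = as.integer(years), values = as.numeric(values),
                 units = units), class = "feature_series")
}

star_flag <- function(p) if (is.na(p)) "" else if (p < 0.01) "**" else
  if (p < 0.05) "*" else ""

#' OLS trend test of a feature series
#'
#' Regresses the value on the calendar year: slope `a` (units per year),
#' intercept, two-sided t-test p-value, and the star flag (`**` for
#' p < 0.01, `*` for 0.01 <= p < 0.05). A constant series returns slope 0
#' with p = 1 and `constant = TRUE`.
#'
#' @param series A [feature_series()] (or a list with `years`, `values`).
#' @return A `trend_result`: list with `slope`, `intercept`, `p_value`,
#'   `flag`, `n`, `constant`.
#' @export
trend_test <- function(series) {
  ok <- is.finite(series$values)
  y <- series$values[ok]; yr <- series$years[ok]
  if (length(y) < 3)
    stop_with("trend test needs at least 3 non-missing years",
              "eslines_insufficient_data")
  if (stats::sd(y) == 0)
    return(structure(list(slope = 0, intercept = y[1], p_value = 1,
                          flag = "", n = length(y), constant = TRUE),
                     class = "trend_result"))
  fit <- stats::lm(y ~ yr)
  sm <- summary(fit)$coefficients
  p <- sm["yr", "Pr(>|t|)"]
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = unname(p), flag = star_flag(p), n = length(y),
                 constant = FALSE), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend> a = %.4g %s (p = %.3g, n = %d)\n", x$slope, x$flag,
              x$p_value, x$n))
  invisible(x)
}

#' Box-plot statistics (type-7 quartiles, 1.5 IQR fences)
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return A `box_stats` list: `min, q1, median, q3, max, iqr`, the
#'   `lower_fence`/`upper_fence` at 1.5 IQR, and the `outliers` outside
#'   them.
#' @export
box_stats <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4)
    stop_with("box statistics need at least 4 values",
              "eslines_insufficient_data")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lf <- q[1] - 1.5 * iqr; uf <- q[3] + 1.5 * iqr
  structure(list(min = min(v), q1 = q[1], median = q[2], q3 = q[3],
                 max = max(v), iqr = iqr, lower_fence = lf, upper_fence = uf,
                 outliers = v[v < lf | v > uf]), class = "box_stats")
}

#' Extrema of a feature series with their years
#'
#' Ties are broken toward the earliest year (reported via a message).
#'
#' @param series A [feature_series()].
#' @return List with `min`, `min_year`, `max`, `max_year`.
#' @export
series_extrema <- function(series) {
  ok <- is.finite(series$values)
  v <- series$values[ok]; yr <- series$years[ok]
  if (length(v) == 0) stop_with("empty series", "eslines_insufficient_data")
  imin <- which(v == min(v)); imax <- which(v == max(v))
  if (length(imin) > 1 || length(imax) > 1)
    message("series_extrema: tie broken toward the earliest year")
  list(min = min(v), min_year = yr[imin[1]],
       max = max(v), max_year = yr[imax[1]])
}

#' Annual ecosystem-service summary with trends
#'
#' For each `<service>_mean` column of a per-year spatial-means table:
#' minimum and maximum with their years, overall mean, and the OLS trend
#' with its star flag.
#'
#' @param es_means data.frame with a `year` column and one or more
#'   `*_mean` columns (as produced by [es_means()]).
#' @return data.frame with one row per service.
#' @export
es_annual_report <- function(es_means) {
  cols <- grep("_mean$", names(es_means), value = TRUE)
  if (nrow(es_means) < 3)
    stop_with("annual report needs at least 3 years",
              "eslines_insufficient_data")
  do.call(rbind, lapply(cols, function(cl) {
    s <- feature_series("", sub("_mean$", "", cl), es_means$year,
                        es_means[[cl]])
    ex <- series_extrema(s)
    tr <- trend_test(s)
    data.frame(service = toupper(sub("_mean$", "", cl)),
               mean = mean(s$values, na.rm = TRUE),
               min = ex$min, min_year = ex$min_year,
               max = ex$max, max_year = ex$max_year,
               slope = tr$slope, p_value = tr$p_value, flag = tr$flag)
  }))
}

#' Characteristic-value table transcribed from the source study
#'
#' 21 years (2000-2020) of constraint-line characteristic values for the
#' six ES pairs: hump thresholds for five pairs and the exponential k and
#' b for SC_FP. Long format: `year, pair, feature, value`. The column
#' printed under NPP_WY with the header "FP" holds the NPP thresholds and
#' is labelled `npp_threshold` here; one further printed inconsistency
#' (the WY_FP minimum stated as 5.35 in prose vs 5.25 in the table) is
#' preserved as the table value.
#'
#' @return data.frame with columns `year`, `pair`, `feature`, `value`.
#' @export
load_table4 <- function() {
  path <- system.file("extdata", "table4_features.csv", package = "eslines")
  if (path == "") path <- file.path("inst", "extdata", "table4_features.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Extract one feature series from the transcribed characteristic table
#' @param tab Output of [load_table4()].
#' @param pair Pair label. @param feature Feature name.
#' @return A [feature_series()].
#' @export
table_feature <- function(tab, pair, feature) {
  sub <- tab[tab$pair == pair & tab$feature == feature, ]
  if (nrow(sub) == 0) stop_invalid(paste("no rows for", pair, feature))
  sub <- sub[order(sub$year), ]
  feature_series(pair, feature, sub$year, sub$value)
}

#' Trend and box summaries for every feature of a curve table
#'
#' @param curves data.frame from [run_pairs()] (columns `year`, `pair`,
#'   `form`, `threshold_x`, `threshold_y`, `k`, `b`).
#' @return List with data.frames `trends` (pair, feature, slope, p, flag)
#'   and `boxstats`.
#' @export
feature_dynamics <- function(curves) {
  feats <- list()
  for (pair in unique(curves$pair)) {
    sub <- curves[curves$pair == pair & curves$status == "ok", ]
    if (nrow(sub) == 0) next
    ab <- strsplit(pair, "_", fixed = TRUE)[[1]]
    if (sub$form[1] == "hump") {
      feats[[paste0(pair, ".", tolower(ab[1]), "_threshold")]] <-
        feature_series(pair, paste0(tolower(ab[1]), "_threshold"),
                       sub$year, sub$threshold_x)
      feats[[paste0(pair, ".", tolower(ab[2]), "_threshold")]] <-
        feature_series(pair, paste0(tolower(ab[2]), "_threshold"),
                       sub$year, sub$threshold_y)
    } else {
      feats[[paste0(pair, ".k")]] <- feature_series(pair, "k", sub$year, sub$k)
      feats[[paste0(pair, ".b")]] <- feature_series(pair, "b", sub$year, sub$b)
    }
  }
  trends <- do.call(rbind, lapply(feats, function(s) {
    tr <- tryCatch(trend_test(s), error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    data.frame(pair = s$pair_label, feature = s$feature, slope = tr$slope,
               p_value = tr$p_value, flag = tr$flag, n = tr$n)
  }))
  boxes <- do.call(rbind, lapply(feats, function(s) {
    bs <- tryCatch(box_stats(s$values), error = function(e) NULL)
    if (is.null(bs)) return(NULL)
    data.frame(pair = s$pair_label, feature = s$feature, min = bs$min,
               q1 = bs$q1, median = bs$median, q3 = bs$q3, max = bs$max,
               n_outliers = length(bs$outliers))
  }))
  rownames(trends) <- rownames(boxes) <- NULL
  list(series = feats, trends = trends, boxstats = boxes)
}
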