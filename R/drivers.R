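# Driver attribution of characteristic-value change. A documented stand-in
# for SPSS automatic linear modelling: standardize response and drivers,
# forward stepwise selection by AICc with a collinearity (VIF) guard,
# relative importance by the LMG decomposition (sequential sums of squares
# averaged over orderings, computed exactly from subset R-squared values),
# accuracy = adjusted R-squared x 100 floored at 0. Model 0 uses main
# effects only; Model 1 adds socioeconomic x landscape-configuration
# interaction products.

DRIVER_SOCIO <- c("gdp", "pop")
DRIVER_CONFIG <- c("pafrac", "lsi", "contag", "shdi", "pd")

#' Assemble the year-by-driver matrix
#'
#' Climate, NDVI, population and GDP enter as annual spatial means of the
#' forcing rasters; the six composition shares and five configuration
#' metrics are copied from the landscape-metrics table. Columns are
#' standardized to mean 0, sd 1 (parameters stored in the attribute
#' `scaling`); near-constant columns (sd < 1e-12) are dropped with a
#' message.
#'
#' @param forcings List of `forcing_stack` objects (one per year).
#' @param metrics data.frame from per-year [landscape_metrics()] rows
#'   (must contain `year`, the composition percentages and
#'   `pafrac, lsi, contag, shdi, pd`).
#' @return A `driver_matrix`: list with `year`, `raw` and `std`
#'   data.frames, and `scaling`.
#' @export
build_driver_matrix <- function(forcings, metrics) {
  years <- vapply(forcings, function(f) f$year, numeric(1))
  if (!setequal(years, metrics$year))
    stop_with(paste("year mismatch between forcing and metrics:",
                    paste(symdiff_years(years, metrics$year), collapse = ", ")),
              "eslines_alignment_error")
  metrics <- metrics[match(years, metrics$year), ]
  raw <- data.frame(
    ppt = vapply(forcings, function(f) mean(f$ppt), numeric(1)),
    tem = vapply(forcings, function(f) mean(f$tem), numeric(1)),
    ndvi = vapply(forcings, function(f) mean(f$ndvi), numeric(1)),
    cropland = metrics$cropland, forest = metrics$forest,
    grassland = metrics$grassland, water = metrics$water,
    urban = metrics$urban, unused = metrics$unused,
    pafrac = metrics$pafrac, lsi = metrics$lsi, contag = metrics$contag,
    shdi = metrics$shdi, pd = metrics$pd,
    gdp = vapply(forcings, function(f) mean(f$gdp), numeric(1)),
    pop = vapply(forcings, function(f) mean(f$pop), numeric(1))
  )
  has_na <- vapply(raw, anyNA, logical(1))
  if (any(has_na))
    message("drivers: dropping column(s) with undefined years: ",
            paste(names(raw)[has_na], collapse = ", "))
  sds <- vapply(raw, function(v) stats::sd(v, na.rm = TRUE), numeric(1))
  near_const <- !has_na & (is.na(sds) | sds < 1e-12)
  if (any(near_const))
    message("drivers: dropping near-constant column(s): ",
            paste(names(raw)[near_const], collapse = ", "))
  keep <- !has_na & !near_const
  raw <- raw[keep]
  ctr <- vapply(raw, mean, numeric(1))
  scl <- vapply(raw, stats::sd, numeric(1))
  std <- as.data.frame(scale(raw, center = ctr, scale = scl))
  structure(list(year = years, raw = raw, std = std,
                 scaling = list(center = ctr, scale = scl)),
            class = "driver_matrix")
}

symdiff_years <- function(a, b) sort(union(setdiff(a, b), setdiff(b, a)))

# ---- stepwise AICc selection with VIF guard ----------------------------

aicc <- function(fit) {
  k <- length(stats::coef(fit)) + 1
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) return(Inf)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

max_vif <- function(X) {
  if (ncol(X) < 2) return(1)
  cm <- tryCatch(solve(stats::cor(X)), error = function(e) NULL)
  if (is.null(cm)) return(Inf)
  max(diag(cm))
}

# Forward selection over columns of standardized design `X` for response
# `y`; a candidate enters only if it lowers AICc by more than `margin` and
# keeps the largest VIF of the selected set at or below `vif_cap`.
# `margin = NULL`/`NA` uses the multiplicity-adjusted default 2 ln(p) for
# p candidates (risk-inflation criterion): picking the best of many noise
# candidates inflates the apparent AICc gain, so a flat margin of 2 lets
# spurious terms through.
stepwise_aicc <- function(y, X, max_terms = 6, margin = NULL, vif_cap = 10) {
  if (is.null(margin) || is.na(margin)) margin <- 2 * log(max(ncol(X), 2))
  selected <- character(0)
  current_aicc <- aicc(stats::lm(y ~ 1))
  tss <- sum((y - mean(y))^2)
  repeat {
    if (length(selected) >= max_terms) break
    # with no residual variance left, AICc on machine-epsilon residuals is
    # meaningless and nothing further may enter
    if (length(selected) > 0) {
      rss <- sum(stats::resid(stats::lm(y ~ .,
                                        data = X[, selected,
                                                 drop = FALSE]))^2)
      if (rss <= 1e-10 * max(tss, 1e-300)) break
    }
    cands <- setdiff(colnames(X), selected)
    best <- NULL; best_aicc <- Inf
    for (cn in cands) {
      cols <- c(selected, cn)
      if (max_vif(X[, cols, drop = FALSE]) > vif_cap) next
      fit <- stats::lm(y ~ ., data = X[, cols, drop = FALSE])
      if (anyNA(stats::coef(fit))) next
      a <- aicc(fit)
      if (a < best_aicc) { best <- cn; best_aicc <- a }
    }
    if (is.null(best) || best_aicc >= current_aicc - margin) break
    selected <- c(selected, best)
    current_aicc <- best_aicc
  }
  selected
}

# LMG relative importance: average over orderings of the sequential
# R-squared increments, computed exactly from all-subset R-squared values.
lmg_importance <- function(y, X) {
  p <- ncol(X)
  if (p == 0) return(numeric(0))
  if (p == 1) return(stats::setNames(1, colnames(X)))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  r2_of <- apply(subsets, 1, function(sel) {
    if (!any(sel)) return(0)
    fit <- stats::lm(y ~ ., data = X[, sel, drop = FALSE])
    summary(fit)$r.squared
  })
  key <- apply(subsets, 1, function(sel)
    paste0("s", paste(which(sel), collapse = ",")))
  r2 <- stats::setNames(r2_of, key)
  imp <- numeric(p)
  others <- seq_len(p)
  for (j in seq_len(p)) {
    rest <- setdiff(others, j)
    total <- 0
    for (sz in 0:(p - 1)) {
      # note: combn() must never see a scalar first argument
      combs <- if (sz == 0) list(integer(0)) else
        utils::combn(seq_along(rest), sz, FUN = function(i) rest[i],
                     simplify = FALSE)
      w <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
      for (S in combs) {
        kS <- paste0("s", paste(S, collapse = ","))
        kSj <- paste0("s", paste(sort(c(S, j)), collapse = ","))
        total <- total + w * (r2[[kSj]] - r2[[kS]])
      }
    }
    imp[j] <- total
  }
  names(imp) <- colnames(X)
  imp
}

fit_alm <- function(y_raw, X, model_id, config) {
  y <- as.numeric(scale(y_raw))
  selected <- stepwise_aicc(y, X, max_terms = config$max_terms,
                            margin = config$aicc_margin,
                            vif_cap = config$vif_cap)
  if (length(selected) == 0) {
    return(structure(list(model_id = model_id, terms = data.frame(
      term = character(0), coefficient = numeric(0), p_value = numeric(0),
      star = character(0), importance = numeric(0), interaction = logical(0)),
      accuracy = 0, empty = TRUE), class = "attribution_result"))
  }
  Xs <- X[, selected, drop = FALSE]
  safe <- make.names(selected)            # lm mangles names like gdp:pafrac
  Xfit <- stats::setNames(Xs, safe)
  fit <- stats::lm(y ~ ., data = Xfit)
  sm <- summary(fit)
  co <- sm$coefficients[safe, , drop = FALSE]
  imp <- lmg_importance(y, Xs)
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  acc <- max(0, min(1, sm$adj.r.squared)) * 100
  terms <- data.frame(
    term = selected,
    coefficient = unname(co[, "Estimate"]),
    p_value = unname(co[, "Pr(>|t|)"]),
    star = vapply(co[, "Pr(>|t|)"], star_flag, ""),
    importance = unname(imp[selected]),
    interaction = grepl(":", selected, fixed = TRUE)
  )
  structure(list(model_id = model_id, terms = terms, accuracy = acc,
                 empty = FALSE), class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution> model %d, accuracy %.1f%%\n", x$model_id,
              x$accuracy))
  if (!x$empty) print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Attribution configuration
#' @param max_terms Cap on retained main effects (default 6; 21 annual
#'   observations do not support more).
#' @param aicc_margin AICc improvement a term must deliver to enter. The
#'   default (`NULL`) is the multiplicity-adjusted `2 ln(p)` for `p`
#'   candidate terms, which keeps the false-entry rate of noise terms low
#'   when dozens of candidates compete; set a numeric value to override.
#' @param vif_cap Largest tolerated variance-inflation factor.
#' @return List of class `alm_config`.
#' @export
alm_config <- function(max_terms = 6, aicc_margin = NULL, vif_cap = 10) {
  structure(list(max_terms = max_terms, aicc_margin = aicc_margin,
                 vif_cap = vif_cap), class = "alm_config")
}

#' Model 0: main-effect attribution of a characteristic value
#'
#' Standardizes the response, runs forward AICc selection over all driver
#' columns with the VIF guard, and reports standardized coefficients with
#' significance stars, LMG relative importances normalized to sum 1, and
#' accuracy (adjusted R-squared x 100, floored at 0).
#'
#' @param y A [feature_series()] (or numeric vector) aligned with the
#'   driver-matrix years.
#' @param X A `driver_matrix` from [build_driver_matrix()].
#' @param config An [alm_config()].
#' @return An `attribution_result`.
#' @export
fit_model0 <- function(y, X, config = alm_config()) {
  yv <- if (inherits(y, "feature_series")) align_series(y, X) else y
  check_usable(yv)
  fit_alm(yv, X$std, 0L, config)
}

#' Model 1: attribution with socioeconomic x configuration interactions
#'
#' Extends the Model 0 candidate set with the products of every
#' socioeconomic driver (GDP, population) and every landscape-
#' configuration metric (PAFRAC, LSI, CONTAG, SHDI, PD), computed on the
#' standardized columns and re-standardized. Interaction terms are flagged
#' in the result.
#'
#' @inheritParams fit_model0
#' @param socio,config_terms Column names forming the interaction products.
#' @return An `attribution_result` with `model_id = 1`.
#' @export
fit_model1 <- function(y, X, config = alm_config(),
                       socio = DRIVER_SOCIO, config_terms = DRIVER_CONFIG) {
  yv <- if (inherits(y, "feature_series")) align_series(y, X) else y
  check_usable(yv)
  std <- X$std
  for (s in intersect(socio, colnames(std))) {
    for (cfg in intersect(config_terms, colnames(std))) {
      v <- std[[s]] * std[[cfg]]
      if (stats::sd(v) < 1e-12) next
      std[[paste0(s, ":", cfg)]] <- as.numeric(scale(v))
    }
  }
  fit_alm(yv, std, 1L, config)
}

align_series <- function(series, X) {
  idx <- match(X$year, series$years)
  if (anyNA(idx))
    stop_with("feature series does not cover all driver years",
              "eslines_alignment_error")
  series$values[idx]
}

check_usable <- function(y) {
  if (sum(is.finite(y)) < 8)
    stop_with("attribution needs at least 8 usable years",
              "eslines_insufficient_data")
  invisible(TRUE)
}

#' Attribution table for every characteristic value
#'
#' Runs Model 0 and Model 1 for each feature series and stacks the term
#' tables in the layout of the study's results (response, model, term,
#' coefficient, star, importance, accuracy).
#'
#' @param series_list Named list of [feature_series()].
#' @param X A `driver_matrix`.
#' @param config An [alm_config()].
#' @return data.frame, one row per retained term per response and model.
#' @export
attribute_all <- function(series_list, X, config = alm_config()) {
  rows <- list()
  for (nm in names(series_list)) {
    s <- series_list[[nm]]
    for (mk in list(fit_model0, fit_model1)) {
      res <- tryCatch(mk(s, X, config), error = function(e) e)
      if (inherits(res, "error")) next
      if (res$empty) {
        rows[[length(rows) + 1L]] <- data.frame(
          response = nm, model = res$model_id, term = NA_character_,
          coefficient = NA_real_, star = "", importance = NA_real_,
          accuracy = res$accuracy)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          response = nm, model = res$model_id, term = res$terms$term,
          coefficient = res$terms$coefficient, star = res$terms$star,
          importance = res$terms$importance, accuracy = res$accuracy)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
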