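# Landscape composition and the five configuration metrics (PAFRAC, LSI,
# CONTAG, SHDI, PD) at the landscape level, from their standard FRAGSTATS
# definitions. Patches are maximal connected components of equal-class
# cells; adjacency counts exclude the landscape boundary, perimeters and
# total edge include it.

#' Label patches of a land-use map
#'
#' Connected-component labelling of equal-class cells under 4- (edge) or
#' 8- (edge or corner) connectivity, by iterated minimum-label propagation.
#'
#' @param landuse A `landuse_map`.
#' @param connectivity 4 or 8 (FRAGSTATS default 8).
#' @return A `patch_set`: list with integer matrix `labels` (patch IDs
#'   1..n), data.frame `patches` (id, class, area_m2, perim_m), and `grid`.
#'   Perimeters count exposed cell edges including the landscape boundary.
#' @export
label_patches <- function(landuse, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop_invalid("connectivity must be 4 or 8")
  cls <- landuse$classes
  nr <- nrow(cls); nc <- ncol(cls)
  off <- if (connectivity == 4) offsets4 else offsets8
  lab <- matrix(seq_len(nr * nc), nr, nc)
  repeat {
    new <- lab
    for (j in seq_len(nrow(off))) {
      nb_lab <- shift_mat(lab, off[j, 1], off[j, 2])
      nb_cls <- shift_mat(cls, off[j, 1], off[j, 2])
      same <- !is.na(nb_cls) & nb_cls == cls
      new[same] <- pmin(new[same], nb_lab[same])
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(as.vector(lab)))
  lab <- matrix(match(lab, ids), nr, nc)

  cs <- landuse$grid$cell_size
  counts <- tabulate(lab, nbins = length(ids))
  # exposed edge count per cell over the 4 edge directions
  exposed <- matrix(0L, nr, nc)
  for (j in seq_len(nrow(offsets4))) {
    nb_cls <- shift_mat(cls, offsets4[j, 1], offsets4[j, 2])
    exposed <- exposed + (is.na(nb_cls) | nb_cls != cls)
  }
  perim <- vapply(seq_along(ids), function(i) sum(exposed[lab == i]),
                  numeric(1)) * cs
  patch_class <- cls[match(seq_along(ids), as.vector(lab))]
  structure(list(
    labels = lab,
    patches = data.frame(id = seq_along(ids), class = patch_class,
                         area_m2 = counts * cs^2, perim_m = perim),
    grid = landuse$grid, connectivity = connectivity
  ), class = "patch_set")
}

#' Landscape composition in percent
#' @param landuse A `landuse_map`.
#' @return Named numeric vector of class percentages (sums to 100).
#' @export
compute_composition <- function(landuse) {
  100 * class_fractions(landuse)
}

#' Landscape-level configuration metrics
#'
#' SHDI `= -sum p_i ln p_i` (nats); LSI `= 0.25 E* / sqrt(A)` with `E*`
#' total edge including the landscape boundary; PD = patches per 100 ha;
#' CONTAG from the double-count class-adjacency matrix (boundary excluded)
#' scaled to (0, 100]; PAFRAC `= 2 / slope` of the OLS regression of
#' ln(area) on ln(perimeter) over all patches. CONTAG needs at least two
#' classes and PAFRAC at least `pafrac_min_patches` patches; otherwise the
#' metric is returned as `NA` (never silently 0).
#'
#' @param patches A `patch_set` from [label_patches()].
#' @param landuse The `landuse_map` the patches came from.
#' @param pafrac_min_patches Minimum patch count for the perimeter-area
#'   regression (default 10).
#' @return A one-row data.frame: `pafrac, lsi, contag, shdi, pd` plus
#'   `n_patches` and the six composition percentages.
#' @export
compute_configuration <- function(patches, landuse, pafrac_min_patches = 10) {
  cls <- landuse$classes
  nr <- nrow(cls); nc <- ncol(cls)
  cs <- landuse$grid$cell_size
  A <- nr * nc * cs^2                      # m2
  comp <- compute_composition(landuse)
  p <- comp[comp > 0] / 100

  shdi <- -sum(p * log(p))

  # total edge once-counted + landscape boundary
  internal <- 0
  for (j in 3:4) {                          # right and down shifts suffice
    nb <- shift_mat(cls, offsets4[j, 1], offsets4[j, 2])
    internal <- internal + sum(nb != cls, na.rm = TRUE)
  }
  E_star <- (internal + 2 * (nr + nc)) * cs
  lsi <- 0.25 * E_star / sqrt(A)

  pd <- nrow(patches$patches) / (A / 1e4) * 100

  contag <- contagion(cls)

  pafrac <- NA_real_
  if (nrow(patches$patches) >= pafrac_min_patches) {
    la <- log(patches$patches$area_m2)
    lp <- log(patches$patches$perim_m)
    if (stats::sd(lp) > 0) {
      slope <- stats::coef(stats::lm(la ~ lp))[[2]]
      if (is.finite(slope) && slope != 0) pafrac <- 2 / slope
    }
  }

  data.frame(pafrac = pafrac, lsi = lsi, contag = contag, shdi = shdi,
             pd = pd, n_patches = nrow(patches$patches),
             t(as.data.frame(comp)), row.names = NULL, check.names = FALSE)
}

# FRAGSTATS landscape contagion from double-count adjacencies, boundary
# excluded; NA when fewer than two classes are present.
contagion <- function(cls) {
  codes <- sort(unique(as.vector(cls)))
  m <- length(codes)
  if (m < 2) return(NA_real_)
  idx <- match(cls, codes)
  g <- matrix(0, m, m)
  for (j in 3:4) {
    nb <- shift_mat(matrix(idx, nrow(cls), ncol(cls)),
                    offsets4[j, 1], offsets4[j, 2])
    ok <- !is.na(nb)
    tab <- table(factor(idx[ok], levels = seq_len(m)),
                 factor(nb[ok], levels = seq_len(m)))
    g <- g + tab + t(tab)                   # double count
  }
  P <- tabulate(idx, m) / length(idx)
  gs <- rowSums(g)
  q <- (P * g / gs)                         # recycled row-wise: P_i * g_ik / sum_k g_ik
  q <- as.vector(q)
  q <- q[q > 0]
  (1 + sum(q * log(q)) / (2 * log(m))) * 100
}

#' All per-year landscape metrics in one call
#'
#' @param landuse A `landuse_map`.
#' @param year Year stamped on the row.
#' @param connectivity Patch connectivity (4 or 8).
#' @return One-row data.frame: `year`, composition percentages, and the
#'   five configuration metrics.
#' @export
landscape_metrics <- function(landuse, year = NA_integer_, connectivity = 8) {
  ps <- label_patches(landuse, connectivity)
  cfg <- compute_configuration(ps, landuse)
  cbind(data.frame(year = year), cfg)
}
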