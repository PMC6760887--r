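#' Ad-hoc reference bandwidth for bivariate kernel home ranges
#'
#' The reference ("href") smoothing parameter used for all utilization
#' distributions in this package:
#' \deqn{h = 0.5 (s_x + s_y) n^{-1/6}}
#' where \eqn{s_x, s_y} are the coordinate standard deviations. This is the
#' ad-hoc bandwidth convention of classical fixed-kernel home-range
#' estimators, optimal for an underlying bivariate normal utilization
#' distribution.
#'
#' @param xy two-column matrix or data frame of coordinates (meters).
#' @return bandwidth in meters.
#' @examples
#' set.seed(1)
#' reference_bandwidth(cbind(rnorm(64, sd = 100), rnorm(64, sd = 100)))
#' @export
reference_bandwidth <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2) stop("need at least 2 points")
  sdx <- stats::sd(xy[, 1])
  sdy <- stats::sd(xy[, 2])
  if (sdx + sdy <= 0) stop("all points identical: bandwidth undefined")
  0.5 * (sdx + sdy) * nrow(xy)^(-1 / 6)
}

#' Fixed-kernel utilization distribution on a regular grid
#'
#' Bivariate Gaussian kernel density of a relocation set, evaluated on a
#' square-celled grid whose extent covers the points with at least
#' \code{3h} of padding (so that truncation loss is negligible), then
#' normalized to integrate to exactly 1 over the grid.
#'
#' The kernel is separable, so the grid evaluation is performed as two
#' one-dimensional Gaussian matrices multiplied together; this is exact, not
#' an approximation.
#'
#' @param xy two-column matrix of relocations (meters).
#' @param h kernel bandwidth (meters); default \code{reference_bandwidth(xy)}.
#' @param n_cells approximate number of cells along the longer grid side
#'   (default 200).
#' @param padding margin added around the point bounding box, in meters;
#'   must be at least \code{3h} (default exactly that).
#' @param cell_size optional explicit cell edge (meters); overrides
#'   \code{n_cells}.
#' @return an object of class \code{ud_grid}: list with \code{x}, \code{y}
#'   (cell-center coordinates), \code{density} (matrix, rows indexed by x,
#'   in 1/m^2), \code{cell_size}, \code{h}, \code{n_points}.
#' @export
kernel_ud <- function(xy, h = reference_bandwidth(xy), n_cells = 200,
                      padding = 3 * h, cell_size = NULL) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 1) stop("no points")
  if (!is.finite(h) || h <= 0) stop("bandwidth must be positive")
  if (padding < 3 * h)
    stop("grid padding below 3*h would truncate the kernel mass")
  xr <- range(xy[, 1]) + c(-padding, padding)
  yr <- range(xy[, 2]) + c(-padding, padding)
  if (is.null(cell_size))
    cell_size <- max(diff(xr), diff(yr)) / n_cells
  gx <- seq(xr[1] + cell_size / 2, xr[2], by = cell_size)
  gy <- seq(yr[1] + cell_size / 2, yr[2], by = cell_size)
  # separable Gaussian kernel: dens = Kx %*% t(Ky) / (n 2 pi h^2)
  kx <- exp(-outer(gx, xy[, 1], "-")^2 / (2 * h^2))
  ky <- exp(-outer(gy, xy[, 2], "-")^2 / (2 * h^2))
  dens <- (kx %*% t(ky)) / (n * 2 * pi * h^2)
  tot <- sum(dens) * cell_size^2
  dens <- dens / tot
  structure(list(x = gx, y = gy, density = dens, cell_size = cell_size,
                 h = h, n_points = n, raw_integral = tot),
            class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("Utilization distribution: %d x %d cells of %.1f m, h = %.1f m, n = %d\n",
              length(x$x), length(x$y), x$cell_size, x$h, x$n_points))
  invisible(x)
}

#' Probability isopleth of a utilization distribution
#'
#' Finds the smallest set of grid cells containing at least fraction
#' \code{p} of the utilization mass (cells are accumulated in order of
#' decreasing density), its area, and its center.
#'
#' @param ud a \code{ud_grid}.
#' @param p probability level in (0, 1), e.g. 0.95 or 0.50.
#' @param center \code{"centroid"} (density-weighted mean of member cell
#'   centers, the default) or \code{"mode"} (highest-density cell).
#' @return list with \code{area_ha} (hectares), \code{centroid} (x, y),
#'   \code{mask} (logical matrix over the grid), \code{p}.
#' @export
isopleth <- function(ud, p, center = c("centroid", "mode")) {
  stopifnot(inherits(ud, "ud_grid"), p > 0, p < 1)
  center <- match.arg(center)
  d <- ud$density
  cell_area <- ud$cell_size^2
  ord <- order(d, decreasing = TRUE)
  cum <- cumsum(d[ord]) * cell_area
  k <- which(cum >= p)[1]
  if (is.na(k)) k <- length(ord)   # p beyond grid mass: take all cells
  member <- ord[seq_len(k)]
  mask <- matrix(FALSE, nrow(d), ncol(d))
  mask[member] <- TRUE
  idx <- arrayInd(member, dim(d))
  w <- d[member]
  centroid <- if (center == "centroid") {
    c(x = sum(ud$x[idx[, 1]] * w) / sum(w),
      y = sum(ud$y[idx[, 2]] * w) / sum(w))
  } else {
    c(x = ud$x[idx[1, 1]], y = ud$y[idx[1, 2]])
  }
  list(area_ha = k * cell_area / 1e4, centroid = centroid, mask = mask,
       p = p)
}

# both isopleth levels from a single density ordering; optionally the
# member cell centers of the widest level (for site-overlap assignment)
ud_levels <- function(ud, probs = c(0.50, 0.95), want_cells = FALSE) {
  d <- ud$density
  cell_area <- ud$cell_size^2
  ord <- order(d, decreasing = TRUE)
  cum <- cumsum(d[ord]) * cell_area
  out <- lapply(probs, function(p) {
    k <- which(cum >= p)[1]
    if (is.na(k)) k <- length(ord)
    member <- ord[seq_len(k)]
    idx <- arrayInd(member, dim(d))
    w <- d[member]
    list(area_ha = k * cell_area / 1e4,
         centroid = c(x = sum(ud$x[idx[, 1]] * w) / sum(w),
                      y = sum(ud$y[idx[, 2]] * w) / sum(w)),
         cells = if (want_cells) cbind(ud$x[idx[, 1]], ud$y[idx[, 2]])
                 else NULL)
  })
  names(out) <- paste0("p", probs * 100)
  out
}

#' Seasonal fixed-kernel home ranges
#'
#' For every individual-by-season combination with at least
#' \code{min_fixes} relocations, estimates a fixed-kernel utilization
#' distribution with the reference bandwidth and extracts the 95% home
#' range area, the 50% core area, and the core (50%) center. Combinations
#' with fewer relocations are omitted; they are listed in the
#' \code{"excluded"} attribute of the result together with the reason.
#'
#' @param relocations data frame with columns \code{individual}, \code{date},
#'   \code{x}, \code{y}; optional \code{sex}, \code{site}, \code{group} are
#'   carried through (first value per individual).
#' @param min_fixes minimum relocations per individual-season (default 10).
#' @param n_cells,center passed to \code{\link{kernel_ud}} /
#'   \code{\link{isopleth}}.
#' @return data frame, one row per retained individual-season: \code{n},
#'   \code{h}, \code{area95_ha}, \code{area50_ha}, \code{center50_x},
#'   \code{center50_y}, \code{year}.
#' @export
seasonal_home_ranges <- function(relocations, min_fixes = 10, n_cells = 200,
                                 center = "centroid") {
  r <- relocations
  r$date <- as.Date(r$date)
  r$season <- classify_season(r$date)
  r <- r[r$season != "excluded" & !is.na(r$season), , drop = FALSE]
  carry <- intersect(c("sex", "site", "group"), names(r))
  out <- list(); excl <- list()
  for (id in unique(r$individual)) {
    ri <- r[r$individual == id, , drop = FALSE]
    for (season in c("pre", "early", "late")) {
      rs <- ri[ri$season == season, , drop = FALSE]
      n <- nrow(rs)
      if (n == 0) next
      if (n < min_fixes) {
        excl[[length(excl) + 1]] <- data.frame(
          individual = id, season = season, n = n,
          reason = sprintf("fewer than %d relocations", min_fixes))
        next
      }
      xy <- cbind(rs$x, rs$y)
      h <- reference_bandwidth(xy)
      ud <- kernel_ud(xy, h = h, n_cells = n_cells)
      lv <- ud_levels(ud)
      if (center == "mode") {
        lv$p50$centroid <- isopleth(ud, 0.50, center = "mode")$centroid
      }
      row <- data.frame(individual = id, season = season, n = n, h = h,
                        area95_ha = lv$p95$area_ha,
                        area50_ha = lv$p50$area_ha,
                        center50_x = lv$p50$centroid[["x"]],
                        center50_y = lv$p50$centroid[["y"]],
                        year = as.integer(format(rs$date[1], "%Y")),
                        stringsAsFactors = FALSE)
      for (cc in carry) row[[cc]] <- ri[[cc]][1]
      out[[length(out) + 1]] <- row
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(individual = character(), season = character(), n = integer(),
               h = numeric(), area95_ha = numeric(), area50_ha = numeric(),
               center50_x = numeric(), center50_y = numeric(),
               year = integer())
  res$season <- factor(res$season, levels = c("pre", "early", "late"))
  rownames(res) <- NULL
  attr(res, "excluded") <- if (length(excl)) do.call(rbind, excl) else NULL
  res
}

#' Seasonal shifts of the core home-range center
#'
#' Euclidean distance from each individual's pre-season 50% home-range
#' center to its early- and late-season centers. Individuals lacking either
#' member of a pair contribute no row for that contrast, mirroring the
#' paired nature of a before/after location analysis.
#'
#' @param estimates output of \code{\link{seasonal_home_ranges}}.
#' @return data frame with \code{individual}, \code{contrast}
#'   (\code{pre_early} or \code{pre_late}), \code{distance} (m), plus any
#'   carried grouping columns.
#' @export
seasonal_shifts <- function(estimates) {
  carry <- intersect(c("sex", "site", "group", "year"), names(estimates))
  out <- list()
  for (id in unique(estimates$individual)) {
    e <- estimates[estimates$individual == id, , drop = FALSE]
    pre <- e[e$season == "pre", , drop = FALSE]
    if (nrow(pre) == 0) next
    for (season in c("early", "late")) {
      s <- e[e$season == season, , drop = FALSE]
      if (nrow(s) == 0) next
      d <- sqrt((s$center50_x - pre$center50_x)^2 +
                  (s$center50_y - pre$center50_y)^2)
      row <- data.frame(individual = id,
                        contrast = paste0("pre_", season),
                        distance = d, stringsAsFactors = FALSE)
      for (cc in carry) row[[cc]] <- e[[cc]][1]
      out[[length(out) + 1]] <- row
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(individual = character(), contrast = character(),
               distance = numeric())
  res$contrast <- factor(res$contrast, levels = c("pre_early", "pre_late"))
  rownames(res) <- NULL
  res
}
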