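#' Sliding-window home ranges from an individual's relocation series
#'
#' Builds one fixed-kernel home range per relocation window: the focal fix
#' plus its five predecessors and five successors (11 relocations), the
#' window advancing one relocation at a time. A series of n relocations
#' yields \code{max(0, n - 10)} windows. Each window gets its own reference
#' bandwidth, 95%/50% areas, 50% center, median date and window length
#' (days between first and last member fix).
#'
#' When \code{sites} is supplied, each window is assigned the study site
#' whose polygon overlaps its 95% region most (overlap measured as the
#' number of 95%-region cell centers falling inside the polygon; ties are
#' broken by site id); windows overlapping no site are \code{offsite}.
#'
#' @param relocations data frame with \code{individual}, \code{date},
#'   \code{x}, \code{y} (all individuals; grouped internally). Optional
#'   \code{sex}, \code{site}, \code{group} are carried through.
#' @param half_width relocations on each side of the focal fix (default 5).
#' @param n_cells grid resolution for the window UDs.
#' @param sites optional site table from \code{\link{read_sites_geojson}}
#'   or \code{\link{simulate_dataset}} (needs \code{site}, \code{group},
#'   \code{polygon} columns).
#' @return data frame, one row per window: \code{individual},
#'   \code{window}, \code{first_date}, \code{median_date}, \code{last_date},
#'   \code{window_length}, \code{h}, \code{area95_ha}, \code{area50_ha},
#'   \code{center50_x}, \code{center50_y}, \code{year},
#'   \code{assigned_site} (when sites given).
#' @export
build_windows <- function(relocations, half_width = 5, n_cells = 60,
                          sites = NULL) {
  r <- relocations
  r$date <- as.Date(r$date)
  r <- r[order(r$individual, r$date), , drop = FALSE]
  carry <- intersect(c("sex", "group"), names(r))
  k <- 2 * half_width + 1
  out <- list()
  for (id in unique(r$individual)) {
    ri <- r[r$individual == id, , drop = FALSE]
    n <- nrow(ri)
    if (n < k) next
    ts <- (half_width + 1):(n - half_width)
    nw <- length(ts)
    num <- matrix(NA_real_, nw, 6,
                  dimnames = list(NULL, c("window_length", "h", "area95_ha",
                                          "area50_ha", "center50_x",
                                          "center50_y")))
    first_d <- med_d <- last_d <- rep(r$date[1], nw)
    site_a <- character(nw)
    dts <- ri$date
    xs <- ri$x; ys <- ri$y
    for (j in seq_len(nw)) {
      t <- ts[j]
      sel <- (t - half_width):(t + half_width)
      xy <- cbind(xs[sel], ys[sel])
      h <- reference_bandwidth(xy)
      ud <- kernel_ud(xy, h = h, n_cells = n_cells)
      lv <- ud_levels(ud, want_cells = !is.null(sites))
      first_d[j] <- dts[sel[1]]
      med_d[j] <- stats::median(dts[sel])
      last_d[j] <- dts[sel[k]]
      num[j, ] <- c(as.numeric(dts[sel[k]] - dts[sel[1]]), h,
                    lv$p95$area_ha, lv$p50$area_ha,
                    lv$p50$centroid[["x"]], lv$p50$centroid[["y"]])
      if (!is.null(sites))
        site_a[j] <- best_overlap_site(lv$p95$cells[, 1],
                                       lv$p95$cells[, 2], sites)
    }
    res_i <- data.frame(individual = id, window = ts,
                        first_date = first_d, median_date = med_d,
                        last_date = last_d, num,
                        year = as.integer(format(first_d[1], "%Y")),
                        stringsAsFactors = FALSE)
    for (cc in carry) res_i[[cc]] <- ri[[cc]][1]
    if (!is.null(sites)) res_i$assigned_site <- site_a
    out[[length(out) + 1]] <- res_i
  }
  res <- if (length(out)) do.call(rbind, out) else NULL
  if (is.null(res)) {
    res <- data.frame(individual = character(), window = integer(),
                      first_date = as.Date(character()),
                      median_date = as.Date(character()),
                      last_date = as.Date(character()),
                      window_length = numeric(), h = numeric(),
                      area95_ha = numeric(), area50_ha = numeric(),
                      center50_x = numeric(), center50_y = numeric(),
                      year = integer())
    if (!is.null(sites)) res$assigned_site <- character()
  }
  rownames(res) <- NULL
  res
}

# site with greatest overlap with a set of region cell centers; ties by id
best_overlap_site <- function(cx, cy, sites) {
  counts <- vapply(seq_len(nrow(sites)), function(i) {
    poly <- sites$polygon[[i]]
    allxy <- do.call(rbind, poly)
    keep <- cx >= min(allxy[, 1]) & cx <= max(allxy[, 1]) &
      cy >= min(allxy[, 2]) & cy <= max(allxy[, 2])
    if (!any(keep)) return(0)
    sum(point_in_polygon(cx[keep], cy[keep], poly))
  }, numeric(1))
  if (all(counts == 0)) return("offsite")
  ord <- order(-counts, as.character(sites$site))
  as.character(sites$site[ord[1]])
}

#' Attribute hunting pressure to moving windows
#'
#' Assigns each window the mean hunters per photo, per site, per day of its
#' assigned site over the window's date range (first to last member fix).
#' Days before the hunting-season opening carry zero pressure by
#' definition; season days missing from the pressure table are dropped
#' from the mean (not imputed as zero). Windows that intersect no study
#' site receive the mean over all low-risk sites for the same date range
#' (the conservative offsite rule). Windows whose entire date range has no
#' usable pressure value are flagged with \code{NA} pressure.
#'
#' @param windows output of \code{\link{build_windows}} (with
#'   \code{assigned_site}; if absent, supply \code{sites} and
#'   \code{relocations} so assignment can be recomputed).
#' @param sites site table (needed for the low-risk fallback and for
#'   re-assignment).
#' @param pressure output of \code{\link{daily_pressure}}.
#' @param relocations only needed when \code{windows} lacks
#'   \code{assigned_site}.
#' @param half_width,n_cells passed through on re-assignment.
#' @return \code{windows} with added \code{pressure} column.
#' @export
assign_site_and_pressure <- function(windows, sites, pressure,
                                     relocations = NULL, half_width = 5,
                                     n_cells = 60) {
  if (!"assigned_site" %in% names(windows)) {
    if (is.null(relocations))
      stop("windows lack assigned_site; supply relocations to recompute")
    windows <- build_windows(relocations, half_width = half_width,
                             n_cells = n_cells, sites = sites)
  }
  if (nrow(windows) == 0) { windows$pressure <- numeric(0); return(windows) }
  pressure$date <- as.Date(pressure$date)
  low_sites <- as.character(sites$site[sites$group == "low"])

  # daily value lookup: rows = sites plus the low-risk mean, cols = days;
  # 0 before the season opening, NA where the table has no usable value
  all_days <- seq(min(as.Date(windows$first_date)),
                  max(as.Date(windows$last_date)), by = "day")
  site_ids <- as.character(sites$site)
  P <- matrix(NA_real_, nrow = length(site_ids) + 1, ncol = length(all_days),
              dimnames = list(c(site_ids, "offsite"), NULL))
  pre_open <- all_days < season_opening(format(all_days, "%Y"))
  P[, pre_open] <- 0
  ci <- match(pressure$date, all_days)
  ri <- match(as.character(pressure$site), site_ids)
  ok <- !is.na(ci) & !is.na(ri) & !pre_open[ci]
  P[cbind(ri[ok], ci[ok])] <- pressure$pressure[ok]
  low_rows <- P[site_ids %in% low_sites, , drop = FALSE]
  P["offsite", !pre_open] <- colMeans(low_rows[, !pre_open, drop = FALSE],
                                      na.rm = TRUE)
  P["offsite", is.nan(P["offsite", ])] <- NA

  i1 <- match(as.Date(windows$first_date), all_days)
  i2 <- match(as.Date(windows$last_date), all_days)
  rw <- match(as.character(windows$assigned_site), rownames(P))
  windows$pressure <- vapply(seq_len(nrow(windows)), function(i) {
    vals <- P[rw[i], i1[i]:i2[i]]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, numeric(1))
  windows
}

#' Steps between successive window centers
#'
#' Euclidean distance between the 50% centers of successive windows of the
#' same individual, each attributed the hunting pressure of the earlier
#' window -- the risk the individual was moving away from. Covariates
#' (median date, window length) are taken from the earlier window for the
#' same reason.
#'
#' @param windows output of \code{\link{assign_site_and_pressure}} (or
#'   \code{\link{build_windows}}; then \code{prev_pressure} is \code{NA}).
#' @return data frame with \code{individual}, \code{from_window},
#'   \code{distance} (m), \code{prev_pressure}, \code{median_date},
#'   \code{window_length}, \code{year} plus carried grouping columns.
#' @export
window_steps <- function(windows) {
  carry <- intersect(c("sex", "group", "assigned_site"), names(windows))
  out <- list()
  for (id in unique(windows$individual)) {
    w <- windows[windows$individual == id, , drop = FALSE]
    w <- w[order(w$window), , drop = FALSE]
    if (nrow(w) < 2) next
    for (j in seq_len(nrow(w) - 1)) {
      if (w$window[j + 1] != w$window[j] + 1) next
      d <- sqrt((w$center50_x[j + 1] - w$center50_x[j])^2 +
                  (w$center50_y[j + 1] - w$center50_y[j])^2)
      row <- data.frame(
        individual = id, from_window = w$window[j], distance = d,
        prev_pressure = if ("pressure" %in% names(w)) w$pressure[j] else NA,
        median_date = w$median_date[j], window_length = w$window_length[j],
        year = w$year[j], stringsAsFactors = FALSE)
      for (cc in carry) {
        col <- if (cc == "assigned_site") "site" else cc
        row[[col]] <- w[[cc]][j]
      }
      out[[length(out) + 1]] <- row
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(individual = character(), from_window = integer(),
               distance = numeric(), prev_pressure = numeric(),
               median_date = as.Date(character()), window_length = numeric(),
               year = integer())
  rownames(res) <- NULL
  res
}
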