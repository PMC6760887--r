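#' Classify study dates into hunting-season periods
#'
#' Splits the field-season calendar into the three analysis periods used
#' throughout the package: \code{pre} (1--25 October, before the hunting
#' season opens), \code{early} (27 October -- 23 November, the high-pressure
#' opening weeks) and \code{late} (24 November -- 15 December, after hunting
#' pressure has declined). Dates outside these windows -- including 26
#' October, which falls in none of them -- are labelled \code{excluded}.
#' Boundaries are applied within each date's own calendar year, so multiple
#' cohorts can be classified together.
#'
#' @param dates a \code{Date} vector (or something coercible via
#'   \code{as.Date}).
#' @return a factor with levels \code{pre}, \code{early}, \code{late},
#'   \code{excluded}.
#' @examples
#' classify_season(as.Date(c("2012-10-20", "2012-11-01", "2012-12-01",
#'                           "2012-10-26")))
#' @export
classify_season <- function(dates) {
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  md <- function(m, d) as.Date(sprintf("%04d-%02d-%02d", yr, m, d))
  out <- rep("excluded", length(dates))
  out[dates >= md(10, 1) & dates <= md(10, 25)] <- "pre"
  out[dates >= md(10, 27) & dates <= md(11, 23)] <- "early"
  out[dates >= md(11, 24) & dates <= md(12, 15)] <- "late"
  out[is.na(dates)] <- NA
  factor(out, levels = c("pre", "early", "late", "excluded"))
}

#' Hunting-season opening date for a cohort year
#'
#' @param year calendar year of the autumn field season.
#' @return a \code{Date}; the first day of the early season (27 October).
#' @export
season_opening <- function(year) {
  as.Date(sprintf("%04d-10-27", as.integer(year)))
}

#' Daily hunting pressure from camera-trap summaries
#'
#' Converts per-camera daily photo summaries into the pipeline's predation
#' risk proxy: mean hunters per photo, per site, per day. Rows sharing a
#' site and date (multiple cameras) are pooled by summing hunters and photos
#' before taking the ratio, so every photo is weighted equally. Days on
#' which no photos were taken (camera failure) yield \code{NA} pressure --
#' missing, not zero.
#'
#' @param camera_days data frame with columns \code{site}, \code{date},
#'   \code{n_photos}, \code{n_hunters}.
#' @param sites optional site table with columns \code{site} and
#'   \code{group}; when supplied the risk group is attached.
#' @return data frame with columns \code{site}, \code{date}, \code{season},
#'   \code{pressure} (and \code{group} when available), one row per
#'   site-date.
#' @export
daily_pressure <- function(camera_days, sites = NULL) {
  stopifnot(all(c("site", "date", "n_photos", "n_hunters") %in%
                  names(camera_days)))
  camera_days$date <- as.Date(camera_days$date)
  if (any(camera_days$n_hunters < 0)) stop("negative hunter counts")
  key <- interaction(camera_days$site, camera_days$date, drop = TRUE)
  agg <- data.frame(
    site = tapply(as.character(camera_days$site), key, `[`, 1),
    date = as.Date(tapply(as.character(camera_days$date), key, `[`, 1)),
    n_photos = as.vector(tapply(camera_days$n_photos, key, sum)),
    n_hunters = as.vector(tapply(camera_days$n_hunters, key, sum)),
    row.names = NULL, stringsAsFactors = FALSE)
  agg$pressure <- ifelse(agg$n_photos > 0, agg$n_hunters / agg$n_photos, NA)
  agg$season <- classify_season(agg$date)
  if (!is.null(sites)) {
    agg$group <- sites$group[match(agg$site, sites$site)]
  }
  agg <- agg[order(agg$site, agg$date), ]
  rownames(agg) <- NULL
  agg[, c("site", "date", "season", "pressure", "n_photos", "n_hunters",
          intersect("group", names(agg)))]
}

#' Mixed model for hunting pressure
#'
#' Fits the predation-risk model: daily pressure as a Gaussian response with
#' risk group, season (early vs late) and their interaction as fixed effects
#' and study site as a random intercept. The intercept is the high-risk,
#' early-season cell. Inference is by posterior simulation
#' (\code{\link{simulate_posterior}}).
#'
#' @param pressure output of \code{\link{daily_pressure}}, with a
#'   \code{group} column; rows outside the early/late seasons are dropped.
#' @param n_draws posterior draws (default 5000).
#' @param seed RNG seed for the posterior simulation.
#' @return a \code{riskspace_fit} object (see \code{\link{fit_lmm}}).
#' @export
fit_risk_model <- function(pressure, n_draws = 5000, seed = NULL) {
  stopifnot("group" %in% names(pressure))
  d <- pressure[pressure$season %in% c("early", "late") &
                  !is.na(pressure$pressure), , drop = FALSE]
  d$season <- factor(as.character(d$season), levels = c("early", "late"))
  d$group <- factor(as.character(d$group), levels = c("high", "low"))
  if (length(unique(d$site)) < 2)
    stop("site random intercept needs at least two sites")
  if (any(table(d$group) == 0)) stop("need data in both risk groups")
  fit <- fit_lmm(pressure ~ group * season + (1 | site), data = d)
  simulate_posterior(fit, n_draws = n_draws, seed = seed)
}
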