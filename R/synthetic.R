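#' Ground-truth parameters for a synthetic study
#'
#' Bundles every parameter of the synthetic data generator, which emulates
#' the design of the field study: ten grassland sites (five per risk
#' group, 29--155 ha), radio-marked individuals of both sexes tracked 3--7
#' days per week from 1 October to 15 December, hunting pressure
#' concentrated on high-risk sites early in the season, male-only harvest
#' mortality driven by that pressure, and a risk-triggered expansion and
#' shift of high-risk home ranges at the season opening.
#'
#' Movement is a daily bivariate mean-reverting (Ornstein-Uhlenbeck-like)
#' walk around an activity center,
#' \eqn{x_{t+1} = c + e^{-\phi}(x_t - c) + \epsilon_t}, whose stationary
#' SD maps directly onto expected kernel home-range area (a stationary SD
#' of \eqn{\sigma} gives a true 95% range of \eqn{5.99\,\pi \sigma^2}).
#' During the early season, high-risk females inflate their stationary SD
#' by \code{range_inflation} (reverting late) and displace their activity
#' center by \code{shift_distance}; males respond with the same effects
#' scaled by \code{male_response} (default 0: in the emulated system the
#' vulnerable sex shows no net population-level response).
#'
#' @param n_sites_per_group sites per risk group.
#' @param site_area_range min/max site area, hectares.
#' @param n_per_sex_group marked individuals per sex-by-risk-group cell.
#' @param year cohort year; the study window is 1 Oct -- 15 Dec of it.
#' @param oudecay per-day mean-reversion rate of the movement walk.
#' @param sigma_base stationary SD (m) of movement around the center.
#' @param range_inflation multiplicative SD factor for high-risk
#'   responders during the early season (>= 1).
#' @param male_response scaling in [0, 1] of the male behavioural
#'   response relative to females.
#' @param shift_distance activity-center displacement (m) for high-risk
#'   responders at the season opening.
#' @param hunter_rate_early_high,hunter_rate_late_high,hunter_rate_low
#'   expected hunters per photo per day by group and season.
#' @param harvest_hazard_coef per-day kill probability per unit hunting
#'   pressure (males on high-risk sites only).
#' @param natural_hazard per-day baseline mortality, all individuals.
#' @param collar_loss_rate per-day collar-loss (censoring) probability.
#' @param veg_group_offset high-risk offset (percentage points) added to
#'   warm-season grass and removed from cool-season grass cover.
#' @param veg_date_slope per-day trend in litter cover and depth.
#' @param photos_per_day camera photos per site per day (5-minute
#'   interval over ~10 legal hours).
#' @param tracking_days_range min/max tracking days per week.
#' @param loc_error_sd triangulation position error SD (m) applied to
#'   recorded relocations.
#' @param n_bearing_sets number of relocations for which raw bearing sets
#'   are also emitted.
#' @param bearing_sd bearing error SD in degrees for those sets.
#' @param n_veg_roosts number of roost plots measured for vegetation
#'   (each paired with a non-use plot 35 m away).
#' @param seed RNG seed; everything stochastic flows from it.
#' @return object of class \code{simulation_truth}.
#' @export
simulation_truth <- function(n_sites_per_group = 5,
                             site_area_range = c(29, 155),
                             n_per_sex_group = 25,
                             year = 2012,
                             oudecay = 0.6,
                             sigma_base = 200,
                             range_inflation = 1.47,
                             male_response = 0,
                             shift_distance = 500,
                             hunter_rate_early_high = 0.006,
                             hunter_rate_late_high = 0.0014,
                             hunter_rate_low = 0.0007,
                             harvest_hazard_coef = 6,
                             natural_hazard = 0.003,
                             collar_loss_rate = 0.0005,
                             veg_group_offset = 8,
                             veg_date_slope = 0.15,
                             photos_per_day = 120,
                             tracking_days_range = c(3, 7),
                             loc_error_sd = 10,
                             n_bearing_sets = 200,
                             bearing_sd = 3,
                             n_veg_roosts = 150,
                             seed = 1) {
  truth <- as.list(environment())
  rates <- c(hunter_rate_early_high, hunter_rate_late_high, hunter_rate_low,
             harvest_hazard_coef, natural_hazard, collar_loss_rate)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (range_inflation < 1) stop("range_inflation must be >= 1")
  if (male_response < 0 || male_response > 1)
    stop("male_response must be in [0, 1]")
  if (n_sites_per_group < 1) stop("need at least one site per group")
  if (n_per_sex_group < 1) stop("need at least one individual per cell")
  if (diff(site_area_range) < 0 || site_area_range[1] <= 0)
    stop("invalid site_area_range")
  class(truth) <- "simulation_truth"
  truth
}

#' Generate a complete synthetic study dataset
#'
#' Simulates sites, marked individuals, daily movement, camera-trap hunter
#' counts, harvest and natural mortality, relocation sampling, raw bearing
#' sets for a subsample of fixes, and roost-site vegetation plots, all
#' driven by a single seed (identical truth implies byte-identical
#' output).
#'
#' @param truth a \code{\link{simulation_truth}}.
#' @return object of class \code{synthetic_dataset}: list with
#'   \code{relocations}, \code{bearing_sets}, \code{camera_days},
#'   \code{sites}, \code{vegetation}, \code{fates}, \code{truth}.
#' @export
simulate_dataset <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(truth$seed)
  start <- as.Date(sprintf("%d-10-01", truth$year))
  end <- as.Date(sprintf("%d-12-15", truth$year))
  opening <- season_opening(truth$year)
  dates <- seq(start, end, by = "day")
  ndays <- length(dates)
  seasons <- classify_season(dates)

  ## ---- sites: rectangles on a sparse grid, areas within the stated range
  ns <- 2 * truth$n_sites_per_group
  groups <- rep(c("high", "low"), each = truth$n_sites_per_group)
  area_ha <- stats::runif(ns, truth$site_area_range[1],
                          truth$site_area_range[2])
  aspect <- stats::runif(ns, 0.6, 1.6)
  width <- sqrt(area_ha * 1e4 * aspect)
  height <- area_ha * 1e4 / width
  ox <- (seq_len(ns) - 1) %% 5 * 5000
  oy <- (seq_len(ns) - 1) %/% 5 * 5000
  sites <- data.frame(
    site = sprintf("S%02d", seq_len(ns)), group = groups,
    area_ha = area_ha, xmin = ox, xmax = ox + width,
    ymin = oy, ymax = oy + height, stringsAsFactors = FALSE)
  sites$polygon <- I(lapply(seq_len(ns), function(i) {
    list(cbind(c(sites$xmin[i], sites$xmax[i], sites$xmax[i],
                 sites$xmin[i], sites$xmin[i]),
               c(sites$ymin[i], sites$ymin[i], sites$ymax[i],
                 sites$ymax[i], sites$ymin[i])))
  }))

  ## ---- camera days (Poisson hunters per photo at group x season rates)
  cam <- expand.grid(site = sites$site, date = dates[dates >= opening],
                     stringsAsFactors = FALSE)
  cam$group <- sites$group[match(cam$site, sites$site)]
  cam_season <- classify_season(cam$date)
  rate <- ifelse(cam$group == "low", truth$hunter_rate_low,
                 ifelse(cam_season == "early", truth$hunter_rate_early_high,
                        truth$hunter_rate_late_high))
  cam$n_photos <- truth$photos_per_day
  cam$n_hunters <- stats::rpois(nrow(cam), cam$n_photos * rate)
  camera_days <- cam[order(cam$site, cam$date),
                     c("site", "date", "n_photos", "n_hunters")]
  rownames(camera_days) <- NULL
  realized_pressure <- camera_days$n_hunters / camera_days$n_photos
  names(realized_pressure) <- paste(camera_days$site, camera_days$date)

  ## ---- individuals
  inds <- list()
  for (sx in c("F", "M")) for (gr in c("high", "low")) {
    gsites <- sites[sites$group == gr, , drop = FALSE]
    for (i in seq_len(truth$n_per_sex_group)) {
      s <- gsites[(i - 1) %% nrow(gsites) + 1, , drop = FALSE]
      inds[[length(inds) + 1]] <- data.frame(
        individual = sprintf("%s-%s-%03d", sx, toupper(substr(gr, 1, 1)), i),
        sex = sx, group = gr, site = s$site,
        cx = stats::runif(1, s$xmin, s$xmax),
        cy = stats::runif(1, s$ymin, s$ymax), stringsAsFactors = FALSE)
    }
  }
  inds <- do.call(rbind, inds)
  n_ind <- nrow(inds)
  resp <- ifelse(inds$group == "high",
                 ifelse(inds$sex == "F", 1, truth$male_response), 0)

  ## ---- movement: daily OU walk; early-season inflation + center shift
  a <- exp(-truth$oudecay)
  theta <- stats::runif(n_ind, 0, 2 * pi)
  shift_x <- truth$shift_distance * resp * cos(theta)
  shift_y <- truth$shift_distance * resp * sin(theta)
  pos <- array(NA_real_, c(n_ind, ndays, 2))
  sd_day <- matrix(truth$sigma_base, n_ind, ndays)
  infl <- 1 + (truth$range_inflation - 1) * resp
  sd_day[, seasons == "early"] <- truth$sigma_base * infl
  cx_day <- matrix(inds$cx, n_ind, ndays)
  cy_day <- matrix(inds$cy, n_ind, ndays)
  shifted <- dates >= opening
  cx_day[, shifted] <- cx_day[, shifted] + shift_x
  cy_day[, shifted] <- cy_day[, shifted] + shift_y
  pos[, 1, 1] <- cx_day[, 1] + stats::rnorm(n_ind, 0, sd_day[, 1])
  pos[, 1, 2] <- cy_day[, 1] + stats::rnorm(n_ind, 0, sd_day[, 1])
  innov <- sqrt(1 - a^2)
  for (t in 2:ndays) {
    st <- sd_day[, t] * innov
    pos[, t, 1] <- cx_day[, t] + a * (pos[, t - 1, 1] - cx_day[, t - 1]) +
      stats::rnorm(n_ind, 0, st)
    pos[, t, 2] <- cy_day[, t] + a * (pos[, t - 1, 2] - cy_day[, t - 1]) +
      stats::rnorm(n_ind, 0, st)
  }

  ## ---- fates: daily hazards; harvest only for males on high-risk sites
  death_day <- rep(NA_integer_, n_ind)
  cause <- rep(NA_character_, n_ind)
  U <- matrix(stats::runif(n_ind * ndays), n_ind, ndays)
  for (i in seq_len(n_ind)) {
    hz_harv <- numeric(ndays)
    if (inds$sex[i] == "M" && inds$group[i] == "high") {
      hunted <- dates >= opening
      pr <- realized_pressure[paste(inds$site[i], dates)]
      pr[is.na(pr)] <- 0
      hz_harv[hunted] <- truth$harvest_hazard_coef * pr[hunted]
    }
    total <- truth$natural_hazard + hz_harv + truth$collar_loss_rate
    hit <- which(U[i, ] < total)
    if (length(hit)) {
      t <- hit[1]
      u <- U[i, t]
      death_day[i] <- t
      cause[i] <- if (u < truth$natural_hazard) "natural"
        else if (u < truth$natural_hazard + hz_harv[t]) "harvest"
        else "censor"
    }
  }
  fates <- data.frame(
    individual = inds$individual, sex = inds$sex, group = inds$group,
    site = inds$site,
    alive_at_onset = is.na(death_day) | dates[death_day] >= opening,
    death_date = as.Date(ifelse(is.na(death_day), NA,
                                as.character(dates[death_day]))),
    cause = ifelse(is.na(cause), "survived", cause),
    stringsAsFactors = FALSE)

  ## ---- relocation sampling: 3-7 tracking days per week, one type each
  types <- c("foraging", "loafing", "roosting")
  relocs <- list()
  week_of <- as.integer(as.numeric(dates - start) %/% 7)
  for (i in seq_len(n_ind)) {
    last_day <- if (is.na(death_day[i])) ndays else death_day[i] - 1
    if (last_day < 1) next
    picked <- integer(0)
    for (w in unique(week_of)) {
      wdays <- which(week_of == w & seq_len(ndays) <= last_day)
      if (length(wdays) == 0) next
      k <- sample(seq(truth$tracking_days_range[1],
                      truth$tracking_days_range[2]), 1)
      picked <- c(picked, sort(sample(wdays, min(k, length(wdays)))))
    }
    if (length(picked) == 0) next
    np <- length(picked)
    ty <- sample(types, np, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    ell <- ifelse(ty == "roosting", stats::runif(np, 100, 900),
                  stats::runif(np, 200, 1800))
    relocs[[length(relocs) + 1]] <- data.frame(
      individual = inds$individual[i], sex = inds$sex[i],
      group = inds$group[i], site = inds$site[i], date = dates[picked],
      type = ty,
      x = pos[i, picked, 1] + stats::rnorm(np, 0, truth$loc_error_sd),
      y = pos[i, picked, 2] + stats::rnorm(np, 0, truth$loc_error_sd),
      ellipse_area = ell, source = "triangulated",
      stringsAsFactors = FALSE)
  }
  relocations <- do.call(rbind, relocs)
  rownames(relocations) <- NULL

  ## ---- raw bearing sets for a subsample of fixes
  nb <- min(truth$n_bearing_sets, nrow(relocations))
  bsel <- sort(sample(nrow(relocations), nb))
  bearing_rows <- list()
  for (j in seq_along(bsel)) {
    r <- relocations[bsel[j], , drop = FALSE]
    nst <- sample(3:4, 1)
    ang <- stats::runif(nst, 0, 2 * pi)
    dist <- stats::runif(nst, 300, 600)
    st <- cbind(r$x + dist * sin(ang), r$y + dist * cos(ang))
    bs <- simulate_bearing_set(c(r$x, r$y), st,
                               kappa = 1 / (truth$bearing_sd * pi / 180)^2)
    bearing_rows[[j]] <- data.frame(
      set_id = sprintf("B%04d", j), individual = r$individual,
      date = r$date, type = r$type, station_x = st[, 1],
      station_y = st[, 2], azimuth = bs$azimuths,
      stringsAsFactors = FALSE)
  }
  bearing_sets <- if (length(bearing_rows)) do.call(rbind, bearing_rows)
    else NULL

  ## ---- vegetation plots at a subsample of roosts, paired non-use 35 m off
  roosts <- relocations[relocations$type == "roosting", , drop = FALSE]
  nv <- min(truth$n_veg_roosts, nrow(roosts))
  veg <- NULL
  if (nv > 0) {
    vsel <- sort(sample(nrow(roosts), nv))
    veg_rows <- list()
    mu_base <- c(warm_grass = 40, cool_grass = 25, bare_ground = 10,
                 litter = 20, litter_depth = 3, visual_obstruction = 2.5)
    sds <- c(10, 8, 5, 8, 1, 0.8)
    for (j in seq_along(vsel)) {
      r <- roosts[vsel[j], , drop = FALSE]
      day <- as.numeric(r$date - start)
      for (use in c("roost", "nonuse")) {
        mu <- mu_base
        if (r$group == "high") {
          mu["warm_grass"] <- mu["warm_grass"] + truth$veg_group_offset
          mu["cool_grass"] <- mu["cool_grass"] - truth$veg_group_offset
        }
        mu["litter"] <- mu["litter"] + truth$veg_date_slope * day
        mu["litter_depth"] <- mu["litter_depth"] +
          truth$veg_date_slope * day / 10
        v <- MASS::mvrnorm(1, mu, diag(sds^2))
        v[1:4] <- pmin(pmax(v[1:4], 0), 100)
        v[5:6] <- pmax(v[5:6], 0)
        veg_rows[[length(veg_rows) + 1]] <- data.frame(
          plot_id = sprintf("V%04d-%s", j, substr(use, 1, 1)), use = use,
          individual = r$individual, site = r$site, group = r$group,
          sex = r$sex, date = r$date, warm_grass = v[[1]],
          cool_grass = v[[2]], bare_ground = v[[3]], litter = v[[4]],
          litter_depth = v[[5]], visual_obstruction = v[[6]],
          stringsAsFactors = FALSE)
      }
    }
    veg <- do.call(rbind, veg_rows)
    rownames(veg) <- NULL
  }

  structure(list(relocations = relocations, bearing_sets = bearing_sets,
                 camera_days = camera_days, sites = sites,
                 vegetation = veg, fates = fates, truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d sites, %d individuals, %d relocations, %d camera-days\n",
    nrow(x$sites), nrow(x$fates), nrow(x$relocations), nrow(x$camera_days)))
  invisible(x)
}

#' Simulate one bearing set around a known location
#'
#' Draws azimuths from each station toward \code{true_point} with von
#' Mises noise of concentration \code{kappa} (Best-Fisher sampler);
#' \code{exact = TRUE} (or infinite kappa) returns the noiseless azimuths.
#'
#' @param true_point length-2 numeric (x, y).
#' @param stations two-column matrix of station coordinates.
#' @param kappa von Mises concentration (radians^-2 scale).
#' @param exact suppress noise entirely.
#' @param seed optional RNG seed.
#' @return list with \code{stations} and \code{azimuths} (degrees
#'   clockwise from north).
#' @export
simulate_bearing_set <- function(true_point, stations, kappa = 400,
                                 exact = FALSE, seed = NULL) {
  stations <- as.matrix(stations)
  if (nrow(stations) < 2) stop("need at least 2 stations")
  dx <- true_point[1] - stations[, 1]
  dy <- true_point[2] - stations[, 2]
  if (any(dx^2 + dy^2 < 1e-12))
    stop("a station coincides with the true point")
  az <- atan2(dx, dy) * 180 / pi %% 360
  az <- az %% 360
  if (!exact && is.finite(kappa)) {
    if (!is.null(seed)) set.seed(seed)
    az <- (az + rvonmises(length(az), kappa) * 180 / pi) %% 360
  }
  list(stations = stations, azimuths = az)
}

# Best & Fisher (1979) rejection sampler, mean direction 0
rvonmises <- function(n, kappa) {
  if (kappa <= 0) return(stats::runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z <- cos(pi * stats::runif(1))
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      u <- stats::runif(1)
      if (c0 * (2 - c0) - u > 0 || log(c0 / u) + 1 - c0 >= 0) {
        out[i] <- sign(stats::runif(1) - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

#' Write a synthetic dataset to a directory
#'
#' Emits \code{relocations.csv}, \code{bearings.csv}, \code{cameras.csv},
#' \code{vegetation.csv}, \code{fates.csv}, \code{sites.geojson} and
#' \code{truth.yaml} (the ground-truth parameters, including the note that
#' the per-photo hunter count model is an assumed Poisson).
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(dataset$relocations, file.path(dir, "relocations.csv"))
  if (!is.null(dataset$bearing_sets))
    write_table_csv(dataset$bearing_sets, file.path(dir, "bearings.csv"))
  write_table_csv(dataset$camera_days, file.path(dir, "cameras.csv"))
  if (!is.null(dataset$vegetation))
    write_table_csv(dataset$vegetation, file.path(dir, "vegetation.csv"))
  write_table_csv(dataset$fates, file.path(dir, "fates.csv"))
  write_sites_geojson(dataset$sites, file.path(dir, "sites.geojson"))
  tr <- dataset$truth
  class(tr) <- NULL
  tr$note <- "per-photo hunter counts are modelled as Poisson (assumption)"
  yaml::write_yaml(tr, file.path(dir, "truth.yaml"))
  invisible(dir)
}
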