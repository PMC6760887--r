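# shared fixtures built in code

# minimal relocation table: one individual, evenly spaced dates
make_relocs <- function(n, individual = "F-H-001", sex = "F",
                        group = "high", site = "S01",
                        start = as.Date("2012-10-01"), by = 2,
                        x = NULL, y = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(x)) x <- rnorm(n, 0, 150)
  if (is.null(y)) y <- rnorm(n, 0, 150)
  data.frame(individual = individual, sex = sex, group = group,
             site = site, date = start + by * (seq_len(n) - 1),
             type = "loafing", x = x, y = y, ellipse_area = 500,
             source = "triangulated", stringsAsFactors = FALSE)
}

# negative von Mises log-likelihood (up to kappa) for the triangulation
# grid-search oracle: independent of the package's estimator internals
bearing_nll <- function(z, stations, azimuths_deg) {
  az <- (azimuths_deg %% 360) * pi / 180
  dx <- z[1] - stations[, 1]
  dy <- z[2] - stations[, 2]
  sum(1 - cos(az - atan2(dx, dy)))
}

grid_search_fix <- function(stations, azimuths_deg, center, half = 60,
                            step = 1) {
  gx <- seq(center[1] - half, center[1] + half, by = step)
  gy <- seq(center[2] - half, center[2] + half, by = step)
  best <- c(NA, NA); bestv <- Inf
  for (x in gx) {
    vals <- vapply(gy, function(y)
      bearing_nll(c(x, y), stations, azimuths_deg), numeric(1))
    j <- which.min(vals)
    if (vals[j] < bestv) { bestv <- vals[j]; best <- c(x, gy[j]) }
  }
  best
}

# tiny camera table builder
make_cameras <- function(sites, dates, n_photos, n_hunters) {
  data.frame(site = sites, date = as.Date(dates), n_photos = n_photos,
             n_hunters = n_hunters, stringsAsFactors = FALSE)
}
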