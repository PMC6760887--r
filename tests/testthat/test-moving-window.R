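test_that("window counts follow max(0, n - 10)", {
  expect_equal(nrow(build_windows(make_relocs(11), n_cells = 40)), 1)
  expect_equal(nrow(build_windows(make_relocs(10), n_cells = 40)), 0)
  expect_equal(nrow(build_windows(make_relocs(25), n_cells = 40)), 15)
  # population total is the sum over individuals, windows consecutive
  set.seed(8)
  sizes <- sample(5:30, 6)
  r <- do.call(rbind, lapply(seq_along(sizes), function(i)
    make_relocs(sizes[i], individual = paste0("id", i), seed = i)))
  w <- build_windows(r, n_cells = 40)
  expect_equal(nrow(w), sum(pmax(0, sizes - 10)))
  for (id in unique(w$individual)) {
    wi <- w$window[w$individual == id]
    expect_equal(wi, seq(min(wi), max(wi)))
  }
  expect_true(all(w$window_length >= 0))
})

test_that("windows carry dates and per-window bandwidths", {
  r <- make_relocs(15, by = 2)
  w <- build_windows(r, n_cells = 60)
  expect_equal(w$window_length, rep(20, 5))   # 11 fixes, 2-day spacing
  expect_equal(w$first_date[1], r$date[1])
  expect_equal(w$median_date[1], r$date[6])
  expect_true(all(diff(w$h) != 0) || length(unique(w$h)) > 1)
})

sim_sites <- function() {
  data.frame(
    site = c("H1", "L1", "L2"), group = c("high", "low", "low"),
    area_ha = c(100, 100, 100),
    polygon = I(list(
      list(cbind(c(-1000, 1000, 1000, -1000, -1000),
                 c(-1000, -1000, 1000, 1000, -1000))),
      list(cbind(c(9000, 11000, 11000, 9000, 9000),
                 c(-1000, -1000, 1000, 1000, -1000))),
      list(cbind(c(9000, 11000, 11000, 9000, 9000),
                 c(9000, 9000, 11000, 11000, 9000))))),
    stringsAsFactors = FALSE)
}

sim_pressure <- function(vals_h, vals_l, dates) {
  rbind(
    data.frame(site = "H1", date = dates, season = "early",
               pressure = vals_h),
    data.frame(site = "L1", date = dates, season = "early",
               pressure = vals_l),
    data.frame(site = "L2", date = dates, season = "early",
               pressure = vals_l * 3))
}

test_that("pressure attribution respects site, date range and offsite rule", {
  sites <- sim_sites()
  r <- make_relocs(11, start = as.Date("2012-11-01"), by = 1)   # inside H1
  w <- build_windows(r, n_cells = 40, sites = sites)
  expect_equal(w$assigned_site, "H1")
  dates <- seq(as.Date("2012-10-27"), as.Date("2012-12-01"), by = "day")
  pr <- sim_pressure(0.02, 0.004, dates)
  w1 <- assign_site_and_pressure(w, sites, pr)
  expect_equal(w1$pressure, 0.02)
  # editing pressures outside the window's date range changes nothing
  pr2 <- pr
  out_range <- pr2$date > max(r$date) | pr2$date < min(r$date)
  pr2$pressure[out_range] <- 99
  w2 <- assign_site_and_pressure(w, sites, pr2)
  expect_equal(w2$pressure, w1$pressure)
  # a window near no site falls back to the low-risk mean (L1, L2)
  r_off <- make_relocs(11, start = as.Date("2012-11-01"), by = 1)
  r_off$x <- r_off$x + 50000
  w_off <- build_windows(r_off, n_cells = 40, sites = sites)
  expect_equal(w_off$assigned_site, "offsite")
  w_off <- assign_site_and_pressure(w_off, sites, pr)
  expect_equal(w_off$pressure, mean(c(0.004, 0.012)))
  # constant sitewide pressure is recovered regardless of geometry
  pr_c <- sim_pressure(0.007, 0.007, dates)
  pr_c$pressure <- 0.007
  expect_equal(assign_site_and_pressure(w, sites, pr_c)$pressure, 0.007)
  # days before the opening contribute zero pressure by definition
  r_pre <- make_relocs(11, start = as.Date("2012-10-22"), by = 1)
  w_pre <- build_windows(r_pre, n_cells = 40, sites = sites)
  w_pre <- assign_site_and_pressure(w_pre, sites, pr)
  n_days <- 11
  n_open <- sum(seq(r_pre$date[1], r_pre$date[11], by = "day") >=
                  as.Date("2012-10-27"))
  expect_equal(w_pre$pressure, 0.02 * n_open / n_days)
})

test_that("steps pair successive windows with the previous pressure", {
  sites <- sim_sites()
  r <- make_relocs(14, start = as.Date("2012-11-01"), by = 1)
  w <- build_windows(r, n_cells = 60, sites = sites)
  dates <- seq(as.Date("2012-10-27"), as.Date("2012-12-01"), by = "day")
  w <- assign_site_and_pressure(w, sites, sim_pressure(0.02, 0.004, dates))
  st <- window_steps(w)
  expect_equal(nrow(st), nrow(w) - 1)             # k windows, k-1 steps
  expect_equal(st$prev_pressure, w$pressure[-nrow(w)])
  expect_equal(st$from_window, w$window[-nrow(w)])
  # consecutive windows share 10 of 11 fixes: centers barely move
  expect_true(all(st$distance < 100))
})

test_that("an abrupt center jump is localized by the step distances", {
  x <- c(rnorm(15, 0, 60), rnorm(15, 2000, 60))
  y <- c(rnorm(15, 0, 60), rnorm(15, 0, 60))
  r <- make_relocs(30, x = x, y = y, seed = 4)
  w <- build_windows(r, n_cells = 60)
  st <- window_steps(w)
  # the largest steps occur while the window straddles the jump
  peak <- st$from_window[which.max(st$distance)]
  expect_true(peak >= 11 && peak <= 20)
  expect_gt(max(st$distance), 10 * median(st$distance))
})
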