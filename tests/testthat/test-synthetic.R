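test_that("truth validation rejects impossible parameters", {
  expect_error(simulation_truth(range_inflation = 0.8), "range_inflation")
  expect_error(simulation_truth(natural_hazard = -0.1), "non-negative")
  expect_error(simulation_truth(n_per_sex_group = 0), "individual")
  expect_error(simulation_truth(n_sites_per_group = 0), "site")
  expect_error(simulation_truth(site_area_range = c(100, 50)),
               "site_area_range")
})

test_that("identical truth yields byte-identical datasets", {
  tr <- simulation_truth(n_per_sex_group = 3, n_bearing_sets = 10,
                         n_veg_roosts = 15, seed = 77)
  d1 <- simulate_dataset(tr)
  d2 <- simulate_dataset(tr)
  expect_identical(d1$relocations, d2$relocations)
  expect_identical(d1$camera_days, d2$camera_days)
  expect_identical(d1$fates, d2$fates)
  expect_identical(d1$vegetation, d2$vegetation)
  expect_identical(d1$bearing_sets, d2$bearing_sets)
})

test_that("the dataset satisfies its structural invariants", {
  tr <- simulation_truth(n_per_sex_group = 6, seed = 13)
  ds <- simulate_dataset(tr)
  r <- ds$relocations
  f <- ds$fates
  expect_true(all(r$individual %in% f$individual))
  # no relocations on or after an individual's death date
  dd <- f$death_date[match(r$individual, f$individual)]
  expect_true(all(is.na(dd) | r$date < dd))
  # dates within the study window
  expect_true(all(r$date >= as.Date("2012-10-01") &
                    r$date <= as.Date("2012-12-15")))
  # site areas within the stated range
  expect_true(all(ds$sites$area_ha >= 29 & ds$sites$area_ha <= 155))
  expect_equal(nrow(ds$sites), 10)
  # harvest deaths only among high-risk males
  h <- f[f$cause == "harvest", ]
  expect_true(all(h$sex == "M" & h$group == "high"))
  # 3-7 tracking days per full week
  cnt <- table(r$individual, as.integer(as.numeric(
    r$date - as.Date("2012-10-01")) %/% 7))
  full_weeks <- as.character(0:9)
  surv <- f$individual[f$cause == "survived"]
  expect_true(all(cnt[surv, full_weeks] >= 3 & cnt[surv, full_weeks] <= 7))
})

test_that("null-effect truths produce no group differences beyond noise", {
  tr <- simulation_truth(n_per_sex_group = 8, range_inflation = 1,
                         shift_distance = 0, seed = 23)
  ds <- simulate_dataset(tr)
  hr <- seasonal_home_ranges(ds$relocations, n_cells = 60)
  m <- aggregate(log(area95_ha) ~ group + season, hr, mean)
  spread <- max(m[[3]]) - min(m[[3]])
  expect_lt(spread, 0.5)   # sampling noise only, no systematic expansion
})

test_that("zero low-risk hunter rate gives all-zero low-risk counts", {
  tr <- simulation_truth(n_per_sex_group = 2, hunter_rate_low = 0,
                         n_bearing_sets = 0, n_veg_roosts = 0, seed = 3)
  ds <- simulate_dataset(tr)
  grp <- ds$sites$group[match(ds$camera_days$site, ds$sites$site)]
  expect_true(all(ds$camera_days$n_hunters[grp == "low"] == 0))
  expect_true(any(ds$camera_days$n_hunters[grp == "high"] > 0))
})

test_that("early high-risk pressure exceeds low-risk across replicates", {
  diffs <- vapply(1:25, function(i) {
    tr <- simulation_truth(n_per_sex_group = 1, n_bearing_sets = 0,
                           n_veg_roosts = 0, seed = 1000 + i)
    ds <- simulate_dataset(tr)
    pr <- daily_pressure(ds$camera_days, ds$sites)
    e <- pr[pr$season == "early", ]
    mean(e$pressure[e$group == "high"]) - mean(e$pressure[e$group == "low"])
  }, numeric(1))
  expect_gte(mean(diffs > 0), 0.95)
})

test_that("male survival declines as the harvest hazard grows", {
  surv_at <- function(coef, reps = 12) {
    mean(vapply(seq_len(reps), function(i) {
      tr <- simulation_truth(n_per_sex_group = 10, n_bearing_sets = 0,
                             n_veg_roosts = 0, harvest_hazard_coef = coef,
                             seed = 500 + i)
      ds <- simulate_dataset(tr)
      m <- ds$fates[ds$fates$sex == "M" & ds$fates$group == "high", ]
      mean(m$cause == "survived")
    }, numeric(1)))
  }
  s <- c(surv_at(0), surv_at(6), surv_at(20))
  expect_true(all(diff(s) < 0))
})

test_that("noiseless bearing sets and von Mises noise behave as stated", {
  st <- rbind(c(0, 0), c(1000, 0), c(0, 1000))
  bs <- simulate_bearing_set(c(500, 500), st, exact = TRUE)
  expect_equal(bs$azimuths,
               (atan2(500 - st[, 1], 500 - st[, 2]) * 180 / pi) %% 360)
  expect_error(simulate_bearing_set(c(0, 0), rbind(c(0, 0), c(1, 1)), 10),
               "coincides")
  expect_error(simulate_bearing_set(c(0, 0), rbind(c(1, 1)), 10),
               "2 stations")
  # two stations, no noise: unique line intersection at the true point
  st2 <- rbind(c(-300, 0), c(0, -400))
  bs2 <- simulate_bearing_set(c(120, 80), st2, exact = TRUE)
  fix <- triangulate(st2, bs2$azimuths)
  expect_lt(sqrt(sum((fix$estimate - c(120, 80))^2)), 1e-6)
})

test_that("dataset writing round-trips through the pipeline readers", {
  tr <- simulation_truth(n_per_sex_group = 2, n_bearing_sets = 5,
                         n_veg_roosts = 10, seed = 41)
  ds <- simulate_dataset(tr)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  r <- read_relocations_csv(file.path(dir, "relocations.csv"))
  expect_equal(nrow(r), nrow(ds$relocations))
  expect_equal(r$x, ds$relocations$x, tolerance = 1e-12)
  s <- read_sites_geojson(file.path(dir, "sites.geojson"))
  expect_equal(s$site, ds$sites$site)
  expect_equal(s$area_ha, ds$sites$area_ha, tolerance = 1e-12)
  ty <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(ty$sigma_base, tr$sigma_base)
  expect_match(ty$note, "Poisson")
})
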