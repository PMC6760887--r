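test_that("reference bandwidth follows the closed form", {
  # sd_x = sd_y = 100 exactly, n = 64: h = 100 * 64^(-1/6) = 50
  set.seed(5)
  x <- rnorm(64); x <- (x - mean(x)) / sd(x) * 100
  y <- rnorm(64); y <- (y - mean(y)) / sd(y) * 100
  expect_equal(reference_bandwidth(cbind(x, y)), 50, tolerance = 1e-12)
  # scale equivariance
  expect_equal(reference_bandwidth(cbind(2 * x, 2 * y)), 100,
               tolerance = 1e-12)
  # n = 17 arbitrary sample matches direct evaluation
  set.seed(9)
  xy <- cbind(rnorm(17), rnorm(17, sd = 2))
  expect_equal(reference_bandwidth(xy),
               0.5 * (sd(xy[, 1]) + sd(xy[, 2])) * 17^(-1 / 6))
  expect_error(reference_bandwidth(cbind(rep(1, 5), rep(2, 5))),
               "identical")
  expect_error(reference_bandwidth(cbind(1, 1)), "at least 2")
})

test_that("gridded UD matches the brute-force kernel sum and integrates to 1", {
  set.seed(21)
  xy <- cbind(rnorm(17, 0, 120), rnorm(17, 30, 90))
  h <- reference_bandwidth(xy)
  ud <- kernel_ud(xy, h = h, n_cells = 80)
  expect_equal(sum(ud$density) * ud$cell_size^2, 1, tolerance = 1e-10)
  # pointwise oracle at 10 random nodes, including the grid normalization
  idx <- cbind(sample(length(ud$x), 10), sample(length(ud$y), 10))
  for (k in 1:10) {
    gx <- ud$x[idx[k, 1]]; gy <- ud$y[idx[k, 2]]
    brute <- sum(exp(-((gx - xy[, 1])^2 + (gy - xy[, 2])^2) / (2 * h^2))) /
      (nrow(xy) * 2 * pi * h^2) / ud$raw_integral
    expect_equal(ud$density[idx[k, 1], idx[k, 2]], brute,
                 tolerance = 1e-10)
  }
})

test_that("single-point UD peaks at 1/(2 pi h^2) and mirrors correctly", {
  h <- 50
  ud <- kernel_ud(cbind(300, 200), h = h, n_cells = 101)
  expect_equal(max(ud$density), 1 / (2 * pi * h^2), tolerance = 0.01)
  # a point set symmetric about x = 0 yields a mirror-symmetric field
  # (extent and cell size chosen so the grid itself is symmetric)
  xy <- rbind(c(-150, 30), c(150, 30), c(0, -80), c(0, 110))
  uds <- kernel_ud(xy, h = 40, padding = 120, cell_size = 5)
  expect_equal(uds$density, uds$density[rev(seq_along(uds$x)), ],
               tolerance = 1e-12)
  expect_error(kernel_ud(xy, h = 40, padding = 40), "padding")
})

test_that("isopleths are nested and match the analytic Gaussian disk", {
  h <- 100
  ud <- kernel_ud(cbind(0, 0), h = h, n_cells = 300, padding = 4 * h,
                  cell_size = h / 10)
  a95 <- isopleth(ud, 0.95)
  a50 <- isopleth(ud, 0.50)
  expect_gte(a95$area_ha, a50$area_ha)
  # one Gaussian kernel: area(p) = pi h^2 (-2 ln(1-p))
  expect_equal(a95$area_ha, pi * h^2 * (-2 * log(0.05)) / 1e4,
               tolerance = 0.02)
  expect_equal(a50$area_ha, pi * h^2 * (-2 * log(0.50)) / 1e4,
               tolerance = 0.02)
  expect_equal(unname(a95$centroid), c(0, 0), tolerance = h / 10)
  # two well-separated kernels double the area
  ud2 <- kernel_ud(rbind(c(0, 0), c(5000, 0)), h = h, n_cells = 700,
                   padding = 4 * h)
  expect_equal(isopleth(ud2, 0.95)$area_ha,
               2 * pi * h^2 * (-2 * log(0.05)) / 1e4, tolerance = 0.03)
  # p -> 1 takes essentially all cells with mass
  expect_gt(isopleth(ud, 0.999)$area_ha, a95$area_ha)
})

test_that("area estimates are stable under grid refinement", {
  set.seed(33)
  xy <- cbind(rnorm(15, 0, 150), rnorm(15, 0, 150))
  ud_a <- kernel_ud(xy, n_cells = 100)
  ud_b <- kernel_ud(xy, cell_size = ud_a$cell_size / 2)
  ia <- isopleth(ud_a, 0.95)$area_ha
  ib <- isopleth(ud_b, 0.95)$area_ha
  expect_lt(abs(ia - ib) / ib, 0.02)
})

test_that("seasonal estimator enforces the 10-relocation rule", {
  r9 <- make_relocs(9, start = as.Date("2012-10-02"), by = 2)   # pre only
  r17 <- make_relocs(17, individual = "F-H-002",
                     start = as.Date("2012-10-28"), by = 1)     # early only
  hr <- seasonal_home_ranges(rbind(r9, r17), n_cells = 80)
  expect_false("F-H-001" %in% hr$individual)
  expect_equal(nrow(hr), 1)
  expect_equal(hr$n, 17)
  expect_equal(as.character(hr$season), "early")
  excl <- attr(hr, "excluded")
  expect_true("F-H-001" %in% excl$individual)
  expect_match(excl$reason[1], "fewer than 10")
})

test_that("relocations outside the defined seasons are never used", {
  r <- make_relocs(30, start = as.Date("2012-12-10"), by = 1)
  hr <- seasonal_home_ranges(r, n_cells = 60)
  # only 6 of the 30 dates (10-15 Dec) are in a defined season
  expect_equal(nrow(hr), 0)
})

test_that("seasonal center shifts are plain Euclidean distances", {
  mk <- function(season, cx, cy, id = "b1") {
    start <- switch(season, pre = as.Date("2012-10-02"),
                    early = as.Date("2012-10-28"),
                    late = as.Date("2012-11-25"))
    make_relocs(12, individual = id, start = start, by = 1,
                x = cx + c(-100, 100, 0, -50, 50, -80, 80, -30, 30, 0, -60, 60),
                y = cy + c(0, 0, -100, 50, -50, 30, -30, -80, 80, 100, 20, -20))
  }
  r <- rbind(mk("pre", 0, 0), mk("early", 300, 400), mk("late", 0, 0))
  hr <- seasonal_home_ranges(r, n_cells = 120)
  sh <- seasonal_shifts(hr)
  expect_equal(nrow(sh), 2)
  d_early <- sh$distance[sh$contrast == "pre_early"]
  expect_equal(d_early, 500, tolerance = 0.05)
  expect_lt(sh$distance[sh$contrast == "pre_late"], 50)
  # missing pre-season member drops the pair entirely
  hr2 <- hr[hr$season != "pre", ]
  expect_equal(nrow(seasonal_shifts(hr2)), 0)
})
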