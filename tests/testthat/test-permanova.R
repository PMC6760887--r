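make_veg <- function(n_per_cell = 10, risk_off = 0, date_slope = 0,
                     sex_off = 0, seed = 1, n_seasons = 2) {
  set.seed(seed)
  rows <- list()
  id <- 0
  season_starts <- c(pre = as.Date("2012-10-05"),
                     early = as.Date("2012-10-28"),
                     late = as.Date("2012-11-25"))[seq_len(n_seasons)]
  for (gr in c("high", "low")) for (sx in c("F", "M")) {
    for (i in seq_len(n_per_cell)) {
      id <- id + 1
      ind <- sprintf("%s-%s-%02d", sx, gr, i)
      for (s in seq_along(season_starts)) {
        date <- season_starts[s] + sample(0:15, 1)
        day <- as.numeric(date - as.Date("2012-10-01"))
        mu <- c(40, 25, 10, 20, 3, 2.5)
        if (gr == "high") mu[1] <- mu[1] + risk_off
        if (sx == "M") mu[2] <- mu[2] + sex_off
        mu[4] <- mu[4] + date_slope * day
        v <- mu + rnorm(6, 0, c(8, 6, 4, 6, 0.8, 0.6))
        for (use in c("roost", "nonuse")) {
          rows[[length(rows) + 1]] <- data.frame(
            plot_id = sprintf("V%04d-%s", length(rows), use), use = use,
            individual = ind, site = paste0("S", gr), group = gr,
            sex = sx, date = date, warm_grass = v[1], cool_grass = v[2],
            bare_ground = v[3], litter = v[4], litter_depth = v[5],
            visual_obstruction = v[6], stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

test_that("single-variable Euclidean pseudo-F equals the classical ANOVA F", {
  set.seed(31)
  for (rep in 1:5) {
    d <- data.frame(group = rep(c("a", "b", "c"), each = 7),
                    sex = "F", date = as.Date("2012-11-01"),
                    y = rnorm(21))
    pf <- permanova(d, response_vars = "y", rhs = ~ group,
                    distance = "euclidean_std", n_perm = 99, seed = rep)
    af <- summary(aov(y ~ group, d))[[1]]$`F value`[1]
    expect_equal(pf$F[pf$term == "group"], af, tolerance = 1e-8)
  }
})

test_that("permutation p matches exhaustive enumeration at small n", {
  set.seed(7)
  d <- data.frame(group = rep(c("a", "b"), each = 3), sex = "F",
                  date = as.Date("2012-11-01"), y = c(1.2, 0.4, 0.9,
                                                      2.1, 2.8, 2.3))
  pf <- permanova(d, response_vars = "y", rhs = ~ group,
                  n_perm = 9999, seed = 2)
  # oracle: F over all choose(6,3) = 20 relabelings via classical ANOVA
  f_of <- function(lab) summary(aov(y ~ g, data.frame(y = d$y,
                                                      g = lab)))[[1]]$`F value`[1]
  labs <- combn(6, 3)
  fs <- apply(labs, 2, function(ix) {
    g <- rep("b", 6); g[ix] <- "a"; f_of(g)
  })
  f_obs <- f_of(d$group)
  p_exact <- mean(fs >= f_obs - 1e-12)
  expect_equal(pf$p[pf$term == "group"], p_exact,
               tolerance = 3 / sqrt(9999) / p_exact)
})

test_that("sequential sums of squares decompose the total exactly", {
  v <- make_veg(6, risk_off = 6, date_slope = 0.2, seed = 3)
  pf <- permanova(v[v$use == "roost", ], n_perm = 99, seed = 1)
  tot <- pf$SS[pf$term == "Total"]
  expect_equal(sum(pf$SS[pf$term != "Total"]), tot, tolerance = 1e-8)
  expect_true(all(pf$p > 0, na.rm = TRUE))       # the +1 convention
  expect_true(all(pf$R2 >= 0 & pf$R2 <= 1, na.rm = TRUE))
  expect_error(permanova(transform(v, warm_grass = 1, cool_grass = 1,
                                   bare_ground = 1, litter = 1,
                                   litter_depth = 1,
                                   visual_obstruction = 1)),
               "constant")
})

test_that("null permutation test holds its nominal size", {
  set.seed(17)
  reject <- vapply(1:200, function(i) {
    d <- data.frame(group = rep(c("a", "b"), each = 10), sex = "F",
                    date = as.Date("2012-11-01"),
                    y1 = rnorm(20), y2 = rnorm(20))
    pf <- permanova(d, response_vars = c("y1", "y2"), rhs = ~ group,
                    n_perm = 199, seed = i)
    pf$p[pf$term == "group"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(reject) - 0.05), 0.045)
})

test_that("degenerate subsampling collapses the bootstrap to a point", {
  v <- make_veg(4, risk_off = 8, seed = 5, n_seasons = 1)
  # exactly one pre-season roost per individual: iterations identical
  b <- subsample_bootstrap(v, "pre", n_iter = 20, n_perm = 199, seed = 3)
  expect_equal(b$F_q2.5, b$F_median)
  expect_equal(b$F_q97.5, b$F_median)
  expect_equal(attr(b, "n_iter"), 20)
  expect_error(subsample_bootstrap(v, "pre", n_iter = 0), "n_iter")
})

test_that("bootstrapped PERMANOVA finds risk and date but not sex effects", {
  v <- make_veg(8, risk_off = 8, date_slope = 0.25, sex_off = 0, seed = 6,
                n_seasons = 3)
  for (m in c("within", "nonuse")) {
    b <- subsample_bootstrap(v, m, n_iter = 40, n_perm = 199, seed = 4)
    expect_true(b$significant[b$term == "group"])
    expect_true(b$significant[b$term == "day"])
    expect_false(b$significant[b$term == "sex"])
    expect_false(b$significant[b$term == "group:sex"])
    expect_true(all(b$F_q2.5 <= b$F_median & b$F_median <= b$F_q97.5))
  }
})

test_that("the subsample bootstrap is reproducible under a fixed seed", {
  v <- make_veg(5, risk_off = 6, seed = 9)
  b1 <- subsample_bootstrap(v, "within", n_iter = 15, n_perm = 99, seed = 8)
  b2 <- subsample_bootstrap(v, "within", n_iter = 15, n_perm = 99, seed = 8)
  expect_identical(b1, b2)
})
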