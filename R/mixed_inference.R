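#' Fit a Gaussian linear mixed model (point fit)
#'
#' Thin wrapper around \code{lme4::lmer} (REML) that returns the pieces the
#' posterior-simulation step needs: fixed-effect estimates, their
#' covariance, the residual SD and degrees of freedom, and the variance
#' components. The fixed-effect design is checked for aliasing before
#' fitting and rejected with the offending columns named.
#'
#' @param formula an \code{lmer} formula (response, fixed terms, random
#'   intercepts such as \code{(1 | site)}).
#' @param data model data frame.
#' @param transform \code{"identity"} or \code{"log"} (natural log applied
#'   to the response before fitting; non-positive responses are rejected).
#' @return object of class \code{riskspace_fit}: list with
#'   \code{coefficients}, \code{vcov}, \code{sigma}, \code{df_residual},
#'   \code{varcomp}, \code{n_obs}, \code{terms}, \code{xlevels},
#'   \code{contrasts}, \code{formula}.
#' @export
fit_lmm <- function(formula, data, transform = c("identity", "log")) {
  transform <- match.arg(transform)
  data <- as.data.frame(data)
  resp_name <- deparse(formula[[2]])
  if (transform == "log") {
    y <- data[[resp_name]]
    if (any(!is.finite(y)) || any(y <= 0))
      stop("log transform requires strictly positive response values")
    data[[resp_name]] <- log(y)
  }
  # aliasing check on the fixed-effect design
  fixed_form <- lme4::nobars(formula)
  mf <- stats::model.frame(fixed_form, data)
  X <- stats::model.matrix(fixed_form, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("aliased fixed-effect term(s): ", paste(bad, collapse = ", "))
  }
  fit <- lme4::lmer(formula, data = data, REML = TRUE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
  beta <- lme4::fixef(fit)
  # degenerate fits (e.g. an exactly constant response) can break the
  # sparse vcov path; the fixed-design form is exact when all variance
  # components vanish
  V <- tryCatch(as.matrix(stats::vcov(fit)), error = function(e) {
    stats::sigma(fit)^2 * solve(crossprod(X))
  })
  vc <- as.data.frame(lme4::VarCorr(fit))
  n <- stats::nobs(fit)
  structure(list(
    coefficients = beta, vcov = V, sigma = stats::sigma(fit),
    df_residual = n - length(beta),
    varcomp = vc[, c("grp", "sdcor")], n_obs = n,
    terms = stats::delete.response(stats::terms(mf)),
    xlevels = stats::.getXlevels(stats::terms(mf), mf),
    contrasts = attr(X, "contrasts"), formula = formula,
    transform = transform, lmer_fit = fit),
    class = "riskspace_fit")
}

#' Posterior simulation for a fitted mixed model
#'
#' Draws fixed-effect vectors from the approximate joint posterior of the
#' model parameters under non-informative priors: for each draw the
#' residual variance is drawn from its scaled inverse-chi-square
#' conditional, and the coefficient vector from a multivariate normal
#' centered at the REML estimates with covariance rescaled by that draw.
#' 95% credible intervals are the 2.5% and 97.5% quantiles of the draws; a
#' coefficient is flagged significant when its interval excludes zero.
#'
#' @param fit a \code{riskspace_fit} from \code{\link{fit_lmm}}.
#' @param n_draws number of posterior draws (default 5000).
#' @param seed optional RNG seed for reproducible intervals.
#' @return \code{fit} with added \code{draws} (n_draws x p matrix) and
#'   \code{summary} data frame (term, estimate, mean, q2.5, q97.5,
#'   significant).
#' @export
simulate_posterior <- function(fit, n_draws = 5000, seed = NULL) {
  stopifnot(inherits(fit, "riskspace_fit"))
  if (!is.null(seed)) set.seed(seed)
  beta <- fit$coefficients
  V <- fit$vcov
  p <- length(beta)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("fixed-effect covariance is not positive semidefinite")
  df <- fit$df_residual
  s2 <- fit$sigma^2
  sigma2_draw <- s2 * df / stats::rchisq(n_draws, df)
  Z <- matrix(stats::rnorm(n_draws * p), n_draws, p)
  R <- chol(V + diag(1e-12 * max(diag(V)), p))
  draws <- sweep(Z %*% R, 1, sqrt(sigma2_draw / s2), `*`)
  draws <- sweep(draws, 2, beta, `+`)
  colnames(draws) <- names(beta)
  q <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975))
  smry <- data.frame(
    term = names(beta), estimate = unname(beta),
    mean = colMeans(draws), q2.5 = q[1, ], q97.5 = q[2, ],
    significant = q[1, ] > 0 | q[2, ] < 0,
    row.names = NULL, stringsAsFactors = FALSE)
  fit$draws <- draws
  fit$n_draws <- n_draws
  fit$summary <- smry
  fit
}

#' @export
print.riskspace_fit <- function(x, ...) {
  cat("Gaussian LMM fit:", deparse(x$formula), "\n")
  if (!is.null(x$summary)) {
    s <- x$summary
    s$sig <- ifelse(s$significant, "*", "")
    print(s, digits = 3)
  } else {
    print(x$coefficients, digits = 3)
  }
  invisible(x)
}

#' Posterior contrasts of factor-cell means
#'
#' Computes, per posterior draw, the model-predicted mean for each
#' requested cell of the fixed-effect design (a row of covariate values),
#' then the difference between pairs of cells. A pair is flagged
#' \code{different} when the 95% interval of the difference excludes zero.
#'
#' @param fit a \code{riskspace_fit} carrying posterior \code{draws}.
#' @param cells data frame of covariate values, one row per cell; row
#'   names label the cells. Every fixed-effect variable must be present.
#' @param pairs optional 2-column matrix/data frame of cell-label pairs;
#'   default all unordered pairs.
#' @return data frame with \code{cell_a}, \code{cell_b}, \code{mean_diff},
#'   \code{q2.5}, \code{q97.5}, \code{different}.
#' @export
group_contrasts <- function(fit, cells, pairs = NULL) {
  stopifnot(inherits(fit, "riskspace_fit"))
  if (is.null(fit$draws)) stop("run simulate_posterior() first")
  vars <- all.vars(fit$terms)
  missing_vars <- setdiff(vars, names(cells))
  if (length(missing_vars))
    stop("cells lack model term(s): ", paste(missing_vars, collapse = ", "))
  for (v in names(fit$xlevels))
    cells[[v]] <- factor(cells[[v]], levels = fit$xlevels[[v]])
  X <- stats::model.matrix(fit$terms, cells, contrasts.arg = fit$contrasts)
  cellmeans <- fit$draws %*% t(X)   # n_draws x n_cells
  labels <- rownames(cells)
  if (is.null(labels)) labels <- paste0("cell", seq_len(nrow(cells)))
  colnames(cellmeans) <- labels
  if (is.null(pairs)) {
    cmb <- utils::combn(labels, 2)
    pairs <- data.frame(a = cmb[1, ], b = cmb[2, ])
  }
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- as.character(pairs[i, 1]); b <- as.character(pairs[i, 2])
    d <- cellmeans[, a] - cellmeans[, b]
    q <- stats::quantile(d, c(0.025, 0.975))
    data.frame(cell_a = a, cell_b = b, mean_diff = mean(d),
               q2.5 = q[[1]], q97.5 = q[[2]],
               different = q[[1]] > 0 | q[[2]] < 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "cell_draws") <- cellmeans
  res
}

#' Fit the full suite of space-use mixed models
#'
#' Fits the six space-use models of the analysis, each with study site and
#' individual as random intercepts and posterior-simulation inference:
#' \itemize{
#'   \item per-sex seasonal home-range size: \code{log(area95) ~ group *
#'     season (+ year)} (reference: low risk, pre season);
#'   \item per-sex seasonal center shift: \code{log(distance) ~ group *
#'     contrast (+ year)};
#'   \item moving-window size: \code{log(area95) ~ log(pressure + offset) +
#'     sex + median season day + window length (+ year)} (reference:
#'     female);
#'   \item moving-window step: same structure with step distance as the
#'     response and the previous window's pressure.
#' }
#' A year fixed effect is included only when more than one cohort year is
#' present. Models whose data are empty after filtering are skipped with a
#' message.
#'
#' @param home_ranges output of \code{\link{seasonal_home_ranges}} with
#'   \code{sex}, \code{site}, \code{group} columns.
#' @param shifts output of \code{\link{seasonal_shifts}}.
#' @param windows output of \code{\link{assign_site_and_pressure}}.
#' @param steps output of \code{\link{window_steps}}.
#' @param n_draws posterior draws per model.
#' @param seed RNG seed.
#' @param pressure_offset additive offset inside the log of hunting
#'   pressure (default 0.001), needed because pre-season pressure is zero.
#' @return named list of \code{riskspace_fit} objects
#'   (\code{size_female}, \code{size_male}, \code{shift_female},
#'   \code{shift_male}, \code{window_size}, \code{window_step}); skipped
#'   models are absent.
#' @export
space_use_model_suite <- function(home_ranges, shifts, windows, steps,
                                  n_draws = 5000, seed = NULL,
                                  pressure_offset = 0.001) {
  if (!is.null(seed)) set.seed(seed)
  fits <- list()

  prep_hr <- function(d) {
    d <- d[!is.na(d$area95_ha) & d$area95_ha > 0, , drop = FALSE]
    d$group <- factor(as.character(d$group), levels = c("low", "high"))
    d$log_area <- log(d$area95_ha)
    d
  }
  add_year <- function(form, d) {
    if (length(unique(d$year)) > 1) {
      d$year <- factor(d$year)
      form <- stats::update(form, . ~ . + year)
    }
    list(form = form, d = d)
  }
  try_fit <- function(name, form, d) {
    if (nrow(d) == 0) { message("model ", name, " skipped: no data"); return() }
    f <- tryCatch(fit_lmm(form, d), error = function(e) {
      message("model ", name, " skipped: ", conditionMessage(e)); NULL })
    if (!is.null(f))
      fits[[name]] <<- simulate_posterior(f, n_draws = n_draws)
  }

  for (sx in c("F", "M")) {
    nm <- if (sx == "F") "female" else "male"
    d <- prep_hr(home_ranges[home_ranges$sex == sx, , drop = FALSE])
    if (nrow(d)) {
      d$season <- factor(as.character(d$season),
                         levels = c("pre", "early", "late"))
      a <- add_year(log_area ~ group * season + (1 | site) +
                      (1 | individual), d)
      try_fit(paste0("size_", nm), a$form, a$d)
    }
    s <- shifts[shifts$sex == sx & is.finite(shifts$distance) &
                  shifts$distance > 0, , drop = FALSE]
    if (nrow(s)) {
      s$group <- factor(as.character(s$group), levels = c("low", "high"))
      s$contrast <- factor(as.character(s$contrast),
                           levels = c("pre_early", "pre_late"))
      s$log_dist <- log(s$distance)
      a <- add_year(log_dist ~ group * contrast + (1 | site) +
                      (1 | individual), s)
      try_fit(paste0("shift_", nm), a$form, a$d)
    }
  }

  prep_w <- function(w, pcol) {
    if (!"site" %in% names(w) && "assigned_site" %in% names(w))
      w$site <- w$assigned_site
    w <- w[is.finite(w[[pcol]]), , drop = FALSE]
    w$sex <- factor(as.character(w$sex), levels = c("F", "M"))
    w$log_pressure <- log(w[[pcol]] + pressure_offset)
    w$median_day <- as.numeric(as.Date(w$median_date) -
                                 as.Date(sprintf("%d-10-01", w$year)))
    w
  }
  if (nrow(windows)) {
    w <- prep_w(windows, "pressure")
    w <- w[is.finite(w$area95_ha) & w$area95_ha > 0, , drop = FALSE]
    w$log_area <- log(w$area95_ha)
    a <- add_year(log_area ~ log_pressure + sex + median_day +
                    window_length + (1 | site) + (1 | individual), w)
    try_fit("window_size", a$form, a$d)
  }
  if (nrow(steps)) {
    s <- prep_w(steps, "prev_pressure")
    s <- s[is.finite(s$distance) & s$distance > 0, , drop = FALSE]
    s$log_dist <- log(s$distance)
    a <- add_year(log_dist ~ log_pressure + sex + median_day +
                    window_length + (1 | site) + (1 | individual), s)
    try_fit("window_step", a$form, a$d)
  }
  fits
}

#' Coefficient table across a suite of fits
#'
#' @param fits named list of \code{riskspace_fit} objects with posterior
#'   summaries.
#' @return one data frame with a \code{model} column.
#' @export
coef_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    s <- fits[[nm]]$summary
    if (is.null(s)) return(NULL)
    cbind(model = nm, s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
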