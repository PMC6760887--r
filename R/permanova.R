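#' PERMANOVA of roost-vegetation characteristics
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (sequential, order-of-entry sums of squares; pseudo-F against the
#' full-model residual; permutation p-values with the +1 convention, so p
#' is never exactly zero). The heavy lifting is done by
#' \code{vegan::adonis2}, the reference adonis implementation; this
#' wrapper fixes the response columns, the distance convention and the
#' term order used throughout the roost analysis.
#'
#' The default distance is Euclidean on column-standardized variables
#' (the six vegetation measures mix percentages, centimeters and an
#' obstruction score); Bray-Curtis on the raw non-negative values is
#' available as an alternative.
#'
#' @param samples data frame of vegetation plots with \code{group},
#'   \code{sex}, \code{date} and the response columns.
#' @param response_vars response column names (default the six vegetation
#'   measures).
#' @param rhs model right-hand side; default
#'   \code{~ group + sex + group:sex + day} -- the order of entry is the
#'   order tested.
#' @param distance \code{"euclidean_std"} or \code{"bray"}.
#' @param n_perm number of permutations (default 999), free permutation of
#'   rows.
#' @param seed optional RNG seed.
#' @return data frame of class \code{permanova_result}: one row per term
#'   plus Residual and Total, with \code{df}, \code{SS}, \code{R2},
#'   \code{F}, \code{p}.
#' @export
permanova <- function(samples,
                      response_vars = c("warm_grass", "cool_grass",
                                        "bare_ground", "litter",
                                        "litter_depth",
                                        "visual_obstruction"),
                      rhs = ~ group + sex + group:sex + day,
                      distance = c("euclidean_std", "bray"),
                      n_perm = 999, seed = NULL) {
  distance <- match.arg(distance)
  stopifnot(all(response_vars %in% names(samples)))
  Y <- as.matrix(samples[, response_vars, drop = FALSE])
  if (nrow(Y) < 3) stop("too few samples")
  if (all(apply(Y, 2, stats::var) == 0))
    stop("constant response matrix: zero total sum of squares")
  samples$day <- as.numeric(as.Date(samples$date) -
                              min(as.Date(samples$date)))
  d <- if (distance == "euclidean_std") {
    keep <- apply(Y, 2, stats::var) > 0
    stats::dist(scale(Y[, keep, drop = FALSE]))
  } else {
    if (any(Y < 0)) stop("Bray-Curtis needs non-negative values")
    vegan::vegdist(Y, method = "bray")
  }
  if (!is.null(seed)) set.seed(seed)
  form <- stats::as.formula(paste("d", paste(deparse(rhs), collapse = "")))
  res <- vegan::adonis2(form, data = samples, permutations = n_perm,
                        by = "terms")
  out <- data.frame(term = rownames(res), df = res$Df, SS = res$SumOfSqs,
                    R2 = res$R2, F = res$F, p = res$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' Subsample-bootstrapped PERMANOVA for roost vegetation
#'
#' Roosts are sampled unevenly across individuals, so a single PERMANOVA
#' would violate independence. This procedure draws one plot per
#' individual per season uniformly at random, runs the PERMANOVA, and
#' repeats \code{n_iter} times with a fresh subsample; per term it reports
#' the median pseudo-F with 2.5%/97.5% bounds and the median p-value with
#' bounds. A term is accepted as significant when its median p-value is
#' below 0.05.
#'
#' Three model datasets are supported: \code{"pre"} (roost plots used
#' before the season opening), \code{"within"} (roost plots used during
#' the season) and \code{"nonuse"} (paired non-use plots, all seasons).
#'
#' @param vegetation vegetation plot table (see
#'   \code{\link{read_vegetation_csv}}).
#' @param model \code{"pre"}, \code{"within"} or \code{"nonuse"}.
#' @param n_iter bootstrap iterations (default 1000).
#' @param n_perm permutations per inner test (default 999).
#' @param seed RNG seed.
#' @param ... passed to \code{\link{permanova}}.
#' @return data frame of class \code{boot_permanova}: per term,
#'   \code{F_median}, \code{F_q2.5}, \code{F_q97.5}, \code{p_median},
#'   \code{p_q2.5}, \code{p_q97.5}, \code{significant}; attributes
#'   \code{model}, \code{n_iter}, \code{n_samples}.
#' @export
subsample_bootstrap <- function(vegetation, model = c("pre", "within",
                                                      "nonuse"),
                                n_iter = 1000, n_perm = 999, seed = NULL,
                                ...) {
  model <- match.arg(model)
  if (n_iter < 1) stop("n_iter must be at least 1")
  v <- vegetation
  v$date <- as.Date(v$date)
  v$season <- classify_season(v$date)
  v <- switch(model,
    pre = v[v$use == "roost" & v$season == "pre", , drop = FALSE],
    within = v[v$use == "roost" & v$season %in% c("early", "late"), ,
               drop = FALSE],
    nonuse = v[v$use == "nonuse", , drop = FALSE])
  if (nrow(v) < 6) stop("too few plots for model '", model, "'")
  if (!is.null(seed)) set.seed(seed)
  cell <- interaction(v$individual, v$season, drop = TRUE)
  cells <- split(seq_len(nrow(v)), cell)
  res_F <- list(); res_p <- list()
  n_sub <- NA_integer_
  for (it in seq_len(n_iter)) {
    pick <- vapply(cells, function(ix)
      if (length(ix) == 1) ix else sample(ix, 1), integer(1))
    sub <- v[pick, , drop = FALSE]
    n_sub <- nrow(sub)
    pr <- permanova(sub, n_perm = n_perm, ...)
    terms <- pr$term[!pr$term %in% c("Residual", "Total")]
    res_F[[it]] <- stats::setNames(pr$F[match(terms, pr$term)], terms)
    res_p[[it]] <- stats::setNames(pr$p[match(terms, pr$term)], terms)
  }
  Fm <- do.call(rbind, res_F)
  Pm <- do.call(rbind, res_p)
  qs <- function(x, p) as.numeric(stats::quantile(x, p, na.rm = TRUE))
  out <- data.frame(
    term = colnames(Fm),
    F_median = apply(Fm, 2, stats::median, na.rm = TRUE),
    F_q2.5 = apply(Fm, 2, qs, 0.025),
    F_q97.5 = apply(Fm, 2, qs, 0.975),
    p_median = apply(Pm, 2, stats::median, na.rm = TRUE),
    p_q2.5 = apply(Pm, 2, qs, 0.025),
    p_q97.5 = apply(Pm, 2, qs, 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
  out$significant <- out$p_median < 0.05
  attr(out, "model") <- model
  attr(out, "n_iter") <- n_iter
  attr(out, "n_samples") <- n_sub
  class(out) <- c("boot_permanova", "data.frame")
  out
}
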