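#' Maximum-likelihood triangulation of a bearing set
#'
#' Estimates a transmitter location from two or more azimuths taken at
#' known stations, by maximizing a von Mises bearing-error likelihood (the
#' Lenth estimator family). Azimuths are degrees clockwise from geographic
#' north; coordinates are planar meters. The estimate is initialized at the
#' least-squares intersection of the bearing lines and refined by damped
#' Newton iteration; the covariance of the estimate is the inverse observed
#' information, and the error-ellipse area is that of the 95% confidence
#' ellipse,
#' \deqn{A = \pi \sqrt{\det \Sigma}\; \chi^2_{2,0.95}.}
#'
#' @param stations two-column matrix of station coordinates (meters), one
#'   row per bearing.
#' @param azimuths bearing azimuths in degrees clockwise from north, one
#'   per station.
#' @param bearing_sd assumed bearing error SD in degrees (default 3); the
#'   von Mises concentration is \code{1/sd^2} in radians.
#' @param conf confidence level of the error ellipse (default 0.95).
#' @param tol convergence tolerance on the Newton step (meters).
#' @param max_iter maximum Newton iterations.
#' @return list of class \code{triangulation}: \code{estimate} (x, y),
#'   \code{covariance} (2x2, m^2), \code{ellipse_area} (m^2),
#'   \code{n_bearings}, \code{converged}.
#' @export
triangulate <- function(stations, azimuths, bearing_sd = 3, conf = 0.95,
                        tol = 1e-8, max_iter = 100) {
  stations <- as.matrix(stations)
  m <- nrow(stations)
  if (m < 2 || length(azimuths) != m)
    stop("need at least 2 bearings, one azimuth per station")
  az <- azimuths %% 360 * pi / 180
  fail <- list(estimate = c(NA_real_, NA_real_),
               covariance = matrix(NA_real_, 2, 2),
               ellipse_area = NA_real_, n_bearings = m, converged = FALSE)
  class(fail) <- "triangulation"

  # least-squares start: bearing line i is {P : n_i . P = n_i . S_i},
  # n_i = (cos az_i, -sin az_i) the left normal of direction (sin, cos)
  nmat <- cbind(cos(az), -sin(az))
  b <- rowSums(nmat * stations)
  A <- crossprod(nmat)
  if (abs(det(A)) < 1e-12 * max(1, sum(diag(A)))^2) return(fail)
  z <- drop(solve(A, crossprod(nmat, b)))

  # objective (up to kappa): f(z) = sum 1 - cos(az_i - mu_i(z))
  angerr <- function(z) {
    dx <- z[1] - stations[, 1]; dy <- z[2] - stations[, 2]
    r2 <- dx^2 + dy^2
    if (any(r2 < 1e-12)) stop("estimate coincides with a station")
    list(e = az - atan2(dx, dy), dmu = cbind(dy / r2, -dx / r2))
  }
  fval <- function(z) sum(1 - cos(angerr(z)$e))
  grad <- function(z) {
    a <- angerr(z)
    -colSums(sin(a$e) * a$dmu)
  }
  hess_num <- function(z) {
    eps <- 1e-4 * max(1, sqrt(sum(z^2)))
    H <- matrix(0, 2, 2)
    for (j in 1:2) {
      zp <- z; zm <- z
      zp[j] <- zp[j] + eps; zm[j] <- zm[j] - eps
      H[, j] <- (grad(zp) - grad(zm)) / (2 * eps)
    }
    (H + t(H)) / 2
  }

  converged <- FALSE
  f0 <- fval(z)
  for (it in seq_len(max_iter)) {
    g <- grad(z)
    H <- hess_num(z)
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) step <- -g
    lambda <- 1
    repeat {   # damping: never accept an increase
      znew <- z + lambda * step
      fnew <- tryCatch(fval(znew), error = function(e) Inf)
      if (fnew <= f0 + 1e-15 || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    if (!is.finite(fnew)) return(fail)
    moved <- sqrt(sum((znew - z)^2))
    z <- znew; f0 <- fnew
    if (moved < tol) { converged <- TRUE; break }
  }
  kappa <- 1 / (bearing_sd * pi / 180)^2
  H <- hess_num(z)
  info <- kappa * H
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(cov)) || det(cov) <= 0 ||
      cov[1, 1] <= 0) {
    res <- fail
    res$estimate <- z
    return(res)
  }
  cov <- (cov + t(cov)) / 2
  area <- pi * sqrt(det(cov)) * stats::qchisq(conf, df = 2)
  structure(list(estimate = z, covariance = cov, ellipse_area = area,
                 n_bearings = m, converged = converged),
            class = "triangulation")
}

#' @export
print.triangulation <- function(x, ...) {
  cat(sprintf("ML fix: (%.1f, %.1f) m, %d bearings, ellipse %.0f m^2%s\n",
              x$estimate[1], x$estimate[2], x$n_bearings, x$ellipse_area,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Triangulate a table of bearing sets into relocations
#'
#' @param bearings long-format data frame, one row per bearing, with
#'   columns \code{set_id}, \code{individual}, \code{date}, \code{type},
#'   \code{station_x}, \code{station_y}, \code{azimuth}.
#' @param bearing_sd assumed bearing error SD in degrees.
#' @return relocation data frame (one row per converged set) with
#'   \code{x}, \code{y}, \code{ellipse_area}, \code{n_bearings},
#'   \code{source = "triangulated"}; non-converged sets are dropped with a
#'   message.
#' @export
triangulate_sets <- function(bearings, bearing_sd = 3) {
  need <- c("set_id", "individual", "date", "type", "station_x",
            "station_y", "azimuth")
  stopifnot(all(need %in% names(bearings)))
  out <- list(); dropped <- 0L
  for (sid in unique(bearings$set_id)) {
    b <- bearings[bearings$set_id == sid, , drop = FALSE]
    tr <- tryCatch(
      triangulate(cbind(b$station_x, b$station_y), b$azimuth,
                  bearing_sd = bearing_sd),
      error = function(e) NULL)
    if (is.null(tr) || !tr$converged) { dropped <- dropped + 1L; next }
    out[[length(out) + 1]] <- data.frame(
      set_id = sid, individual = b$individual[1],
      date = as.Date(b$date[1]), type = b$type[1],
      x = tr$estimate[1], y = tr$estimate[2],
      ellipse_area = tr$ellipse_area, n_bearings = tr$n_bearings,
      source = "triangulated", stringsAsFactors = FALSE)
  }
  if (dropped > 0)
    message(dropped, " bearing set(s) did not converge and were dropped")
  if (length(out)) do.call(rbind, out) else
    data.frame(set_id = character(), individual = character(),
               date = as.Date(character()), type = character(),
               x = numeric(), y = numeric(), ellipse_area = numeric(),
               n_bearings = integer(), source = character())
}

#' Precision filter for relocations
#'
#' Applies the study's error-ellipse quality thresholds: triangulated
#' daytime fixes (foraging, loafing) are retained only when the 95% error
#' ellipse is at most 2000 m^2 (about a 25 m radius); roosting fixes only
#' when at most 1000 m^2, because roosts must be relocated on the ground
#' for vegetation sampling. Directly observed fixes (\code{source ==
#' "direct"}) are always retained. Input order is preserved; filtering is
#' idempotent.
#'
#' @param fixes relocation data frame with columns \code{type},
#'   \code{ellipse_area} and optionally \code{source}.
#' @param daytime_max,roost_max ellipse-area thresholds in m^2.
#' @return the retained subset of \code{fixes}.
#' @export
filter_relocations <- function(fixes, daytime_max = 2000, roost_max = 1000) {
  if (nrow(fixes) == 0) return(fixes)
  src <- if ("source" %in% names(fixes)) fixes$source else "triangulated"
  limit <- ifelse(fixes$type == "roosting", roost_max, daytime_max)
  keep <- src == "direct" |
    (!is.na(fixes$ellipse_area) & fixes$ellipse_area <= limit)
  fixes[keep, , drop = FALSE]
}
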