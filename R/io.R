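#' Point-in-polygon test (even-odd rule, holes supported)
#'
#' Ray-casting test of points against a polygon given as a list of rings
#' (two-column matrices; the first ring is the outer boundary, further
#' rings are holes). The even-odd rule makes holes subtract automatically.
#' Points exactly on an edge may fall on either side at double precision;
#' site polygons in this pipeline are far larger than that ambiguity.
#'
#' @param px,py point coordinates.
#' @param polygon list of rings, each a matrix with columns x, y.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, polygon) {
  if (is.matrix(polygon)) polygon <- list(polygon)
  inside <- logical(length(px))
  for (ring in polygon) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    # drop closing vertex if the ring repeats it
    if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
    j <- n
    cross <- logical(length(px))
    for (i in seq_len(n)) {
      hit <- ((y[i] > py) != (y[j] > py)) &
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      cross <- xor(cross, hit)
      j <- i
    }
    inside <- xor(inside, cross)
  }
  inside
}

#' Write / read study-site polygons as GeoJSON
#'
#' Sites travel as a GeoJSON FeatureCollection of Polygons with
#' \code{site}, \code{group} and \code{area_ha} properties. Coordinates
#' are planar projected meters (no CRS handling; inputs must be
#' pre-projected).
#'
#' @param sites data frame with \code{site}, \code{group}, \code{area_ha}
#'   and a \code{polygon} list-column of ring lists.
#' @param path file path.
#' @return \code{read_sites_geojson} returns the site data frame.
#' @export
write_sites_geojson <- function(sites, path) {
  feats <- lapply(seq_len(nrow(sites)), function(i) {
    rings <- lapply(sites$polygon[[i]], function(ring) {
      if (!all(ring[1, ] == ring[nrow(ring), ]))
        ring <- rbind(ring, ring[1, ])
      lapply(seq_len(nrow(ring)), function(j) c(ring[j, 1], ring[j, 2]))
    })
    list(type = "Feature",
         properties = list(site = as.character(sites$site[i]),
                           group = as.character(sites$group[i]),
                           area_ha = sites$area_ha[i]),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_sites_geojson
#' @export
read_sites_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  rows <- lapply(fc$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("site geometry must be Polygon")
    rings <- lapply(f$geometry$coordinates, function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    })
    list(site = f$properties$site, group = f$properties$group,
         area_ha = f$properties$area_ha, polygon = rings)
  })
  data.frame(
    site = vapply(rows, `[[`, character(1), "site"),
    group = vapply(rows, `[[`, character(1), "group"),
    area_ha = vapply(rows, function(r)
      if (is.null(r$area_ha)) NA_real_ else as.numeric(r$area_ha),
      numeric(1)),
    polygon = I(lapply(rows, `[[`, "polygon")),
    stringsAsFactors = FALSE)
}

#' Typed CSV readers and writers for the pipeline tables
#'
#' Plain RFC-4180 CSV with headers, ISO-8601 dates and '.' decimal
#' separator. Readers validate required columns (missing ones fail with
#' the file and column named; unknown extra columns warn).
#'
#' @param x data frame to write.
#' @param path file path.
#' @name pipeline_io
#' @export
write_table_csv <- function(x, path) {
  x <- as.data.frame(x)
  for (cc in names(x)) if (inherits(x[[cc]], "Date"))
    x[[cc]] <- format(x[[cc]], "%Y-%m-%d")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_typed_csv <- function(path, required, date_cols = "date") {
  if (!file.exists(path)) stop("input file missing: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  for (cc in intersect(date_cols, names(x))) x[[cc]] <- as.Date(x[[cc]])
  x
}

#' @rdname pipeline_io
#' @export
read_relocations_csv <- function(path)
  read_typed_csv(path, c("individual", "date", "x", "y"))

#' @rdname pipeline_io
#' @export
read_cameras_csv <- function(path)
  read_typed_csv(path, c("site", "date", "n_photos", "n_hunters"))

#' @rdname pipeline_io
#' @export
read_bearings_csv <- function(path)
  read_typed_csv(path, c("set_id", "individual", "date", "type",
                         "station_x", "station_y", "azimuth"))

#' @rdname pipeline_io
#' @export
read_vegetation_csv <- function(path)
  read_typed_csv(path, c("plot_id", "use", "individual", "site", "group",
                         "sex", "date", "warm_grass", "cool_grass",
                         "bare_ground", "litter", "litter_depth",
                         "visual_obstruction"))

#' @rdname pipeline_io
#' @export
read_fates_csv <- function(path)
  read_typed_csv(path, c("individual", "sex", "group", "site",
                         "alive_at_onset", "death_date", "cause"),
                 date_cols = c("death_date", "censor_date"))

#' Utilization-distribution export as an ESRI ASCII grid
#'
#' Plain-text raster dialect readable by standard GIS tools; cell values
#' are densities in 1/m^2, row order north to south.
#'
#' @param ud a \code{ud_grid}.
#' @param path file path.
#' @export
write_ud_ascii <- function(ud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", length(ud$x)),
    sprintf("nrows %d", length(ud$y)),
    sprintf("xllcorner %.6f", ud$x[1] - ud$cell_size / 2),
    sprintf("yllcorner %.6f", ud$y[1] - ud$cell_size / 2),
    sprintf("cellsize %.6f", ud$cell_size),
    "NODATA_value -9999"), con)
  for (j in rev(seq_along(ud$y)))
    writeLines(paste(sprintf("%.10e", ud$density[, j]), collapse = " "), con)
  invisible(path)
}
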