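# GeoJSON writers for the package's vector outputs.  Geometries are written
# in the projected coordinate system of the input (no datum handling).

geojson_feature <- function(geometry, properties = list()) {
  list(type = "Feature",
       properties = if (length(properties)) properties else NULL,
       geometry = geometry)
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write polylines as GeoJSON LineStrings
#' @param lines list of two-column coordinate matrices.
#' @param path output file.
#' @param properties optional list (one element per line) of property lists.
#' @return `path`, invisibly.
#' @export
write_geojson_lines <- function(lines, path, properties = NULL) {
  feats <- lapply(seq_along(lines), function(i) {
    geojson_feature(
      list(type = "LineString",
           coordinates = lapply(seq_len(nrow(lines[[i]])),
                                function(k) unname(lines[[i]][k, 1:2]))),
      if (is.null(properties)) list() else properties[[i]])
  })
  write_geojson(feats, path)
}

#' Write a home-range polygon (cell union) as GeoJSON
#'
#' The isopleth region is a union of grid cells; each cell is emitted as one
#' square ring of a MultiPolygon.
#'
#' @param hr a `home_range` object (see [extract_isopleth()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geojson_homerange <- function(hr, path) {
  idx <- which(hr$mask, arr.ind = TRUE)
  half <- hr$res / 2
  cx <- hr$xmin + (idx[, 2] - 0.5) * hr$res
  cy <- hr$ymin + (idx[, 1] - 0.5) * hr$res
  polys <- lapply(seq_len(nrow(idx)), function(k) {
    x0 <- cx[k] - half; x1 <- cx[k] + half
    y0 <- cy[k] - half; y1 <- cy[k] + half
    list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
  })
  feats <- list(geojson_feature(
    list(type = "MultiPolygon", coordinates = polys),
    list(level = hr$level, area_m2 = hr_area(hr))))
  write_geojson(feats, path)
}
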