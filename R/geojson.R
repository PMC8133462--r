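# GeoJSON interchange for facility polygons. Facilities are lists with
# fields id, city, kind ("park"/"mall"), poly (n x 2 matrix) and centroid.

#' Write facility polygons to GeoJSON
#'
#' Emits a FeatureCollection of Polygon features with properties `id`,
#' `city` and `kind` (one of "park", "mall"). Coordinates are planar metres
#' unless the facilities were built from lon/lat input.
#'
#' @param facilities list of facility objects.
#' @param path output file path.
#' @export
write_facilities_geojson <- function(facilities, path) {
  features <- lapply(facilities, function(f) {
    ring <- rbind(f$poly, f$poly[1, , drop = FALSE])  # closed ring
    list(
      type = "Feature",
      properties = list(id = f$id, city = f$city, kind = f$kind),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) ring[i, ]))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read facility polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features; each feature must carry a
#' `kind` property in \{park, mall\}. Only the outer ring is used (holes are
#' not supported). Multi-polygon facilities should be supplied as one feature
#' per part.
#'
#' @param path GeoJSON file path.
#' @return list of facility objects (id, city, kind, poly, centroid).
#' @export
read_facilities_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    if (f$geometry$type != "Polygon") {
      stop("only Polygon features are supported (feature ", i, " is ",
           f$geometry$type, ")")
    }
    kind <- f$properties$kind
    if (is.null(kind) || !kind %in% c("park", "mall")) {
      stop("feature ", i, " lacks a 'kind' property in {park, mall}")
    }
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    # drop the closing vertex if present
    if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ])) {
      poly <- poly[-nrow(poly), , drop = FALSE]
    }
    list(
      id = if (is.null(f$properties$id)) paste0(kind, "_", i) else f$properties$id,
      city = if (is.null(f$properties$city)) NA else f$properties$city,
      kind = kind, poly = poly, centroid = polygon_centroid(poly)
    )
  })
}
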