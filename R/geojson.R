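## Minimal planar GeoJSON support: one Polygon feature per area, the
## area ID in property "area_id", optional extra per-area properties.
## Coordinates are plain planar numbers (no CRS handling).

#' Write a polygon layer to GeoJSON
#'
#' @param layer an `area_polygons` object.
#' @param path output file path.
#' @param properties optional data.frame of extra per-feature properties
#'   with a column `area_id` matching the layer IDs.
#' @return The path, invisibly.
#' @export
write_geojson <- function(layer, path, properties = NULL) {
  stopifnot(inherits(layer, "area_polygons"))
  if (!is.null(properties)) {
    if (!"area_id" %in% names(properties))
      stop("`properties` must have an `area_id` column")
    miss <- setdiff(properties$area_id, layer$ids)
    if (length(miss)) stop("unknown area_id in properties: ",
                           paste(miss, collapse = ", "))
  }
  feats <- lapply(seq_along(layer$ids), function(i) {
    poly <- layer$polygons[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE])  # closed ring
    props <- list(area_id = jsonlite::unbox(layer$ids[i]))
    if (!is.null(properties)) {
      row <- properties[match(layer$ids[i], properties$area_id), , drop = FALSE]
      if (nrow(row) == 1L && !is.na(row$area_id)) {
        for (nm in setdiff(names(row), "area_id"))
          props[[nm]] <- jsonlite::unbox(row[[nm]])
      }
    }
    list(type = jsonlite::unbox("Feature"),
         properties = props,
         geometry = list(type = jsonlite::unbox("Polygon"),
                         coordinates = list(ring)))
  })
  fc <- list(type = jsonlite::unbox("FeatureCollection"),
             bbox = layer$window[c(1, 2, 3, 4)],
             features = feats)
  jsonlite::write_json(fc, path, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a polygon layer from GeoJSON
#'
#' @param path a GeoJSON FeatureCollection of Polygon features with an
#'   `area_id` property.
#' @return A list with `layer` (an `area_polygons`) and `properties`
#'   (data.frame of all feature properties).
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection")
  ids <- character(0)
  polys <- list()
  props <- list()
  for (ft in fc$features) {
    p <- ft$properties
    ids <- c(ids, p$area_id)
    ring <- ft$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ]))
      m <- m[-nrow(m), , drop = FALSE]
    polys[[length(polys) + 1L]] <- m
    props[[length(props) + 1L]] <- lapply(p, function(v) {
      if (is.null(v)) return(NA)
      if (is.list(v)) {
        if (length(v) == 0L || is.null(v[[1]])) return(NA)
        v <- v[[1]]
      }
      v
    })
  }
  nms <- unique(unlist(lapply(props, names)))
  pdf <- do.call(rbind, lapply(props, function(p) {
    p <- p[nms]
    names(p) <- nms
    as.data.frame(lapply(p, function(v) if (is.null(v)) NA else v))
  }))
  window <- if (!is.null(fc$bbox)) unlist(fc$bbox) else {
    allv <- do.call(rbind, polys)
    c(min(allv[, 1]), min(allv[, 2]), max(allv[, 1]), max(allv[, 2]))
  }
  list(layer = new_area_polygons(ids, polys, window), properties = pdf)
}
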