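## Choropleth-ready outputs: a seven-class diverging scheme centred on
## SIR = 1, exceedance-probability flags standing in for cross-hatch
## overlays, box-plot shrinkage summaries, and annotated GeoJSON map
## layers.

#' Seven-class diverging class scheme for SIR maps
#'
#' Eight strictly increasing break points bounding seven classes, with
#' one class containing 1.0 in its interior (the near-unity class).
#' The defaults (0, 0.5, 0.75, 0.95, 1.05, 1.33, 2, Inf) round the
#' class edges to intuitive risk levels and are fully configurable.
#'
#' @param breaks numeric vector of 8 strictly increasing break points.
#' @param labels optional class labels (length 7).
#' @return A `class_scheme` list.
#' @export
class_scheme <- function(breaks = c(0, 0.5, 0.75, 0.95, 1.05, 1.33, 2,
                                    Inf),
                         labels = NULL) {
  if (length(breaks) != 8L) stop("need 8 break points for 7 classes")
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  k <- findInterval(1.0, breaks)
  if (k < 1 || k > 7 || breaks[k] >= 1 || breaks[k + 1] <= 1)
    stop("one class must contain 1.0 in its interior")
  if (is.null(labels))
    labels <- paste0("[", formatC(breaks[-8]), ", ",
                     formatC(breaks[-1]), ")")
  structure(list(breaks = breaks, labels = labels, n_classes = 7L),
            class = "class_scheme")
}

#' Classify values into map classes
#'
#' Half-open interval assignment `[b_k, b_{k+1})`; values below the
#' first break clamp to class 1, values at or above the last break to
#' class 7; undefined values (NA) are unclassified (NA).
#'
#' @param values numeric vector (e.g. raw or smoothed SIRs).
#' @param scheme a [class_scheme()].
#' @return Integer class indices 1-7 (NA = unclassified).
#' @export
classify <- function(values, scheme = class_scheme()) {
  stopifnot(inherits(scheme, "class_scheme"))
  idx <- findInterval(values, scheme$breaks)
  idx[!is.na(idx) & idx < 1L] <- 1L
  idx[!is.na(idx) & idx > 7L] <- 7L
  as.integer(idx)
}

#' Exceedance flags for map overlays
#'
#' Flag an area when its posterior probability of above-average risk is
#' at or above the threshold (default 0.80).
#'
#' @param prob exceedance probabilities in `[0, 1]`.
#' @param threshold flag cut in (0, 1).
#' @return Logical flags (NA probabilities give NA).
#' @export
exceedance_flags <- function(prob, threshold = 0.80) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  prob >= threshold
}

#' Box-plot statistics and shrinkage check
#'
#' Tukey summaries per series (quartiles, mean, median, whiskers at
#' Q1 - 1.5 IQR and Q3 + 1.5 IQR, outliers beyond the whiskers), plus
#' the shrinkage comparison of interquartile ranges: hierarchical
#' smoothing should never widen the IQR relative to the raw SIRs.
#'
#' @param raw raw SIRs.
#' @param smoothed posterior-mean SIRs.
#' @return List with `raw`, `smoothed` (each a stats list) and
#'   `shrunk` (logical: IQR_smoothed <= IQR_raw).
#' @export
shrinkage_summary <- function(raw, smoothed) {
  one <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) stop("series must be non-empty")
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lw <- q[1] - 1.5 * iqr
    uw <- q[3] + 1.5 * iqr
    list(q1 = q[1], median = q[2], q3 = q[3], mean = mean(x), iqr = iqr,
         whisker_low = lw, whisker_high = uw,
         outliers = x[x < lw | x > uw])
  }
  r <- one(raw); s <- one(smoothed)
  list(raw = r, smoothed = s, shrunk = s$iqr <= r$iqr)
}

#' Build per-area map records
#'
#' @param area_id character IDs.
#' @param value raw or smoothed SIRs (NA = unclassified).
#' @param scheme a [class_scheme()].
#' @param significant logical: exact interval excludes 1 (raw maps), or
#'   any user flag; recycled.
#' @param exceedance logical exceedance flags; recycled.
#' @return A `map_records` data.frame: `area_id, value, class,
#'   significant, exceedance`.
#' @export
map_records <- function(area_id, value, scheme = class_scheme(),
                        significant = FALSE, exceedance = FALSE) {
  data.frame(area_id = area_id, value = value,
             class = classify(value, scheme),
             significant = rep_len(significant, length(area_id)),
             exceedance = rep_len(exceedance, length(area_id)),
             stringsAsFactors = FALSE)
}

#' Write an annotated map layer
#'
#' Attaches `value`, `class`, `significant` and `exceedance` properties
#' to the polygon features and writes GeoJSON; the records round-trip
#' losslessly through [read_map_layer()].
#'
#' @param layer an `area_polygons` object.
#' @param records a [map_records()] data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_map_layer <- function(layer, records, path) {
  miss <- setdiff(records$area_id, layer$ids)
  if (length(miss)) stop("unknown area_id: ", paste(miss, collapse = ", "))
  write_geojson(layer, path, properties = records)
}

#' @rdname write_map_layer
#' @export
read_map_layer <- function(path) {
  gj <- read_geojson(path)
  props <- gj$properties
  want <- c("area_id", "value", "class", "significant", "exceedance")
  have <- intersect(want, names(props))
  list(layer = gj$layer, records = props[, have, drop = FALSE])
}

#' Simple choropleth plot of classified areas
#'
#' @param layer an `area_polygons`.
#' @param records a [map_records()] data.frame.
#' @param palette 7 fill colours, low to high.
#' @param ... passed to [plot.area_polygons()].
#' @return The layer, invisibly.
#' @export
plot_choropleth <- function(layer, records,
                            palette = grDevices::hcl.colors(7, "Blue-Red"),
                            ...) {
  cls <- records$class[match(layer$ids, records$area_id)]
  col <- ifelse(is.na(cls), "grey90", palette[cls])
  plot(layer, col = col, ...)
  flag <- records$exceedance[match(layer$ids, records$area_id)]
  if (any(flag %in% TRUE)) {
    cen <- area_centroids(layer)
    graphics::points(cen[which(flag %in% TRUE), , drop = FALSE],
                     pch = 4, cex = 0.6)
  }
  invisible(layer)
}
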