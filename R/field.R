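#' High power field container
#'
#' Wraps one RGB high power field (HPF) together with its spatial resolution
#' and provenance identifiers. Pixels are stored as a `rows x cols x 3`
#' numeric array with 8-bit values in `[0, 255]`; pixel centres sit at
#' 0-based integer `(row, col)` coordinates.
#'
#' @param pixels numeric array `rows x cols x 3`, values in `[0, 255]`.
#' @param um_per_px microns per pixel (default 0.5, i.e. roughly 20x
#'   magnification).
#' @param field_id,wsi_id,patient_id identifier strings.
#' @return an object of class `high_power_field`.
#' @export
high_power_field <- function(pixels, um_per_px = 0.5, field_id = "field",
                             wsi_id = "wsi", patient_id = "patient") {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) {
    abort("`pixels` must be a rows x cols x 3 array")
  }
  if (d[1] < 64 || d[2] < 64) {
    abort("fields must be at least 64 x 64 pixels")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort("pixel values must lie in [0, 255]")
  }
  if (!is.numeric(um_per_px) || um_per_px <= 0) {
    abort("`um_per_px` must be a positive real")
  }
  structure(
    list(pixels = pixels, um_per_px = um_per_px, field_id = field_id,
         wsi_id = wsi_id, patient_id = patient_id),
    class = "high_power_field"
  )
}

#' @export
print.high_power_field <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<high_power_field> %s (%s / %s): %d x %d px, %.2f um/px\n",
              x$field_id, x$wsi_id, x$patient_id, d[1], d[2], x$um_per_px))
  invisible(x)
}

#' Tubule annotation: closed polygon delineations
#'
#' Holds the expert-style tubule delineations of one field as a list of
#' polygon rings. Each ring is a matrix with columns `x` (column coordinate)
#' and `y` (row coordinate), 0-based, vertices listed once (the closing edge
#' back to the first vertex is implicit). Rings must have at least three
#' vertices and must not self-intersect.
#'
#' @param polygons list of numeric matrices with columns `x`, `y`.
#' @param field_id identifier of the annotated field.
#' @param tubule_ids optional character vector of ids (default `t1`, `t2`, ...).
#' @return an object of class `tubule_annotation`.
#' @export
tubule_annotation <- function(polygons = list(), field_id = "field",
                              tubule_ids = NULL) {
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2) abort("each polygon must be an n x 2 (x, y) matrix")
    # drop an explicitly repeated closing vertex
    n <- nrow(p)
    if (n >= 2 && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
    if (nrow(p) < 3) abort("each polygon ring needs at least 3 vertices")
    if (polygon_self_intersects(p)) abort("self-intersecting polygon")
    colnames(p) <- c("x", "y")
    p
  })
  if (is.null(tubule_ids)) tubule_ids <- sprintf("t%d", seq_along(polygons))
  if (length(tubule_ids) != length(polygons)) {
    abort("`tubule_ids` must match `polygons` in length")
  }
  names(polygons) <- tubule_ids
  structure(list(polygons = polygons, field_id = field_id),
            class = "tubule_annotation")
}

#' @export
print.tubule_annotation <- function(x, ...) {
  cat(sprintf("<tubule_annotation> %s: %d polygon(s)\n",
              x$field_id, length(x$polygons)))
  invisible(x)
}

#' @export
length.tubule_annotation <- function(x) length(x$polygons)

# proper-segment intersection test on an open polygon ring (closing edge
# included); adjacent edges share endpoints by construction and are skipped
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    j <- (i + 2):jmax
    d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
    d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
    d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
    d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
    hit <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
           ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Rasterize tubule polygons to a binary mask
#'
#' A pixel is foreground (1) iff its centre lies inside or on the boundary
#' of any tubule polygon. Pixel centres are at 0-based integer coordinates:
#' mask entry `[i, j]` corresponds to the point `(row = i - 1, col = j - 1)`.
#'
#' @param annotation a [tubule_annotation()].
#' @param shape integer `(rows, cols)` of the target mask.
#' @return integer matrix of 0/1 values.
#' @export
rasterize_annotation <- function(annotation, shape) {
  if (!inherits(annotation, "tubule_annotation")) {
    abort("`annotation` must be a tubule_annotation")
  }
  if (length(shape) != 2 || any(shape < 1)) abort("`shape` must be (rows, cols)")
  mask <- matrix(0L, shape[1], shape[2])
  for (p in annotation$polygons) {
    cmin <- max(0L, floor(min(p[, "x"])))
    cmax <- min(shape[2] - 1L, ceiling(max(p[, "x"])))
    rmin <- max(0L, floor(min(p[, "y"])))
    rmax <- min(shape[1] - 1L, ceiling(max(p[, "y"])))
    if (cmin > cmax || rmin > rmax) next
    cols <- cmin:cmax
    rows <- rmin:rmax
    gx <- rep(cols, each = length(rows))
    gy <- rep(rows, times = length(cols))
    inside <- pracma::inpolygon(gx, gy, p[, "x"], p[, "y"], boundary = TRUE)
    if (any(inside)) {
      mask[cbind(gy[inside] + 1L, gx[inside] + 1L)] <- 1L
    }
  }
  mask
}

#' Write / read tubule annotations as GeoJSON
#'
#' One `FeatureCollection` per field; one `Polygon` feature per tubule with
#' property `tubule_id`. Coordinates are `[x = col, y = row]`, 0-based pixel
#' units, with the ring explicitly closed as GeoJSON requires.
#'
#' @param annotation a [tubule_annotation()].
#' @param path file path.
#' @return `write_annotation_geojson()` returns `path` invisibly;
#'   `read_annotation_geojson()` returns a [tubule_annotation()].
#' @export
write_annotation_geojson <- function(annotation, path) {
  features <- purrr::imap(annotation$polygons, function(p, id) {
    ring <- rbind(p, p[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(tubule_id = id, field_id = annotation$field_id),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(i) unname(ring[i, ])))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation_geojson
#' @param field_id field identifier for the returned annotation (read back
#'   from the feature properties when present).
#' @export
read_annotation_geojson <- function(path, field_id = NULL) {
  fc <- jsonlite::read_json(path)
  polys <- list()
  ids <- character()
  for (f in fc$features) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(x = v[[1]], y = v[[2]])))
    polys[[length(polys) + 1]] <- m
    ids <- c(ids, f$properties$tubule_id %||% sprintf("t%d", length(ids) + 1))
    if (is.null(field_id)) field_id <- f$properties$field_id
  }
  tubule_annotation(polys, field_id = field_id %||% "field", tubule_ids = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
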