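#' Blue ratio transform
#'
#' Per-pixel map emphasising hematoxylin-stained (blue/purple) nuclei
#' against the eosin-pink background:
#' `BR = (100 * B / (1 + R + G)) * (256 / (1 + R + G + B))`
#' with 8-bit channel values. The output is non-negative and, for fixed R
#' and G, increases monotonically with B.
#'
#' @param field a [high_power_field()] or a `rows x cols x 3` array of
#'   values in `[0, 255]`.
#' @return a `rows x cols` numeric matrix.
#' @export
blue_ratio <- function(field) {
  px <- if (inherits(field, "high_power_field")) field$pixels else field
  d <- dim(px)
  if (length(d) != 3 || d[3] != 3) abort("expected a rows x cols x 3 RGB array")
  r <- matrix(px[, , 1], d[1], d[2])
  g <- matrix(px[, , 2], d[1], d[2])
  b <- matrix(px[, , 3], d[1], d[2])
  (100 * b / (1 + r + g)) * (256 / (1 + r + g + b))
}

#' Otsu's global threshold
#'
#' Bins the values into `bins` equal-width histogram bins and returns the
#' bin boundary that maximises the between-class variance. Foreground is
#' defined as values strictly above the returned threshold, so a constant
#' image (a degenerate input, reported with a warning) yields no foreground.
#'
#' @param values numeric matrix or vector (at least one value).
#' @param bins number of histogram bins (default 256).
#' @return the threshold, a scalar on the scale of `values`.
#' @export
otsu_threshold <- function(values, bins = 256) {
  v <- as.numeric(values)
  if (length(v) == 0 || any(!is.finite(v))) abort("`values` must be non-empty and finite")
  if (bins < 2) abort("`bins` must be at least 2")
  lo <- min(v)
  hi <- max(v)
  if (lo == hi) {
    warn("constant image: Otsu threshold is degenerate, returning max(values)")
    return(hi)
  }
  edges <- seq(lo, hi, length.out = bins + 1)
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = bins)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  n <- length(v)
  w0 <- cumsum(counts) / n                      # class weight below boundary
  m0 <- cumsum(counts * mids) / n               # unnormalised class mean
  mu <- m0[bins]
  # between-class variance at each interior boundary k (split after bin k)
  k <- seq_len(bins - 1)
  w <- w0[k]
  valid <- w > 0 & w < 1
  sigma_b <- rep(-Inf, bins - 1)
  sigma_b[valid] <- (mu * w[valid] - m0[k][valid])^2 /
    (w[valid] * (1 - w[valid]))
  best <- which.max(sigma_b)
  edges[best + 1]
}

#' Nuclei detection parameters
#'
#' Free parameters of the detector. Defaults assume ~0.5 um/pixel: a disc
#' of radius 2 px for the morphological opening and a 15 px minimum
#' component area, so that a ~6 um nucleus survives while specks are
#' removed.
#'
#' @param opening_radius_px radius of the disc structuring element.
#' @param min_component_area_px components smaller than this are dropped.
#' @param blue_ratio_quantization histogram bins for the Otsu threshold.
#' @param min_bimodality minimum Otsu effectiveness coefficient
#'   (between-class variance over total variance, in `[0, 1]`) for the
#'   threshold to be considered meaningful. A field without nuclei has a
#'   near-unimodal blue-ratio histogram (the coefficient is about 0.64 for
#'   pure Gaussian noise) and yields no detections; fields containing
#'   stained nuclei are strongly bimodal (coefficient near 1).
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(opening_radius_px = 2,
                             min_component_area_px = 15,
                             blue_ratio_quantization = 256,
                             min_bimodality = 0.8) {
  if (opening_radius_px < 1) abort("`opening_radius_px` must be positive")
  if (min_component_area_px < 0) abort("`min_component_area_px` must be >= 0")
  if (blue_ratio_quantization < 2) abort("`blue_ratio_quantization` must be >= 2")
  if (min_bimodality < 0 || min_bimodality > 1) {
    abort("`min_bimodality` must lie in [0, 1]")
  }
  structure(list(opening_radius_px = as.integer(opening_radius_px),
                 min_component_area_px = as.integer(min_component_area_px),
                 blue_ratio_quantization = as.integer(blue_ratio_quantization),
                 min_bimodality = min_bimodality),
            class = "detection_params")
}

# Otsu effectiveness: between-class variance at `thr` over total variance
otsu_effectiveness <- function(values, thr) {
  v <- as.numeric(values)
  tot <- mean((v - mean(v))^2)
  if (tot == 0) return(0)
  hi <- v > thr
  w1 <- mean(hi)
  if (w1 == 0 || w1 == 1) return(0)
  (1 - w1) * w1 * (mean(v[hi]) - mean(v[!hi]))^2 / tot
}

#' Detect nuclei candidates in a high power field
#'
#' Pipeline: blue ratio transform -> Otsu global threshold (strictly-above
#' foreground) -> binary opening with a disc -> 8-connected components ->
#' drop components below the minimum area -> one candidate per surviving
#' component at its unweighted pixel-centroid. Candidates near the field
#' border are retained (patch extraction mirror-pads). Overlapping nuclei
#' merge into a single component and therefore a single candidate: the
#' detector is a rough estimator of the nuclei population, not a segmenter.
#'
#' @param field a [high_power_field()] or RGB array.
#' @param params a [detection_params()].
#' @return a tibble with columns `field_id`, `candidate_id`, `row`, `col`
#'   (0-based real centroid coordinates) and `area_px`, sorted by
#'   `(row, col)`. Possibly zero rows.
#' @export
detect_nuclei <- function(field, params = detection_params()) {
  field_id <- if (inherits(field, "high_power_field")) field$field_id else "field"
  br <- blue_ratio(field)
  thr <- withCallingHandlers(
    otsu_threshold(br, bins = params$blue_ratio_quantization),
    warning = function(w) invokeRestart("muffleWarning"))
  mask <- br > thr
  empty <- tibble(field_id = character(), candidate_id = character(),
                  row = double(), col = double(), area_px = integer())
  if (!any(mask)) return(empty)
  if (otsu_effectiveness(br, thr) < params$min_bimodality) return(empty)
  size <- 2L * params$opening_radius_px + 1L
  opened <- EBImage::opening(mask * 1, EBImage::makeBrush(size, shape = "disc"))
  labels <- cpp_label_components8(matrix(as.integer(opened > 0), nrow(mask)))
  nlab <- max(labels)
  if (nlab == 0) return(empty)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows0 <- (idx - 1) %% nrow(labels)        # 0-based row of each fg pixel
  cols0 <- (idx - 1) %/% nrow(labels)
  area <- tabulate(lab, nbins = nlab)
  crow <- rowsum(rows0, lab)[, 1] / area[sort(unique(lab))]
  ccol <- rowsum(cols0, lab)[, 1] / area[sort(unique(lab))]
  keep <- area >= params$min_component_area_px
  out <- tibble(row = crow[keep], col = ccol[keep],
                area_px = as.integer(area[keep]))
  out <- dplyr::arrange(out, .data$row, .data$col)
  dplyr::mutate(out,
                field_id = field_id,
                candidate_id = sprintf("c%04d", dplyr::row_number()),
                .before = 1)
}
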