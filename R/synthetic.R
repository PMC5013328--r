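#' Configuration for one synthetic H&E-like field
#'
#' Describes the content of a synthetic high power field: white elliptical
#' lumina each surrounded by a ring of hematoxylin-dark nuclei (a tubule),
#' plus scattered free (non-tubule) nuclei on an eosin-pink background.
#' All coordinates are 0-based `(row, col)` pixels.
#'
#' Nucleus shape is an ellipse whose major semi-axis is drawn from
#' `nucleus_axis_px_range`; the minor semi-axis is the major one times a
#' ratio drawn from `nucleus_axis_ratio_range`. Ring nuclei are oriented
#' radially (major axis pointing at the lumen centre) so neighbouring ring
#' nuclei stay separated; free nuclei get random orientations.
#'
#' @param field_height_px,field_width_px field size in pixels (>= 64).
#' @param um_per_px microns per pixel.
#' @param n_tubules number of tubules to place.
#' @param n_free_nuclei number of scattered non-tubule nuclei. The default
#'   density (30 nuclei in a 224 px square field) keeps whole-cohort runs
#'   cheap while leaving per-field TFI estimates stable.
#' @param lumen_radius_px_range `(min, max)` lumen radius in pixels.
#' @param nucleus_axis_px_range `(min, max)` nucleus major semi-axis in px.
#' @param nucleus_axis_ratio_range `(min, max)` minor/major axis ratio.
#' @param nuclei_per_tubule_ring nuclei forming each tubule ring.
#' @param color_params list with `background`, `nucleus`, `lumen` mean RGB
#'   triplets in `[0, 255]`, per-nucleus colour `jitter` sd and background
#'   `texture_sd`.
#' @param allow_overlap if `TRUE`, nucleus-nucleus distance constraints are
#'   dropped so that deliberately merged components can be produced.
#' @param max_attempts rejection-sampling attempts per structure before a
#'   placement failure is raised.
#' @param seed integer seed; the generated field is a pure function of the
#'   configuration.
#' @param field_id,wsi_id,patient_id identifiers stamped on the output.
#' @return a list of class `field_config`.
#' @export
field_config <- function(field_height_px = 224, field_width_px = 224,
                         um_per_px = 0.5,
                         n_tubules = 1, n_free_nuclei = 30,
                         lumen_radius_px_range = c(9, 13),
                         nucleus_axis_px_range = c(4.5, 5.5),
                         nucleus_axis_ratio_range = c(0.6, 0.8),
                         nuclei_per_tubule_ring = 8,
                         color_params = list(
                           background = c(230, 160, 195),
                           nucleus = c(70, 45, 120),
                           lumen = c(246, 244, 248),
                           jitter = 8, texture_sd = 4),
                         allow_overlap = FALSE,
                         max_attempts = 1000,
                         seed = 1L,
                         field_id = "field", wsi_id = "wsi",
                         patient_id = "patient") {
  if (field_height_px < 64 || field_width_px < 64) {
    abort("field dimensions must be at least 64 px")
  }
  if (n_tubules < 0 || n_free_nuclei < 0) abort("counts must be non-negative")
  if (nuclei_per_tubule_ring < 1) abort("`nuclei_per_tubule_ring` must be positive")
  check_range(lumen_radius_px_range, "lumen_radius_px_range")
  check_range(nucleus_axis_px_range, "nucleus_axis_px_range")
  check_range(nucleus_axis_ratio_range, "nucleus_axis_ratio_range")
  for (nm in c("background", "nucleus", "lumen")) {
    col <- color_params[[nm]]
    if (length(col) != 3 || any(col < 0) || any(col > 255)) {
      abort(sprintf("color_params$%s must be an RGB triplet in [0, 255]", nm))
    }
  }
  structure(
    list(field_height_px = as.integer(field_height_px),
         field_width_px = as.integer(field_width_px),
         um_per_px = um_per_px,
         n_tubules = as.integer(n_tubules),
         n_free_nuclei = as.integer(n_free_nuclei),
         lumen_radius_px_range = lumen_radius_px_range,
         nucleus_axis_px_range = nucleus_axis_px_range,
         nucleus_axis_ratio_range = nucleus_axis_ratio_range,
         nuclei_per_tubule_ring = as.integer(nuclei_per_tubule_ring),
         color_params = color_params,
         allow_overlap = isTRUE(allow_overlap),
         max_attempts = as.integer(max_attempts),
         seed = as.integer(seed),
         field_id = field_id, wsi_id = wsi_id, patient_id = patient_id),
    class = "field_config"
  )
}

#' Generate one synthetic high power field
#'
#' Places `n_tubules` tubules (white elliptical lumen plus a ring of
#' `nuclei_per_tubule_ring` dark nuclei, enclosed by a polygon annotation)
#' and `n_free_nuclei` scattered nuclei outside every tubule polygon, then
#' renders the scene with Gaussian colour jitter and background texture
#' noise. Output is deterministic given the configuration (seed included).
#'
#' Placement uses rejection sampling with at most `max_attempts` draws per
#' structure; when a structure cannot be placed without violating the
#' separation constraints an error of class `tubulequant_placement_error`
#' is raised. With `allow_overlap = TRUE` nucleus separation constraints are
#' dropped (tubule footprints are still kept apart).
#'
#' @param config a [field_config()].
#' @return a list of class `synthetic_field` with elements
#'   `field` (a [high_power_field()]), `annotation` (a
#'   [tubule_annotation()]) and `nuclei`, a tibble of ground-truth nuclei
#'   with columns `nucleus_id`, `row`, `col`, `is_tubule`, `tubule_id`
#'   (`NA` for free nuclei).
#' @export
generate_field <- function(config) {
  if (!inherits(config, "field_config")) abort("`config` must be a field_config")
  withr::local_seed(config$seed)

  H <- config$field_height_px
  W <- config$field_width_px
  amax <- config$nucleus_axis_px_range[2]
  m <- config$nuclei_per_tubule_ring

  ## ---- tubule geometry -------------------------------------------------
  tubules <- list()
  if (config$n_tubules > 0) {
    for (t in seq_len(config$n_tubules)) {
      lr <- runif_range(1, config$lumen_radius_px_range)
      poly_r <- lr + 2 * amax + 3.5          # encloses lumen + nucleus ring
      margin <- poly_r + 2
      if (2 * margin >= H || 2 * margin >= W) {
        placement_error("field too small for a tubule footprint")
      }
      ok <- FALSE
      for (attempt in seq_len(config$max_attempts)) {
        cy <- runif(1, margin, H - 1 - margin)
        cx <- runif(1, margin, W - 1 - margin)
        clear <- TRUE
        for (tb in tubules) {
          if (sqrt((cy - tb$cy)^2 + (cx - tb$cx)^2) < poly_r + tb$poly_r + 4) {
            clear <- FALSE
            break
          }
        }
        if (clear) { ok <- TRUE; break }
      }
      if (!ok) placement_error("could not place tubule without overlap")
      tubules[[t]] <- list(cy = cy, cx = cx, lumen_r = lr, poly_r = poly_r,
                           id = sprintf("t%d", t))
    }
  }

  ## ---- nuclei ----------------------------------------------------------
  nuc <- list()   # each: row, col, a, b, theta, is_tubule, tubule_id
  add_nucleus <- function(row, col, a, b, theta, is_tubule, tubule_id) {
    nuc[[length(nuc) + 1]] <<- list(row = row, col = col, a = a, b = b,
                                    theta = theta, is_tubule = is_tubule,
                                    tubule_id = tubule_id)
  }

  for (tb in tubules) {
    base_angle <- runif(1, 0, 2 * pi)
    angles <- base_angle + 2 * pi * (seq_len(m) - 1) / m + rnorm(m, 0, 0.04)
    a <- runif_range(m, config$nucleus_axis_px_range)
    ratio <- runif_range(m, config$nucleus_axis_ratio_range)
    rad <- tb$lumen_r + a + 1.5
    for (i in seq_len(m)) {
      add_nucleus(row = tb$cy + rad[i] * sin(angles[i]),
                  col = tb$cx + rad[i] * cos(angles[i]),
                  a = a[i], b = a[i] * ratio[i],
                  theta = angles[i],          # radial orientation
                  is_tubule = TRUE, tubule_id = tb$id)
    }
  }

  if (config$n_free_nuclei > 0) {
    for (i in seq_len(config$n_free_nuclei)) {
      a <- runif_range(1, config$nucleus_axis_px_range)
      b <- a * runif_range(1, config$nucleus_axis_ratio_range)
      ok <- FALSE
      for (attempt in seq_len(config$max_attempts)) {
        row <- runif(1, a + 2, H - 1 - a - 2)
        col <- runif(1, a + 2, W - 1 - a - 2)
        clear <- TRUE
        for (tb in tubules) {  # stay clearly outside every tubule polygon
          if (sqrt((row - tb$cy)^2 + (col - tb$cx)^2) < tb$poly_r + a + 2) {
            clear <- FALSE
            break
          }
        }
        if (clear && !config$allow_overlap) {
          for (nn in nuc) {
            if (sqrt((row - nn$row)^2 + (col - nn$col)^2) < a + nn$a + 3) {
              clear <- FALSE
              break
            }
          }
        }
        if (clear) { ok <- TRUE; break }
      }
      if (!ok) placement_error("could not place free nucleus without overlap")
      add_nucleus(row, col, a, b, theta = runif(1, 0, pi),
                  is_tubule = FALSE, tubule_id = NA_character_)
    }
  }

  ## ---- rendering -------------------------------------------------------
  # ellipse pixel sets are gathered first and painted with a single indexed
  # assignment per channel (later objects overwrite earlier ones)
  cp <- config$color_params
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    img[, , ch] <- cp$background[ch] + matrix(rnorm(H * W, 0, cp$texture_sd), H, W)
  }
  idx_r <- list(); idx_c <- list(); vals <- list(list(), list(), list())
  add_paint <- function(px, color, noise_sd) {
    k <- length(idx_r) + 1
    idx_r[[k]] <<- px$r
    idx_c[[k]] <<- px$c
    n <- length(px$r)
    for (ch in 1:3) {
      vals[[ch]][[k]] <<- clip(color[ch] + rnorm(n, 0, noise_sd), 0, 255)
    }
  }
  for (tb in tubules) {
    lum_theta <- runif(1, 0, pi)
    lum_ratio <- runif(1, 0.85, 1)
    add_paint(ellipse_pixels(tb$cy, tb$cx, tb$lumen_r, tb$lumen_r * lum_ratio,
                             lum_theta, H, W),
              cp$lumen, noise_sd = 1.5)
  }
  for (nn in nuc) {
    col_mean <- clip(cp$nucleus + rnorm(3, 0, cp$jitter), 0, 255)
    add_paint(ellipse_pixels(nn$row, nn$col, nn$a, nn$b, nn$theta, H, W),
              col_mean, noise_sd = 3)
  }
  if (length(idx_r) > 0) {
    rr <- unlist(idx_r) + 1L
    cc <- unlist(idx_c) + 1L
    for (ch in 1:3) {
      img[cbind(rr, cc, ch)] <- unlist(vals[[ch]])
    }
  }
  img <- round(clip(img, 0, 255))

  ## ---- outputs ---------------------------------------------------------
  polys <- lapply(tubules, function(tb) {
    ang <- seq(0, 2 * pi, length.out = 29)[-29]
    cbind(x = tb$cx + tb$poly_r * cos(ang), y = tb$cy + tb$poly_r * sin(ang))
  })
  annotation <- tubule_annotation(polys, field_id = config$field_id,
                                  tubule_ids = vapply(tubules, `[[`, "", "id"))
  nuclei <- tibble(
    nucleus_id = sprintf("n%03d", seq_along(nuc)),
    row = vapply(nuc, `[[`, 0, "row"),
    col = vapply(nuc, `[[`, 0, "col"),
    is_tubule = vapply(nuc, `[[`, TRUE, "is_tubule"),
    tubule_id = vapply(nuc, `[[`, "", "tubule_id")
  )
  field <- high_power_field(img, um_per_px = config$um_per_px,
                            field_id = config$field_id,
                            wsi_id = config$wsi_id,
                            patient_id = config$patient_id)
  structure(list(field = field, annotation = annotation, nuclei = nuclei),
            class = "synthetic_field")
}

placement_error <- function(msg) {
  abort(msg, class = "tubulequant_placement_error")
}

# 0-based (row, col) pixel centres covered by a filled rotated ellipse
ellipse_pixels <- function(cy, cx, a, b, theta, H, W) {
  r0 <- max(0L, floor(cy - a))
  r1 <- min(H - 1L, ceiling(cy + a))
  c0 <- max(0L, floor(cx - a))
  c1 <- min(W - 1L, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(list(r = integer(), c = integer()))
  rows <- r0:r1
  cols <- c0:c1
  dy <- rep(rows - cy, times = length(cols))
  dx <- rep(cols - cx, each = length(rows))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  list(r = rep(rows, times = length(cols))[inside],
       c = rep(cols, each = length(rows))[inside])
}
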