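#' Extract a 64 x 64 RGB patch around a centroid
#'
#' The centroid is rounded to the nearest pixel (half up) and the patch
#' covers rows `[r - 32, r + 32)` and columns likewise, in 0-based pixel
#' coordinates. Windows extending past the image are filled by mirror
#' reflection about the image edge (the edge pixel is duplicated), so every
#' detected nucleus yields a full-size patch regardless of position.
#'
#' @param field a [high_power_field()] or RGB array.
#' @param centroid numeric `(row, col)`, 0-based.
#' @return a `64 x 64 x 3` numeric array with values in `[0, 255]`.
#' @export
extract_patch <- function(field, centroid) {
  px <- if (inherits(field, "high_power_field")) field$pixels else field
  d <- dim(px)
  if (length(centroid) != 2 || any(centroid < 0) ||
      centroid[1] > d[1] - 1 || centroid[2] > d[2] - 1) {
    abort("`centroid` must be a (row, col) pair inside the field")
  }
  r0 <- round_half_up(centroid[1])
  c0 <- round_half_up(centroid[2])
  rows <- mirror_index(seq(r0 - 32L, length.out = 64L), d[1])
  cols <- mirror_index(seq(c0 - 32L, length.out = 64L), d[2])
  px[rows + 1L, cols + 1L, , drop = FALSE]
}

# reflect 0-based indices about the image edges (edge pixel duplicated):
# -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2. A single reflection suffices for
# fields of at least 64 px.
mirror_index <- function(i, n) {
  i <- ifelse(i < 0, -i - 1L, i)
  ifelse(i >= n, 2L * n - 1L - i, i)
}

#' Extract patches for a table of candidates
#'
#' @param field a [high_power_field()] or RGB array.
#' @param candidates tibble with `row` and `col` columns (0-based), e.g.
#'   from [detect_nuclei()].
#' @return an `n x 64 x 64 x 3` numeric array (n may be zero).
#' @export
extract_patches <- function(field, candidates) {
  n <- nrow(candidates)
  out <- array(0, dim = c(n, 64, 64, 3))
  for (i in seq_len(n)) {
    out[i, , , ] <- extract_patch(field, c(candidates$row[i], candidates$col[i]))
  }
  out
}

#' Label candidates from a tubule annotation
#'
#' A candidate is a `tubule` nucleus iff its centroid lies inside or on the
#' boundary of any tubule polygon (boundary-inclusive: the delineations
#' enclose the whole tubule including its nuclear ring), else `non_tubule`.
#'
#' @param candidates tibble with `field_id`, `row`, `col` columns.
#' @param annotation a [tubule_annotation()] for the same field.
#' @return `candidates` with an added `label` column
#'   (`"tubule"` / `"non_tubule"`).
#' @export
label_candidates <- function(candidates, annotation) {
  if (!inherits(annotation, "tubule_annotation")) {
    abort("`annotation` must be a tubule_annotation")
  }
  if (nrow(candidates) > 0 && "field_id" %in% names(candidates)) {
    ids <- unique(candidates$field_id)
    if (length(ids) != 1 || ids != annotation$field_id) {
      abort("candidates and annotation refer to different fields",
            class = "tubulequant_field_mismatch")
    }
  }
  inside <- rep(FALSE, nrow(candidates))
  for (p in annotation$polygons) {
    inside <- inside | pracma::inpolygon(candidates$col, candidates$row,
                                         p[, "x"], p[, "y"], boundary = TRUE)
  }
  dplyr::mutate(candidates,
                label = ifelse(inside, "tubule", "non_tubule"))
}

#' Patient-level cross-validation folds
#'
#' Randomly permutes the distinct patients (by `seed`) and deals them
#' round-robin into `k` folds, so fold sizes differ by at most one and every
#' patient -- hence every patch of that patient -- belongs to exactly one
#' fold. Splitting at the patient level prevents leakage of a patient's
#' fields between training and testing.
#'
#' @param patient_ids character vector (duplicates allowed; folds are
#'   assigned per distinct patient).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return a tibble with columns `patient_id` and `fold` (integers
#'   `1..k`).
#' @export
split_folds_by_patient <- function(patient_ids, k = 5, seed = 1L) {
  ids <- unique(patient_ids)
  if (k < 2) abort("`k` must be at least 2")
  if (length(ids) < k) abort("fewer distinct patients than folds")
  withr::local_seed(seed)
  perm <- sample(ids)
  tibble(patient_id = perm,
         fold = rep_len(seq_len(k), length(perm))) |>
    dplyr::arrange(.data$patient_id)
}
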