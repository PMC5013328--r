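#' Risk-group sampling rules
#'
#' The cohort generator understands the standard Oncotype DX / Bloom-
#' Richardson group labels. ODX scores and BR grades are sampled uniformly
#' from the configured ranges, which must satisfy the group's defining rule
#' so that every emitted slide belongs to its group by construction:
#' `HH` requires ODX > 30 and BR > 7; `LL` requires ODX < 18 and BR < 6;
#' `HIGH_ODX` ODX > 30; `LOW_ODX` ODX < 18; `INTERMEDIATE_ODX`
#' 18 <= ODX <= 30.
#'
#' @name risk-group-rules
#' @keywords internal
NULL

group_rule_ok <- function(label, odx, br) {
  switch(label,
    HH = odx > 30 & br > 7,
    LL = odx < 18 & br < 6,
    HIGH_ODX = odx > 30,
    LOW_ODX = odx < 18,
    INTERMEDIATE_ODX = odx >= 18 & odx <= 30,
    abort(sprintf("unknown group label '%s'", label))
  )
}

#' Per-group sampling specification
#'
#' @param n_wsi number of slides (one patient per slide).
#' @param mean_tfi_target target mean ground-truth tubule-formation
#'   indicator per field for this group; converted to a tubule-count
#'   Poisson rate with [calibrate_tubule_lambda()]. Exactly one of
#'   `mean_tfi_target` and `tubule_lambda` must be given.
#' @param tubule_lambda per-field tubule-count Poisson rate (truncated at
#'   `max_tubules`), given directly.
#' @param odx_values integer ODX scores to sample from.
#' @param br_values integer BR grades (3-9) to sample from.
#' @param max_tubules truncation point of the tubule-count distribution.
#' @return a list of class `group_spec`.
#' @export
group_spec <- function(n_wsi, mean_tfi_target = NULL, tubule_lambda = NULL,
                       odx_values, br_values, max_tubules = 4) {
  if (n_wsi < 0) abort("`n_wsi` must be non-negative")
  if (is.null(mean_tfi_target) == is.null(tubule_lambda)) {
    abort("give exactly one of `mean_tfi_target` or `tubule_lambda`")
  }
  if (any(br_values < 3 | br_values > 9)) {
    abort("`br_values` must lie in the Bloom-Richardson range 3..9")
  }
  structure(
    list(n_wsi = as.integer(n_wsi), mean_tfi_target = mean_tfi_target,
         tubule_lambda = tubule_lambda,
         odx_values = as.integer(odx_values),
         br_values = as.integer(br_values),
         max_tubules = as.integer(max_tubules)),
    class = "group_spec"
  )
}

#' Calibrate the tubule-count rate to a target mean TFI
#'
#' With `T ~ Poisson(lambda)` truncated at `max_tubules`, a ring of `m`
#' nuclei per tubule and `F` free nuclei per field, the expected per-field
#' ground-truth TFI is `E[mT / (mT + F)]`. This solves for the `lambda`
#' that attains a requested expectation, so synthetic cohorts can be pinned
#' to observed group means (e.g. 0.126 for low-risk-like and 0.029 for
#' high-risk-like slides).
#'
#' @param target_tfi desired expected per-field TFI, in `(0, 1)`.
#' @param n_free free (non-tubule) nuclei per field.
#' @param ring_size nuclei per tubule ring.
#' @param max_tubules truncation point of the Poisson tubule count.
#' @return the calibrated rate `lambda`.
#' @export
calibrate_tubule_lambda <- function(target_tfi, n_free, ring_size,
                                    max_tubules = 4) {
  if (target_tfi <= 0 || target_tfi >= 1) abort("`target_tfi` must be in (0, 1)")
  expected <- function(lambda) {
    t <- 0:max_tubules
    p <- stats::dpois(t, lambda)
    p <- p / sum(p)
    sum(p * (ring_size * t) / (ring_size * t + n_free))
  }
  upper <- max_tubules
  if (expected(upper) < target_tfi) {
    abort("`target_tfi` not attainable: raise `ring_size` or lower `n_free`")
  }
  stats::uniroot(function(l) expected(l) - target_tfi,
                 lower = 1e-9, upper = upper, tol = 1e-10)$root
}

expected_tfi_for_lambda <- function(lambda, n_free, ring_size, max_tubules = 4) {
  t <- 0:max_tubules
  p <- stats::dpois(t, lambda)
  p <- p / sum(p)
  sum(p * (ring_size * t) / (ring_size * t + n_free))
}

#' Configuration of a synthetic cohort
#'
#' A cohort is a set of labelled slide groups; each slide (one patient per
#' slide) contributes `hpfs_per_wsi` high power fields whose per-field
#' tubule counts follow the group's truncated-Poisson density. ODX scores
#' and BR grades are sampled from the group's value sets and are checked
#' against the group rule at configuration time.
#'
#' @param groups named list of [group_spec()]s; names must be known group
#'   labels (see [risk-group-rules]).
#' @param hpfs_per_wsi fields generated per slide.
#' @param field_template a [field_config()] providing field geometry,
#'   colours and the free-nucleus count shared by all groups.
#' @param seed integer seed for the whole cohort.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(groups, hpfs_per_wsi = 10,
                          field_template = field_config(), seed = 1L) {
  if (length(groups) == 0 || is.null(names(groups)) ||
      any(names(groups) == "")) {
    abort("`groups` must be a named list of group_spec objects")
  }
  if (hpfs_per_wsi < 1) abort("`hpfs_per_wsi` must be positive")
  for (label in names(groups)) {
    g <- groups[[label]]
    if (!inherits(g, "group_spec")) abort("each group must be a group_spec")
    grid <- expand.grid(odx = g$odx_values, br = g$br_values)
    if (!all(group_rule_ok(label, grid$odx, grid$br))) {
      abort(sprintf("ODX/BR values for group '%s' violate its rule", label))
    }
  }
  structure(
    list(groups = groups, hpfs_per_wsi = as.integer(hpfs_per_wsi),
         field_template = field_template, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default two-group study cohort
#'
#' High-risk-like (`HH`: ODX > 30 and BR > 7) and low-risk-like (`LL`:
#' ODX < 18 and BR < 6) slides with tubule densities calibrated so the
#' expected ground-truth TFI per field is 0.029 and 0.126 respectively --
#' the observed group means this generator emulates.
#'
#' @param n_hh,n_ll slides per group.
#' @param hpfs_per_wsi fields per slide.
#' @param field_template a [field_config()].
#' @param seed integer seed.
#' @return a [cohort_config()].
#' @export
default_cohort_config <- function(n_hh = 15, n_ll = 15, hpfs_per_wsi = 10,
                                  field_template = field_config(),
                                  seed = 1L) {
  cohort_config(
    groups = list(
      HH = group_spec(n_hh, mean_tfi_target = 0.029,
                      odx_values = 31:50, br_values = 8:9),
      LL = group_spec(n_ll, mean_tfi_target = 0.126,
                      odx_values = 2:17, br_values = 3:5)
    ),
    hpfs_per_wsi = hpfs_per_wsi,
    field_template = field_template,
    seed = seed
  )
}

#' Generate a synthetic cohort
#'
#' Samples slide metadata (ODX score, BR grade) and per-field tubule counts
#' for every group, and derives one child seed per field so that fields can
#' be materialised lazily and reproducibly with [realize_field()]. When
#' `dir` is given the whole cohort is also written to disk via
#' [write_cohort()].
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory.
#' @return a list of class `synthetic_cohort` with `metadata` (tibble:
#'   `wsi_id`, `patient_id`, `odx_score`, `br_grade`, `group_label`),
#'   `fields` (tibble: `wsi_id`, `field_id`, `n_tubules`, `field_seed`) and
#'   the originating `config`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config")
  withr::local_seed(config$seed)

  ft <- config$field_template
  meta <- list()
  fields <- list()
  for (label in names(config$groups)) {
    g <- config$groups[[label]]
    lambda <- g$tubule_lambda %||% calibrate_tubule_lambda(
      g$mean_tfi_target, n_free = ft$n_free_nuclei,
      ring_size = ft$nuclei_per_tubule_ring, max_tubules = g$max_tubules)
    if (g$n_wsi == 0) next
    for (i in seq_len(g$n_wsi)) {
      wsi_id <- sprintf("%s_wsi%03d", label, i)
      odx <- sample(g$odx_values, 1)
      br <- sample(g$br_values, 1)
      stopifnot(group_rule_ok(label, odx, br))
      meta[[length(meta) + 1]] <- tibble(
        wsi_id = wsi_id, patient_id = paste0(wsi_id, "_pt"),
        odx_score = odx, br_grade = br, group_label = label)
      nt <- sample(0:g$max_tubules, config$hpfs_per_wsi, replace = TRUE,
                   prob = stats::dpois(0:g$max_tubules, lambda))
      fields[[length(fields) + 1]] <- tibble(
        wsi_id = wsi_id,
        field_id = sprintf("%s_f%03d", wsi_id, seq_len(config$hpfs_per_wsi)),
        n_tubules = nt,
        field_seed = draw_seeds(config$hpfs_per_wsi))
    }
  }
  metadata <- if (length(meta)) dplyr::bind_rows(meta) else
    tibble(wsi_id = character(), patient_id = character(),
           odx_score = integer(), br_grade = integer(),
           group_label = character())
  field_tbl <- if (length(fields)) dplyr::bind_rows(fields) else
    tibble(wsi_id = character(), field_id = character(),
           n_tubules = integer(), field_seed = integer())

  cohort <- structure(list(metadata = metadata, fields = field_tbl,
                           config = config),
                      class = "synthetic_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d slide(s), %d field(s)\n",
              nrow(x$metadata), nrow(x$fields)))
  print(dplyr::count(x$metadata, .data$group_label))
  invisible(x)
}

#' Materialise one field of a synthetic cohort
#'
#' Regenerates a cohort field from its stored per-field seed; repeated calls
#' return identical artifacts, so cohorts can be streamed without holding
#' every image in memory.
#'
#' @param cohort a [generate_cohort()] result.
#' @param field_id one of `cohort$fields$field_id`.
#' @return a `synthetic_field` (see [generate_field()]).
#' @export
realize_field <- function(cohort, field_id) {
  if (!inherits(cohort, "synthetic_cohort")) abort("`cohort` must be a synthetic_cohort")
  row <- cohort$fields[cohort$fields$field_id == field_id, ]
  if (nrow(row) != 1) abort(sprintf("unknown field_id '%s'", field_id))
  ft <- cohort$config$field_template
  cfg <- ft
  cfg$n_tubules <- row$n_tubules
  cfg$seed <- row$field_seed
  cfg$field_id <- row$field_id
  cfg$wsi_id <- row$wsi_id
  cfg$patient_id <- cohort$metadata$patient_id[
    match(row$wsi_id, cohort$metadata$wsi_id)]
  generate_field(cfg)
}

#' Write a synthetic cohort to disk
#'
#' Layout: `metadata.csv` (slide table), `fields.csv` (per-field tubule
#' counts and seeds), `images/<field_id>.png` (8-bit RGB),
#' `annotations/<field_id>.geojson` and `nuclei.csv` with the ground-truth
#' nucleus table (`field_id`, `row`, `col`, `is_tubule`, `tubule_id`).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$fields[, c("wsi_id", "field_id", "n_tubules",
                                     "field_seed")],
                   file.path(dir, "fields.csv"), row.names = FALSE)
  all_nuclei <- list()
  for (fid in cohort$fields$field_id) {
    sf <- realize_field(cohort, fid)
    png::writePNG(sf$field$pixels / 255,
                  file.path(dir, "images", paste0(fid, ".png")))
    write_annotation_geojson(sf$annotation,
                             file.path(dir, "annotations",
                                       paste0(fid, ".geojson")))
    all_nuclei[[fid]] <- dplyr::mutate(sf$nuclei, field_id = fid,
                                       .before = 1)
  }
  nuc <- if (length(all_nuclei)) dplyr::bind_rows(all_nuclei) else
    tibble(field_id = character(), nucleus_id = character(), row = double(),
           col = double(), is_tubule = logical(), tubule_id = character())
  utils::write.csv(nuc, file.path(dir, "nuclei.csv"), row.names = FALSE)
  invisible(dir)
}
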