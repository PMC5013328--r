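test_that("generator is deterministic and handles degenerate configs", {
  cfg <- field_config(seed = 31)
  a <- generate_field(cfg)
  b <- generate_field(cfg)
  expect_identical(a$field$pixels, b$field$pixels)
  expect_identical(a$nuclei, b$nuclei)
  expect_identical(a$annotation$polygons, b$annotation$polygons)

  no_tub <- generate_field(field_config(n_tubules = 0, seed = 5))
  expect_length(no_tub$annotation, 0)
  expect_false(any(no_tub$nuclei$is_tubule))

  empty <- generate_field(field_config(n_tubules = 0, n_free_nuclei = 0,
                                       seed = 5))
  expect_equal(nrow(empty$nuclei), 0)
  expect_equal(dim(empty$field$pixels), c(224, 224, 3))
})

test_that("tubule rings surround lumina and respect the configured counts", {
  cfg <- field_config(n_tubules = 2, n_free_nuclei = 20, seed = 9)
  sf <- generate_field(cfg)
  expect_length(sf$annotation, 2)
  expect_equal(sum(sf$nuclei$is_tubule), 2 * cfg$nuclei_per_tubule_ring)
  expect_equal(sum(!sf$nuclei$is_tubule), 20)
  expect_true(all(sf$nuclei$row >= 0 & sf$nuclei$row <= 223))
  expect_true(all(sf$nuclei$col >= 0 & sf$nuclei$col <= 223))
  # is_tubule iff a parent tubule id is present
  expect_identical(sf$nuclei$is_tubule, !is.na(sf$nuclei$tubule_id))
})

test_that("ground-truth labels agree with the rasterized annotation mask", {
  for (seed in c(2, 12, 22)) {
    sf <- generate_field(field_config(n_tubules = 2, seed = seed))
    mask <- rasterize_annotation(sf$annotation, dim(sf$field$pixels)[1:2])
    at_centroid <- mask[cbind(round_half_up(sf$nuclei$row) + 1,
                              round_half_up(sf$nuclei$col) + 1)] == 1
    expect_identical(at_centroid, sf$nuclei$is_tubule)
  }
})

test_that("impossible placements raise a placement failure", {
  cfg <- field_config(field_height_px = 70, field_width_px = 70,
                      n_tubules = 2, n_free_nuclei = 0, seed = 1)
  expect_error(generate_field(cfg), class = "tubulequant_placement_error")
  crowded <- field_config(n_free_nuclei = 2000, n_tubules = 0,
                          max_attempts = 50, seed = 1)
  expect_error(generate_field(crowded), class = "tubulequant_placement_error")
})

test_that("rasterization matches a brute-force point-in-polygon oracle", {
  square <- tubule_annotation(
    list(cbind(x = c(3, 12, 12, 3), y = c(4, 4, 13, 13))), "f")
  mask <- rasterize_annotation(square, c(20, 20))
  # exhaustive pixel-centre evaluation for an axis-aligned rectangle
  oracle <- outer(0:19, 0:19,
                  function(r, c) c >= 3 & c <= 12 & r >= 4 & r <= 13)
  expect_equal(mask == 1, oracle)
  expect_equal(sum(mask), 100)

  empty <- tubule_annotation(list(), "f")
  expect_true(all(rasterize_annotation(empty, c(8, 8)) == 0))

  whole <- tubule_annotation(
    list(cbind(x = c(-1, 8, 8, -1), y = c(-1, -1, 8, 8))), "f")
  expect_true(all(rasterize_annotation(whole, c(8, 8)) == 1))

  bowtie <- list(cbind(x = c(0, 4, 4, 0), y = c(0, 4, 0, 4)))
  expect_error(tubule_annotation(bowtie, "f"), "self-intersecting")
})

test_that("geojson annotations round-trip", {
  sf <- generate_field(field_config(n_tubules = 3, seed = 77))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_annotation_geojson(sf$annotation, path)
  back <- read_annotation_geojson(path)
  expect_equal(back$field_id, sf$annotation$field_id)
  expect_equal(length(back), length(sf$annotation))
  for (id in names(sf$annotation$polygons)) {
    expect_equal(back$polygons[[id]], sf$annotation$polygons[[id]],
                 tolerance = 1e-12)
  }
})

test_that("cohort generation respects group rules and is reproducible", {
  cc <- default_cohort_config(n_hh = 4, n_ll = 5, hpfs_per_wsi = 2, seed = 88)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$fields, b$fields)

  hh <- a$metadata[a$metadata$group_label == "HH", ]
  ll <- a$metadata[a$metadata$group_label == "LL", ]
  expect_equal(nrow(hh), 4)
  expect_true(all(hh$odx_score > 30 & hh$br_grade > 7))
  expect_true(all(ll$odx_score < 18 & ll$br_grade < 6))
  expect_equal(nrow(a$fields), 9 * 2)

  # unknown group labels are rejected
  expect_error(
    cohort_config(groups = list(XX = group_spec(
      1, tubule_lambda = 1, odx_values = 1:5, br_values = 3:5))),
    "unknown group label")
  # a rule-violating sampling range is rejected
  expect_error(
    cohort_config(groups = list(HH = group_spec(
      1, tubule_lambda = 1, odx_values = 20:40, br_values = 8:9))),
    "violate")

  empty <- generate_cohort(cohort_config(
    groups = list(HH = group_spec(0, tubule_lambda = 0.2,
                                  odx_values = 31:40, br_values = 8:9)),
    seed = 1))
  expect_equal(nrow(empty$metadata), 0)
  expect_named(empty$metadata, c("wsi_id", "patient_id", "odx_score",
                                 "br_grade", "group_label"))
})

test_that("a written cohort round-trips images, polygons and tables", {
  cc <- default_cohort_config(n_hh = 1, n_ll = 1, hpfs_per_wsi = 1, seed = 12)
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cc, dir = dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  meta <- utils::read.csv(file.path(dir, "metadata.csv"))
  expect_equal(nrow(meta), 2)
  fid <- cohort$fields$field_id[1]
  img <- png::readPNG(file.path(dir, "images", paste0(fid, ".png")))
  sf <- realize_field(cohort, fid)
  expect_equal(round(img * 255), sf$field$pixels, ignore_attr = TRUE)
  ann <- read_annotation_geojson(file.path(dir, "annotations",
                                           paste0(fid, ".geojson")))
  expect_equal(length(ann), length(sf$annotation))
})

test_that("tubule density calibration hits the requested mean TFI", {
  for (target in c(0.029, 0.126)) {
    lam <- calibrate_tubule_lambda(target, n_free = 30, ring_size = 8)
    expect_equal(tubulequant:::expected_tfi_for_lambda(lam, 30, 8), target,
                 tolerance = 1e-6)
  }
  # over generated fields the ground-truth TFI mean lands near the target
  cc <- default_cohort_config(n_hh = 6, n_ll = 6, hpfs_per_wsi = 10,
                              seed = 314)
  cohort <- generate_cohort(cc)
  gt <- purrr::map_dfr(cohort$fields$field_id, function(fid) {
    nuc <- realize_field(cohort, fid)$nuclei
    tibble::tibble(wsi_id = cohort$fields$wsi_id[
      cohort$fields$field_id == fid],
      tfi = mean(nuc$is_tubule))
  })
  gt <- dplyr::left_join(gt, cohort$metadata, by = "wsi_id")
  means <- tapply(gt$tfi, gt$group_label, mean)
  expect_lt(abs(means[["HH"]] - 0.029), 0.03)
  expect_lt(abs(means[["LL"]] - 0.126), 0.03)
})
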