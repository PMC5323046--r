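test_that("segmentation recovers planted cells and handles degenerate frames", {
  blank <- list(channels = list(nuclear = matrix(0, 128, 128),
                                marker = matrix(0, 128, 128)))
  expect_warning(seg0 <- segment_cells(blank), "0 cells")
  expect_equal(nrow(seg0$cells), 0)

  img <- render_well_image(10, spots_per_cell = 0, size = 256, seed = 7)
  seg <- segment_cells(img)
  expect_equal(nrow(seg$cells), 10)
  err <- vapply(seq_len(10), function(i) {
    min(sqrt((seg$cells$row - (img$cells$row[i] - 1))^2 +
               (seg$cells$col - (img$cells$col[i] - 1))^2))
  }, numeric(1))
  expect_true(all(err <= 2))
  # nucleus inside cell, masks consistent
  expect_true(all(seg$cells$nucleus_area > 0))
  expect_true(all(seg$nucleus_labels[seg$nucleus_labels > 0] ==
                    seg$cell_labels[seg$nucleus_labels > 0]))
})

test_that("touching nuclei are split by the distance-transform watershed", {
  merged <- disc_image(nuc_centers = rbind(c(60, 58), c(60, 69)),
                       nuc_radius = 6, cyto_radius = 28)
  seg <- segment_cells(merged)
  expect_equal(nrow(seg$cells), 2)
  # and a single nucleus stays single
  single <- disc_image(nuc_centers = rbind(c(60, 64)), nuc_radius = 6,
                       cyto_radius = 28)
  expect_equal(nrow(segment_cells(single)$cells), 1)
})

test_that("spot detection is exact on clean images and filters correctly", {
  img <- render_well_image(10, spots_per_cell = 5, size = 256, seed = 3,
                           noise_sd = 1, illumination = 0)
  seg <- segment_cells(img)
  spots <- detect_spots(img, seg$cell_labels)
  expect_equal(nrow(spots), 50)
  mm <- match_spots(img$spots, spots)
  # every planted spot matched and assigned to the planted owner cell
  expect_true(all(!is.na(mm$detected)))
  # detected owner ids come from segmentation; map via nearest nucleus
  owner_ok <- vapply(seq_len(nrow(img$cells)), function(i) {
    det_cells <- mm$cell[mm$true_cell == i]
    length(unique(det_cells)) == 1
  }, logical(1))
  expect_true(all(owner_ok))

  # maximal contrast threshold kills everything on a noisy image
  noisy <- render_well_image(5, spots_per_cell = 3, size = 128, seed = 5)
  segn <- segment_cells(noisy)
  none <- detect_spots(noisy, segn$cell_labels,
                       params = list(contrast_threshold = 1))
  expect_equal(nrow(none), 0)

  # a 1 px spot is excluded at min_area 2, kept at min_area 1
  one_px <- disc_image(nuc_centers = rbind(c(40, 40)), cyto_radius = 25,
                       marker_px = rbind(c(45, 50)), marker_val = 800)
  segp <- segment_cells(one_px)
  s2 <- detect_spots(one_px, segp$cell_labels,
                     params = list(min_area = 2, flatfield = FALSE))
  s1 <- detect_spots(one_px, segp$cell_labels,
                     params = list(min_area = 1, flatfield = FALSE))
  expect_equal(nrow(s2), 0)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$area, 1)

  # flat marker channel -> empty list, no error
  flat <- list(channels = list(nuclear = one_px$channels$nuclear,
                               marker = matrix(5, 128, 128)))
  expect_equal(nrow(detect_spots(flat, segp$cell_labels)), 0)
})

test_that("every retained spot lies inside exactly one cytoplasm mask", {
  img <- render_well_image(8, spots_per_cell = 4, size = 256, seed = 9)
  seg <- segment_cells(img)
  spots <- detect_spots(img, seg$cell_labels)
  idx <- cbind(pmin(pmax(round(spots$row + 1), 1), 256),
               pmin(pmax(round(spots$col + 1), 1), 256))
  labs <- seg$cell_labels[idx]
  expect_true(all(labs > 0))
  expect_equal(labs, spots$cell)
})

test_that("raising detection thresholds never increases spot counts", {
  for (s in 1:10) {
    img <- render_well_image(5, spots_per_cell = 4, size = 128, seed = s,
                             spot_amplitude = stats::runif(1, 100, 400))
    seg <- segment_cells(img)
    prev_i <- Inf
    for (thr in c(0, 50, 120, 250, 500)) {
      n <- nrow(detect_spots(img, seg$cell_labels,
                             params = list(intensity_threshold = thr)))
      expect_lte(n, prev_i)
      prev_i <- n
    }
    prev_c <- Inf
    for (thr in c(0, 0.3, 0.6, 0.9)) {
      n <- nrow(detect_spots(img, seg$cell_labels,
                             params = list(contrast_threshold = thr)))
      expect_lte(n, prev_c)
      prev_c <- n
    }
  }
})

test_that("well summaries follow the per-cell averaging contract", {
  cells <- data.frame(cell = 1:10, row = 1:10, col = 1:10,
                      nucleus_area = 100, nucleus_mean_intensity = 900,
                      cytoplasm_area = 500, cytoplasm_mean_intensity = 250)
  spots <- data.frame(spot = 1:50, cell = rep(1:10, each = 5),
                      row = 1, col = 1, area = 4, mean_intensity = 100,
                      peak_corrected = 80, integrated = 200,
                      contrast = 0.5)
  s <- summarize_well(cells, spots)
  expect_equal(s$spots_per_cell, 5.0)
  expect_equal(s$iss_per_cell, 200 * 5)

  none <- spots[0, ]
  s0 <- summarize_well(cells, none)
  expect_equal(s0$spots_per_cell, 0.0)
  expect_equal(s0$iss_per_cell, 0.0)

  # one cell with spots of corrected integrals 100 and 50, 10 cells
  two <- data.frame(spot = 1:2, cell = c(1, 1), row = 1, col = 1,
                    area = 4, mean_intensity = 10, peak_corrected = 8,
                    integrated = c(100, 50), contrast = 0.5)
  expect_equal(summarize_well(cells, two)$iss_per_cell, 15.0)

  empty <- summarize_well(cells[0, ], none)
  expect_equal(empty$n_cells, 0)
  expect_true(is.na(empty$spots_per_cell))
  expect_true(empty$low_coverage)

  bad <- data.frame(spot = 1, cell = 99, row = 1, col = 1, area = 4,
                    mean_intensity = 1, peak_corrected = 1,
                    integrated = 1, contrast = 0.1)
  expect_error(summarize_well(cells, bad), "unknown cells")
})

test_that("coalescence percentages and tandem classification enumerate correctly", {
  a <- data.frame(row = c(0, 10, 20, 30), col = c(0, 10, 20, 30))
  expect_equal(unname(colocalize_spots(a, a, radius = 3)), c(100, 100))

  b <- data.frame(row = a$row + 50, col = a$col + 50)
  expect_equal(unname(colocalize_spots(a, b, radius = 3)), c(0, 0))

  one_b <- data.frame(row = 1, col = 1)
  expect_equal(unname(colocalize_spots(a, one_b, radius = 3)), c(25, 100))

  expect_true(all(is.na(colocalize_spots(a[0, ], one_b, radius = 3))))
  expect_error(colocalize_spots(a, b, radius = 0), "radius")

  red <- data.frame(row = c(1, 10, 20, 30, 40, 50),
                    col = c(1, 10, 20, 30, 40, 50))
  green <- data.frame(row = c(1, 10, 20, 30), col = c(1, 10, 20, 30))
  r <- classify_tandem(red, green, radius = 3)
  expect_equal(r$n_autophagosomes, 4)
  expect_equal(r$n_autolysosomes, 2)
  expect_equal(r$ratio, 2.0)

  all_paired <- classify_tandem(green, green, radius = 3)
  expect_equal(all_paired$n_autolysosomes, 0)
  expect_true(is.na(all_paired$ratio))

  no_green <- classify_tandem(red, green[0, ], radius = 3)
  expect_equal(no_green$n_autolysosomes, 6)
  expect_equal(no_green$ratio, 0.0)
})

test_that("PGM and well-image round trips are lossless and deterministic", {
  m <- matrix(stats::runif(64 * 48, 0, 900), 48, 64)
  tf <- tempfile(fileext = ".pgm")
  write_pgm(m, tf)
  back <- read_pgm(tf)
  expect_equal(back, m, tolerance = 0.051)  # 0.1 AU quantization

  img <- render_well_image(3, spots_per_cell = 2, size = 128, seed = 4)
  stem1 <- tempfile(); stem2 <- tempfile()
  write_well_image(img, stem1)
  write_well_image(img, stem2)
  expect_identical(readLines(paste0(stem1, "_marker.pgm")),
                   readLines(paste0(stem2, "_marker.pgm")))
  back_img <- read_well_image(stem1)
  expect_equal(back_img$channels$nuclear, img$channels$nuclear,
               tolerance = 0.051)
  expect_equal(back_img$spots$integral, img$spots$integral)
})
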