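#' Segment nuclei and cytoplasm from the nuclear/cytoplasm channel
#'
#' Segmentation starts from the nuclei: the stain channel is thresholded
#' twice (Otsu on the full frame separates background from cells; Otsu
#' within the cell foreground separates the dim cytoplasm from the bright
#' nuclei). Nucleus components below the minimum area are dropped; merged
#' nuclei are split by seeding at local maxima of the distance transform
#' (minimum seed separation) and geodesically growing the seed labels, a
#' marker-based watershed. Cytoplasm is then assigned by seeded region
#' growing from each nucleus, bounded by the cytoplasm-stain mask.
#'
#' @param image Two-channel image: the list returned by
#'   [render_well_image()] or a bare `list(nuclear =, marker =)` of
#'   matrices.
#' @param params List overriding any of: `min_nucleus_area` (px^2, default
#'   20), `min_seed_sep` (px, default 6), `foreground_threshold`,
#'   `nucleus_threshold` (absolute intensities; default automatic Otsu),
#'   `exclude_border` (drop cells touching the frame, default FALSE),
#'   `nuclear_channel` (name/index of the stain channel, default
#'   `"nuclear"`).
#' @return List of class `segmentation`: `cells` (data.frame: `cell`,
#'   `row`, `col` intensity-weighted nucleus centroid, 0-based px,
#'   `nucleus_area`, `nucleus_mean_intensity`, `cytoplasm_area`,
#'   `cytoplasm_mean_intensity`), `nucleus_labels` and `cell_labels`
#'   (integer matrices), `thresholds`. An empty or saturated frame yields
#'   zero cells with a warning, never an error.
#' @export
segment_cells <- function(image, params = list()) {
  p <- utils::modifyList(
    list(min_nucleus_area = 20, min_seed_sep = 6,
         foreground_threshold = NULL, nucleus_threshold = NULL,
         exclude_border = FALSE, nuclear_channel = "nuclear"),
    params)
  ch <- if (!is.null(image$channels)) image$channels[[p$nuclear_channel]]
  else image[[p$nuclear_channel]]
  assert_that(is.matrix(ch), "segment_cells: nuclear channel missing")

  empty <- function(msg) {
    warning(sprintf("segment_cells: %s; returning 0 cells", msg))
    list(cells = data.frame(cell = integer(), row = numeric(),
                            col = numeric(), nucleus_area = numeric(),
                            nucleus_mean_intensity = numeric(),
                            cytoplasm_area = numeric(),
                            cytoplasm_mean_intensity = numeric()),
         nucleus_labels = matrix(0L, nrow(ch), ncol(ch)),
         cell_labels = matrix(0L, nrow(ch), ncol(ch)),
         thresholds = c(foreground = NA_real_, nucleus = NA_real_))
  }
  if (diff(range(ch)) == 0) return(empty("flat (empty or saturated) image"))

  t_fg <- p$foreground_threshold %||% otsu_threshold(as.numeric(ch))
  fg <- ch > t_fg
  if (!any(fg) || mean(fg) > 0.95) {
    return(empty("no usable foreground/background separation"))
  }
  t_nuc <- p$nucleus_threshold %||% otsu_threshold(ch[fg])
  nuc_mask <- ch > t_nuc
  if (!any(nuc_mask)) return(empty("no nuclei above threshold"))

  comp <- label_components(nuc_mask)
  sizes <- tabulate(comp[comp > 0])
  small <- which(sizes < p$min_nucleus_area)
  if (length(small)) {
    nuc_mask[comp %in% small] <- FALSE
  }
  if (!any(nuc_mask)) return(empty("no nuclei above minimum area"))

  # Split touching nuclei: distance-transform seeds + geodesic growth.
  dt <- distance_transform(nuc_mask)
  seeds <- local_maxima(dt, nuc_mask, p$min_seed_sep)
  lab <- matrix(0L, nrow(ch), ncol(ch))
  lab[seeds] <- seq_len(nrow(seeds))
  nuc_lab <- propagate_labels(lab, nuc_mask)

  # Cytoplasm: grow nucleus labels through the stain foreground.
  cell_lab <- propagate_labels(nuc_lab, fg)

  ids <- sort(unique(nuc_lab[nuc_lab > 0]))
  if (p$exclude_border) {
    h <- nrow(ch); w <- ncol(ch)
    border <- unique(c(cell_lab[1, ], cell_lab[h, ], cell_lab[, 1],
                       cell_lab[, w]))
    drop <- intersect(ids, border[border > 0])
    nuc_lab[nuc_lab %in% drop] <- 0L
    cell_lab[cell_lab %in% drop] <- 0L
    ids <- setdiff(ids, drop)
  }

  rows <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    npx <- which(nuc_lab == id, arr.ind = TRUE)
    cpx_n <- sum(cell_lab == id) - nrow(npx)
    wgt <- ch[npx]
    rows[[i]] <- data.frame(
      cell = i,
      row = sum((npx[, 1] - 1) * wgt) / sum(wgt),
      col = sum((npx[, 2] - 1) * wgt) / sum(wgt),
      nucleus_area = nrow(npx),
      nucleus_mean_intensity = mean(wgt),
      cytoplasm_area = max(cpx_n, 0),
      cytoplasm_mean_intensity = if (cpx_n > 0) {
        mean(ch[cell_lab == id & nuc_lab != id])
      } else NA_real_)
    # renumber masks to compact ids
    if (id != i) {
      nuc_lab[nuc_lab == id] <- i
      cell_lab[cell_lab == id] <- i
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  structure(list(cells = cells, nucleus_labels = nuc_lab,
                 cell_labels = cell_lab,
                 thresholds = c(foreground = t_fg, nucleus = t_nuc)),
            class = "segmentation")
}

#' Detect cytosolic spots in the marker channel
#'
#' The marker channel is first flat-field corrected (block-median
#' estimate of the smooth illumination profile, divided out) and smoothed
#' with a 3x3 box for detection only. Candidate maxima are local maxima
#' (minimum separation `split_sep`) of the smoothed channel inside the
#' mask of pixels exceeding the robust background level by `detect_k`
#' noise SDs of the smoothed channel; mask pixels are assigned to
#' their nearest maximum, so touching spots are split rather than merged.
#' Each candidate gets an intensity-weighted centroid, an area, a local
#' background from a median annulus around its integration disk (annulus
#' pixels covered by other candidates are excluded), a
#' background-corrected integrated intensity over an adaptive disk
#' (pixels assigned to other candidates excluded), and a contrast
#' `(mean - background) / (mean + background)`. Candidates are then
#' filtered by minimum area, background-corrected peak intensity and
#' contrast; spots whose centroid lies outside every cytoplasm mask are
#' discarded. Raising `intensity_threshold` or `contrast_threshold` can
#' only shrink the fixed candidate set, so detection is monotone in both.
#'
#' @param image Two-channel image (see [segment_cells()]).
#' @param cell_labels Integer label matrix of cell (cytoplasm) masks, e.g.
#'   `segment_cells(...)$cell_labels`.
#' @param params List overriding any of: `min_area` (px^2, default 2),
#'   `intensity_threshold` (AU over local background, default 0),
#'   `contrast_threshold` (default 0), `detect_k` (default 3),
#'   `split_sep` (minimum maxima separation in px, default 3),
#'   `annulus_gap` (default 1), `annulus_width` (default 3),
#'   `flatfield` (default TRUE), `marker_channel` (default `"marker"`).
#' @return data.frame (`spot_records`): `spot`, `cell`, `row`, `col`
#'   (0-based px), `area`, `mean_intensity`, `peak_corrected`,
#'   `integrated` (background-corrected), `contrast`.
#' @export
detect_spots <- function(image, cell_labels, params = list()) {
  p <- utils::modifyList(
    list(min_area = 2, intensity_threshold = 0, contrast_threshold = 0,
         detect_k = 3, split_sep = 3, annulus_gap = 1, annulus_width = 3,
         flatfield = TRUE, marker_channel = "marker"),
    params)
  m <- if (!is.null(image$channels)) image$channels[[p$marker_channel]]
  else image[[p$marker_channel]]
  assert_that(is.matrix(m), "detect_spots: marker channel missing")
  assert_that(is.matrix(cell_labels), "detect_spots: cell masks required")
  assert_that(p$intensity_threshold >= 0 && p$contrast_threshold >= 0,
              "detect_spots: thresholds must be >= 0")

  empty_spots <- data.frame(
    spot = integer(), cell = integer(), row = numeric(), col = numeric(),
    area = numeric(), mean_intensity = numeric(),
    peak_corrected = numeric(), integrated = numeric(),
    contrast = numeric())
  if (diff(range(m)) == 0) return(empty_spots)

  if (p$flatfield) m <- flatfield_correct(m)
  sm <- box_filter3(m)
  bg <- background_stats(m)
  bg_sm <- background_stats(sm)
  cand_mask <- sm > bg_sm$level + p$detect_k * bg_sm$noise_sd
  if (!any(cand_mask)) return(empty_spots)
  h <- nrow(m); w <- ncol(m)

  # Split touching spots: maxima are found on the smoothed channel; spot
  # pixel sets come from the raw threshold mask, assigned to their nearest
  # maximum (so area keeps its raw-pixel meaning).
  maxima <- local_maxima(sm, cand_mask, p$split_sep)
  if (!nrow(maxima)) return(empty_spots)
  # refine each maximum to the raw-channel argmax in its 3x3 neighborhood
  # (box smoothing can shift plateau maxima by a pixel)
  for (k in seq_len(nrow(maxima))) {
    rr <- max(1, maxima[k, 1] - 1):min(h, maxima[k, 1] + 1)
    cc <- max(1, maxima[k, 2] - 1):min(w, maxima[k, 2] + 1)
    loc <- which(m[rr, cc, drop = FALSE] ==
                   max(m[rr, cc, drop = FALSE]), arr.ind = TRUE)[1, ]
    maxima[k, ] <- c(rr[loc[1]], cc[loc[2]])
  }
  raw_mask <- m > bg$level + p$detect_k * bg$noise_sd
  raw_mask[maxima] <- TRUE
  mask_px <- which(raw_mask, arr.ind = TRUE)
  d2 <- outer(mask_px[, 1], maxima[, 1], "-")^2 +
    outer(mask_px[, 2], maxima[, 2], "-")^2
  assign_id <- max.col(-d2, ties.method = "first")
  # raw pixels far from every maximum are isolated noise, not spot pixels
  near_enough <- d2[cbind(seq_len(nrow(mask_px)), assign_id)] <= 8^2
  mask_px <- mask_px[near_enough, , drop = FALSE]
  assign_id <- assign_id[near_enough]
  comp <- matrix(0L, h, w)
  comp[mask_px] <- assign_id
  n_comp <- nrow(maxima)

  # Integration radius follows the smoothed detection support (tracks the
  # true spot extent better than the raw core for faint spots).
  sm_px <- which(cand_mask, arr.ind = TRUE)
  sm_d2 <- outer(sm_px[, 1], maxima[, 1], "-")^2 +
    outer(sm_px[, 2], maxima[, 2], "-")^2
  sm_assign <- max.col(-sm_d2, ties.method = "first")
  sm_area <- tabulate(sm_assign, nbins = n_comp)

  rows <- vector("list", n_comp)
  for (i in seq_len(n_comp)) {
    px <- mask_px[assign_id == i, , drop = FALSE]
    if (!nrow(px)) next
    vals <- m[px]
    wgt <- pmax(vals - bg$level, 1e-9)
    r0 <- sum(px[, 1] * wgt) / sum(wgt)
    c0 <- sum(px[, 2] * wgt) / sum(wgt)
    area <- nrow(px)
    r_eq <- sqrt(max(sm_area[i], area) / pi)
    r_int <- max(4, ceiling(1.2 * r_eq) + 2)

    rr <- max(1, floor(r0 - r_int - p$annulus_gap - p$annulus_width)):
      min(h, ceiling(r0 + r_int + p$annulus_gap + p$annulus_width))
    cc <- max(1, floor(c0 - r_int - p$annulus_gap - p$annulus_width)):
      min(w, ceiling(c0 + r_int + p$annulus_gap + p$annulus_width))
    dd <- outer((rr - r0)^2, (cc - c0)^2, "+")
    sub <- m[rr, cc, drop = FALSE]
    sub_cand <- cand_mask[rr, cc, drop = FALSE]
    # Voronoi guard: a disk pixel belongs to this spot only if no other
    # candidate maximum is closer (caps cross-talk between close spots).
    own <- matrix(TRUE, length(rr), length(cc))
    if (n_comp > 1) {
      near <- which((maxima[, 1] - r0)^2 + (maxima[, 2] - c0)^2 <=
                      (2 * (r_int + p$annulus_gap + p$annulus_width))^2)
      near <- setdiff(near, i)
      if (length(near)) {
        for (j in near) {
          dj <- outer((rr - maxima[j, 1])^2, (cc - maxima[j, 2])^2, "+")
          own <- own & (dd <= dj)
        }
      }
    }
    in_disk <- dd <= r_int^2 & own
    # annulus: background-only ring (smoothed spot support and pixels
    # contested by other maxima are excluded)
    in_ann <- dd > (r_int + p$annulus_gap)^2 &
      dd <= (r_int + p$annulus_gap + p$annulus_width)^2 & !sub_cand & own
    local_bg <- if (sum(in_ann) >= 8) stats::median(sub[in_ann])
    else bg$level

    mean_i <- mean(vals)
    integrated <- sum(sub[in_disk] - local_bg)
    contrast <- max(0, (mean_i - local_bg) / (mean_i + local_bg))
    rows[[i]] <- data.frame(
      spot = i, cell = NA_integer_, row = r0 - 1, col = c0 - 1,
      area = area, mean_intensity = mean_i,
      peak_corrected = max(vals) - local_bg,
      integrated = max(integrated, 0), contrast = contrast)
  }
  spots <- do.call(rbind, rows)
  if (is.null(spots) || !nrow(spots)) return(empty_spots)

  keep <- spots$area >= p$min_area &
    spots$peak_corrected >= p$intensity_threshold &
    spots$contrast >= p$contrast_threshold
  spots <- spots[keep, , drop = FALSE]
  if (!nrow(spots)) return(empty_spots)

  # ownership: cell label under the (1-based) rounded centroid
  ri <- pmin(pmax(round(spots$row + 1), 1), h)
  ci <- pmin(pmax(round(spots$col + 1), 1), w)
  spots$cell <- cell_labels[cbind(ri, ci)]
  spots <- spots[spots$cell > 0, , drop = FALSE]
  spots$spot <- seq_len(nrow(spots))
  rownames(spots) <- NULL
  class(spots) <- c("spot_records", "data.frame")
  spots
}

#' Summarize a well from its cell and spot records
#'
#' Per-cell spot count and summed background-corrected integrated spot
#' intensity, averaged over all cells (cells without spots contribute
#' zero). Wells with no cells report missing per-cell fields, never zero;
#' wells below `min_cells` are flagged low-coverage.
#'
#' @param cells Cell records (data.frame from [segment_cells()]).
#' @param spots Spot records (data.frame from [detect_spots()]); must
#'   reference existing cells.
#' @param plate,well Identifiers carried into the summary.
#' @param min_cells Low-coverage flag threshold (default 10 cells/field;
#'   screens accumulate fields until >= 1000 cells per condition).
#' @return One-row data.frame: `plate`, `well`, `n_cells`,
#'   `spots_per_cell`, `iss_per_cell`, `nuc_intensity`, `nuc_area`,
#'   `cyto_intensity`, `cyto_area`, `low_coverage`.
#' @export
summarize_well <- function(cells, spots, plate = "P01", well = "A01",
                           min_cells = 10L) {
  if (is.list(cells) && !is.data.frame(cells) && !is.null(cells$cells)) {
    cells <- cells$cells
  }
  n <- nrow(cells)
  if (n == 0) {
    return(data.frame(plate = plate, well = well, n_cells = 0L,
                      spots_per_cell = NA_real_, iss_per_cell = NA_real_,
                      nuc_intensity = NA_real_, nuc_area = NA_real_,
                      cyto_intensity = NA_real_, cyto_area = NA_real_,
                      low_coverage = TRUE))
  }
  if (nrow(spots)) {
    assert_that(all(spots$cell %in% cells$cell),
                "summarize_well: spots reference unknown cells")
  }
  per_count <- tabulate(spots$cell, nbins = n)
  per_iss <- rep(0, n)
  if (nrow(spots)) {
    agg <- tapply(spots$integrated, spots$cell, sum)
    per_iss[as.integer(names(agg))] <- as.numeric(agg)
  }
  data.frame(plate = plate, well = well, n_cells = n,
             spots_per_cell = mean(per_count),
             iss_per_cell = mean(per_iss),
             nuc_intensity = mean(cells$nucleus_mean_intensity),
             nuc_area = mean(cells$nucleus_area),
             cyto_intensity = mean(cells$cytoplasm_mean_intensity,
                                   na.rm = TRUE),
             cyto_area = mean(cells$cytoplasm_area),
             low_coverage = n < min_cells)
}

#' Two-way spot coalescence percentages
#'
#' A spot in A is colocalized when any B centroid lies within `radius`;
#' both directions are reported as percentages. An empty list on either
#' side yields `NA` for the corresponding percentage.
#'
#' @param spots_a,spots_b Spot tables with `row`, `col` centroid columns.
#' @param radius Colocalization distance in px (> 0; default 3).
#' @return Named numeric vector: `pct_a_with_b`, `pct_b_with_a`.
#' @export
colocalize_spots <- function(spots_a, spots_b, radius = 3) {
  assert_that(radius > 0, "colocalize_spots: radius must be > 0")
  frac_within <- function(x, y) {
    if (!nrow(x)) return(NA_real_)
    if (!nrow(y)) return(NA_real_)
    hit <- vapply(seq_len(nrow(x)), function(i) {
      any((y$row - x$row[i])^2 + (y$col - x$col[i])^2 <= radius^2)
    }, logical(1))
    100 * mean(hit)
  }
  c(pct_a_with_b = frac_within(spots_a, spots_b),
    pct_b_with_a = frac_within(spots_b, spots_a))
}

#' Tandem-reporter (RFP-GFP) spot classification
#'
#' Red spots with a green partner within `radius` are autophagosomes
#' (RFP+GFP+); red-only spots are autolysosomes (the GFP moiety is quenched
#' in the acidic lumen). The ratio autophagosomes/autolysosomes is missing
#' when there are no autolysosomes.
#'
#' @param spots_red,spots_green Spot tables with `row`, `col` columns from
#'   the same field.
#' @param radius Pairing distance in px (> 0; default 3).
#' @return List: `n_autophagosomes`, `n_autolysosomes`, `ratio` (`NA` when
#'   the denominator is zero).
#' @export
classify_tandem <- function(spots_red, spots_green, radius = 3) {
  assert_that(radius > 0, "classify_tandem: radius must be > 0")
  if (!nrow(spots_red)) {
    return(list(n_autophagosomes = 0L, n_autolysosomes = 0L,
                ratio = NA_real_))
  }
  if (!nrow(spots_green)) {
    return(list(n_autophagosomes = 0L, n_autolysosomes = nrow(spots_red),
                ratio = 0))
  }
  paired <- vapply(seq_len(nrow(spots_red)), function(i) {
    any((spots_green$row - spots_red$row[i])^2 +
          (spots_green$col - spots_red$col[i])^2 <= radius^2)
  }, logical(1))
  n_ap <- sum(paired)
  n_al <- sum(!paired)
  list(n_autophagosomes = n_ap, n_autolysosomes = n_al,
       ratio = if (n_al == 0) NA_real_ else n_ap / n_al)
}
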