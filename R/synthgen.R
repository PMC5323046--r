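#' Ground-truth effect model for a synthetic spot screen
#'
#' Describes the "world" a synthetic screen is drawn from: per-gene
#' fold-changes on the two spot parameters, per-siRNA knockdown efficiency,
#' cytotoxic siRNAs, and the baseline plate model shared by all wells.
#' Downstream generators ([simulate_well_table()], [render_well_image()])
#' consume this object, and every planted quantity is recoverable from it,
#' so recovery tests never rely on hidden state.
#'
#' The count model is negative binomial per cell (overdispersed spot counts)
#' and per-spot intensities are gamma distributed, so the integrated spot
#' signal (ISS) per cell is a compound gamma. A multiplicative log-normal
#' well effect (`well_cv`) models plate/well-level technical variation; it is
#' the component that dominates the SD of per-well means at realistic cell
#' numbers and therefore sets the width of the control band used by the
#' SD hit-calling criterion.
#'
#' @param gene_effects data.frame with columns `gene`, `fold_spots`,
#'   `fold_iss` (both > 0), optionally `marker` (default `"all"` applies to
#'   every marker). Genes absent from the table have fold 1 (no effect).
#' @param toxic_sirnas data.frame with columns `sirna`, `cell_fold` (> 0,
#'   multiplies cells/well) and `morph_shift` (>= 0, relative shift applied to
#'   nucleus/cytoplasm intensity and area summaries), or `NULL` for none.
#' @param knockdown Named numeric vector: siRNA id -> residual mRNA fraction
#'   in (0, 1]. Efficacy of an oligo scales its phenotypic fold towards 1.
#'   siRNAs not listed are drawn lazily by the generators from
#'   `sirna_effective_p` / `residual_range`.
#' @param baseline List of baseline parameters; see Details. Partial lists
#'   are completed with defaults.
#' @param seed Integer master seed; all generator substreams derive from it.
#' @param sirna_effective_p Probability that an unlisted deconvolution oligo
#'   is phenotypically effective (default 0.95).
#' @param residual_range Range of residual mRNA fractions for effective
#'   unlisted oligos (default `c(0.10, 0.45)`).
#'
#' @details Baseline defaults (overridable through `baseline`):
#' \describe{
#'   \item{cells_per_well}{1500 seeded cells per 384-well (Poisson mean).}
#'   \item{spots_per_cell}{Named per-marker means:
#'     WIPI2 15, ATG12 12, LC3B 20, GABARAP 18, STX17 8.}
#'   \item{spot_intensity_mean, spot_intensity_shape}{Gamma mean 500 AU,
#'     shape 2 for single-spot integrated intensity.}
#'   \item{nb_size}{Per-cell negative binomial size (dispersion) 4.}
#'   \item{well_cv}{Log-scale well-to-well CV 0.05.}
#'   \item{nuc_intensity, nuc_area, cyto_intensity, cyto_area, morph_cv}{
#'     Morphology summary means (1000 AU, 180 px^2, 300 AU, 900 px^2)
#'     and their CV (0.03).}
#'   \item{positive_fold, negative_fold}{Control phenotypes: positive
#'     controls c(spots = 2.5, iss = 2.5); negative controls
#'     c(spots = 0.9, iss = 0.35) (ISS collapse, near-baseline count).}
#'   \item{treatment_fold}{Spot multipliers: none/DMSO 1, Torin1 1.8,
#'     BafA1 2.5.}
#' }
#'
#' @return An object of class `effect_model`.
#' @export
#' @examples
#' m <- effect_model(gene_effects = data.frame(
#'   gene = "RAB7A", fold_spots = 2.5, fold_iss = 2.5))
effect_model <- function(gene_effects = NULL, toxic_sirnas = NULL,
                         knockdown = NULL, baseline = list(), seed = 1L,
                         sirna_effective_p = 0.95,
                         residual_range = c(0.10, 0.45)) {
  base_defaults <- list(
    cells_per_well = 1500,
    spots_per_cell = c(WIPI2 = 15, ATG12 = 12, LC3B = 20,
                       GABARAP = 18, STX17 = 8),
    spot_intensity_mean = 500,
    spot_intensity_shape = 2,
    nb_size = 4,
    well_cv = 0.05,
    nuc_intensity = 1000, nuc_area = 180,
    cyto_intensity = 300, cyto_area = 900,
    morph_cv = 0.03,
    positive_fold = c(spots = 2.5, iss = 2.5),
    negative_fold = c(spots = 0.9, iss = 0.35),
    treatment_fold = c(none = 1, DMSO = 1, Torin1 = 1.8, BafA1 = 2.5)
  )
  baseline <- utils::modifyList(base_defaults, as.list(baseline))

  if (is.null(gene_effects)) {
    gene_effects <- data.frame(gene = character(), fold_spots = numeric(),
                               fold_iss = numeric(),
                               marker = character())
  }
  need_cols(gene_effects, c("gene", "fold_spots", "fold_iss"), "gene_effects")
  if (!"marker" %in% names(gene_effects)) {
    gene_effects$marker <- rep("all", nrow(gene_effects))
  }
  assert_that(all(gene_effects$fold_spots > 0) && all(gene_effects$fold_iss > 0),
              "effect_model: all fold-changes must be > 0")
  if (!is.null(toxic_sirnas)) {
    need_cols(toxic_sirnas, c("sirna", "cell_fold", "morph_shift"),
              "toxic_sirnas")
    assert_that(all(toxic_sirnas$cell_fold > 0),
                "effect_model: toxic cell_fold must be > 0")
  } else {
    toxic_sirnas <- data.frame(sirna = character(), cell_fold = numeric(),
                               morph_shift = numeric())
  }
  if (!is.null(knockdown)) {
    assert_that(all(knockdown > 0 & knockdown <= 1),
                "effect_model: residual fractions must be in (0, 1]")
  } else {
    knockdown <- stats::setNames(numeric(), character())
  }
  structure(list(gene_effects = gene_effects, toxic_sirnas = toxic_sirnas,
                 knockdown = knockdown, baseline = baseline,
                 seed = as.integer(seed),
                 sirna_effective_p = sirna_effective_p,
                 residual_range = residual_range),
            class = "effect_model")
}

#' @export
print.effect_model <- function(x, ...) {
  cat("<effect_model>\n")
  cat("  genes with planted effects:", nrow(x$gene_effects), "\n")
  cat("  toxic siRNAs:", nrow(x$toxic_sirnas), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# 384-well geometry ----------------------------------------------------------

plate_rows <- function() LETTERS[1:16]

well_name <- function(row, col) sprintf("%s%02d", plate_rows()[row], col)

# Fixed control block: column 1 = sicon (rows A..L) + mock (M..P);
# column 24 = positive (A..H) + negative (I..P). Test wells fill cols 2..23.
control_block <- function() {
  data.frame(
    row = c(1:16, 1:16),
    col = rep(c(1L, 24L), each = 16),
    class = c(rep("sicon", 12), rep("mock", 4),
              rep("positive", 8), rep("negative", 8)),
    stringsAsFactors = FALSE
  )
}

#' Build a 384-well screen layout
#'
#' Lays out an siRNA screen on 384-well plates, one plate series per marker:
#' every plate carries a fixed control block (12 non-targeting `sicon` wells,
#' 4 `mock`, 8 `positive`, 8 `negative` controls) in the outer columns, and
#' each (gene, siRNA, treatment) condition occupies `replicates` adjacent
#' test wells so quadruplicates can be averaged before plate normalization.
#'
#' @param n_genes Number of target genes (>= 1). Gene symbols are `G001`...
#'   unless `genes` is supplied.
#' @param markers Character vector of marker names (one plate series each).
#' @param sirnas_per_gene 1 for pooled siRNA ("pool") or 4 for the
#'   deconvolution design (ids `<gene>_si1..4`).
#' @param seed Integer; reserved for layout randomization (current layout is
#'   deterministic fill order, the seed is recorded for provenance).
#' @param genes Optional explicit gene symbols (length `n_genes`).
#' @param treatments Character vector of treatments applied to every gene
#'   condition (default "none").
#' @param replicates Replicate wells per condition (default 4, quadruplicate).
#' @return data.frame of class `plate_layout` with columns `plate`, `well`,
#'   `row`, `col`, `marker`, `gene`, `class`, `sirna`, `treatment`,
#'   `replicate`.
#' @export
#' @examples
#' lay <- make_screen_layout(8, markers = "LC3B", sirnas_per_gene = 1, seed = 1)
#' table(lay$class)
make_screen_layout <- function(n_genes, markers = c("WIPI2", "ATG12", "LC3B",
                                                    "GABARAP", "STX17"),
                               sirnas_per_gene = 1, seed = 1L,
                               genes = NULL, treatments = "none",
                               replicates = 4L) {
  assert_that(n_genes >= 1, "make_screen_layout: n_genes must be >= 1")
  assert_that(sirnas_per_gene %in% c(1L, 4L),
              "make_screen_layout: sirnas_per_gene must be 1 (pool) or 4")
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(n_genes))
  assert_that(length(genes) == n_genes,
              "make_screen_layout: genes must have length n_genes")

  ctrl <- control_block()
  test_cells <- expand.grid(row = 1:16, col = 2:23)
  test_cells <- test_cells[order(test_cells$col, test_cells$row), ]
  capacity <- nrow(test_cells)  # 352 test wells per plate

  sirnas <- if (sirnas_per_gene == 1) "pool" else paste0("si", 1:4)
  # One condition = gene x sirna x treatment, occupying `replicates` wells.
  cond <- expand.grid(sirna = sirnas, treatment = treatments, gene = genes,
                      stringsAsFactors = FALSE)
  cond <- cond[, c("gene", "sirna", "treatment")]
  wells_per_cond <- replicates
  conds_per_plate <- capacity %/% wells_per_cond
  if (conds_per_plate < 1) {
    stop_named("layout error: plate capacity exceeded on plate %s (condition needs %d wells, plate holds %d test wells)",
               "P01", wells_per_cond, capacity)
  }

  out <- vector("list", length(markers))
  for (mi in seq_along(markers)) {
    marker <- markers[mi]
    n_plates <- ceiling(nrow(cond) / conds_per_plate)
    plates <- vector("list", n_plates)
    for (pi in seq_len(n_plates)) {
      pid <- sprintf("P%02d-%s", pi, marker)
      lo <- (pi - 1) * conds_per_plate + 1
      hi <- min(pi * conds_per_plate, nrow(cond))
      cc <- cond[lo:hi, , drop = FALSE]
      n_test <- nrow(cc) * wells_per_cond
      tc <- test_cells[seq_len(n_test), , drop = FALSE]
      test_df <- data.frame(
        plate = pid,
        well = well_name(tc$row, tc$col),
        row = tc$row, col = tc$col,
        marker = marker,
        gene = rep(cc$gene, each = wells_per_cond),
        class = "test",
        sirna = ifelse(rep(cc$sirna, each = wells_per_cond) == "pool", "pool",
                       paste0(rep(cc$gene, each = wells_per_cond), "_",
                              rep(cc$sirna, each = wells_per_cond))),
        treatment = rep(cc$treatment, each = wells_per_cond),
        replicate = rep(seq_len(wells_per_cond), times = nrow(cc)),
        stringsAsFactors = FALSE
      )
      ctrl_df <- data.frame(
        plate = pid,
        well = well_name(ctrl$row, ctrl$col),
        row = ctrl$row, col = ctrl$col,
        marker = marker,
        gene = ctrl$class,
        class = ctrl$class,
        sirna = ctrl$class,
        treatment = treatments[1],
        replicate = stats::ave(seq_len(nrow(ctrl)), ctrl$class,
                               FUN = seq_along),
        stringsAsFactors = FALSE
      )
      plates[[pi]] <- rbind(ctrl_df, test_df)
    }
    out[[mi]] <- do.call(rbind, plates)
  }
  layout <- do.call(rbind, out)
  rownames(layout) <- NULL
  attr(layout, "seed") <- as.integer(seed)
  attr(layout, "replicates") <- as.integer(replicates)
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

# Effect lookup --------------------------------------------------------------

# Resolve (fold_spots, fold_iss) per layout row, combining gene effect,
# control class, and per-siRNA efficacy.
resolve_folds <- function(layout, model) {
  n <- nrow(layout)
  fs <- rep(1, n)
  fi <- rep(1, n)
  b <- model$baseline
  fs[layout$class == "positive"] <- b$positive_fold[["spots"]]
  fi[layout$class == "positive"] <- b$positive_fold[["iss"]]
  fs[layout$class == "negative"] <- b$negative_fold[["spots"]]
  fi[layout$class == "negative"] <- b$negative_fold[["iss"]]

  ge <- model$gene_effects
  if (nrow(ge)) {
    key_all <- ge$marker == "all"
    for (j in seq_len(nrow(ge))) {
      sel <- layout$class == "test" & layout$gene == ge$gene[j] &
        (key_all[j] | layout$marker == ge$marker[j])
      fs[sel] <- ge$fold_spots[j]
      fi[sel] <- ge$fold_iss[j]
    }
  }

  # Per-siRNA efficacy: residual mRNA r scales the effect towards null.
  # Efficacy e = clamp((1 - r) / 0.75, 0, 1); realized fold = fold^e.
  sirna_ids <- unique(layout$sirna[layout$class == "test" &
                                     layout$sirna != "pool"])
  if (length(sirna_ids)) {
    kd <- model$knockdown
    unknown <- setdiff(sirna_ids, names(kd))
    if (length(unknown)) {
      kd_new <- with_seed(derive_seed(model$seed, 7001L), {
        eff <- stats::runif(length(unknown)) < model$sirna_effective_p
        r <- ifelse(eff,
                    stats::runif(length(unknown), model$residual_range[1],
                                 model$residual_range[2]),
                    stats::runif(length(unknown), 0.8, 1.0))
        stats::setNames(r, unknown)
      })
      kd <- c(kd, kd_new)
    }
    idx <- layout$class == "test" & layout$sirna != "pool"
    r <- kd[layout$sirna[idx]]
    e <- pmin(1, pmax(0, (1 - r) / 0.75))
    fs[idx] <- fs[idx]^e
    fi[idx] <- fi[idx]^e
  }
  list(fold_spots = fs, fold_iss = fi)
}

#' Simulate per-well screen summaries from a layout and effect model
#'
#' Bypasses imaging: draws the per-well quantities the imaging module would
#' produce. Cell counts are Poisson around the baseline (scaled for toxic
#' siRNAs); per-cell spot counts are negative binomial scaled by the gene's
#' spot fold-change and the treatment multiplier, with a shared log-normal
#' well effect; ISS/cell is a sum of gamma per-spot intensities whose scale
#' is adjusted so the planted ISS fold is honored independently of the spot
#' fold. Sums over cells/spots use NB and gamma additivity, so each well is
#' drawn in O(1).
#'
#' @param layout A `plate_layout` from [make_screen_layout()].
#' @param model An [effect_model()]. Layout genes absent from the model
#'   default to fold 1.
#' @return data.frame (`well_summary`): layout columns plus `n_cells`,
#'   `spots_per_cell`, `iss_per_cell`, `nuc_intensity`, `nuc_area`,
#'   `cyto_intensity`, `cyto_area`, and the planted truth columns
#'   `true_fold_spots`, `true_fold_iss`.
#' @export
simulate_well_table <- function(layout, model) {
  stopifnot(inherits(model, "effect_model"))
  need_cols(layout, c("plate", "well", "marker", "gene", "class", "sirna",
                      "treatment"), "layout")
  b <- model$baseline
  folds <- resolve_folds(layout, model)
  n <- nrow(layout)

  base_spots <- b$spots_per_cell[layout$marker]
  base_spots[is.na(base_spots)] <- mean(b$spots_per_cell)
  treat <- b$treatment_fold[layout$treatment]
  treat[is.na(treat)] <- 1

  cell_fold <- rep(1, n)
  morph_shift <- rep(0, n)
  tox <- model$toxic_sirnas
  if (nrow(tox)) {
    m <- match(layout$sirna, tox$sirna)
    hit <- !is.na(m)
    cell_fold[hit] <- tox$cell_fold[m[hit]]
    morph_shift[hit] <- tox$morph_shift[m[hit]]
  }

  with_seed(derive_seed(model$seed, 1L), {
    well_eff <- exp(stats::rnorm(n, -b$well_cv^2 / 2, b$well_cv))
    n_cells <- stats::rpois(n, b$cells_per_well * cell_fold)
    mu_spots <- base_spots * treat * folds$fold_spots * well_eff
    total_spots <- ifelse(
      n_cells > 0,
      stats::rnbinom(n, size = pmax(n_cells, 1) * b$nb_size,
                     mu = pmax(n_cells, 1) * mu_spots),
      0L)
    spots_per_cell <- ifelse(n_cells > 0, total_spots / n_cells, NA_real_)
    # Per-spot intensity scale carries the residual ISS effect.
    iss_ratio <- folds$fold_iss / folds$fold_spots
    shape <- b$spot_intensity_shape
    scl <- (b$spot_intensity_mean * iss_ratio) / shape
    iss_total <- ifelse(total_spots > 0,
                        stats::rgamma(n, shape = pmax(total_spots, 1) * shape,
                                      scale = scl),
                        0)
    iss_per_cell <- ifelse(n_cells > 0, iss_total / n_cells, NA_real_)

    morph <- function(mean_val, shift_sign) {
      m <- mean_val * (1 + shift_sign * morph_shift)
      stats::rnorm(n, m, b$morph_cv * mean_val)
    }
    out <- as.data.frame(layout)
    out$n_cells <- n_cells
    out$spots_per_cell <- spots_per_cell
    out$iss_per_cell <- iss_per_cell
    out$nuc_intensity <- morph(b$nuc_intensity, +1)
    out$nuc_area <- morph(b$nuc_area, -1)
    out$cyto_intensity <- morph(b$cyto_intensity, +1)
    out$cyto_area <- morph(b$cyto_area, -1)
    out$true_fold_spots <- folds$fold_spots
    out$true_fold_iss <- folds$fold_iss
    class(out) <- c("well_summary", "data.frame")
    out
  })
}

# Image rendering -------------------------------------------------------------

# Unit gaussian kernel stamped additively into a matrix.
stamp_gaussian <- function(img, r0, c0, amp, sigma) {
  h <- nrow(img); w <- ncol(img)
  rad <- ceiling(4 * sigma)
  rr <- max(1, round(r0) - rad):min(h, round(r0) + rad)
  cc <- max(1, round(c0) - rad):min(w, round(c0) + rad)
  if (!length(rr) || !length(cc)) return(img)
  dr <- (rr - r0)^2
  dc <- (cc - c0)^2
  k <- amp * exp(-(outer(dr, dc, "+")) / (2 * sigma^2))
  img[rr, cc] <- img[rr, cc] + k
  img
}

#' Render a synthetic two-channel well image with ground truth
#'
#' Channel 1 is the nuclear + cytoplasm stain: each cell is a bright
#' elliptical nucleus inside a dimmer cytoplasm disk; cells are placed by
#' rejection sampling under a minimum-distance constraint. Channel 2 is the
#' spot (marker) channel: isotropic Gaussian spots planted inside each
#' cell's cytoplasm mask, over Gaussian read noise plus a low-frequency
#' illumination field. All planted objects are returned as ground truth.
#'
#' @param n_cells Number of cells to place (0 allowed: blank field).
#' @param spots_per_cell Spots planted per cell (integer, may be 0).
#' @param size Image side in pixels (square, >= 128).
#' @param model Optional [effect_model()]; supplies intensity baselines.
#' @param seed Integer seed (default: derived from `model$seed`).
#' @param spot_amplitude Peak amplitude of planted spots (AU).
#' @param spot_sigma_range Range of spot Gaussian sigmas in px.
#' @param min_spot_sep Minimum distance between planted spot centroids of
#'   the same cell in px (keeps planted counts recoverable by detection).
#' @param noise_sd Gaussian read-noise SD (0 allowed for analytic tests).
#' @param illumination Peak-to-center relative amplitude of the smooth
#'   illumination field (0 disables it).
#' @param nucleus_radius,cell_radius Mean nucleus semi-axis and cytoplasm
#'   radius in px.
#' @param background Constant background offset (AU).
#' @return List with `channels` (list of two `size` x `size` matrices:
#'   `nuclear` and `marker`), `cells` (truth data.frame: `cell`, `row`,
#'   `col`, `nucleus_a`, `nucleus_b`, `cell_radius`), `spots` (truth
#'   data.frame: `spot`, `cell`, `row`, `col`, `sigma`, `amplitude`,
#'   `integral` = amplitude x analytic kernel sum), and `params`.
#' @export
render_well_image <- function(n_cells, spots_per_cell = 5, size = 256,
                              model = NULL, seed = NULL,
                              spot_amplitude = 300,
                              spot_sigma_range = c(1, 3),
                              min_spot_sep = 8,
                              noise_sd = 20, illumination = 0.15,
                              nucleus_radius = 7, cell_radius = 18,
                              background = 50) {
  assert_that(size >= 128, "render_well_image: size must be >= 128 px")
  if (is.null(seed)) {
    seed <- if (!is.null(model)) derive_seed(model$seed, 11L) else 1L
  }
  nuc_int <- if (!is.null(model)) model$baseline$nuc_intensity else 1000
  cyto_int <- if (!is.null(model)) model$baseline$cyto_intensity else 300

  with_seed(seed, {
    ch0 <- matrix(0, size, size)
    ch1 <- matrix(0, size, size)

    # Cell placement: rejection sampling, centers at least 2*cell_radius
    # apart and one radius from the border.
    centers <- matrix(numeric(0), ncol = 2)
    margin <- cell_radius + 2
    min_d2 <- (2 * cell_radius)^2
    attempts <- 0L
    max_attempts <- 2000L * max(n_cells, 1L)
    while (nrow(centers) < n_cells) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop_named("render_well_image: could not place %d cells of radius %g in a %d px field",
                   n_cells, cell_radius, size)
      }
      p <- stats::runif(2, margin, size - margin)
      if (nrow(centers) == 0 ||
          all((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 > min_d2)) {
        centers <- rbind(centers, p)
      }
    }

    cells <- data.frame(cell = integer(), row = numeric(), col = numeric(),
                        nucleus_a = numeric(), nucleus_b = numeric(),
                        cell_radius = numeric())
    if (n_cells > 0) {
      a <- nucleus_radius * stats::runif(n_cells, 0.85, 1.15)
      bax <- nucleus_radius * stats::runif(n_cells, 0.65, 0.95)
      th <- stats::runif(n_cells, 0, pi)
      cells <- data.frame(cell = seq_len(n_cells), row = centers[, 1],
                          col = centers[, 2], nucleus_a = a, nucleus_b = bax,
                          cell_radius = cell_radius)
      # Paint cytoplasm disks then nuclei ellipses (vectorized per cell).
      rows <- row(ch0); cols <- col(ch0)
      for (i in seq_len(n_cells)) {
        dr <- rows - centers[i, 1]; dc <- cols - centers[i, 2]
        cyto <- (dr^2 + dc^2) <= cell_radius^2
        ch0[cyto] <- pmax(ch0[cyto], cyto_int)
        u <- dr * cos(th[i]) + dc * sin(th[i])
        v <- -dr * sin(th[i]) + dc * cos(th[i])
        nuc <- (u / a[i])^2 + (v / bax[i])^2 <= 1
        ch0[nuc] <- nuc_int
      }
    }

    # Spots: planted uniformly inside the cytoplasm annulus of the owner
    # cell (outside the nucleus bounding ellipse, inside the cell disk).
    spot_list <- list()
    sid <- 0L
    if (n_cells > 0 && spots_per_cell > 0) {
      for (i in seq_len(n_cells)) {
        placed <- 0L
        guard <- 0L
        pos <- matrix(numeric(0), ncol = 2)
        while (placed < spots_per_cell && guard < 500L * spots_per_cell) {
          guard <- guard + 1L
          rr <- stats::runif(1, 2.5, cells$cell_radius[i] - 1.5)
          ang <- stats::runif(1, 0, 2 * pi)
          pr <- cells$row[i] + rr * sin(ang)
          pc <- cells$col[i] + rr * cos(ang)
          u <- (pr - cells$row[i]) * cos(th[i]) + (pc - cells$col[i]) * sin(th[i])
          v <- -(pr - cells$row[i]) * sin(th[i]) + (pc - cells$col[i]) * cos(th[i])
          inside_nuc <- (u / cells$nucleus_a[i])^2 +
            (v / cells$nucleus_b[i])^2 <= 1
          if (inside_nuc) next
          if (nrow(pos) &&
              any((pos[, 1] - pr)^2 + (pos[, 2] - pc)^2 < min_spot_sep^2)) {
            next
          }
          pos <- rbind(pos, c(pr, pc))
          placed <- placed + 1L
          sid <- sid + 1L
          sg <- stats::runif(1, spot_sigma_range[1], spot_sigma_range[2])
          amp <- spot_amplitude * stats::runif(1, 0.8, 1.2)
          # Analytic discrete kernel sum for the planted integral.
          rad <- ceiling(4 * sg)
          g1r <- exp(-((-rad:rad) - (pr - round(pr)))^2 / (2 * sg^2))
          g1c <- exp(-((-rad:rad) - (pc - round(pc)))^2 / (2 * sg^2))
          ksum <- sum(g1r) * sum(g1c)
          ch1 <- stamp_gaussian(ch1, pr, pc, amp, sg)
          spot_list[[sid]] <- data.frame(spot = sid, cell = i, row = pr,
                                         col = pc, sigma = sg,
                                         amplitude = amp,
                                         integral = amp * ksum)
        }
        if (placed < spots_per_cell) {
          stop_named("render_well_image: could not place %d spots in cell %d",
                     spots_per_cell, i)
        }
      }
    }
    spots <- if (length(spot_list)) do.call(rbind, spot_list) else
      data.frame(spot = integer(), cell = integer(), row = numeric(),
                 col = numeric(), sigma = numeric(), amplitude = numeric(),
                 integral = numeric())

    # Background: offset + smooth illumination field + read noise, both
    # channels.
    xs <- seq(-1, 1, length.out = size)
    illum <- 1 + illumination * outer(-xs^2, -xs^2, "+") / 2
    add_bg <- function(img) {
      img <- (img + background) * illum
      if (noise_sd > 0) {
        img <- img + matrix(stats::rnorm(size * size, 0, noise_sd), size, size)
      }
      img
    }
    list(channels = list(nuclear = add_bg(ch0), marker = add_bg(ch1)),
         cells = cells, spots = spots,
         params = list(size = size, noise_sd = noise_sd,
                       background = background, illumination = illumination,
                       spot_amplitude = spot_amplitude,
                       nucleus_radius = nucleus_radius,
                       cell_radius = cell_radius, seed = seed))
  })
}

#' Simulate control wells only (assay-window estimation)
#'
#' Generates `n_per_group` wells of each requested control class per
#' marker from the effect model's baseline, e.g. to estimate the
#' z'-factor between the elevated positive controls and the baseline
#' non-targeting wells.
#'
#' @param model An [effect_model()].
#' @param markers Marker panel (default: the model baseline's markers).
#' @param n_per_group Wells per control class per marker (default 16).
#' @param classes Control classes to simulate.
#' @return A `well_summary` data.frame restricted to control wells.
#' @export
simulate_control_wells <- function(model, markers = NULL, n_per_group = 16L,
                                   classes = c("sicon", "positive",
                                               "negative")) {
  if (is.null(markers)) markers <- names(model$baseline$spots_per_cell)
  lay <- do.call(rbind, lapply(markers, function(mk) {
    do.call(rbind, lapply(classes, function(cl) {
      data.frame(plate = paste0("C01-", mk),
                 well = sprintf("%s%03d", toupper(substr(cl, 1, 1)),
                                seq_len(n_per_group)),
                 marker = mk, gene = cl, class = cl, sirna = cl,
                 treatment = "none", replicate = seq_len(n_per_group),
                 stringsAsFactors = FALSE)
    }))
  }))
  simulate_well_table(lay, model)
}

# qPCR ------------------------------------------------------------------------

#' Simulate a qPCR Ct table with planted knockdown fractions
#'
#' Generates Ct values for target genes and the three reference genes
#' (ACTB, HMBS, TBP) in a control condition (`sicon`) and one knockdown
#' condition per target, such that perfect-efficiency relative
#' quantification ([relative_expression()]) recovers the planted residual
#' fraction: the target Ct shifts by `-log2(fraction)` cycles while
#' references are unchanged.
#'
#' @param targets Character vector of target genes.
#' @param knockdown Named numeric vector of residual fractions in (0, 1]
#'   (names must cover `targets`).
#' @param seed Integer seed.
#' @param n_replicates Technical replicates per (condition, gene).
#' @param noise_sd Replicate Ct noise SD in cycles (default 0.1; 0 allowed).
#' @param base_ct Named baseline Ct for the references and default for
#'   targets.
#' @return data.frame (`ct_table`): `sample`, `gene`, `replicate`, `ct`,
#'   with attribute `reference_genes`.
#' @export
simulate_qpcr <- function(targets, knockdown, seed = 1L, n_replicates = 4L,
                          noise_sd = 0.1,
                          base_ct = c(ACTB = 17, HMBS = 26, TBP = 27)) {
  assert_that(all(knockdown > 0 & knockdown <= 1),
              "simulate_qpcr: knockdown fractions must be in (0, 1]")
  assert_that(all(targets %in% names(knockdown)),
              "simulate_qpcr: every target needs a knockdown entry")
  refs <- names(base_ct)
  target_base <- stats::setNames(
    with_seed(derive_seed(seed, 3L), stats::runif(length(targets), 22, 27)),
    targets)
  rows <- list()
  conditions <- c("sicon", paste0("si", targets))
  with_seed(derive_seed(seed, 4L), {
    for (cond in conditions) {
      for (g in c(refs, targets)) {
        mu <- if (g %in% refs) base_ct[[g]] else target_base[[g]]
        if (cond != "sicon" && g == sub("^si", "", cond)) {
          mu <- mu - log2(knockdown[[g]])  # fewer transcripts -> later Ct
        }
        ct <- mu + if (noise_sd > 0) stats::rnorm(n_replicates, 0, noise_sd)
        else rep(0, n_replicates)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = cond, gene = g, replicate = seq_len(n_replicates),
          ct = ct, stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "reference_genes") <- refs
  class(out) <- c("ct_table", "data.frame")
  out
}

# AP-MS -----------------------------------------------------------------------

#' Simulate AP-MS spectral-count runs over a multi-bait background
#'
#' True interactors yield high counts in their bait's runs only; background
#' preys appear across a configurable fraction of baits at low counts, so
#' frequency-penalized interaction scores can separate the two.
#'
#' @param n_baits Number of baits (>= 2); bait ids `B001`...
#' @param prey_network Named list: bait id -> named numeric vector of true
#'   interactor mean counts (e.g. `list(B001 = c(PREY1 = 30))`).
#' @param background_freq Named numeric vector: background prey ->
#'   probability that a given bait retrieves it. If `NULL`, a default
#'   background of `n_background` preys with detection probability 0.3 and
#'   mean count 3 is generated.
#' @param seed Integer seed.
#' @param n_runs Technical replicate runs per bait (default 2).
#' @param background_mean Mean spectral count of background preys.
#' @param n_background Number of default background preys.
#' @return data.frame (`spectral_runs`): `bait`, `prey`, `run`, `counts`.
#'   Undetected (bait, prey) pairs are absent; [aggregate_runs()] fills
#'   zeros within a bait's run set.
#' @export
simulate_apms <- function(n_baits, prey_network = list(),
                          background_freq = NULL, seed = 1L, n_runs = 2L,
                          background_mean = 3, n_background = 150L) {
  assert_that(n_baits >= 2, "simulate_apms: n_baits must be >= 2")
  baits <- sprintf("B%03d", seq_len(n_baits))
  if (is.null(background_freq)) {
    background_freq <- stats::setNames(rep(0.3, n_background),
                                       sprintf("bg%03d", seq_len(n_background)))
  }
  rows <- list()
  with_seed(derive_seed(seed, 5L), {
    for (b in baits) {
      # planted interactors
      tp <- prey_network[[b]]
      if (!is.null(tp)) {
        for (p in names(tp)) {
          cnt <- stats::rpois(n_runs, tp[[p]])
          for (r in seq_len(n_runs)) {
            rows[[length(rows) + 1L]] <- data.frame(
              bait = b, prey = p, run = r, counts = cnt[r])
          }
        }
      }
      # background
      det <- stats::runif(length(background_freq)) < background_freq
      for (p in names(background_freq)[det]) {
        cnt <- stats::rpois(n_runs, background_mean)
        if (all(cnt == 0)) cnt[1] <- 1L
        for (r in seq_len(n_runs)) {
          rows[[length(rows) + 1L]] <- data.frame(
            bait = b, prey = p, run = r, counts = cnt[r])
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  out <- out[out$counts > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spectral_runs", "data.frame")
  out
}

# Expression ratios -----------------------------------------------------------

#' Simulate replicate knockdown/control expression-ratio tables
#'
#' Three (by default) independent experiments, each reporting a per-gene
#' knockdown/control ratio with log-normal noise around the planted truth.
#'
#' @param n_genes Number of genes (ids `E0001`... unless covered by
#'   `de_truth` names).
#' @param de_truth Named numeric vector gene -> true ratio (> 0). Genes not
#'   named default to ratio 1.
#' @param noise Log-scale SD of the per-experiment ratio noise (0 allowed).
#' @param seed Integer seed.
#' @param n_experiments Number of replicate experiments (default 3).
#' @return data.frame (`ratio_runs`): `gene`, `experiment`, `ratio`, plus
#'   truth column `true_ratio`.
#' @export
simulate_expression <- function(n_genes, de_truth = numeric(), noise = 0.1,
                                seed = 1L, n_experiments = 3L) {
  assert_that(all(de_truth > 0), "simulate_expression: ratios must be > 0")
  genes <- sprintf("E%04d", seq_len(n_genes))
  extra <- setdiff(names(de_truth), genes)
  genes <- c(genes, extra)
  truth <- stats::setNames(rep(1, length(genes)), genes)
  truth[names(de_truth)] <- de_truth
  with_seed(derive_seed(seed, 6L), {
    out <- expand.grid(gene = genes, experiment = seq_len(n_experiments),
                       stringsAsFactors = FALSE)
    eps <- if (noise > 0) stats::rnorm(nrow(out), 0, noise) else 0
    out$ratio <- truth[out$gene] * exp(eps)
    out$true_ratio <- unname(truth[out$gene])
    class(out) <- c("ratio_runs", "data.frame")
    out
  })
}
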