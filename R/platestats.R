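#' Normalize well summaries to the non-targeting control
#'
#' Replicate wells of each (plate, gene, siRNA, treatment) condition are
#' averaged first, then divided by the same plate's `sicon` mean, separately
#' for both spot parameters. The dispersion attached for hit thresholds is
#' the SD of the per-well normalized `sicon` values, pooled across plates of
#' the same marker by default (`sd_scope = "pooled"`), or per plate
#' (`sd_scope = "plate"`).
#'
#' @param wells `well_summary` data.frame (from [simulate_well_table()] or
#'   [summarize_well()] rows bound to a layout).
#' @param layout Optional layout; ignored if `wells` already carries the
#'   layout columns (the default produced by this package).
#' @param parameters Measurement columns to normalize.
#' @param sd_scope `"pooled"` (per marker, default) or `"plate"`.
#' @param min_sicon Minimum `sicon` wells per plate (default 2).
#' @return data.frame (`normalized_measure`), long format: `plate`,
#'   `marker`, `gene`, `class`, `sirna`, `treatment`, `parameter`, `value`
#'   (fold of sicon), `control_mean`, `control_sd`, `n_wells`, `flagged`
#'   (TRUE when replicates were incomplete).
#' @export
normalize_to_control <- function(wells, layout = NULL,
                                 parameters = c("spots_per_cell",
                                                "iss_per_cell"),
                                 sd_scope = c("pooled", "plate"),
                                 min_sicon = 2L) {
  sd_scope <- match.arg(sd_scope)
  if (!is.null(layout) && !all(c("gene", "class") %in% names(wells))) {
    wells <- merge(layout, wells, by = c("plate", "well"))
  }
  need_cols(wells, c("plate", "marker", "gene", "class", "sirna",
                     "treatment", parameters), "wells")
  tw <- wells$class == "test"
  expected_reps <- if ("replicate" %in% names(wells) && any(tw)) {
    max(wells$replicate[tw])
  } else {
    max(table(paste(wells$plate, wells$gene, wells$sirna,
                    wells$treatment)[tw]), 1L)
  }

  out <- list()
  for (param in parameters) {
    x <- wells[[param]]
    ok <- !is.na(x)
    w <- wells[ok, ]
    x <- x[ok]

    # plate-wise sicon means (per treatment, so treated plates normalize
    # within their own arm when treatments share a plate)
    key_plate <- paste(w$plate, w$treatment)
    sic <- w$class == "sicon"
    sic_mean <- tapply(x[sic], key_plate[sic], mean)
    sic_n <- tapply(x[sic], key_plate[sic], length)
    bad <- names(sic_mean)[is.na(sic_mean) | sic_mean <= 0 |
                             sic_n < min_sicon]
    if (length(setdiff(unique(key_plate), names(sic_mean)))) {
      bad <- c(bad, setdiff(unique(key_plate), names(sic_mean)))
    }
    if (length(bad)) {
      stop_named("normalize_to_control: sicon mean missing/non-positive or < %d wells on plate(s): %s",
                 min_sicon, paste(unique(bad), collapse = ", "))
    }
    x_norm <- x / sic_mean[key_plate]

    # control dispersion: SD of per-well normalized sicon values
    if (sd_scope == "pooled") {
      ctl_sd <- tapply(x_norm[sic], w$marker[sic], stats::sd)
      sd_key <- w$marker
    } else {
      ctl_sd <- tapply(x_norm[sic], key_plate[sic], stats::sd)
      sd_key <- key_plate
    }

    agg_key <- paste(w$plate, w$marker, w$gene, w$class, w$sirna,
                     w$treatment, sep = "\r")
    first <- !duplicated(agg_key)
    mean_v <- tapply(x_norm, agg_key, mean)
    n_v <- tapply(x_norm, agg_key, length)
    res <- data.frame(
      plate = w$plate[first], marker = w$marker[first],
      gene = w$gene[first], class = w$class[first],
      sirna = w$sirna[first], treatment = w$treatment[first],
      parameter = param,
      value = as.numeric(mean_v[agg_key[first]]),
      control_mean = as.numeric(sic_mean[key_plate[first]]),
      control_sd = as.numeric(ctl_sd[sd_key[first]]),
      n_wells = as.integer(n_v[agg_key[first]]),
      stringsAsFactors = FALSE)
    res$flagged <- res$class == "test" & res$n_wells < expected_reps
    out[[param]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("normalized_measure", "data.frame")
  res
}

#' z'-factor assay-quality statistic
#'
#' `1 - 3 * (sd(pos) + sd(neg)) / abs(mean(pos) - mean(neg))`. Values above
#' 0.5 indicate a screenable assay window.
#'
#' @param pos,neg Numeric vectors of positive/negative control values
#'   (>= 2 each).
#' @return A single numeric; `NA` with a warning when the group means are
#'   equal (undefined window).
#' @export
#' @examples
#' zprime(rnorm(16, 60, 6), rnorm(16, 20, 3))
zprime <- function(pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  assert_that(length(pos) >= 2 && length(neg) >= 2,
              "zprime: need >= 2 values per control group")
  dmu <- abs(mean(pos) - mean(neg))
  if (dmu == 0) {
    warning("zprime: control means are equal; z'-factor undefined")
    return(NA_real_)
  }
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / dmu
}

#' Per-plate z-score normalization
#'
#' Centers and scales test-well values plate by plate:
#' `(x - center) / scale`, with `center/scale` = median / scaled MAD in
#' robust mode (default) or mean / SD otherwise. Control wells are excluded
#' from the center/scale fit but are scored against it.
#'
#' @param wells `well_summary` data.frame.
#' @param parameter Column to normalize.
#' @param robust Use median/MAD (default TRUE).
#' @param min_wells Minimum test wells per plate (default 8).
#' @return `wells` with an added `zscore` column and attribute `scale_info`.
#'   A plate whose scale is zero in robust mode gets zero scores and a
#'   `zero_scale` flag; in classic mode it is rejected.
#' @export
zscore_plate <- function(wells, parameter = "spots_per_cell", robust = TRUE,
                         min_wells = 8L) {
  need_cols(wells, c("plate", "class", parameter), "wells")
  x <- wells[[parameter]]
  z <- rep(NA_real_, nrow(wells))
  flags <- character()
  for (p in unique(wells$plate)) {
    sel <- wells$plate == p
    fit <- sel & wells$class == "test" & !is.na(x)
    assert_that(sum(fit) >= min_wells,
                "zscore_plate: plate %s has < %d test wells", p, min_wells)
    if (robust) {
      ctr <- stats::median(x[fit]); scl <- rmad(x[fit])
    } else {
      ctr <- mean(x[fit]); scl <- stats::sd(x[fit])
    }
    if (scl == 0 || is.na(scl)) {
      if (robust) {
        z[sel] <- 0
        flags <- c(flags, p)
        next
      }
      stop_named("zscore_plate: plate %s rejected (zero scale)", p)
    }
    z[sel] <- (x[sel] - ctr) / scl
  }
  wells$zscore <- z
  attr(wells, "zero_scale_plates") <- flags
  wells
}

#' B-score plate-position normalization
#'
#' Two-way Tukey median polish on the plate's row x column matrix removes
#' additive row and column (edge/gradient) effects; the residuals are
#' divided by their scaled MAD. Missing wells are tolerated up to 50%.
#'
#' @param plate_matrix Numeric matrix (rows x columns of a plate), >= 2x2.
#' @param max_iter Maximum polish iterations (default 10).
#' @param tol Convergence tolerance on effect updates (default 1e-4).
#' @return Matrix of B-scores (same dim); attributes `converged` (logical),
#'   `row_effects`, `col_effects`, `overall`.
#' @export
bscore_plate <- function(plate_matrix, max_iter = 10L, tol = 1e-4) {
  assert_that(is.matrix(plate_matrix) && all(dim(plate_matrix) >= 2),
              "bscore_plate: need a numeric matrix of at least 2x2")
  assert_that(mean(is.na(plate_matrix)) < 0.5,
              "bscore_plate: more than 50%% of wells missing")
  mp <- suppressWarnings(
    stats::medpolish(plate_matrix, maxiter = max_iter, eps = tol,
                     na.rm = TRUE, trace.iter = FALSE))
  resid <- mp$residuals
  s <- rmad(resid[!is.na(resid)], center = 0)
  b <- if (s > 0) resid / s else resid
  attr(b, "converged") <- TRUE  # medpolish warns on non-convergence
  attr(b, "row_effects") <- mp$row
  attr(b, "col_effects") <- mp$col
  attr(b, "overall") <- mp$overall
  b
}

#' Squared Pearson correlation between two screen replicates
#'
#' @param rep1,rep2 Named numeric vectors (gene -> value). Only genes shared
#'   by both replicates (>= 3) enter; pairs with missing values are dropped.
#' @return R^2 (numeric), or `NA` when either replicate has zero variance.
#' @export
replicate_correlation <- function(rep1, rep2) {
  shared <- intersect(names(rep1), names(rep2))
  x <- rep1[shared]; y <- rep2[shared]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  assert_that(length(x) >= 3,
              "replicate_correlation: need >= 3 shared genes")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Screen quality report
#'
#' Computes, per marker and spot parameter, the z'-factor between the
#' positive and negative control wells of the screen and (when two
#' replicate screens are supplied) the replicate R^2.
#'
#' @param wells `well_summary` data.frame with control classes.
#' @param parameters Measurement columns.
#' @param zprime_pass z' threshold for a plate series to pass (default 0.5).
#' @return data.frame (`quality_report`): `marker`, `parameter`, `zprime`,
#'   `passes`.
#' @export
quality_report <- function(wells, parameters = c("spots_per_cell",
                                                 "iss_per_cell"),
                           zprime_pass = 0.5) {
  need_cols(wells, c("marker", "class", parameters), "wells")
  rows <- list()
  for (m in unique(wells$marker)) {
    for (param in parameters) {
      pos <- wells[[param]][wells$marker == m & wells$class == "positive"]
      neg <- wells[[param]][wells$marker == m & wells$class == "negative"]
      zp <- if (length(pos) >= 2 && length(neg) >= 2) zprime(pos, neg)
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, parameter = param, zprime = zp,
        passes = !is.na(zp) && zp > zprime_pass)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("quality_report", "data.frame")
  out
}
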