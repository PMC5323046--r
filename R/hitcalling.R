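#' Hit-calling thresholds
#'
#' Per-marker multiples of the control SD that a normalized value must
#' exceed to be called. Defaults follow the screen convention of a stricter
#' band for the high-count early markers: WIPI2 and ATG12 use k = 3, LC3B,
#' GABARAP and STX17 use k = 2.
#'
#' @param k Named numeric vector marker -> SD multiplier (> 0); unnamed
#'   single value applies to all markers.
#' @param require_both Require both spot parameters to pass in the same
#'   direction (default TRUE).
#' @param direction `"either"` (default), `"increase"` or `"decrease"`.
#' @return List of class `hit_thresholds`.
#' @export
hit_thresholds <- function(k = c(WIPI2 = 3, ATG12 = 3, LC3B = 2,
                                 GABARAP = 2, STX17 = 2),
                           require_both = TRUE,
                           direction = c("either", "increase", "decrease")) {
  assert_that(all(k > 0), "hit_thresholds: k must be > 0")
  structure(list(k = k, require_both = require_both,
                 direction = match.arg(direction)),
            class = "hit_thresholds")
}

threshold_k <- function(thresholds, marker) {
  k <- thresholds$k
  if (is.null(names(k))) return(k[1])
  if (marker %in% names(k)) k[[marker]] else stop_named(
    "hit_thresholds: no SD multiplier defined for marker %s", marker)
}

#' Primary hit calling by the standard-deviation criterion
#'
#' A condition is a hit for a marker iff both normalized spot parameters
#' (spots/cell and ISS/cell) deviate from 1 by more than `k * SD(sicon)` in
#' the same direction, where k is the marker's SD multiplier. The band is
#' additive on the fold scale: `1 +/- k * control_sd`.
#'
#' @param normalized `normalized_measure` table carrying `control_sd`.
#' @param thresholds A [hit_thresholds()] object.
#' @return data.frame (`gene_verdict`): one row per
#'   (gene, marker, sirna, treatment) with `value_spots`, `value_iss`,
#'   `pass_spots`, `pass_iss`, `direction` (`"increase"`, `"decrease"` or
#'   `"none"`), `is_hit`, `deviation` (max |log value| over both
#'   parameters), `stage`, and a human-readable `rule` trail.
#' @export
call_primary_hits <- function(normalized, thresholds = hit_thresholds()) {
  need_cols(normalized, c("marker", "gene", "class", "sirna", "treatment",
                          "parameter", "value", "control_sd"), "normalized")
  nz <- normalized[normalized$class == "test", ]
  key <- paste(nz$gene, nz$marker, nz$sirna, nz$treatment, sep = "\r")
  sp <- nz[nz$parameter == "spots_per_cell", ]
  is_ <- nz[nz$parameter == "iss_per_cell", ]
  ksp <- paste(sp$gene, sp$marker, sp$sirna, sp$treatment, sep = "\r")
  kis <- paste(is_$gene, is_$marker, is_$sirna, is_$treatment, sep = "\r")
  common <- intersect(ksp, kis)
  skipped <- setdiff(unique(key), common)
  if (length(skipped)) {
    message(sprintf(
      "call_primary_hits: %d condition(s) missing one parameter; skipped",
      length(skipped)))
  }
  sp <- sp[match(common, ksp), ]
  is_ <- is_[match(common, kis), ]

  k <- vapply(sp$marker, function(m) threshold_k(thresholds, m), numeric(1))
  band_sp <- k * sp$control_sd
  band_is <- k * is_$control_sd
  dev_sp <- sp$value - 1
  dev_is <- is_$value - 1
  pass_sp <- abs(dev_sp) > band_sp
  pass_is <- abs(dev_is) > band_is
  same_dir <- sign(dev_sp) == sign(dev_is)
  if (thresholds$require_both) {
    is_hit <- pass_sp & pass_is & same_dir
  } else {
    is_hit <- pass_sp | pass_is
  }
  dir <- ifelse(!is_hit, "none",
                ifelse(dev_sp > 0, "increase", "decrease"))
  if (thresholds$direction != "either") {
    is_hit <- is_hit & dir == thresholds$direction
    dir[!is_hit] <- "none"
  }
  out <- data.frame(
    gene = sp$gene, marker = sp$marker, sirna = sp$sirna,
    treatment = sp$treatment,
    value_spots = sp$value, value_iss = is_$value,
    pass_spots = pass_sp, pass_iss = pass_is,
    direction = dir, is_hit = is_hit,
    deviation = pmax(abs(log(sp$value)), abs(log(is_$value))),
    stage = ifelse(is_hit, "primary_hit", "not_hit"),
    rule = sprintf(
      "spots %.3f %s 1+/-%.3f; ISS %.3f %s 1+/-%.3f; dirs %s",
      sp$value, ifelse(pass_sp, "outside", "within"), band_sp,
      is_$value, ifelse(pass_is, "outside", "within"), band_is,
      ifelse(same_dir, "agree", "disagree")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_verdict", "data.frame")
  out
}

#' Rank primary hits and select the deconvolution candidate set
#'
#' Per marker, hits are ranked by the maximal absolute log fold-change over
#' the two spot parameters; the top `n_top` are retained (ties at the last
#' rank keep all tied genes). Genes that hit two or more markers are added
#' regardless of rank.
#'
#' @param verdicts `gene_verdict` table from [call_primary_hits()].
#' @param n_top Hits kept per marker (default 10).
#' @return data.frame: `gene`, `marker`, `deviation`, `direction`, `rank`,
#'   `selected`, `reason` (`"top"`, `"multi_marker"`, or `""`). Attribute
#'   `candidates` holds the unique selected gene set.
#' @export
rank_candidates <- function(verdicts, n_top = 10L) {
  need_cols(verdicts, c("gene", "marker", "deviation", "direction",
                        "is_hit"), "verdicts")
  hits <- verdicts[verdicts$is_hit, ]
  multi <- names(which(tapply(hits$marker, hits$gene,
                              function(m) length(unique(m))) >= 2))
  rows <- list()
  for (m in unique(verdicts$marker)) {
    h <- hits[hits$marker == m, ]
    if (!nrow(h)) next
    h <- h[order(-h$deviation, h$gene), ]
    h$rank <- seq_len(nrow(h))
    if (nrow(h) < n_top) {
      message(sprintf("rank_candidates: marker %s has only %d hits (< %d); all retained",
                      m, nrow(h), n_top))
      cutoff <- -Inf
    } else {
      cutoff <- h$deviation[n_top]  # ties at rank n_top kept
    }
    top <- h$deviation >= cutoff
    via_multi <- h$gene %in% multi
    h$selected <- top | via_multi
    h$reason <- ifelse(top, "top", ifelse(via_multi, "multi_marker", ""))
    rows[[m]] <- h[, c("gene", "marker", "deviation", "direction", "rank",
                       "selected", "reason")]
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), marker = character(),
               deviation = numeric(), direction = character(),
               rank = integer(), selected = logical(), reason = character())
  rownames(out) <- NULL
  attr(out, "candidates") <- sort(unique(out$gene[out$selected]))
  out
}

#' Cytotoxicity filter parameters
#'
#' @param observables Morphology columns inspected.
#' @param cutoff Robust-z cutoff per observable (single value or named
#'   vector, > 0; default 3).
#' @param max_toxic_sirnas_per_gene Genes with more than this many toxic
#'   siRNAs are excluded (default 1).
#' @return List of class `toxicity_params`.
#' @export
toxicity_params <- function(observables = c("n_cells", "nuc_intensity",
                                            "nuc_area", "cyto_intensity",
                                            "cyto_area"),
                            cutoff = 3, max_toxic_sirnas_per_gene = 1L) {
  assert_that(all(cutoff > 0), "toxicity_params: cutoffs must be > 0")
  structure(list(observables = observables, cutoff = cutoff,
                 max_toxic_sirnas_per_gene = max_toxic_sirnas_per_gene),
            class = "toxicity_params")
}

#' Flag cytotoxic siRNAs from well morphology summaries
#'
#' An siRNA is flagged toxic when, for any observable, the robust z of its
#' replicate mean against the `sicon` wells exceeds the cutoff. The center
#' is the same plate's sicon median; the scale is the MAD of sicon
#' deviations from their plate medians pooled across plates (a dozen
#' sicon wells per plate make an unusably noisy per-plate MAD). When an
#' siRNA appears on several plates (one per marker), its per-plate z
#' values are aggregated by the median, so a genuine cytotoxic phenotype
#' (which reproduces on every plate) is kept while single-plate
#' estimation noise is not. Genes with more than
#' `max_toxic_sirnas_per_gene` toxic siRNAs are marked excluded.
#'
#' @param wells `well_summary` data.frame with morphology columns.
#' @param params A [toxicity_params()] object.
#' @return List with `sirnas` (data.frame `gene`, `sirna`, `toxic`,
#'   `worst_observable`, `worst_z`) and `excluded_genes` (character).
#' @export
flag_toxicity <- function(wells, params = toxicity_params()) {
  need_cols(wells, c("plate", "gene", "class", "sirna", params$observables),
            "wells")
  cutoffs <- params$cutoff
  if (is.null(names(cutoffs))) {
    cutoffs <- stats::setNames(rep(cutoffs[1], length(params$observables)),
                               params$observables)
  }
  tw <- wells[wells$class == "test", ]
  key <- paste(tw$plate, tw$gene, tw$sirna, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(plate = tw$plate[first], gene = tw$gene[first],
                    sirna = tw$sirna[first], stringsAsFactors = FALSE)
  k2 <- paste(res$gene, res$sirna, sep = "\r")
  f2 <- !duplicated(k2)
  sirnas <- data.frame(gene = res$gene[f2], sirna = res$sirna[f2],
                       toxic = FALSE, worst_observable = NA_character_,
                       worst_z = 0, stringsAsFactors = FALSE)
  k_s <- paste(sirnas$gene, sirnas$sirna, sep = "\r")
  for (obs in params$observables) {
    x <- wells[[obs]]
    sic <- wells$class == "sicon"
    sic_med <- tapply(x[sic], wells$plate[sic], stats::median)
    # pooled scale: sicon deviations from their own plate medians
    dev <- x[sic] - as.numeric(sic_med[wells$plate[sic]])
    scale <- rmad(dev, center = 0)
    if (scale == 0 || is.na(scale)) scale <- NA
    means <- tapply(tw[[obs]], key, mean, na.rm = TRUE)
    z_plate <- (as.numeric(means[key[first]]) -
                  as.numeric(sic_med[res$plate])) / scale
    # median across the siRNA's plates (one per marker)
    z <- as.numeric(tapply(z_plate, k2, stats::median, na.rm = TRUE)[k_s])
    exceed <- !is.na(z) & abs(z) > cutoffs[[obs]]
    update <- !is.na(z) & abs(z) > abs(sirnas$worst_z)
    sirnas$worst_z[update] <- z[update]
    sirnas$worst_observable[update] <- obs
    sirnas$toxic <- sirnas$toxic | exceed
  }
  n_tox <- tapply(sirnas$toxic, sirnas$gene, sum)
  excluded <- names(n_tox)[n_tox > params$max_toxic_sirnas_per_gene]
  list(sirnas = sirnas, excluded_genes = excluded)
}

#' Deconvolution validation rule
#'
#' With four individual siRNAs per gene/marker: validated iff at least 3 of
#' 4 non-toxic siRNAs pass the SD criterion; if exactly one siRNA is toxic,
#' validated iff at least 2 of the remaining 3 pass; two or more toxic
#' siRNAs exclude the gene.
#'
#' @param passes Logical vector, length 4: SD-criterion result per siRNA.
#' @param toxic Logical vector, length 4: toxicity flag per siRNA.
#' @return List: `stage` (`"validated"`, `"not_validated"` or
#'   `"excluded_toxicity"`), `n_pass`, `n_toxic`, `rule` (trail string).
#' @export
#' @examples
#' validate_deconvolution(c(TRUE, TRUE, TRUE, FALSE),
#'                        rep(FALSE, 4))$stage  # "validated"
validate_deconvolution <- function(passes, toxic = rep(FALSE, 4)) {
  assert_that(length(passes) == 4 && length(toxic) == 4,
              "validate_deconvolution: exactly 4 siRNAs per gene required")
  passes <- as.logical(passes); toxic <- as.logical(toxic)
  n_toxic <- sum(toxic)
  n_pass <- sum(passes & !toxic)
  if (n_toxic >= 2) {
    stage <- "excluded_toxicity"
    rule <- sprintf("%d toxic siRNAs (> 1): gene removed", n_toxic)
  } else if (n_toxic == 1) {
    stage <- if (n_pass >= 2) "validated" else "not_validated"
    rule <- sprintf("1 toxic; %d/3 remaining pass (need >= 2)", n_pass)
  } else {
    stage <- if (n_pass >= 3) "validated" else "not_validated"
    rule <- sprintf("0 toxic; %d/4 pass (need >= 3)", n_pass)
  }
  list(stage = stage, n_pass = n_pass, n_toxic = n_toxic, rule = rule)
}

#' Validate all genes of a deconvolution screen
#'
#' Applies [validate_deconvolution()] per (gene, marker) using per-siRNA
#' verdicts and toxicity flags.
#'
#' @param verdicts `gene_verdict` table over individual siRNAs (4 per
#'   gene/marker).
#' @param toxicity Result of [flag_toxicity()], or `NULL` for no toxicity.
#' @param direction Optional required direction for a pass (`"increase"`,
#'   `"decrease"`, or `"either"`, the default).
#' @return data.frame: `gene`, `marker`, `stage`, `n_pass`, `n_toxic`,
#'   `direction`, `rule`.
#' @export
validate_screen <- function(verdicts, toxicity = NULL,
                            direction = c("either", "increase",
                                          "decrease")) {
  direction <- match.arg(direction)
  need_cols(verdicts, c("gene", "marker", "sirna", "is_hit", "direction"),
            "verdicts")
  tox_map <- if (!is.null(toxicity)) {
    stats::setNames(toxicity$sirnas$toxic, toxicity$sirnas$sirna)
  } else {
    stats::setNames(logical(), character())
  }
  rows <- list()
  for (g in unique(verdicts$gene)) {
    for (m in unique(verdicts$marker[verdicts$gene == g])) {
      v <- verdicts[verdicts$gene == g & verdicts$marker == m, ]
      v <- v[order(v$sirna), ]
      if (nrow(v) != 4) {
        stop_named("validate_screen: gene %s marker %s has %d siRNAs (need 4)",
                   g, m, nrow(v))
      }
      pass <- v$is_hit
      if (direction != "either") pass <- pass & v$direction == direction
      else {
        # require a consistent direction across passing siRNAs
        dirs <- unique(v$direction[pass])
        if (length(dirs) > 1) {
          dom <- names(sort(table(v$direction[pass]), decreasing = TRUE))[1]
          pass <- pass & v$direction == dom
        }
      }
      tox <- unname(tox_map[v$sirna])
      tox[is.na(tox)] <- FALSE
      r <- validate_deconvolution(pass, tox)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, marker = m, stage = r$stage, n_pass = r$n_pass,
        n_toxic = r$n_toxic,
        direction = if (any(pass)) v$direction[pass][1] else "none",
        rule = r$rule, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify treatment response of a validated candidate
#'
#' Given per-treatment SD-criterion passes (each treatment arm normalized
#' to its own sicon) and adjusted significance, assigns the response
#' category: candidates passing in both basal (DMSO) and induced (Torin1)
#' conditions score `"DMSO+Torin1"`; otherwise single-arm categories; a
#' condition that passes no SD criterion but shows a significant spot
#' increase is kept as `"significant-only"`.
#'
#' @param passes Named logical vector with entries `DMSO`, `Torin1`,
#'   `BafA1` (missing arms allowed; result is flagged).
#' @param p_adj Named numeric vector of Bonferroni-adjusted p values per
#'   treatment (optional).
#' @param alpha Significance level for the rescue category (default 0.05).
#' @return List: `category`, `flagged` (TRUE when arms were missing).
#' @export
classify_treatment_response <- function(passes, p_adj = NULL, alpha = 0.05) {
  arms <- c("DMSO", "Torin1", "BafA1")
  flagged <- !all(arms %in% names(passes))
  if (flagged) {
    warning("classify_treatment_response: missing treatment arm(s); classifying on available arms")
  }
  p <- function(a) a %in% names(passes) && isTRUE(unname(passes[[a]]))
  category <- if (p("DMSO") && p("Torin1")) "DMSO+Torin1"
  else if (p("Torin1")) "Torin1"
  else if (p("DMSO")) "DMSO"
  else if (p("BafA1")) "BafA1"
  else if (!is.null(p_adj) && any(p_adj < alpha, na.rm = TRUE)) {
    "significant-only"
  } else "none"
  list(category = category, flagged = flagged)
}

#' Group-vs-control significance with Bonferroni adjustment
#'
#' One-way ANOVA-style comparison of a treatment group against the control
#' group (for two groups the F test equals the pooled t test), with the raw
#' p value multiplied by the number of comparisons in the family.
#'
#' @param group,control Numeric vectors (>= 2 values each).
#' @param n_groups Number of comparisons in the family (default 1).
#' @return List: `p_raw`, `p_adj` (capped at 1), `stars` (`""`, `"*"`,
#'   `"**"`, `"***"`). Degenerate zero variance gives `NA` p with a flag.
#' @export
significance_vs_control <- function(group, control, n_groups = 1L) {
  group <- group[!is.na(group)]; control <- control[!is.na(control)]
  assert_that(length(group) >= 2 && length(control) >= 2,
              "significance_vs_control: need >= 2 values per group")
  pooled_var <- (stats::var(group) * (length(group) - 1) +
                   stats::var(control) * (length(control) - 1))
  if (pooled_var == 0) {
    if (mean(group) == mean(control)) {
      return(list(p_raw = 1, p_adj = 1, stars = "", degenerate = FALSE))
    }
    warning("significance_vs_control: zero within-group variance")
    return(list(p_raw = NA_real_, p_adj = NA_real_, stars = "",
                degenerate = TRUE))
  }
  d <- data.frame(y = c(group, control),
                  g = factor(rep(c("group", "control"),
                                 c(length(group), length(control)))))
  fit <- stats::aov(y ~ g, data = d)
  p_raw <- summary(fit)[[1]][["Pr(>F)"]][1]
  p_adj <- min(1, p_raw * n_groups)
  stars <- if (is.na(p_adj)) "" else if (p_adj < 0.001) "***"
  else if (p_adj < 0.01) "**" else if (p_adj < 0.05) "*" else ""
  list(p_raw = p_raw, p_adj = p_adj, stars = stars, degenerate = FALSE)
}
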