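#' Average replicate knockdown/control expression ratios
#'
#' Per gene, the mean over available experiment ratios on the linear scale
#' (set `log_scale = TRUE` for a geometric mean). Genes whose
#' between-experiment coefficient of variation exceeds `cv_cutoff` or that
#' were measured in a single experiment are flagged by the quality control.
#'
#' @param runs `ratio_runs` data.frame (`gene`, `experiment`, `ratio`).
#' @param cv_cutoff Between-experiment CV above which a gene is flagged
#'   (default 0.5).
#' @param log_scale Average log ratios instead (default FALSE).
#' @return data.frame (`ratio_table`): `gene`, `n_experiments`,
#'   `mean_ratio`, `cv`, `qc_flag` (`""`, `"high_cv"` or `"low_n"`).
#' @export
average_ratios <- function(runs, cv_cutoff = 0.5, log_scale = FALSE) {
  need_cols(runs, c("gene", "ratio"), "ratio runs")
  assert_that(all(runs$ratio > 0), "average_ratios: ratios must be > 0")
  genes <- unique(runs$gene)
  n <- tapply(runs$ratio, runs$gene, length)
  m <- if (log_scale) tapply(runs$ratio, runs$gene, geomean)
  else tapply(runs$ratio, runs$gene, mean)
  cv <- tapply(runs$ratio, runs$gene,
               function(x) if (length(x) < 2) NA_real_
               else stats::sd(x) / mean(x))
  out <- data.frame(
    gene = genes,
    n_experiments = as.integer(n[genes]),
    mean_ratio = as.numeric(m[genes]),
    cv = as.numeric(cv[genes]),
    stringsAsFactors = FALSE)
  out$qc_flag <- ifelse(out$n_experiments < 2, "low_n",
                        ifelse(!is.na(out$cv) & out$cv > cv_cutoff,
                               "high_cv", ""))
  rownames(out) <- NULL
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Fold-change gates for up/down-regulated gene sets
#'
#' Up iff mean ratio strictly exceeds `up_cut` (default 1.3); down iff
#' strictly below `down_cut` (default 0.7); everything else is neither.
#' The three sets partition the gene list.
#'
#' @param ratios `ratio_table` from [average_ratios()].
#' @param up_cut,down_cut Fold boundaries.
#' @param strict Strict inequalities at the boundary (default TRUE, per the
#'   "more than"-style definition); inclusive when FALSE.
#' @return List: `up`, `down`, `neither` (character vectors of genes) and
#'   `table` (ratios with a `de_class` column).
#' @export
threshold_de <- function(ratios, up_cut = 1.3, down_cut = 0.7,
                         strict = TRUE) {
  need_cols(ratios, c("gene", "mean_ratio"), "ratio table")
  r <- ratios$mean_ratio
  up <- if (strict) r > up_cut else r >= up_cut
  down <- if (strict) r < down_cut else r <= down_cut
  cls <- ifelse(up, "up", ifelse(down, "down", "neither"))
  ratios$de_class <- cls
  list(up = ratios$gene[up], down = ratios$gene[down],
       neither = ratios$gene[cls == "neither"], table = ratios)
}

#' Curated panel table for a supplied gene list
#'
#' Subsets a DE-classified ratio table to a curated panel (e.g. autophagy /
#' mTORC1 / lysosome genes), preserving the panel's ordering; panel genes
#' absent from the measurements appear with missing values.
#'
#' @param de Result of [threshold_de()].
#' @param panel Character vector of panel genes, or a path to a plain-text
#'   file with one gene per line (`#` comments allowed).
#' @return data.frame: `gene`, `mean_ratio`, `de_class`, `qc_flag`,
#'   `measured`.
#' @export
curate_panel <- function(de, panel) {
  if (length(panel) == 1 && file.exists(panel)) {
    panel <- readLines(panel)
    panel <- trimws(sub("#.*$", "", panel))
    panel <- panel[nzchar(panel)]
  }
  tab <- de$table
  idx <- match(panel, tab$gene)
  data.frame(
    gene = panel,
    mean_ratio = tab$mean_ratio[idx],
    de_class = ifelse(is.na(idx), NA_character_, tab$de_class[idx]),
    qc_flag = ifelse(is.na(idx), NA_character_,
                     if ("qc_flag" %in% names(tab)) tab$qc_flag[idx]
                     else ""),
    measured = !is.na(idx),
    stringsAsFactors = FALSE)
}
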