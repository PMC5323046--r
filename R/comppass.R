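#' Aggregate AP-MS runs into per-bait-prey spectral-count statistics
#'
#' APSM (average peptide spectral matches) is the mean count of a prey over
#' all of its bait's runs, counting zero for runs in which the prey was not
#' detected; reproducibility `p` is the number of runs with a nonzero
#' count.
#'
#' @param runs `spectral_runs` data.frame (`bait`, `prey`, `run`, `counts`).
#' @return data.frame (`spectral_count_table`): `bait`, `prey`, `apsm`,
#'   `p` (runs detected), `n_runs` (the bait's run count), `total`.
#' @export
#' @examples
#' runs <- data.frame(bait = "B1", prey = "X", run = 1:2, counts = c(4, 6))
#' aggregate_runs(runs)$apsm  # 5
aggregate_runs <- function(runs) {
  need_cols(runs, c("bait", "prey", "run", "counts"), "runs")
  assert_that(all(runs$counts >= 0), "aggregate_runs: counts must be >= 0")
  dup <- duplicated(runs[, c("bait", "prey", "run")])
  if (any(dup)) {
    stop_named("aggregate_runs: duplicate (bait, prey, run) entries, e.g. %s/%s run %s",
               runs$bait[dup][1], runs$prey[dup][1], runs$run[dup][1])
  }
  n_runs <- tapply(runs$run, runs$bait, function(r) length(unique(r)))
  key <- paste(runs$bait, runs$prey, sep = "\r")
  first <- !duplicated(key)
  total <- tapply(runs$counts, key, sum)
  det <- tapply(runs$counts, key, function(x) sum(x > 0))
  out <- data.frame(
    bait = runs$bait[first], prey = runs$prey[first],
    apsm = as.numeric(total[key[first]]) /
      as.numeric(n_runs[runs$bait[first]]),
    p = as.integer(det[key[first]]),
    n_runs = as.integer(n_runs[runs$bait[first]]),
    total = as.numeric(total[key[first]]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("spectral_count_table", "data.frame")
  out
}

#' Weighted, normalized D-score (WD^N) interaction scoring
#'
#' For each bait-prey pair with `K` baits in the background, prey frequency
#' `f` (number of baits retrieving the prey) and reproducibility `p` (runs
#' detected), the D-score is `sqrt(APSM * (K / f)^p)`. The weighted variant
#' multiplies `K / f` by a weight `w >= 1` derived from the dispersion of
#' the prey's APSM across the baits that retrieve it
#' (`w = max(1, sd / mean)`; bait-unique preys get `w = 1`), boosting preys
#' that are recovered broadly but strongly by only some baits. WD scores
#' are then normalized by the score magnitude at a background percentile
#' (default 98th) so that 1.0 is the HCIP boundary. A pair is a
#' high-confidence candidate interacting protein (HCIP) iff `WD^N >= 1` and
#' `APSM >= 2`.
#'
#' @param table `spectral_count_table` from [aggregate_runs()].
#' @param background Character vector of baits forming the frequency
#'   background (>= 10; default: all baits in `table`).
#' @param params List: `weighted` (default TRUE), `norm_percentile`
#'   (default 0.98), `apsm_min` (default 2), `wdn_min` (default 1).
#' @param annotations Optional named character vector prey -> class
#'   (`"autophagy-related"`, `"other known"`); unlisted preys are
#'   `"orphan"`.
#' @return data.frame (`hcip_records`): `bait`, `prey`, `apsm`, `f`, `p`,
#'   `weight`, `d_score`, `wd_score`, `wdn_score`, `is_hcip`,
#'   `annotation`. Attribute `norm_factor` holds the normalization divisor.
#' @export
score_wdn <- function(table, background = NULL, params = list(),
                      annotations = NULL) {
  need_cols(table, c("bait", "prey", "apsm", "p"), "spectral count table")
  defaults <- list(weighted = TRUE, norm_percentile = 0.98, apsm_min = 2,
                   wdn_min = 1)
  params <- utils::modifyList(defaults, params)
  if (is.null(background)) background <- unique(table$bait)
  assert_that(length(background) >= 10,
              "score_wdn: background must contain >= 10 baits")
  K <- length(background)

  bg <- table[table$bait %in% background & table$apsm > 0, ]
  f_tab <- tapply(bg$bait, bg$prey, function(b) length(unique(b)))
  w_tab <- tapply(bg$apsm, bg$prey, function(a) {
    if (length(a) < 2) 1 else max(1, stats::sd(a) / mean(a))
  })

  f <- as.numeric(f_tab[table$prey])
  unseen <- is.na(f)
  if (any(unseen)) {
    message(sprintf("score_wdn: %d prey(s) absent from background stats; treated as bait-unique (f = 1)",
                    sum(unseen)))
    f[unseen] <- 1
  }
  w <- as.numeric(w_tab[table$prey])
  w[is.na(w)] <- 1
  if (!params$weighted) w <- rep(1, nrow(table))

  d <- sqrt(table$apsm * (K / f)^table$p)
  wd <- sqrt(table$apsm * (w * K / f)^table$p)
  norm_factor <- as.numeric(stats::quantile(wd, params$norm_percentile,
                                            names = FALSE, type = 7))
  if (!is.finite(norm_factor) || norm_factor <= 0) norm_factor <- 1
  wdn <- wd / norm_factor

  ann <- rep("orphan", nrow(table))
  if (!is.null(annotations)) {
    hit <- table$prey %in% names(annotations)
    ann[hit] <- unname(annotations[table$prey[hit]])
  }
  out <- data.frame(
    bait = table$bait, prey = table$prey, apsm = table$apsm,
    f = as.integer(f), p = table$p, weight = w,
    d_score = d, wd_score = wd, wdn_score = wdn,
    is_hcip = wdn >= params$wdn_min & table$apsm >= params$apsm_min,
    annotation = ann, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "norm_factor") <- norm_factor
  class(out) <- c("hcip_records", "data.frame")
  out
}

#' Export an HCIP interaction network as a tab-separated edge list
#'
#' One edge per HCIP with the WD^N score and a display weight clamped to
#' [1, 15]; node annotation classes travel in a `class` column. Rows are
#' ordered (bait, then prey) so output is stable; [read_network()] performs
#' the round trip.
#'
#' @param hcips `hcip_records` table ([score_wdn()]).
#' @param path Output file path (TSV).
#' @param hcip_only Keep only `is_hcip` edges (default TRUE).
#' @return The written edge data.frame, invisibly.
#' @export
export_network <- function(hcips, path, hcip_only = TRUE) {
  need_cols(hcips, c("bait", "prey", "wdn_score", "annotation"), "hcips")
  e <- if (hcip_only) hcips[hcips$is_hcip, ] else hcips
  edges <- data.frame(
    bait = e$bait, prey = e$prey,
    wdn_score = e$wdn_score,
    display_weight = pmin(15, pmax(1, e$wdn_score)),
    class = e$annotation, stringsAsFactors = FALSE)
  edges <- edges[order(edges$bait, edges$prey), , drop = FALSE]
  rownames(edges) <- NULL
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges)
}

#' @rdname export_network
#' @export
read_network <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
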