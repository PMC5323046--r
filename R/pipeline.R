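#' Screen run configuration
#'
#' Builds and validates the configuration consumed by [run_screen()].
#' Unknown keys are rejected so typos fail loudly; every run writes the
#' fully resolved configuration beside its outputs.
#'
#' @param ... Key = value overrides of the defaults listed below.
#' @return List of class `run_config`.
#'
#' @details Keys and defaults: `n_genes` (186), `markers` (the five-marker
#'   panel), `n_hits` (10 planted hit genes), `hit_fold` (2.5, applied to
#'   both spot parameters), `seed` (42), `replicates` (4), `treatments`
#'   ("none"), `sd_scope` ("pooled"), `thresholds_k` (per-marker SD
#'   multipliers, see [hit_thresholds()]), `n_top` (10), `deconvolute`
#'   (TRUE), `toxic_sirnas` (NULL or data.frame for [effect_model()]),
#'   `baseline` (list of [effect_model()] baseline overrides), `outdir`
#'   (NULL: keep results in memory only).
#' @export
screen_config <- function(...) {
  defaults <- list(
    n_genes = 186L,
    markers = c("WIPI2", "ATG12", "LC3B", "GABARAP", "STX17"),
    n_hits = 10L,
    hit_fold = 2.5,
    seed = 42L,
    replicates = 4L,
    treatments = "none",
    sd_scope = "pooled",
    thresholds_k = c(WIPI2 = 3, ATG12 = 3, LC3B = 2, GABARAP = 2,
                     STX17 = 2),
    n_top = 10L,
    deconvolute = TRUE,
    toxic_sirnas = NULL,
    baseline = list(),
    outdir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop_named("screen_config: unknown key(s): %s",
               paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "run_config"
  cfg
}

log_stage <- function(log, stage, ...) {
  line <- sprintf("[%s] stage=%s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  paste(sprintf("%s=%s", names(list(...)),
                                unlist(list(...))), collapse = " "))
  c(log, line)
}

#' Run the screen pipeline end to end on synthetic data
#'
#' Generates a primary pooled-siRNA screen from the configuration's effect
#' world, normalizes it to the non-targeting control, calls
#' standard-deviation hits, ranks and selects deconvolution candidates,
#' then (optionally) simulates the four-oligo deconvolution screen,
#' applies the toxicity filter and the 3-of-4 / 2-of-3 validation rule.
#' With `outdir` set, all stage tables are written as CSV, the quality
#' report and resolved configuration as JSON, plus a structured run log.
#'
#' @param config A [screen_config()] object (or arguments to build one).
#' @return List: `config`, `model`, `layout`, `wells`, `quality`,
#'   `normalized`, `verdicts`, `ranking`, `candidates`, and when
#'   deconvoluted `decon_wells`, `decon_verdicts`, `toxicity`,
#'   `validation`, `validated_genes`; plus `hit_genes` (planted truth) and
#'   `log`.
#' @export
run_screen <- function(config = screen_config()) {
  if (!inherits(config, "run_config")) config <- do.call(screen_config, config)
  log <- character()
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  hit_genes <- with_seed(derive_seed(config$seed, 99L),
                         sort(sample(genes, config$n_hits)))
  effects <- if (config$n_hits > 0) {
    data.frame(gene = hit_genes, fold_spots = config$hit_fold,
               fold_iss = config$hit_fold)
  } else NULL
  model <- effect_model(gene_effects = effects,
                        toxic_sirnas = config$toxic_sirnas,
                        baseline = config$baseline, seed = config$seed)

  layout <- make_screen_layout(config$n_genes, markers = config$markers,
                               sirnas_per_gene = 1, seed = config$seed,
                               genes = genes,
                               treatments = config$treatments,
                               replicates = config$replicates)
  wells <- simulate_well_table(layout, model)
  log <- log_stage(log, "simulate", seed = config$seed, wells = nrow(wells))

  quality <- quality_report(wells)
  normalized <- normalize_to_control(wells, sd_scope = config$sd_scope)
  log <- log_stage(log, "normalize", rows = nrow(normalized))

  thr <- hit_thresholds(k = config$thresholds_k)
  verdicts <- call_primary_hits(normalized, thr)
  ranking <- rank_candidates(verdicts, n_top = config$n_top)
  candidates <- attr(ranking, "candidates")
  log <- log_stage(log, "call_hits", hits = sum(verdicts$is_hit),
                   candidates = length(candidates))

  res <- list(config = config, model = model, layout = layout,
              wells = wells, quality = quality, normalized = normalized,
              verdicts = verdicts, ranking = ranking,
              candidates = candidates, hit_genes = hit_genes)

  if (config$deconvolute && length(candidates)) {
    dlay <- make_screen_layout(length(candidates),
                               markers = config$markers,
                               sirnas_per_gene = 4,
                               seed = derive_seed(config$seed, 2L),
                               genes = candidates,
                               treatments = config$treatments,
                               replicates = config$replicates)
    dwells <- simulate_well_table(dlay, model)
    dnorm <- normalize_to_control(dwells, sd_scope = config$sd_scope)
    dverd <- call_primary_hits(dnorm, thr)
    tox <- flag_toxicity(dwells)
    validation <- validate_screen(dverd, tox)
    validated <- sort(unique(
      validation$gene[validation$stage == "validated"]))
    log <- log_stage(log, "deconvolute", genes = length(candidates),
                     validated = length(validated))
    res <- c(res, list(decon_wells = dwells, decon_verdicts = dverd,
                       toxicity = tox, validation = validation,
                       validated_genes = validated))
  }
  res$log <- log

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(config$outdir, f)
    write_csv_out(as.data.frame(layout), o("layout.csv"))
    write_csv_out(as.data.frame(wells), o("wells.csv"))
    write_csv_out(as.data.frame(normalized), o("normalized.csv"))
    write_csv_out(as.data.frame(verdicts), o("verdicts.csv"))
    write_csv_out(as.data.frame(ranking), o("ranking.csv"))
    jsonlite::write_json(quality, o("quality.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    cfg_out <- config
    cfg_out$markers <- as.list(cfg_out$markers)
    jsonlite::write_json(unclass(cfg_out), o("config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    if (!is.null(res$validation)) {
      write_csv_out(res$validation, o("validation.csv"))
      write_csv_out(data.frame(gene = res$validated_genes),
                    o("validated_genes.csv"))
    }
    writeLines(res$log, o("run.log"))
  }
  res
}

#' Write self-contained demo fixtures to disk
#'
#' Each profile produces input files plus ground-truth sidecars so every
#' pipeline stage can be exercised from files alone. Output is
#' byte-identical for a fixed seed.
#'
#' @param profile One of `"small-screen"` (plate map + well table, 20
#'   genes), `"imaging-demo"` (4 rendered wells as PGM pairs + truth
#'   JSON), `"apms-demo"` (spectral-count runs), `"qpcr-demo"` (Ct table),
#'   `"expression-demo"` (ratio tables).
#' @param seed Integer seed.
#' @param outdir Output directory (created if needed).
#' @return Character vector of written files, invisibly.
#' @export
make_fixtures <- function(profile, seed = 1L, outdir = ".") {
  profiles <- c("small-screen", "imaging-demo", "apms-demo", "qpcr-demo",
                "expression-demo")
  if (!profile %in% profiles) {
    stop_named("make_fixtures: unknown profile '%s' (known: %s)", profile,
               paste(profiles, collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  o <- function(f) file.path(outdir, f)
  written <- character()
  if (profile == "small-screen") {
    genes <- sprintf("G%03d", 1:20)
    eff <- data.frame(gene = genes[1:3], fold_spots = 2.5, fold_iss = 2.5)
    model <- effect_model(gene_effects = eff, seed = seed)
    lay <- make_screen_layout(20, markers = "LC3B", sirnas_per_gene = 1,
                              seed = seed, genes = genes)
    wells <- simulate_well_table(lay, model)
    written <- c(write_csv_out(as.data.frame(lay), o("plate_map.csv")),
                 write_csv_out(as.data.frame(wells), o("well_table.csv")))
    truth <- list(hit_genes = genes[1:3], hit_fold = 2.5, seed = seed)
    jsonlite::write_json(truth, o("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, o("truth.json"))
  } else if (profile == "imaging-demo") {
    for (i in 1:4) {
      img <- render_well_image(n_cells = 8, spots_per_cell = 4, size = 192,
                               seed = derive_seed(seed, i))
      written <- c(written,
                   write_well_image(img, o(sprintf("well%02d", i))))
    }
  } else if (profile == "apms-demo") {
    net <- list(B001 = c(PREY_A = 30, PREY_B = 25),
                B002 = c(PREY_C = 40))
    runs <- simulate_apms(12, prey_network = net, seed = seed)
    written <- write_csv_out(runs, o("spectral_runs.csv"))
    jsonlite::write_json(net, o("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, o("truth.json"))
  } else if (profile == "qpcr-demo") {
    kd <- c(GENE1 = 0.2, GENE2 = 0.5, GENE3 = 0.8)
    ct <- simulate_qpcr(names(kd), kd, seed = seed)
    written <- write_csv_out(as.data.frame(ct), o("ct_table.csv"))
    jsonlite::write_json(as.list(kd), o("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, o("truth.json"))
  } else if (profile == "expression-demo") {
    truth <- c(E0001 = 1.8, E0002 = 0.5, E0003 = 1.0)
    runs <- simulate_expression(50, de_truth = truth, seed = seed)
    written <- write_csv_out(as.data.frame(runs), o("ratio_runs.csv"))
    jsonlite::write_json(as.list(truth), o("truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, o("truth.json"))
  }
  invisible(written)
}
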