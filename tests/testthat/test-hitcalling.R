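test_that("SD-criterion hit calling applies per-marker bands on both parameters", {
  nm <- rbind(
    norm_row("G1", "LC3B", 1.25, 1.25),    # band 1 +/- 0.20 -> hit
    norm_row("G1", "WIPI2", 1.25, 1.25),   # band 1 +/- 0.30 -> no hit
    norm_row("G2", "LC3B", 1.50, 0.70),    # directions disagree -> no hit
    norm_row("G3", "LC3B", 0.70, 0.75),    # decrease hit
    norm_row("G4", "LC3B", 1.25, 1.05))    # ISS inside band -> no hit
  v <- call_primary_hits(nm)
  verdict <- function(g, m) v$is_hit[v$gene == g & v$marker == m]
  expect_true(verdict("G1", "LC3B"))
  expect_false(verdict("G1", "WIPI2"))
  expect_false(verdict("G2", "LC3B"))
  expect_true(verdict("G3", "LC3B"))
  expect_equal(v$direction[v$gene == "G3"], "decrease")
  expect_false(verdict("G4", "LC3B"))
  # rule trail is human readable
  expect_match(v$rule[v$gene == "G2"], "disagree")

  # direction filter drops decreases
  v_inc <- call_primary_hits(nm, hit_thresholds(direction = "increase"))
  expect_false(v_inc$is_hit[v_inc$gene == "G3"])

  # a condition missing one parameter is skipped with a message
  nm_half <- nm[!(nm$gene == "G4" & nm$parameter == "iss_per_cell"), ]
  expect_message(v2 <- call_primary_hits(nm_half), "skipped")
  expect_false("G4" %in% v2$gene)
})

test_that("lowering the SD multiplier never removes a hit (cascade monotonicity)", {
  set.seed(11)
  genes <- sprintf("G%02d", 1:30)
  nm <- do.call(rbind, lapply(genes, function(g) {
    v <- exp(rnorm(1, 0, 0.25))
    norm_row(g, "LC3B", v * exp(rnorm(1, 0, 0.02)),
             v * exp(rnorm(1, 0, 0.02)))
  }))
  for (k_hi in c(3, 2.5, 2)) {
    hits_hi <- call_primary_hits(nm, hit_thresholds(k = k_hi))
    hits_lo <- call_primary_hits(nm, hit_thresholds(k = k_hi - 0.5))
    expect_true(all(hits_hi$gene[hits_hi$is_hit] %in%
                      hits_lo$gene[hits_lo$is_hit]))
  }
})

test_that("candidate ranking keeps the top ten plus multi-marker hits", {
  # 12 hits on STX17 with distinct deviations; G11 also hits LC3B
  nm <- do.call(rbind, c(
    lapply(1:12, function(i) {
      norm_row(sprintf("G%02d", i), "STX17", 1 + 0.2 + i * 0.1,
               1 + 0.2 + i * 0.1)
    }),
    list(norm_row("G01", "LC3B", 1.9, 1.9))))
  v <- call_primary_hits(nm)
  r <- rank_candidates(v, n_top = 10)
  stx <- r[r$marker == "STX17", ]
  # G01 has the smallest deviation (rank 12) but hits two markers
  expect_equal(sum(stx$selected & stx$reason == "top"), 10)
  expect_true(stx$selected[stx$gene == "G01"])
  expect_equal(stx$reason[stx$gene == "G01"], "multi_marker")
  expect_false(stx$selected[stx$gene == "G02"])  # rank 11, single marker

  # tie at rank 10 keeps all tied genes
  nm_tie <- do.call(rbind, lapply(1:11, function(i) {
    dev <- if (i >= 10) 1.5 else 1.5 + i * 0.1
    norm_row(sprintf("T%02d", i), "STX17", dev, dev)
  }))
  v_tie <- call_primary_hits(nm_tie)
  r_tie <- rank_candidates(v_tie, n_top = 10)
  expect_equal(sum(r_tie$selected), 11)

  # fewer hits than n_top: all retained with a message
  expect_message(r_few <- rank_candidates(
    call_primary_hits(norm_row("G1", "LC3B", 1.5, 1.5))), "all retained")
  expect_true(all(r_few$selected))
})

test_that("toxicity flags follow the robust-z rule on plate sicon", {
  lay <- flat_layout(c("GTOX", "GOK"), 4, n_sicon = 12)
  m <- effect_model(
    toxic_sirnas = data.frame(sirna = "GTOX_si1", cell_fold = 0.2,
                              morph_shift = 0.4),
    seed = 8)
  lay$sirna[lay$gene == "GTOX"] <- "GTOX_si1"
  lay$sirna[lay$gene == "GOK"] <- "GOK_si1"
  wells <- simulate_well_table(lay, m)
  tox <- flag_toxicity(wells)
  expect_true(tox$sirnas$toxic[tox$sirnas$sirna == "GTOX_si1"])
  expect_false(tox$sirnas$toxic[tox$sirnas$sirna == "GOK_si1"])
  expect_equal(tox$excluded_genes, character(0))

  # all observables within 1 MAD -> never flagged
  calm <- wells[wells$class %in% c("sicon", "test") & wells$gene != "GTOX", ]
  tox2 <- flag_toxicity(calm)
  expect_false(any(tox2$sirnas$toxic))
})

test_that("genes with more than one toxic siRNA are excluded", {
  lay <- flat_layout("G1", 4, n_sicon = 12)
  lay4 <- do.call(rbind, lapply(1:4, function(i) {
    x <- lay[lay$class == "test", ]
    x$sirna <- sprintf("G1_si%d", i)
    x
  }))
  lay_all <- rbind(lay[lay$class == "sicon", ], lay4)
  m <- effect_model(
    toxic_sirnas = data.frame(sirna = c("G1_si1", "G1_si2"),
                              cell_fold = 0.15, morph_shift = 0.5),
    seed = 9)
  wells <- simulate_well_table(lay_all, m)
  tox <- flag_toxicity(wells)
  expect_equal(sum(tox$sirnas$toxic), 2)
  expect_equal(tox$excluded_genes, "G1")
})

test_that("deconvolution rule equals the brute-force oracle on all patterns", {
  grid <- expand.grid(p1 = c(TRUE, FALSE), p2 = c(TRUE, FALSE),
                      p3 = c(TRUE, FALSE), p4 = c(TRUE, FALSE),
                      t1 = c(TRUE, FALSE), t2 = c(TRUE, FALSE),
                      t3 = c(TRUE, FALSE), t4 = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    passes <- unlist(grid[i, 1:4])
    toxic <- unlist(grid[i, 5:8])
    got <- validate_deconvolution(passes, toxic)$stage
    expect_identical(got, oracle_decon(passes, toxic),
                     info = paste(i, paste(passes, collapse = ""),
                                  paste(toxic, collapse = "")))
  }
  # spec worked examples
  expect_equal(validate_deconvolution(c(TRUE, TRUE, TRUE, FALSE))$stage,
               "validated")
  expect_equal(validate_deconvolution(
    c(TRUE, TRUE, FALSE, FALSE), c(FALSE, FALSE, FALSE, TRUE))$stage,
    "validated")  # 2 of 3 after one toxic removal
  expect_error(validate_deconvolution(c(TRUE, TRUE)), "4 siRNAs")
})

test_that("treatment response classification follows the category precedence", {
  expect_equal(classify_treatment_response(
    c(DMSO = TRUE, Torin1 = TRUE, BafA1 = FALSE))$category, "DMSO+Torin1")
  expect_equal(classify_treatment_response(
    c(DMSO = FALSE, Torin1 = TRUE, BafA1 = FALSE))$category, "Torin1")
  expect_equal(classify_treatment_response(
    c(DMSO = FALSE, Torin1 = FALSE, BafA1 = TRUE))$category, "BafA1")
  expect_equal(classify_treatment_response(
    c(DMSO = FALSE, Torin1 = FALSE, BafA1 = FALSE),
    p_adj = c(Torin1 = 0.01))$category, "significant-only")
  expect_equal(classify_treatment_response(
    c(DMSO = FALSE, Torin1 = FALSE, BafA1 = FALSE))$category, "none")
  expect_warning(r <- classify_treatment_response(c(DMSO = TRUE)),
                 "missing")
  expect_true(r$flagged)
})

test_that("significance against control uses ANOVA F with Bonferroni", {
  expect_equal(significance_vs_control(c(1, 1, 1), c(1, 1, 1))$p_adj, 1)

  # separation of 10 sigma with n = 4 -> adjusted p < 0.001
  set.seed(2)
  g <- rnorm(4, 10, 1); ctl <- rnorm(4, 0, 1)
  r <- significance_vs_control(g, ctl, n_groups = 5)
  expect_lt(r$p_adj, 0.001)
  expect_equal(r$stars, "***")

  # Bonferroni is plain multiplication, capped at 1
  set.seed(5)
  repeat {  # find a draw with raw p in (0.01, 0.05)
    a <- rnorm(5, 1.5, 1); b <- rnorm(5, 0, 1)
    raw <- significance_vs_control(a, b, n_groups = 1)
    if (raw$p_raw > 0.01 && raw$p_raw < 0.05) break
  }
  adj <- significance_vs_control(a, b, n_groups = 5)
  expect_equal(adj$p_adj, min(1, raw$p_raw * 5), tolerance = 1e-12)
  expect_equal(adj$stars, if (adj$p_adj < 0.05) "*" else "")

  expect_warning(d <- significance_vs_control(c(1, 1), c(2, 2)),
                 "zero within-group")
  expect_true(is.na(d$p_adj))
})

test_that("validate_screen applies the rule per gene/marker with toxicity", {
  v <- rbind(
    data.frame(gene = "G1", marker = "LC3B", sirna = sprintf("G1_si%d", 1:4),
               is_hit = c(TRUE, TRUE, TRUE, FALSE),
               direction = c("increase", "increase", "increase", "none")),
    data.frame(gene = "G2", marker = "LC3B", sirna = sprintf("G2_si%d", 1:4),
               is_hit = c(TRUE, TRUE, FALSE, FALSE),
               direction = c("increase", "increase", "none", "none")))
  val <- validate_screen(v)
  expect_equal(val$stage[val$gene == "G1"], "validated")
  expect_equal(val$stage[val$gene == "G2"], "not_validated")

  # toxicity turns 2-of-3 into a validation for G2
  tox <- list(sirnas = data.frame(gene = "G2", sirna = "G2_si4",
                                  toxic = TRUE))
  val2 <- validate_screen(v, tox)
  expect_equal(val2$stage[val2$gene == "G2"], "validated")

  v_bad <- v[1:6, ]
  expect_error(validate_screen(v_bad), "need 4")
})
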