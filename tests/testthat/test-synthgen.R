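test_that("screen layouts have the right shape, controls and determinism", {
  lay <- make_screen_layout(186, sirnas_per_gene = 1, seed = 1)
  test <- lay[lay$class == "test", ]
  # 186 genes x 5 markers, quadruplicate wells per condition
  expect_equal(length(unique(paste(test$gene, test$marker))), 186 * 5)
  expect_true(all(table(paste(test$gene, test$marker, test$sirna)) == 4))
  # every plate carries at least 8 sicon wells
  sicon_per_plate <- table(lay$plate[lay$class == "sicon"])
  expect_true(all(sicon_per_plate >= 8))
  expect_identical(lay, make_screen_layout(186, sirnas_per_gene = 1,
                                           seed = 1))

  tiny <- make_screen_layout(1, markers = "LC3B", sirnas_per_gene = 1,
                             seed = 0)
  expect_equal(sum(tiny$class == "test"), 4)
  expect_true(all(c("sicon", "positive", "negative") %in% tiny$class))

  dec <- make_screen_layout(71, sirnas_per_gene = 4, seed = 2)
  dtest <- dec[dec$class == "test", ]
  expect_equal(length(unique(paste(dtest$gene, dtest$sirna, dtest$marker))),
               71 * 4 * 5)

  expect_error(make_screen_layout(5, markers = "LC3B", replicates = 400),
               "capacity")
  expect_error(make_screen_layout(0), "n_genes")
  expect_error(make_screen_layout(2, sirnas_per_gene = 3), "sirnas_per_gene")
})

test_that("well table honors the planted effect model", {
  # null gene indistinguishable from sicon at n = 1000 wells
  lay <- flat_layout("GNULL", 1000, n_sicon = 1000)
  m <- effect_model(seed = 3)
  w <- simulate_well_table(lay, m)
  p <- t.test(w$spots_per_cell[w$class == "test"],
              w$spots_per_cell[w$class == "sicon"])$p.value
  expect_gt(p, 0.01)

  # fold (3, 3) on a 20 spots/cell baseline -> ~60 within sampling error
  lay2 <- flat_layout("GBIG", 200)
  m2 <- effect_model(gene_effects = data.frame(gene = "GBIG",
                                               fold_spots = 3,
                                               fold_iss = 3), seed = 4)
  w2 <- simulate_well_table(lay2, m2)
  got <- mean(w2$spots_per_cell[w2$class == "test"])
  expect_lt(abs(got - 60) / 60, 0.02)
  # ISS fold honored independently: baseline ISS/cell = 20 * 500
  iss <- mean(w2$iss_per_cell[w2$class == "test"])
  expect_lt(abs(iss - 3 * 20 * 500) / (3 * 20 * 500), 0.02)

  # toxic siRNA scales cell counts
  m3 <- effect_model(toxic_sirnas = data.frame(sirna = "pool",
                                               cell_fold = 0.2,
                                               morph_shift = 0.4),
                     seed = 5)
  w3 <- simulate_well_table(flat_layout("GTOX", 100), m3)
  expect_lt(abs(mean(w3$n_cells[w3$class == "test"]) - 0.2 * 1500) /
              (0.2 * 1500), 0.05)
  # morphology shifted relative to sicon
  expect_gt(mean(w3$nuc_intensity[w3$class == "test"]),
            mean(w3$nuc_intensity[w3$class == "sicon"]))

  # determinism: identical layout + model + seed -> bit-identical tables
  expect_identical(simulate_well_table(lay2, m2),
                   simulate_well_table(lay2, m2))
})

test_that("rendered well images carry a complete, consistent ground truth", {
  blank <- render_well_image(0, size = 128, seed = 1)
  expect_equal(nrow(blank$cells), 0)
  expect_equal(nrow(blank$spots), 0)

  img <- render_well_image(10, spots_per_cell = 5, size = 256, seed = 7)
  expect_equal(nrow(img$spots), 50)
  # every planted spot lies within its owner's cytoplasm disk
  d <- sqrt((img$spots$row - img$cells$row[img$spots$cell])^2 +
              (img$spots$col - img$cells$col[img$spots$cell])^2)
  expect_true(all(d <= img$cells$cell_radius[img$spots$cell]))

  # zero noise, no illumination: channel sum equals planted kernel sums
  clean <- render_well_image(1, spots_per_cell = 1, size = 128, seed = 2,
                             noise_sd = 0, illumination = 0)
  flux <- sum(clean$channels$marker - 50)
  expect_equal(flux, sum(clean$spots$integral), tolerance = 1e-8)

  expect_error(render_well_image(500, size = 128, seed = 1),
               "could not place")
  expect_error(render_well_image(5, size = 64), "size")

  # determinism
  expect_identical(render_well_image(5, size = 128, seed = 11),
                   render_well_image(5, size = 128, seed = 11))
})

test_that("qPCR generator plants recoverable knockdown fractions", {
  # fraction 1: identical Ct in both conditions at zero noise
  ct1 <- simulate_qpcr("G1", c(G1 = 1), seed = 1, noise_sd = 0)
  t_con <- ct1$ct[ct1$gene == "G1" & ct1$sample == "sicon"]
  t_kd <- ct1$ct[ct1$gene == "G1" & ct1$sample == "siG1"]
  expect_equal(t_con, t_kd)

  # fraction 0.25: +2 cycles (log2(1/0.25))
  ct2 <- simulate_qpcr("G1", c(G1 = 0.25), seed = 1, noise_sd = 0)
  shift <- mean(ct2$ct[ct2$gene == "G1" & ct2$sample == "siG1"]) -
    mean(ct2$ct[ct2$gene == "G1" & ct2$sample == "sicon"])
  expect_equal(shift, 2, tolerance = 1e-12)

  # noise SD 0.1, 4 replicates: recovered fraction within [0.4, 0.6]
  ct3 <- simulate_qpcr("G1", c(G1 = 0.5), seed = 2, noise_sd = 0.1,
                       n_replicates = 4)
  rec <- relative_expression(ct3, "G1", "siG1", "sicon")
  expect_gt(rec, 0.4)
  expect_lt(rec, 0.6)

  expect_error(simulate_qpcr("G1", c(G1 = 0)), "fractions")
})

test_that("AP-MS generator separates planted interactors from background", {
  net <- list(B001 = c(UNIQ = 10))
  runs <- simulate_apms(12, prey_network = net, seed = 1)
  # bait-unique prey appears in exactly one bait's runs
  expect_equal(unique(runs$bait[runs$prey == "UNIQ"]), "B001")
  # background preys spread across many baits
  bgf <- tapply(runs$bait[grepl("^bg", runs$prey)],
                runs$prey[grepl("^bg", runs$prey)],
                function(b) length(unique(b)))
  expect_gt(median(bgf), 1)
  expect_identical(runs, simulate_apms(12, prey_network = net, seed = 1))
  expect_error(simulate_apms(1), "n_baits")
})

test_that("expression generator is exact at zero noise", {
  r <- simulate_expression(5, de_truth = c(E0001 = 1.5, E0002 = 0.6),
                           noise = 0, seed = 1)
  expect_true(all(r$ratio[r$gene == "E0001"] == 1.5))
  expect_true(all(r$ratio[r$gene == "E0002"] == 0.6))
  expect_true(all(r$ratio[r$gene == "E0003"] == 1.0))
  expect_equal(sum(r$gene == "E0001"), 3)  # three experiments
  expect_error(simulate_expression(2, de_truth = c(E0001 = -1)), "ratios")
})
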