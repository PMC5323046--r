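# Fixture builders shared across test files. Everything is generated in
# code; no binary data ships with the package.

# A free-form layout data.frame (bypasses the 384-well filler) for tests
# that need many wells of one condition.
flat_layout <- function(genes, n_wells_each, n_sicon = 24,
                        marker = "LC3B", sirna = "pool",
                        treatment = "none", plate = "P01-TEST") {
  test <- do.call(rbind, lapply(genes, function(g) {
    data.frame(plate = plate, well = sprintf("T%s%04d", g,
                                             seq_len(n_wells_each)),
               marker = marker, gene = g, class = "test",
               sirna = sirna, treatment = treatment,
               replicate = seq_len(n_wells_each),
               stringsAsFactors = FALSE)
  }))
  ctrl <- data.frame(plate = plate, well = sprintf("S%04d",
                                                   seq_len(n_sicon)),
                     marker = marker, gene = "sicon", class = "sicon",
                     sirna = "sicon", treatment = treatment,
                     replicate = seq_len(n_sicon),
                     stringsAsFactors = FALSE)
  rbind(ctrl, test)
}

# Hand-built two-channel image: circular "nuclei" of the given radius at
# the given centers inside a shared cytoplasm disk, plus optional marker
# pixels. Used where the renderer's placement constraints get in the way.
disc_image <- function(size = 128, nuc_centers, nuc_radius = 6,
                       cyto_center = NULL, cyto_radius = 30,
                       nuc_int = 1000, cyto_int = 300, bg = 50,
                       marker_px = NULL, marker_val = 500) {
  ch0 <- matrix(bg, size, size)
  ch1 <- matrix(bg, size, size)
  rows <- row(ch0); cols <- col(ch0)
  if (is.null(cyto_center)) cyto_center <- colMeans(nuc_centers)
  cy <- (rows - cyto_center[1])^2 + (cols - cyto_center[2])^2 <=
    cyto_radius^2
  ch0[cy] <- cyto_int
  for (i in seq_len(nrow(nuc_centers))) {
    nm <- (rows - nuc_centers[i, 1])^2 + (cols - nuc_centers[i, 2])^2 <=
      nuc_radius^2
    ch0[nm] <- nuc_int
  }
  if (!is.null(marker_px)) {
    for (i in seq_len(nrow(marker_px))) {
      ch1[marker_px[i, 1], marker_px[i, 2]] <- marker_val
    }
  }
  list(channels = list(nuclear = ch0, marker = ch1))
}

# Minimal normalized_measure rows for hit-calling unit tests.
norm_row <- function(gene, marker, v_spots, v_iss, sd = 0.10,
                     sirna = "pool", treatment = "none") {
  data.frame(
    plate = "P01", marker = marker, gene = gene, class = "test",
    sirna = sirna, treatment = treatment,
    parameter = c("spots_per_cell", "iss_per_cell"),
    value = c(v_spots, v_iss), control_mean = 20, control_sd = sd,
    n_wells = 4L, flagged = FALSE, stringsAsFactors = FALSE)
}
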