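# Independent oracles used by the unit and acceptance suites. These stay
# deliberately naive (explicit loops / case analysis) and never call the
# implementation paths they check.

# Deconvolution rule, written as direct case analysis over the textual
# rule: drop toxic oligos; >= 2 dropped excludes the gene; otherwise the
# pass quota is 3 (of 4) or 2 (of 3 after one toxic removal).
oracle_decon <- function(passes, toxic) {
  kept <- passes[!toxic]
  n_removed <- sum(toxic)
  if (n_removed >= 2) return("excluded_toxicity")
  quota <- if (n_removed == 1) 2 else 3
  if (sum(kept) >= quota) "validated" else "not_validated"
}

# Brute-force CompPASS scoring over an aggregated (bait, prey, apsm, p)
# table: explicit loops over preys and baits.
oracle_comppass <- function(tab, baits, weighted = TRUE,
                            norm_percentile = 0.98) {
  K <- length(baits)
  wd <- numeric(nrow(tab))
  d <- numeric(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    prey <- tab$prey[r]
    vals <- c()
    for (b in baits) {
      v <- tab$apsm[tab$bait == b & tab$prey == prey]
      if (length(v) && v > 0) vals <- c(vals, v)
    }
    f <- max(length(vals), 1)
    w <- if (weighted && length(vals) >= 2) {
      max(1, stats::sd(vals) / mean(vals))
    } else 1
    d[r] <- sqrt(tab$apsm[r] * (K / f)^tab$p[r])
    wd[r] <- sqrt(tab$apsm[r] * (w * K / f)^tab$p[r])
  }
  norm <- as.numeric(stats::quantile(wd, norm_percentile, names = FALSE))
  list(d = d, wd = wd, wdn = wd / norm, norm = norm)
}

# Direct z'-factor formula evaluation.
oracle_zprime <- function(mu_p, sd_p, mu_n, sd_n) {
  1 - 3 * (sd_p + sd_n) / abs(mu_p - mu_n)
}

# Match detected spots to planted truth by nearest centroid (truth
# centroids are 1-based from the renderer, records are 0-based).
match_spots <- function(truth, detected, max_dist = 3) {
  if (!nrow(detected)) {
    return(data.frame(planted = truth$integral,
                      detected = rep(NA_real_, nrow(truth))))
  }
  det <- rep(NA_real_, nrow(truth))
  cell <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d2 <- (detected$row - (truth$row[i] - 1))^2 +
      (detected$col - (truth$col[i] - 1))^2
    j <- which.min(d2)
    if (d2[j] <= max_dist^2) {
      det[i] <- detected$integrated[j]
      cell[i] <- detected$cell[j]
    }
  }
  data.frame(planted = truth$integral, detected = det, cell = cell,
             true_cell = truth$cell)
}
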