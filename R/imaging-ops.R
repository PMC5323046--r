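# Low-level raster operations used by segmentation and spot detection.
# Everything works on plain numeric matrices (row = y, col = x, 1-based
# internally; exported centroids are 0-based per the package convention).

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (!length(rs) || !length(cs)) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

neighbor_offsets8 <- function() {
  cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
        dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
}

# Connected-component labeling (8-connectivity) by iterative minimum-label
# propagation; objects in screen images are small so this converges in a
# few dozen cheap vectorized sweeps.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(seq_len(h * w), h, w)
  lab[!mask] <- 0L
  off <- neighbor_offsets8()
  repeat {
    new_lab <- lab
    for (k in seq_len(nrow(off))) {
      sh <- shift_mat(lab, off[k, 1], off[k, 2], fill = 0)
      take <- mask & sh > 0 & (new_lab == 0 | sh < new_lab)
      new_lab[take] <- sh[take]
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  # compact labels to 1..n
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) {
    lut <- integer(max(ids))
    lut[ids] <- seq_along(ids)
    lab[lab > 0] <- lut[lab[lab > 0]]
  }
  lab
}

# Chamfer-style distance to the background, by iterative relaxation
# (converges in O(max object radius) sweeps).
distance_transform <- function(mask) {
  d <- matrix(0, nrow(mask), ncol(mask))
  d[mask] <- 1e9  # large finite so the convergence check stays NaN-free
  off <- neighbor_offsets8()
  cost <- ifelse(abs(off[, 1]) + abs(off[, 2]) == 2, sqrt(2), 1)
  repeat {
    new_d <- d
    for (k in seq_len(nrow(off))) {
      sh <- shift_mat(d, off[k, 1], off[k, 2], fill = 0)
      new_d <- pmin(new_d, sh + cost[k])
    }
    if (max(abs(new_d - d)[mask]) < 1e-9) break
    d <- new_d
  }
  d
}

# Grey-scale dilation with a (2r+1) square structuring element.
max_filter <- function(m, r) {
  out <- m
  for (i in seq_len(r)) {
    out <- pmax(out,
                shift_mat(out, 1, 0, -Inf), shift_mat(out, -1, 0, -Inf),
                shift_mat(out, 0, 1, -Inf), shift_mat(out, 0, -1, -Inf),
                shift_mat(out, 1, 1, -Inf), shift_mat(out, 1, -1, -Inf),
                shift_mat(out, -1, 1, -Inf), shift_mat(out, -1, -1, -Inf))
  }
  out
}

# Local maxima of `m` inside `mask`, with greedy suppression of maxima
# closer than `min_sep` (strongest kept). Returns a matrix with columns
# row, col.
local_maxima <- function(m, mask, min_sep) {
  mx <- max_filter(m, max(1L, ceiling(min_sep / 2)))
  cand <- which(mask & m >= mx - 1e-9, arr.ind = TRUE)
  if (!nrow(cand)) return(cand)
  vals <- m[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2
    keep[i] <- all(d2 >= min_sep^2)
  }
  cand[keep, , drop = FALSE]
}

# Geodesic propagation of seed labels through `mask` (8-connected BFS
# rounds; deterministic neighbor precedence).
propagate_labels <- function(lab, mask) {
  off <- neighbor_offsets8()
  repeat {
    changed <- FALSE
    new_lab <- lab
    for (k in seq_len(nrow(off))) {
      sh <- shift_mat(lab, off[k, 1], off[k, 2], fill = 0)
      take <- mask & new_lab == 0 & sh > 0
      if (any(take)) {
        new_lab[take] <- sh[take]
        changed <- TRUE
      }
    }
    lab <- new_lab
    if (!changed) break
  }
  lab
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# Robust background level and noise SD of a channel (median / scaled MAD
# over the full frame; spots and cells occupy a minority of pixels).
background_stats <- function(m) {
  med <- stats::median(m)
  list(level = med, noise_sd = rmad(as.numeric(m), center = med))
}

# 3x3 box smoothing (reduces pixel noise ~3x before maxima detection).
box_filter3 <- function(m) {
  acc <- m
  for (k in seq_len(8)) {
    off <- neighbor_offsets8()
    acc <- acc + shift_mat(m, off[k, 1], off[k, 2], fill = NA)
  }
  out <- acc / 9
  # borders: fall back to the raw value where the window is clipped
  out[is.na(out)] <- m[is.na(out)]
  out
}

# Multiplicative flat-field correction: the smooth illumination profile is
# estimated from block medians (background dominates each block), bilinearly
# upsampled, normalized to its 99th percentile, and divided out.
flatfield_correct <- function(m, block = 32L) {
  h <- nrow(m); w <- ncol(m)
  rb <- unique(pmin(seq(1, h, by = block), h))
  cb <- unique(pmin(seq(1, w, by = block), w))
  surf <- matrix(0, length(rb), length(cb))
  ctr_r <- numeric(length(rb)); ctr_c <- numeric(length(cb))
  for (i in seq_along(rb)) {
    ri <- rb[i]:min(rb[i] + block - 1L, h)
    ctr_r[i] <- mean(ri)
    for (j in seq_along(cb)) {
      cj <- cb[j]:min(cb[j] + block - 1L, w)
      if (i == 1) ctr_c[j] <- mean(cj)
      surf[i, j] <- stats::median(m[ri, cj])
    }
  }
  # bilinear upsample: interpolate along rows, then columns
  tmp <- apply(surf, 2, function(col) {
    stats::approx(ctr_r, col, xout = seq_len(h), rule = 2)$y
  })
  full <- t(apply(tmp, 1, function(rw) {
    stats::approx(ctr_c, rw, xout = seq_len(w), rule = 2)$y
  }))
  f <- full / stats::quantile(full, 0.99, names = FALSE)
  f[f <= 0.1] <- 0.1
  m / f
}
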