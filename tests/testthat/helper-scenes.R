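# Shared fixtures, built in code.

# 10x10 worked scene: uniform cell of value 10 with a 2x2 condensate of
# value 100 (background 0). Hand arithmetic: area_dense = 4,
# mean_dense = 100, mean_dilute = 10, total = 96*10 + 4*100 = 1360,
# fraction = 4*(100-10)/1360 = 360/1360, intensity ratio = 400/1360.
toy_scene <- function() {
  frame <- matrix(10, 10, 10)
  frame[5:6, 5:6] <- 100
  cond <- matrix(FALSE, 10, 10); cond[5:6, 5:6] <- TRUE
  seg <- list(condensate_mask = cond, cell_mask = matrix(TRUE, 10, 10))
  list(frame = frame, seg = seg,
       fraction = 360 / 1360, ratio = 400 / 1360)
}

# seeded random image with guaranteed full 8-bit range [0, 255]
random_8bit <- function(seed, n = 64L) {
  set.seed(seed)
  img <- matrix(sample(0:255, n * n, replace = TRUE), n, n)
  img[1] <- 0; img[2] <- 255
  img
}

# exhaustive-search threshold oracles: direct loops over every candidate
# bin edge, scoring the objective from the histogram counts
oracle_hist <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  counts <- integer(n_bins)
  for (i in seq_len(n_bins)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    counts[i] <- if (i < n_bins) sum(v >= lo & v < hi) else sum(v >= lo & v <= hi)
  }
  list(counts = counts, edges = edges,
       mids = (edges[-1L] + edges[-(n_bins + 1L)]) / 2)
}

oracle_otsu <- function(img, n_bins = 256L) {
  h <- oracle_hist(img, n_bins)
  p <- h$counts / sum(h$counts)
  best_k <- NA; best <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * h$mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):n_bins] * h$mids[(k + 1):n_bins]) / w1
    obj <- w0 * w1 * (mu0 - mu1)^2
    if (obj > best) { best <- obj; best_k <- k }
  }
  h$edges[best_k + 1L]
}

oracle_maxentropy <- function(img, n_bins = 256L) {
  h <- oracle_hist(img, n_bins)
  p <- h$counts / sum(h$counts)
  best_k <- NA; best <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    pb <- p[1:k]; pf <- p[(k + 1):n_bins]
    Pb <- sum(pb); Pf <- sum(pf)
    if (Pb == 0 || Pf == 0) next
    qb <- pb[pb > 0] / Pb; qf <- pf[pf > 0] / Pf
    obj <- -sum(qb * log(qb)) - sum(qf * log(qf))
    if (obj > best) { best <- obj; best_k <- k }
  }
  h$edges[best_k + 1L]
}

# small, fast simulator configuration for property tests
quick_config <- function(seed = 1L, ...) {
  args <- list(image_shape = c(64L, 64L), n_frames = 12L,
               frame_interval_s = 5, n_droplets = 3L,
               droplet_radius_px = c(3, 4), tau_s = 10, onset_s = 10,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}
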