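# Shared fixtures and brute-force oracles, built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

# full fixture -> tracks pipeline, cached per (seed, cells, group2)
hox_pipeline <- function(seed = 42, cells = 500, group2 = 0.4) {
  key <- paste("fx", seed, cells, group2, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- sim_config(seed = seed, cells_per_type = cells,
                    group2_fraction = group2)
  g <- make_genome(cfg)
  fx <- make_hox_fixture(g, cfg)
  scheme <- bin_scheme(stats::setNames(g$length, g$chrom), cfg$bin_width)
  mats <- lapply(fx$fragments, bin_counts, scheme = scheme,
                 cells = fx$barcodes)
  tracks <- lapply(mats, function(m) {
    pseudobulk_track(m, list(all = fx$barcodes), scheme)$all
  })
  lt <- lapply(tracks, track_subset, start = fx$locus[1], end = fx$locus[2])
  out <- list(cfg = cfg, genome = g, fx = fx, scheme = scheme,
              mats = mats, tracks = tracks, locus_tracks = lt)
  assign(key, out, envir = .fixture_cache)
  out
}

random_fragments <- function(n, seed = 1, chrom = "chr1", max_pos = 99000,
                             barcodes = sprintf("BC%02d", 1:5)) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = chrom, start = start,
             end = start + sample(50:500, n, replace = TRUE),
             barcode = sample(barcodes, n, replace = TRUE),
             count = sample(1:3, n, replace = TRUE))
}

# independent step-up BH oracle (hand implementation, not p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# textbook Pearson correlation oracle
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# direct Gaussian convolution with symmetric reflection padding
smooth_oracle <- function(v, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  n <- length(v)
  pad <- c(v[r:1], v, v[n:(n - r + 1)])
  vapply(seq_len(n), function(i) sum(pad[i:(i + 2 * r)] * rev(k)), 0)
}

# diamond insulation sums by explicit double loop
diamond_oracle <- function(m, w) {
  n <- nrow(m)
  out <- rep(NA_real_, n)
  for (b in (w + 1):(n - w)) {
    s <- 0
    for (i in (b - w):(b - 1)) for (j in (b + 1):(b + w)) s <- s + m[i, j]
    out[b] <- s
  }
  out
}
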