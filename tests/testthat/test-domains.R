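test_that("boundary detector handles constants, steps and ties", {
  const <- binned_track("chr1", 2000L, rep(2, 50), group = "ATAC")
  expect_equal(nrow(detect_boundaries(const)), 0)

  step <- binned_track("chr1", 2000L, c(rep(1, 30), rep(5, 30)),
                       group = "ATAC")
  b <- detect_boundaries(step)
  expect_equal(nrow(b), 1)
  edge <- 30 * 2000  # planted bin-edge coordinate
  expect_lte(abs(b$position - edge), 2000)
  expect_equal(b$direction, "up")

  # two equal steps one bin apart with min separation 2: leftmost kept
  two <- binned_track("chr1", 1000L,
                      c(rep(0, 20), 1, rep(2, 20)), group = "ATAC")
  p <- border_params(sigma = 0.5, threshold = 2, min_sep = 2)
  b2 <- detect_boundaries(two, p)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$position, 20 * 1000)

  expect_error(detect_boundaries(binned_track("chr1", 1000L, c(1, 2))),
               "at least 3 bins")
})

test_that("noisy single steps are located within one bin by exhaustive scan", {
  for (sd in 1:5) {
    set.seed(sd)
    n <- 80
    edge_bin <- 35
    v <- c(rpois(edge_bin, 20), rpois(n - edge_bin, 120))
    tr <- binned_track("chr1", 2000L, sqrt(v), group = "x")
    b <- detect_boundaries(tr)
    expect_equal(nrow(b), 1)
    # oracle: exhaustive scan for the best two-level split
    sse <- vapply(2:(n - 2), function(k) {
      sum((v[1:k] - mean(v[1:k]))^2) + sum((v[(k + 1):n] - mean(v[(k + 1):n]))^2)
    }, 0)
    best_edge <- (which.min(sse) + 1) * 2000
    expect_lte(abs(b$position - best_edge), 2000)
  }
})

test_that("border grades count supporting modalities", {
  mk <- function(mod, pos, z) {
    data.frame(modality = mod, position = pos, direction = "up",
               z = z, amplitude = abs(z))
  }
  three <- rbind(mk("ATAC", 10000, 8), mk("H3K27ac", 10000, 6),
                 mk("H3K27me3", 10000, 5))
  agg <- aggregate_boundaries(three, tolerance = 2, width = 2000)
  expect_equal(agg$grade, 3)
  expect_equal(agg$position, weighted.mean(c(10000, 10000, 10000), c(8, 6, 5)))

  two <- rbind(mk("ATAC", 10000, 8), mk("H3K27ac", 12000, 6))
  expect_equal(aggregate_boundaries(two, 2, 2000)$grade, 2)

  one <- mk("H3K27me3", 10000, 5)
  expect_equal(aggregate_boundaries(one, 2, 2000)$grade, 1)

  # a modality contributes once per border: duplicate kept at max |z|
  dup <- rbind(mk("ATAC", 10000, 8), mk("ATAC", 12000, 4),
               mk("H3K27ac", 11000, 6))
  aggd <- aggregate_boundaries(dup, 2, 2000)
  expect_equal(aggd$grade, 2)
  expect_equal(aggd$n_members, 2)

  # far-apart boundaries stay separate
  sep <- rbind(mk("ATAC", 10000, 8), mk("ATAC", 50000, 8))
  expect_equal(nrow(aggregate_boundaries(sep, 2, 2000)), 2)
})

test_that("grades are invariant to modality order and single-track rescaling", {
  hp <- hox_pipeline(seed = 42)
  base <- call_borders(hp$locus_tracks)$borders
  perm <- call_borders(hp$locus_tracks[c(3, 1, 2)])$borders
  expect_equal(perm$grade, base$grade)
  expect_equal(perm$position, base$position, tolerance = 1e-9)

  scaled <- hp$locus_tracks
  scaled$H3K27me3$values <- scaled$H3K27me3$values * 37.5
  resc <- call_borders(scaled)$borders
  expect_equal(resc$grade, base$grade)
  expect_equal(resc$position, base$position, tolerance = 1e-9)
})

test_that("deeper sequencing never loses a planted border grade", {
  planted <- hox_pipeline(seed = 11, cells = 200)$fx$transitions
  grades <- sapply(c(200, 500, 1000), function(nc) {
    hp <- hox_pipeline(seed = 11, cells = nc)
    b <- call_borders(hp$locus_tracks)$borders
    vapply(planted$position, function(p) {
      hit <- abs(b$position - p) <= 2 * 2000
      if (any(hit)) max(b$grade[hit]) else 0L
    }, 0)
  })
  expect_true(all(diff(t(grades)) >= 0))
})

test_that("domain classification follows the fold-change rule", {
  mkt <- function(v) binned_track("chr1", 2000L, v, normalization = "CPM")
  n <- 50
  base_bins <- 1:10
  tracks <- list(
    ATAC = mkt(c(rep(10, 10), rep(0, 20), rep(5, 20))),
    H3K27ac = mkt(c(rep(10, 10), rep(0, 20), rep(100, 20))),
    H3K27me3 = mkt(c(rep(10, 10), rep(100, 20), rep(110, 20))))
  locus <- c(0, n * 2000)
  baseline <- c(0, 10 * 2000)
  borders <- data.frame(position = c(20000, 60000))
  dom <- classify_domains(borders, tracks, locus, baseline)
  # all-zero ATAC/K27ac with K27me3 fold 10 -> silenced
  expect_equal(dom$state, c("inactive", "silenced", "silenced"))

  # K27me3 fold 10 but accessible -> not silenced by the rule
  tracks$ATAC <- mkt(c(rep(10, 10), rep(50, 20), rep(5, 20)))
  tracks$H3K27ac <- mkt(c(rep(10, 10), rep(50, 20), rep(100, 20)))
  dom2 <- classify_domains(borders, tracks, locus, baseline)
  expect_equal(dom2$state[2], "primed")

  tracks$ATAC <- mkt(rep(0, n))
  expect_error(classify_domains(borders, tracks, locus, baseline),
               "pseudocount")
})

test_that("fixture domains are inactive upstream, primed 3prime, silenced 5prime", {
  hp <- hox_pipeline(seed = 42)
  called <- call_borders(hp$locus_tracks)
  dom <- classify_domains(called$borders, hp$tracks, hp$fx$locus,
                          c(hp$fx$segments$start[1], hp$fx$segments$end[1]))
  expect_equal(dom$state[1], "inactive")
  seg <- hp$fx$segments
  in3p <- dom$start >= seg$start[2] - 4000 & dom$end <= seg$end[4] + 4000
  expect_true(all(dom$state[in3p] == "primed"))
  in5p <- dom$start >= seg$start[5] - 4000 & dom$end <= seg$end[5] + 4000
  expect_true(all(dom$state[in5p] == "silenced"))
})

test_that("trimodal clustering recovers planted blocks deterministically", {
  set.seed(14)
  a <- matrix(rnorm(60, 10, 0.5), 20, 3)
  b <- matrix(rnorm(60, 0, 0.5), 20, 3)
  m <- cbind(rbind(a, b), rbind(b, a))
  colnames(m) <- sprintf("c%d", 1:6)
  tc <- trimodal_cluster(m)
  k2 <- cutree(tc$row_hclust, 2)
  expect_equal(length(unique(k2[1:20])), 1)
  expect_equal(length(unique(k2[21:40])), 1)
  expect_false(k2[1] == k2[21])

  # duplicated column: zero cophenetic distance within the pair
  m2 <- cbind(m, dup = m[, 1])
  tc2 <- trimodal_cluster(m2)
  cd <- as.matrix(stats::cophenetic(tc2$col_hclust))
  expect_equal(cd["c1", "dup"], 0)

  expect_identical(trimodal_cluster(m)$row_order, tc$row_order)
})

test_that("modality correlation matches the textbook formula", {
  set.seed(15)
  m <- cbind(x = rnorm(30), y = rnorm(30), z = rnorm(30))
  cc <- modality_correlation(m)
  expect_equal(diag(cc), c(x = 1, y = 1, z = 1))
  expect_equal(cc, t(cc))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cc[i, j], pearson_oracle(m[, i], m[, j]), tolerance = 1e-12)
  }
  # anti-phased accessibility and repression anticorrelate
  atac <- sin(seq(0, 6 * pi, length.out = 50)) + rnorm(50, 0, 0.05)
  me3 <- -atac + rnorm(50, 0, 0.05)
  cc2 <- modality_correlation(cbind(atac, me3))
  expect_lt(cc2["atac", "me3"], -0.9)
  expect_error(modality_correlation(m[1:2, ]), "at least 3")
})
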