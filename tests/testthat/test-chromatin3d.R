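make_cm <- function(n = 40, seed = 1, lambda_fun = NULL) {
  set.seed(seed)
  if (is.null(lambda_fun)) lambda_fun <- function(d) 200 / (1 + d)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- lambda_fun(d)
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- rpois(sum(ut), lam[ut])
  m <- m + t(m) - diag(diag(m))
  contact_matrix(data.frame(chrom = "chr1", start = 0:(n - 1) * 1e4,
                            end = 1:n * 1e4), m)
}

test_that("ICE balancing equalizes row sums and is idempotent", {
  ones <- contact_matrix(data.frame(chrom = "chr1", start = 0:9 * 1e4,
                                    end = 1:10 * 1e4),
                         matrix(1, 10, 10))
  bal <- ice_balance(ones)
  expect_equal(unname(bal$weights), rep(1, 10))
  expect_equal(bal$balanced, ones$counts, ignore_attr = TRUE)

  cm <- make_cm(40, seed = 2)
  bal2 <- ice_balance(cm)
  rs <- rowSums(bal2$balanced[!bal2$mask, !bal2$mask])
  expect_lt(stats::sd(rs) / mean(rs), 1e-4)

  rebal <- ice_balance(contact_matrix(cm$bins, bal2$balanced,
                                      mask = bal2$mask))
  expect_lt(max(abs(rebal$weights[!rebal$mask] - 1)), 1e-4)

  # zero-coverage row is masked with undefined weight
  cnt <- cm$counts
  cnt[5, ] <- 0
  cnt[, 5] <- 0
  bal3 <- ice_balance(contact_matrix(cm$bins, cnt))
  expect_true(bal3$mask[5])
  expect_true(is.na(bal3$weights[5]))
})

test_that("expected profile and O/E match brute force", {
  cm <- ice_balance(make_cm(30, seed = 3))
  ex <- expected_by_distance(cm)
  m <- cm$balanced
  for (k in c(0, 1, 5, 20)) {
    vals <- m[abs(outer(1:30, 1:30, "-")) == k]
    expect_equal(ex[k + 1], mean(vals), tolerance = 1e-12)
  }
  oe <- obs_exp(cm)
  expect_equal(oe[3, 7], m[3, 7] / ex[5], tolerance = 1e-12)

  # matrix equal to its own expected profile gives O/E of ones
  n <- 20
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  flat <- contact_matrix(data.frame(chrom = "chr1", start = 0:(n - 1) * 1e4,
                                    end = 1:n * 1e4),
                         matrix(100 / (1 + d), n, n))
  oe2 <- obs_exp(flat)
  expect_equal(oe2, matrix(1, n, n), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("compartment eigenvector separates planted blocks with anchored sign", {
  n <- 24
  blk <- rep(c(1, -1), each = n / 2)
  oe <- 1 + 0.5 * outer(blk, blk)  # checkerboard: 1.5 within, 0.5 across
  set.seed(4)
  oe <- oe * matrix(exp(rnorm(n * n, 0, 0.01)), n, n)
  oe <- (oe + t(oe)) / 2
  ref <- blk + rnorm(n, 0, 0.1)
  pc <- compartment_eigenvector(oe, reference = ref)
  expect_true(pc$defined)
  expect_true(all(sign(pc$pc1[1:(n / 2)]) == 1))
  expect_true(all(sign(pc$pc1[(n / 2 + 1):n]) == -1))
  pc_flip <- compartment_eigenvector(oe, reference = -ref)
  expect_equal(pc_flip$pc1, -pc$pc1)

  flat <- compartment_eigenvector(matrix(1, 15, 15))
  expect_false(flat$defined)
})

test_that("diamond insulation matches the double-loop oracle and calls planted junctions", {
  cm <- ice_balance(make_cm(50, seed = 6))
  ins <- insulation(cm, window = 100000)
  oracle <- diamond_oracle(cm$balanced, 10)
  defined <- !is.na(ins$score)
  expect_equal(2^ins$score[defined] * mean(oracle, na.rm = TRUE),
               oracle[defined], tolerance = 1e-9)

  # uniform matrix: constant score, no boundaries
  uni <- contact_matrix(data.frame(chrom = "chr1", start = 0:29 * 1e4,
                                   end = 1:30 * 1e4), matrix(50, 30, 30))
  insu <- insulation(uni, window = 50000)
  expect_equal(diff(range(insu$score, na.rm = TRUE)), 0)
  expect_equal(nrow(insu$boundaries), 0)

  # two planted blocks: unique minimum at the junction +/- 1
  n <- 60
  jb <- 30
  lamf <- function(d) 150 / (1 + d)
  set.seed(7)
  dmat <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- lamf(dmat)
  within <- outer(seq_len(n) <= jb, seq_len(n) <= jb, "==")
  lam[within] <- lam[within] * 3
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- rpois(sum(ut), lam[ut])
  m <- m + t(m) - diag(diag(m))
  cmb <- ice_balance(contact_matrix(
    data.frame(chrom = "chr1", start = 0:(n - 1) * 1e4, end = 1:n * 1e4), m))
  insb <- insulation(cmb, window = 100000)
  expect_gte(nrow(insb$boundaries), 1)
  top <- insb$boundaries$bin[which.max(insb$boundaries$prominence)]
  expect_lte(abs(top - (jb + 1)), 1)

  expect_error(insulation(cm, window = 15000), "multiple")
  expect_error(insulation(uni, window = 400000), "larger")
})

test_that("virtual 4C is the balanced viewpoint row", {
  cm <- ice_balance(make_cm(40, seed = 8))
  v <- virtual_4c(cm, 20)
  expect_equal(v$value, cm$balanced[20, ], tolerance = 1e-12)
  expect_true(v$is_viewpoint[20])
  expect_equal(which.max(v$value), 20)  # diagonal-dominant decay
  expect_error(virtual_4c(contact_matrix(cm$bins, cm$counts,
                                         mask = replace(cm$mask, 20, TRUE)),
                          20), "masked")
})

test_that("loop pileup averages O/E windows and scores planted loops", {
  cfg <- sim_config(seed = 17)
  g <- make_genome(cfg)
  loops <- data.frame(a = g$cluster_start - 150000,
                      b = g$cluster_end + 150000)
  cm <- ice_balance(simulate_contact_matrix("single_tad", loops, cfg, g))
  oe <- obs_exp(cm)
  lb <- attr(cm, "truth")$loop_bins
  pl <- loop_pileup(oe, lb, flank_bins = 10)
  expect_gt(pl$enrichment, 1.5)
  # after removing distance decay, the planted loop partner is the
  # off-diagonal maximum of the viewpoint profile
  v <- virtual_4c(cm, lb$bin_a[1])
  expect_equal(v$value, cm$balanced[lb$bin_a[1], ], tolerance = 1e-12)
  voe <- oe[lb$bin_a[1], ]
  offd <- which(abs(seq_along(voe) - lb$bin_a[1]) > 5)
  expect_equal(offd[which.max(voe[offd])], lb$bin_b[1])

  # single anchor with flank 0 is that O/E pixel; mean oracle for several
  one <- loop_pileup(oe, data.frame(bin_a = 15, bin_b = 40), flank_bins = 0)
  expect_equal(one$pileup[1, 1], oe[15, 40])
  anchors <- data.frame(bin_a = c(12, 15, 20), bin_b = c(40, 45, 50))
  pl3 <- loop_pileup(oe, anchors, flank_bins = 3)
  acc <- (oe[(12 - 3):(12 + 3), (40 - 3):(40 + 3)] +
            oe[(15 - 3):(15 + 3), (45 - 3):(45 + 3)] +
            oe[(20 - 3):(20 + 3), (50 - 3):(50 + 3)]) / 3
  expect_equal(pl3$pileup, acc, tolerance = 1e-9)

  expect_error(loop_pileup(oe, data.frame(bin_a = 2, bin_b = 40), 10),
               "outside")
  expect_error(loop_pileup(oe, data.frame(bin_a = 30, bin_b = 35), 10),
               "separated")
})
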