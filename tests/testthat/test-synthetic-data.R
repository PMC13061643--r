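test_that("toy genome is ordered, deterministic and bounds-checked", {
  cfg <- sim_config(seed = 9)
  g <- make_genome(cfg)
  expect_equal(nrow(g$cluster), 13)
  expect_true(all(diff(g$cluster$tss) > 0))  # 3' -> 5' coordinate order
  expect_gte(g$length, 1e6)
  expect_gte(sum(g$genes$role != "cluster"),
             20 * length(cfg$celltypes))
  expect_identical(make_genome(cfg), make_genome(sim_config(seed = 9)))
  expect_error(make_genome(sim_config(chrom_length = 1e5,
                                      cluster_start = 0L)),
               "configuration error")
})

test_that("fixture realizes the planted segment rates and transition grades", {
  hp <- hox_pipeline(seed = 42)
  fx <- hp$fx
  # exactly 3 three-modality, 1 two-modality, 1 one-modality transitions
  expect_equal(sort(fx$transitions$grade), c(1, 2, 3, 3, 3))
  expect_equal(unname(table(factor(fx$transitions$grade, 1:3))), c(1L, 1L, 3L),
               ignore_attr = TRUE)
  # the single-modality transition steps only H3K27me3
  expect_equal(fx$transitions$modalities[fx$transitions$grade == 1],
               "H3K27me3")

  # empirical per-segment mean fragments/cell/bin within 3 SE of the rates
  # (group1 cells only, whose H3K27me3 rates are unmodified)
  cfg <- hp$cfg
  g1 <- names(fx$groups)[fx$groups == "group1"]
  for (mod in c("ATAC", "H3K27ac", "H3K27me3")) {
    fr <- fx$fragments[[mod]]
    fr <- fr[fr$barcode %in% g1, ]
    for (i in seq_len(nrow(fx$segments))) {
      seg <- fx$segments[i, ]
      nbins <- (seg$end - seg$start) / cfg$bin_width
      nobs <- sum(fr$start >= seg$start & fr$start < seg$end)
      rate <- seg[[mod]]
      se <- sqrt(rate / (length(g1) * nbins))
      expect_lt(abs(nobs / (length(g1) * nbins) - rate), 3 * se + 1e-9)
    }
  }
})

test_that("group2 depletes 3' H3K27me3 only; fraction 0 gives one profile", {
  hp <- hox_pipeline(seed = 5, cells = 300)
  fx <- hp$fx
  reg <- c(fx$segments$start[2], fx$segments$end[4])
  sig <- percell_region_signal(fx$fragments["H3K27me3"], hp$genome$chrom,
                               reg, fx$barcodes)
  m1 <- mean(sig$raw[fx$groups[sig$barcode] == "group1"])
  m2 <- mean(sig$raw[fx$groups[sig$barcode] == "group2"])
  expect_gt(m1, 2 * m2)

  fx0 <- make_hox_fixture(hp$genome, sim_config(seed = 5, cells_per_type = 50,
                                                group2_fraction = 0))
  expect_true(all(fx0$groups == "group1"))
})

test_that("fixture generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 31, cells_per_type = 60)
  g <- make_genome(cfg)
  f1 <- make_hox_fixture(g, cfg)
  f2 <- make_hox_fixture(g, cfg)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_fragments(f1$fragments$ATAC, p1)
  write_fragments(f2$fragments$ATAC, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(f1$groups, f2$groups)
})

test_that("cell-type simulation enriches own markers and plants differential bins", {
  cfg <- sim_config(seed = 21, cells_per_type = 300, diff_fold = 3)
  g <- make_genome(cfg)
  ct <- simulate_celltype_fragments(g, cfg)
  mat <- bin_counts(ct$fragments$ATAC, ct$scheme, ct$cells$barcode)
  ty <- cfg$celltypes[1]
  own <- ct$cells$barcode[ct$cells$celltype == ty]
  oth <- ct$cells$barcode[ct$cells$celltype != ty]
  mb <- ct$truth$marker_bins[[ty]]
  expect_gt(mean(as.matrix(mat[own, mb])), 2 * mean(as.matrix(mat[oth, mb])))

  # planted 3-fold bins: pseudobulk fold-change sign correct in >= 45/50
  ga <- ct$cells$barcode[!is.na(ct$cells$region) & ct$cells$region == "regionA"]
  gb <- ct$cells$barcode[!is.na(ct$cells$region) & ct$cells$region == "regionB"]
  pa <- Matrix::colSums(mat[ga, ct$truth$diff_bins])
  pb <- Matrix::colSums(mat[gb, ct$truth$diff_bins])
  expect_gte(sum(pa > pb), 45)

  # determinism of the barcode -> count tables
  ct2 <- simulate_celltype_fragments(g, cfg)
  expect_identical(ct$fragments$ATAC, ct2$fragments$ATAC)

  # zero cells: empty set, not an error
  ct0 <- simulate_celltype_fragments(g, sim_config(seed = 21,
                                                   cells_per_type = 0))
  expect_equal(nrow(ct0$fragments$ATAC), 0)
})

test_that("simulated contact matrices are symmetric with enriched TADs", {
  cfg <- sim_config(seed = 13)
  g <- make_genome(cfg)
  cm <- simulate_contact_matrix("split_tad", NULL, cfg, g)
  expect_identical(cm$counts, t(cm$counts))
  truth <- attr(cm, "truth")

  bal <- ice_balance(cm)
  oe <- obs_exp(bal)
  cl <- truth$cluster_bins[1]:truth$cluster_bins[2]
  tad1 <- truth$cluster_bins[1]:(truth$junction_bin - 1)
  within <- oe[tad1, tad1]
  cross <- oe[tad1, (truth$junction_bin):truth$cluster_bins[2]]
  expect_gt(mean(within, na.rm = TRUE) / mean(cross, na.rm = TRUE), 1.5)

  # single-TAD scenario: no insulation minimum inside the cluster
  cm1 <- ice_balance(simulate_contact_matrix("single_tad", NULL, cfg, g))
  ins <- insulation(cm1)
  internal <- ins$boundaries$bin > truth$cluster_bins[1] &
    ins$boundaries$bin < truth$cluster_bins[2]
  expect_equal(sum(internal), 0)

  expect_error(simulate_contact_matrix("single_tad",
                                       data.frame(a = 0, b = 1e7), cfg, g),
               "outside")
})

test_that("TF edge simulator respects propensities and excludes self-edges", {
  hub_wins <- 0L
  for (sd in 1:60) {
    sim <- simulate_tf_edges(20, sim_config(seed = sd),
                             propensities = c(10, rep(1, 19)))
    expect_false(any(sim$edges$regulator == sim$edges$target))
    if (which.max(sim$truth$out_degree) == 1) hub_wins <- hub_wins + 1L
  }
  expect_gte(hub_wins, 57)  # hub has the max out-degree in >= 95% of seeds

  sim0 <- simulate_tf_edges(5, sim_config(seed = 1), edge_prob = 0)
  expect_equal(nrow(sim0$edges), 0)
})

test_that("group H3K27ac distributions are exchangeable across groups", {
  pvals <- vapply(1:15, function(sd) {
    hp <- hox_pipeline(seed = sd + 100, cells = 200)
    fx <- hp$fx
    reg <- c(fx$segments$start[2], fx$segments$end[4])
    sig <- percell_region_signal(fx$fragments["H3K27ac"], hp$genome$chrom,
                                 reg, fx$barcodes)
    suppressWarnings(stats::ks.test(
      sig$norm[fx$groups[sig$barcode] == "group1"],
      sig$norm[fx$groups[sig$barcode] == "group2"])$p.value)
  }, 0)
  expect_gte(sum(pvals > 0.05), 12)
})
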