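# End-to-end demonstration: simulate -> QC -> pseudobulk -> graded borders
# and domain states -> within-cell grouping -> contact-matrix analytics ->
# TF networks -> differential accessibility, with a structured report.

#' Run the end-to-end demonstration pipeline
#'
#' Generates the HOX-like fixture and supporting simulations from one
#' seed, runs every analysis stage, and returns a structured report.
#' Synthetic per-cell depths are far below real single-cell data, so the
#' QC stage applies demonstration thresholds (\code{demo_tsse_min},
#' \code{demo_frag_min}); \code{qc_filter} itself defaults to the
#' stringent thresholds used for real data.
#'
#' @param config A \code{sim_config}.
#' @param out_dir Optional directory for report JSON, border/domain BED
#'   and bedGraph tracks.
#' @param n_perm Permutations for the within-cell mark-uniformity test.
#' @param demo_tsse_min,demo_frag_min QC thresholds applied to the
#'   synthetic cells.
#' @return A report list; \code{report$checks} holds named logicals for
#'   the pipeline's internal consistency properties and \code{report$pass}
#'   their conjunction.
#' @export
run_demo <- function(config = sim_config(), out_dir = NULL, n_perm = 2000,
                     demo_tsse_min = 1, demo_frag_min = 10) {
  t0 <- Sys.time()
  genome <- make_genome(config)
  fixture <- make_hox_fixture(genome, config)
  scheme <- bin_scheme(stats::setNames(genome$length, genome$chrom),
                       config$bin_width)

  # --- QC on the ATAC modality
  qc <- cell_qc(fixture$fragments$ATAC, genome$cluster$tss,
                chrom = genome$chrom)
  keep <- qc_filter(qc, tsse_min = demo_tsse_min, frag_min = demo_frag_min)
  retained <- intersect(fixture$barcodes, keep$retained)

  # --- pseudobulk CPM tracks and graded borders
  mats <- lapply(fixture$fragments, bin_counts, scheme = scheme,
                 cells = fixture$barcodes)
  tracks <- lapply(mats, function(m) {
    pseudobulk_track(m, list(all = fixture$barcodes), scheme)$all
  })
  locus_tracks <- lapply(tracks, track_subset, start = fixture$locus[1],
                         end = fixture$locus[2])
  called <- call_borders(locus_tracks, border_params())
  borders <- called$borders
  baseline <- c(fixture$segments$start[1], fixture$segments$end[1])
  domains <- classify_domains(borders, tracks, fixture$locus, baseline)

  # --- within-cell joint-mark grouping over the 3' block (s1-s3)
  reg3p <- c(fixture$segments$start[2], fixture$segments$end[4])
  sig <- percell_region_signal(fixture$fragments[c("H3K27ac", "H3K27me3")],
                               genome$chrom, reg3p, fixture$barcodes)
  me3 <- sig$norm[sig$modality == "H3K27me3"]
  names(me3) <- sig$barcode[sig$modality == "H3K27me3"]
  split <- split_groups_by_mark(me3)
  ac <- sig$norm[sig$modality == "H3K27ac"]
  unif <- if (!split$refused) {
    test_mark_uniformity(ac, split$labels, n_perm = n_perm,
                         seed = config$seed)
  } else NULL

  # --- contact-matrix analytics
  loops <- data.frame(a = genome$cluster_start - 150000,
                      b = genome$cluster_end + 150000)
  cms <- lapply(c(single_tad = "single_tad", split_tad = "split_tad"),
                function(sc) {
                  ice_balance(simulate_contact_matrix(sc, loops, config,
                                                      genome))
                })
  ins <- lapply(cms, insulation)
  truth <- attr(cms$split_tad, "truth")
  oe <- obs_exp(cms$split_tad)
  loop_bins <- truth$loop_bins
  pile <- loop_pileup(oe, loop_bins, flank_bins = 10)
  v4c <- virtual_4c(cms$split_tad, loop_bins$bin_a[1])

  # --- TF networks
  props <- c(10, rep(1, 29))
  simA <- simulate_tf_edges(30, config, propensities = props)
  cfgB <- config
  cfgB$seed <- config$seed + 1000L
  simB <- simulate_tf_edges(30, cfgB, propensities = props)
  netA <- tf_network(simA$edges)
  netB <- tf_network(simB$edges)
  ranked <- rank_tfs(tf_strength(netA))
  netcmp <- compare_networks(netA, netB)

  # --- cell types, metagene labels and differential accessibility
  ct <- simulate_celltype_fragments(genome, config)
  amat <- bin_counts(ct$fragments$ATAC, ct$scheme, ct$cells$barcode)
  markers <- genome$genes[genome$genes$role %in% config$celltypes, ]
  act <- gene_activity(amat, ct$scheme, markers)
  sets <- split(markers$name, markers$role)
  meta <- metagene_score(act, sets)
  label_acc <- mean(meta$label == ct$cells$celltype, na.rm = TRUE)
  ga <- ct$cells$barcode[!is.na(ct$cells$region) &
                           ct$cells$region == "regionA"]
  gb <- ct$cells$barcode[!is.na(ct$cells$region) &
                           ct$cells$region == "regionB"]
  diff <- differential_accessibility(amat, ga, gb)
  sig_bins <- as.integer(diff$feature[diff$significant])
  pa <- Matrix::colSums(amat[ga, ct$truth$diff_bins, drop = FALSE])
  pb <- Matrix::colSums(amat[gb, ct$truth$diff_bins, drop = FALSE])
  diff_sign_frac <- mean(pa > pb)

  grades <- c(weak = 1L, moderate = 2L, strong = 3L)
  n_by_grade <- vapply(grades, function(g) sum(borders$grade == g), 0L)
  ins_internal <- vapply(ins, function(x) {
    sum(x$boundaries$bin > truth$cluster_bins[1] &
          x$boundaries$bin < truth$cluster_bins[2])
  }, 0L)

  checks <- c(
    border_grades = all(n_by_grade == c(1L, 1L, 3L)),
    domain_states = identical(domains$state[c(1, 2, nrow(domains) - 1)],
                              c("inactive", "primed", "silenced")),
    group_split = !split$refused,
    k27ac_uniform = is.null(unif) || unif$p_value > 0.01,
    split_tad_junction = ins_internal[["split_tad"]] >= 1 &&
      ins_internal[["single_tad"]] == 0,
    loop_enrichment = pile$enrichment > 1.5,
    strength_zero_sum = abs(sum(tf_strength(netA))) < 1e-12,
    differential_sign = diff_sign_frac >= 0.9,
    label_accuracy = label_acc >= 0.9
  )

  report <- list(
    seed = config$seed,
    n_cells = length(fixture$barcodes), n_retained_qc = length(retained),
    borders = borders, borders_by_grade = n_by_grade,
    domains = domains,
    group_split = list(refused = split$refused,
                       silhouette = split$silhouette,
                       sizes = table(split$labels)),
    k27ac_uniformity = unif,
    insulation_internal_boundaries = ins_internal,
    pileup_enrichment = pile$enrichment,
    tf_ranked_head = utils::head(ranked, 5),
    network_comparison = netcmp[c("shared_fraction", "slope", "intercept")],
    n_differential = length(sig_bins),
    differential_sign_fraction = diff_sign_frac,
    metagene_label_accuracy = label_acc,
    checks = checks, pass = all(checks),
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (mod in names(tracks)) {
      write_bedgraph(tracks[[mod]],
                     file.path(out_dir, paste0("pseudobulk_", mod,
                                               ".bedGraph")))
    }
    write_bed(data.frame(chrom = genome$chrom,
                         start = as.integer(borders$position) -
                           config$bin_width %/% 2,
                         end = as.integer(borders$position) +
                           config$bin_width %/% 2,
                         name = c("weak", "moderate",
                                  "strong")[borders$grade],
                         score = pmin(999, borders$grade * 333)),
              file.path(out_dir, "borders.bed"))
    write_bed(data.frame(chrom = genome$chrom,
                         start = as.integer(domains$start),
                         end = as.integer(domains$end),
                         name = domains$state),
              file.path(out_dir, "domains.bed"))
    jsonlite::write_json(
      report[c("seed", "n_cells", "n_retained_qc", "borders_by_grade",
               "insulation_internal_boundaries", "pileup_enrichment",
               "n_differential", "metagene_label_accuracy", "checks",
               "pass")],
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
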