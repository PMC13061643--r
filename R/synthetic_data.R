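# Synthetic-data generator: a toy genome with a 13-gene HOX-like cluster,
# trimodal fragment sets with planted signal borders, cell-type fragment
# sets with marker structure and differential bins, contact matrices with
# distance decay / TADs / loops, and TF edge lists. Every generator is
# deterministic given config$seed.

.default_rates <- function() {
  m <- rbind(s0 = c(0.05, 0.05, 0.10),
             s1 = c(0.60, 0.60, 0.25),
             s2 = c(0.40, 0.40, 0.40),
             s3 = c(0.40, 0.40, 0.70),
             s4 = c(0.05, 0.05, 1.20),
             s5 = c(0.05, 0.20, 0.30))
  colnames(m) <- c("ATAC", "H3K27ac", "H3K27me3")
  m
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators: the random seed,
#' cell numbers, the fragment-length mixture (subnucleosomal mode ~80 bp,
#' mononucleosomal mode ~200 bp), the count noise model (Poisson, or
#' negative binomial with the given dispersion), the fraction of cells with
#' depleted 3' H3K27me3 (group 2), and the per-segment expected
#' fragments/cell/2-kb-bin rate table for (ATAC, H3K27ac, H3K27me3).
#'
#' @param seed Integer RNG seed; fixed seed implies identical outputs.
#' @param cells_per_type Cells simulated per cell type (and for the fixture).
#' @param celltypes Character vector of cell-type names (>= 2).
#' @param markers_per_type Marker genes per cell type in the toy genome.
#' @param chrom_length Toy chromosome length (bp).
#' @param cluster_start 0-based start of the 13-gene cluster.
#' @param gene_spacing Spacing between cluster gene TSSs (bp).
#' @param n_cluster_genes Number of cluster genes.
#' @param flank Flanking width around the cluster in the fixture (bp).
#' @param frag_len_modes,frag_len_sds Means/sds of the two fragment-length
#'   mixture components (bp).
#' @param subnuc_weight Mixture weight of the subnucleosomal component.
#' @param noise "poisson" or "nb".
#' @param dispersion Negative-binomial dispersion (used when noise = "nb").
#' @param group2_fraction Fraction of fixture cells with 3' H3K27me3
#'   depleted to the upstream-flank level.
#' @param n_diff_bins,diff_fold Differentially accessible bins planted
#'   between the two regions of the first cell type, and their fold change.
#' @param bin_width Fragment count matrix bin width (bp).
#' @param contact_bin Contact-matrix bin width (bp).
#' @param contact_depth Expected diagonal contact count.
#' @param rates 6 x 3 segment rate table (rows s0..s5).
#' @return A validated \code{sim_config} object.
#' @export
sim_config <- function(seed = 1L, cells_per_type = 500L,
                       celltypes = c("OLG", "AST", "MIGL"),
                       markers_per_type = 20L,
                       chrom_length = 2e6, cluster_start = 900000L,
                       gene_spacing = 12000L, n_cluster_genes = 13L,
                       flank = 50000L,
                       frag_len_modes = c(80, 200),
                       frag_len_sds = c(15, 35),
                       subnuc_weight = 0.5,
                       noise = c("poisson", "nb"), dispersion = 0.3,
                       group2_fraction = 0.4,
                       n_diff_bins = 50L, diff_fold = 3,
                       bin_width = 2000L, contact_bin = 10000L,
                       contact_depth = 300,
                       rates = .default_rates()) {
  noise <- match.arg(noise)
  stopifnot(length(seed) == 1, is.finite(seed),
            cells_per_type >= 0, length(celltypes) >= 2,
            markers_per_type >= 1, chrom_length > 0,
            subnuc_weight >= 0, subnuc_weight <= 1,
            group2_fraction >= 0, group2_fraction <= 1,
            dispersion > 0, all(rates >= 0),
            nrow(rates) == 6, ncol(rates) == 3,
            bin_width > 0, gene_spacing %% bin_width == 0,
            cluster_start %% bin_width == 0, flank %% bin_width == 0)
  structure(list(seed = as.integer(seed),
                 cells_per_type = as.integer(cells_per_type),
                 celltypes = celltypes,
                 markers_per_type = as.integer(markers_per_type),
                 chrom_length = as.integer(chrom_length),
                 cluster_start = as.integer(cluster_start),
                 gene_spacing = as.integer(gene_spacing),
                 n_cluster_genes = as.integer(n_cluster_genes),
                 flank = as.integer(flank),
                 frag_len_modes = frag_len_modes,
                 frag_len_sds = frag_len_sds,
                 subnuc_weight = subnuc_weight,
                 noise = noise, dispersion = dispersion,
                 group2_fraction = group2_fraction,
                 n_diff_bins = as.integer(n_diff_bins),
                 diff_fold = diff_fold,
                 bin_width = as.integer(bin_width),
                 contact_bin = as.integer(contact_bin),
                 contact_depth = contact_depth,
                 rates = rates),
            class = "sim_config")
}

# counts from the configured noise model
.sim_counts <- function(n, lambda, config) {
  if (config$noise == "poisson") {
    stats::rpois(n, lambda)
  } else {
    stats::rnbinom(n, size = 1 / config$dispersion, mu = lambda)
  }
}

# expand per-(cell, bin) counts into fragment records
.counts_to_fragments <- function(cell_idx, bin_start, counts, barcodes,
                                 chrom, chrom_length, config) {
  tot <- sum(counts)
  if (tot == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), barcode = character(),
                      count = integer()))
  }
  ci <- rep.int(cell_idx, counts)
  bs <- rep.int(bin_start, counts)
  comp <- stats::runif(tot) < config$subnuc_weight
  len <- ifelse(comp,
                stats::rnorm(tot, config$frag_len_modes[1], config$frag_len_sds[1]),
                stats::rnorm(tot, config$frag_len_modes[2], config$frag_len_sds[2]))
  len <- pmax(30L, as.integer(round(len)))
  start <- bs + as.integer(floor(stats::runif(tot) * config$bin_width))
  end <- pmin(start + len, chrom_length)
  start <- pmin(start, end - 1L)
  data.frame(chrom = chrom, start = start, end = end,
             barcode = barcodes[ci], count = 1L)
}

#' Build the toy genome
#'
#' One chromosome carrying a 13-gene cluster (genes strictly ordered 3' to
#' 5' along increasing coordinates, evenly spaced) plus background marker
#' genes for each configured cell type.
#'
#' @param config A \code{sim_config}.
#' @return A \code{toy_genome}: chromosome name/length, gene table
#'   (name, tss, strand, role), and the ordered cluster gene table.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  span <- config$n_cluster_genes * config$gene_spacing
  if (config$cluster_start + span > config$chrom_length) {
    stop("cluster span exceeds chromosome length (configuration error)")
  }
  cl_tss <- config$cluster_start +
    (seq_len(config$n_cluster_genes) - 1L) * config$gene_spacing
  cluster <- data.frame(name = sprintf("HX%d", seq_len(config$n_cluster_genes)),
                        tss = cl_tss, strand = "+", role = "cluster")
  n_mark <- length(config$celltypes) * config$markers_per_type
  mk_tss <- 50000L + (seq_len(n_mark) - 1L) * 12000L
  if (any(mk_tss + 12000L > config$cluster_start - config$flank)) {
    stop("marker genes would overlap the cluster flank; enlarge the chromosome")
  }
  type <- rep(config$celltypes, length.out = n_mark)
  markers <- data.frame(
    name = sprintf("%s_M%d", type,
                   stats::ave(seq_len(n_mark), type, FUN = seq_along)),
    tss = mk_tss, strand = "+", role = type)
  structure(list(chrom = "chrS", length = config$chrom_length,
                 genes = rbind(markers, cluster), cluster = cluster,
                 cluster_start = config$cluster_start,
                 cluster_end = config$cluster_start + span),
            class = "toy_genome")
}

#' Generate the HOX-like fixture: segment profiles and trimodal fragments
#'
#' Six segments tile the cluster plus flanks: an inactive upstream flank
#' (s0), a 3' accessible/H3K27ac-marked block with intermediate H3K27me3
#' (s1, genes 1-4), two internal sub-transitions (s2 genes 5-6, s3 genes
#' 7-9 stepping only H3K27me3), a heavily H3K27me3-marked 5' block (s4,
#' genes 10-13), and a downstream flank (s5). A configured fraction of
#' cells ("group 2") has its 3' (s1-s3) H3K27me3 rates reduced to the
#' upstream-flank level while H3K27ac is identical across groups.
#'
#' @param genome A \code{toy_genome}.
#' @param config A \code{sim_config}.
#' @return A \code{hox_fixture}: locus, segment profile table, planted
#'   transition table (position, modalities, grade), barcodes, per-cell
#'   group labels, and one fragment table per modality.
#' @export
make_hox_fixture <- function(genome, config) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"))
  set.seed(config$seed)
  w <- config$bin_width
  g <- genome$cluster$tss
  seg_bounds <- c(genome$cluster_start - config$flank,
                  g[1], g[5], g[7], g[10],
                  genome$cluster_end,
                  genome$cluster_end + config$flank)
  rates <- config$rates
  segments <- data.frame(name = rownames(rates),
                         start = seg_bounds[-length(seg_bounds)],
                         end = seg_bounds[-1],
                         ATAC = rates[, "ATAC"],
                         H3K27ac = rates[, "H3K27ac"],
                         H3K27me3 = rates[, "H3K27me3"],
                         row.names = NULL)
  # planted transitions: which modalities change between adjacent segments
  trans <- lapply(seq_len(nrow(segments) - 1L), function(i) {
    d <- abs(rates[i + 1L, ] - rates[i, ]) > 1e-12
    data.frame(position = segments$end[i],
               modalities = paste(colnames(rates)[d], collapse = ","),
               grade = sum(d))
  })
  transitions <- do.call(rbind, trans)

  n <- config$cells_per_type
  barcodes <- sprintf("FIXC%05d", seq_len(n))
  n2 <- round(n * config$group2_fraction)
  group <- rep("group1", n)
  if (n2 > 0) group[sample.int(n, n2)] <- "group2"
  names(group) <- barcodes

  bin_start <- seq(segments$start[1], segments$end[6] - w, by = w)
  seg_of_bin <- findInterval(bin_start, segments$start)
  frags <- list()
  for (mod in colnames(rates)) {
    rate_bin <- rates[seg_of_bin, mod]
    if (mod == "H3K27me3") {
      dep <- rate_bin
      dep[seg_of_bin %in% 2:4] <- rates["s0", mod]  # s1-s3 depleted
      lam <- matrix(rate_bin, n, length(bin_start), byrow = TRUE)
      if (any(group == "group2")) {
        lam[group == "group2", ] <- matrix(dep, sum(group == "group2"),
                                           length(bin_start), byrow = TRUE)
      }
      counts <- matrix(.sim_counts(length(lam), as.vector(lam), config),
                       n, length(bin_start))
    } else {
      counts <- matrix(.sim_counts(n * length(bin_start),
                                   rep(rate_bin, each = n), config),
                       n, length(bin_start))
    }
    idx <- which(counts > 0, arr.ind = TRUE)
    frags[[mod]] <- .counts_to_fragments(
      idx[, 1], bin_start[idx[, 2]], counts[idx], barcodes,
      genome$chrom, genome$length, config)
  }
  structure(list(locus = c(segments$start[1], segments$end[6]),
                 segments = segments, transitions = transitions,
                 barcodes = barcodes, groups = group,
                 fragments = frags),
            class = "hox_fixture")
}

#' Simulate cell-type-structured fragment sets
#'
#' Each cell type enriches its own marker-gene promoters in ATAC and
#' H3K27ac and depletes them in H3K27me3 (other cell types carry the
#' repressive mark there instead). The first cell type is split into two
#' equal "regions", with a configured number of background bins planted as
#' differentially accessible (ATAC rate multiplied by \code{diff_fold} in
#' region A).
#'
#' @param genome A \code{toy_genome}.
#' @param config A \code{sim_config}.
#' @return List with per-modality fragment tables, a cell table
#'   (barcode, celltype, region), the 2-kb \code{bin_scheme} used, and a
#'   truth list (marker bins per type, differential bins, fold).
#' @export
simulate_celltype_fragments <- function(genome, config) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"))
  if (length(config$celltypes) < 2) stop("need >= 2 cell types")
  set.seed(config$seed + 1L)
  w <- config$bin_width
  scheme <- bin_scheme(stats::setNames(genome$length, genome$chrom), w)
  nb <- scheme$total_bins
  types <- config$celltypes
  n <- config$cells_per_type

  markers <- genome$genes[genome$genes$role %in% types, ]
  marker_bins <- lapply(stats::setNames(types, types), function(ty) {
    tss <- markers$tss[markers$role == ty]
    unique(unlist(lapply(tss, function(p) {
      bin_index(scheme, genome$chrom,
                seq(max(0, p - 2000), min(genome$length - 1, p + 1999), by = w))
    })))
  })
  all_marker_bins <- unique(unlist(marker_bins))
  locus_bins <- bin_index(scheme, genome$chrom,
                          seq(genome$cluster_start - config$flank,
                              genome$cluster_end + config$flank - 1, by = w))
  free_bins <- setdiff(seq_len(nb), c(all_marker_bins, locus_bins))
  diff_bins <- sort(sample(free_bins, min(config$n_diff_bins, length(free_bins))))

  bc <- sprintf("%s%05d", rep(types, each = n), seq_len(n * length(types)))
  cells <- data.frame(barcode = bc, celltype = rep(types, each = n),
                      region = rep(NA_character_, length(bc)))
  i1 <- which(cells$celltype == types[1])
  cells$region[i1] <- rep(c("regionA", "regionB"), length.out = length(i1))

  base <- 0.05
  frags <- list()
  for (mod in c("ATAC", "H3K27ac", "H3K27me3")) {
    recs <- vector("list", length(types) * 2L)
    k <- 0L
    for (ty in types) {
      for (rg in unique(cells$region[cells$celltype == ty])) {
        sel <- cells$celltype == ty &
          (is.na(rg) & is.na(cells$region) | !is.na(rg) & cells$region %in% rg)
        bc <- cells$barcode[sel]
        if (!length(bc)) next
        rate <- rep(base, nb)
        if (mod %in% c("ATAC", "H3K27ac")) {
          rate[marker_bins[[ty]]] <- 0.6
        } else {
          rate[all_marker_bins] <- 0.4
          rate[marker_bins[[ty]]] <- 0.02
        }
        if (mod == "ATAC" && ty == types[1] && identical(rg, "regionA")) {
          rate[diff_bins] <- rate[diff_bins] * config$diff_fold
        }
        counts <- matrix(.sim_counts(length(bc) * nb, rep(rate, each = length(bc)),
                                     config), length(bc), nb)
        idx <- which(counts > 0, arr.ind = TRUE)
        k <- k + 1L
        recs[[k]] <- .counts_to_fragments(
          idx[, 1], (idx[, 2] - 1L) * w, counts[idx], bc,
          genome$chrom, genome$length, config)
      }
    }
    frags[[mod]] <- if (k > 0) {
      do.call(rbind, recs[seq_len(k)])
    } else {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 barcode = character(), count = integer())
    }
  }
  list(fragments = frags, cells = cells, scheme = scheme,
       truth = list(marker_bins = marker_bins, diff_bins = diff_bins,
                    diff_fold = config$diff_fold))
}

#' Simulate a binned contact matrix with distance decay, TADs and loops
#'
#' Expected counts follow \code{depth / (1 + d)} in bin units, multiplied
#' by 2 within a TAD and by 3 at planted loop anchor pixels, with Poisson
#' noise; the matrix is symmetric by construction. \code{single_tad} wraps
#' the whole cluster in one domain; \code{split_tad} places an internal
#' junction at the fixture's mid-cluster border (the transition into the
#' heavily repressed 5' block).
#'
#' @param scenario "single_tad" or "split_tad".
#' @param loops Optional data.frame of anchor midpoints in bp
#'   (columns a, b), or NULL.
#' @param config A \code{sim_config}.
#' @param genome A \code{toy_genome}.
#' @return A \code{contact_matrix} with a "truth" attribute (bin origin,
#'   cluster bins, junction bin, loop pixels).
#' @export
simulate_contact_matrix <- function(scenario = c("single_tad", "split_tad"),
                                    loops = NULL, config, genome) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  wb <- config$contact_bin
  r0 <- (genome$cluster_start - 300000L) %/% wb * wb
  r1 <- as.integer(ceiling((genome$cluster_end + 300000L) / wb) * wb)
  n <- (r1 - r0) %/% wb
  pos2bin <- function(p) as.integer((p - r0) %/% wb + 1L)
  cl0 <- pos2bin(genome$cluster_start)
  cl1 <- pos2bin(genome$cluster_end - 1L)
  junction <- pos2bin(genome$cluster$tss[10])
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lambda <- config$contact_depth / (1 + d)
  tads <- if (scenario == "single_tad") {
    list(c(cl0, cl1))
  } else {
    list(c(cl0, junction - 1L), c(junction, cl1))
  }
  for (td in tads) {
    idx <- td[1]:td[2]
    lambda[idx, idx] <- lambda[idx, idx] * 2
  }
  loop_bins <- NULL
  if (!is.null(loops) && nrow(loops)) {
    ba <- pos2bin(loops$a)
    bb <- pos2bin(loops$b)
    if (any(c(ba, bb) < 1 | c(ba, bb) > n)) {
      stop("loop anchor outside contact matrix")
    }
    loop_bins <- data.frame(bin_a = pmin(ba, bb), bin_b = pmax(ba, bb))
    for (k in seq_len(nrow(loop_bins))) {
      i <- loop_bins$bin_a[k]; j <- loop_bins$bin_b[k]
      lambda[i, j] <- lambda[i, j] * 3
      lambda[j, i] <- lambda[i, j]
    }
  }
  counts <- matrix(0, n, n)
  ut <- upper.tri(counts, diag = TRUE)
  counts[ut] <- stats::rpois(sum(ut), lambda[ut])
  counts <- counts + t(counts) - diag(diag(counts))
  bins <- data.frame(chrom = genome$chrom,
                     start = r0 + (seq_len(n) - 1L) * wb,
                     end = r0 + seq_len(n) * wb)
  cm <- contact_matrix(bins, counts)
  attr(cm, "truth") <- list(region_start = r0, bin = wb, scenario = scenario,
                            cluster_bins = c(cl0, cl1),
                            junction_bin = junction, loop_bins = loop_bins)
  cm
}

#' Simulate a directed TF edge list
#'
#' Each ordered pair (i, j), i != j, becomes an edge with probability
#' proportional to TF i's out-propensity (self-edges are excluded).
#' Ground-truth out/in degrees are returned alongside the edges.
#'
#' @param n_tfs Number of TFs (>= 2).
#' @param config A \code{sim_config} (seed).
#' @param propensities Per-TF out-propensities (recycled to n_tfs).
#' @param edge_prob Baseline edge probability for propensity 1.
#' @return List with edges (regulator, target), and truth out/in degrees.
#' @export
simulate_tf_edges <- function(n_tfs, config, propensities = 1,
                              edge_prob = 0.08) {
  stopifnot(n_tfs >= 2, inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  propensities <- rep_len(propensities, n_tfs)
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  p <- pmin(0.95, edge_prob * propensities)
  adj <- matrix(stats::runif(n_tfs * n_tfs) < rep(p, times = n_tfs),
                n_tfs, n_tfs)  # row = regulator
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- data.frame(regulator = tfs[idx[, 1]], target = tfs[idx[, 2]])
  list(edges = edges,
       truth = list(out_degree = stats::setNames(rowSums(adj), tfs),
                    in_degree = stats::setNames(colSums(adj), tfs)))
}
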