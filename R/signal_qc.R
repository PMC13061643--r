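# Per-cell QC (TSS enrichment, fragment counts), pseudobulk CPM tracks,
# Gaussian smoothing, V-plots and k-means gene clustering on mark profiles.

#' Per-cell TSS enrichment score
#'
#' For each cell, the mean Tn5 insertion rate (insertions per bp, pooled
#' over all TSSs) in the +/- \code{flank} window around TSSs, divided by
#' the mean rate in the outermost 100 bp at each end of the +/-
#' \code{window} region. Cells with no background insertions score 0 and
#' are flagged.
#'
#' @param frags Fragment table.
#' @param tss_positions 0-based TSS positions (single chromosome assumed;
#'   supply a \code{chrom} to restrict).
#' @param window,flank Background half-window and center half-window (bp).
#' @param chrom Optional chromosome filter.
#' @return data.frame(barcode, tsse, flagged).
#' @export
tss_enrichment <- function(frags, tss_positions, window = 2000, flank = 100,
                           chrom = NULL) {
  if (window <= flank) stop("window must exceed flank (configuration error)")
  if (!length(tss_positions)) stop("need at least one TSS")
  validate_fragments(frags)
  if (!is.null(chrom)) frags <- frags[frags$chrom == chrom, , drop = FALSE]
  barcodes <- sort(unique(frags$barcode))
  pos <- c(frags$start, frags$end - 1L)
  bc <- factor(rep(frags$barcode, 2L), levels = barcodes)
  cnt <- rep(frags$count, 2L)
  center <- numeric(length(barcodes))
  backgr <- numeric(length(barcodes))
  for (tss in tss_positions) {
    off <- pos - tss
    inc <- off >= -flank & off < flank
    inb <- (off >= -window & off < -window + 100) |
      (off >= window - 100 & off < window)
    if (any(inc)) {
      t1 <- tapply(cnt[inc], bc[inc], sum, default = 0)
      center <- center + ifelse(is.na(t1), 0, t1)
    }
    if (any(inb)) {
      t2 <- tapply(cnt[inb], bc[inb], sum, default = 0)
      backgr <- backgr + ifelse(is.na(t2), 0, t2)
    }
  }
  nt <- length(tss_positions)
  rate_c <- center / (2 * flank * nt)
  rate_b <- backgr / (200 * nt)
  flagged <- backgr == 0
  tsse <- ifelse(flagged, 0, rate_c / rate_b)
  data.frame(barcode = barcodes, tsse = tsse, flagged = flagged)
}

#' Per-cell QC table
#'
#' Unique fragment count (number of distinct fragment records) and TSS
#' enrichment per barcode.
#'
#' @inheritParams tss_enrichment
#' @return data.frame(barcode, fragments, tsse).
#' @export
cell_qc <- function(frags, tss_positions, window = 2000, flank = 100,
                    chrom = NULL) {
  ts <- tss_enrichment(frags, tss_positions, window, flank, chrom)
  nf <- table(frags$barcode)
  ts$fragments <- as.integer(nf[ts$barcode])
  ts[, c("barcode", "fragments", "tsse")]
}

#' Filter cells on TSS enrichment and fragment count
#'
#' Both thresholds are strict: a cell at exactly the threshold is rejected.
#'
#' @param qc data.frame with barcode, fragments, tsse.
#' @param tsse_min,frag_min Strict lower thresholds.
#' @return List with \code{retained} barcodes and a \code{report}
#'   data.frame giving the rejection reason per cell.
#' @export
qc_filter <- function(qc, tsse_min = 7, frag_min = 3000) {
  ok_t <- qc$tsse > tsse_min
  ok_f <- qc$fragments > frag_min
  reason <- rep("retained", nrow(qc))
  reason[!ok_t & ok_f] <- "low_tsse"
  reason[ok_t & !ok_f] <- "low_fragments"
  reason[!ok_t & !ok_f] <- "low_tsse_and_fragments"
  list(retained = qc$barcode[ok_t & ok_f],
       report = data.frame(barcode = qc$barcode, reason = reason))
}

#' Pseudobulk signal tracks per cell group
#'
#' Sums the cell-by-bin matrix over each group and (by default) scales to
#' counts per million of the group total, so every track sums to 1e6.
#'
#' @param mat Cell-by-bin count matrix (rownames = barcodes).
#' @param groups Named list of barcode vectors; groups must not overlap.
#' @param scheme Single-chromosome \code{bin_scheme} matching the columns.
#' @param normalization "CPM" or "raw".
#' @return Named list of \code{binned_track}, one per group.
#' @export
pseudobulk_track <- function(mat, groups, scheme, normalization = "CPM") {
  if (length(scheme$n_bins) != 1) stop("tracks cover a single chromosome")
  all_bc <- unlist(groups)
  if (anyDuplicated(all_bc)) stop("groups must not overlap")
  if (!all(all_bc %in% rownames(mat))) stop("group barcode missing from matrix")
  lapply(groups, function(bc) {
    v <- Matrix::colSums(mat[bc, , drop = FALSE])
    if (normalization == "CPM") {
      tot <- sum(v)
      if (tot > 0) v <- v * 1e6 / tot
    }
    binned_track(names(scheme$n_bins), scheme$width, as.numeric(v),
                 normalization = normalization)
  })
}

#' Gaussian-smooth a binned track
#'
#' Discrete Gaussian convolution with symmetric (reflected) boundaries;
#' total mass is conserved.
#'
#' @param track A \code{binned_track}.
#' @param sigma_bins Kernel standard deviation in bins (> 0).
#' @return Smoothed \code{binned_track}.
#' @export
smooth_track <- function(track, sigma_bins) {
  if (sigma_bins <= 0) stop("sigma_bins must be > 0")
  v <- track$values
  r <- max(1L, as.integer(ceiling(4 * sigma_bins)))
  k <- stats::dnorm(-r:r, 0, sigma_bins)
  k <- k / sum(k)
  n <- length(v)
  if (n < 2) return(track)
  ri <- min(r, n)
  pad <- c(v[ri:1], v, v[n:(n - ri + 1)])
  if (ri < r) pad <- c(rep(v[1], r - ri), pad, rep(v[n], r - ri))
  sm <- stats::filter(pad, k, sides = 2)
  out <- track
  out$values <- as.numeric(sm[(r + 1):(r + n)])
  out
}

#' V-plot: fragment midpoints versus fragment length around a locus
#'
#' Two-dimensional histogram of (midpoint offset from center, fragment
#' length) for fragments whose midpoint falls within the window, plus the
#' per-position Tn5 insertion density.
#'
#' @param frags Fragment table.
#' @param chrom Chromosome of the center.
#' @param center 0-based center position.
#' @param half_window Half-width of the window (bp).
#' @param max_len Maximum fragment length retained.
#' @param len_bin,pos_bin Histogram bin sizes (bp).
#' @return List with \code{hist} (length-bin x offset-bin count matrix),
#'   \code{insertion_density} (per-bp terminus counts, offsets
#'   -half_window..half_window), and the retained fragment count.
#' @export
vplot <- function(frags, chrom, center, half_window = 1750, max_len = 600,
                  len_bin = 5, pos_bin = 5) {
  validate_fragments(frags)
  f <- frags[frags$chrom == chrom, , drop = FALSE]
  len <- f$end - f$start
  mid <- (f$start + f$end) / 2
  off <- mid - center
  keep <- abs(off) <= half_window & len <= max_len & len >= 1
  f <- f[keep, , drop = FALSE]
  off <- off[keep]
  len <- len[keep]
  npos <- as.integer(ceiling(2 * half_window / pos_bin))
  nlen <- as.integer(ceiling(max_len / len_bin))
  pb <- pmin(npos, as.integer(floor((off + half_window) / pos_bin)) + 1L)
  lb <- pmin(nlen, as.integer(floor((len - 1) / len_bin)) + 1L)
  h <- matrix(0L, nlen, npos,
              dimnames = list(length = NULL, offset = NULL))
  for (i in seq_along(pb)) h[lb[i], pb[i]] <- h[lb[i], pb[i]] + f$count[i]
  ins <- integer(2 * half_window + 1)
  term <- c(f$start, f$end - 1L) - center
  tc <- rep(f$count, 2L)
  ok <- abs(term) <= half_window
  ti <- term[ok] + half_window + 1L
  for (i in seq_along(ti)) ins[ti[i]] <- ins[ti[i]] + tc[ok][i]
  list(hist = h, insertion_density = ins, n_fragments = nrow(f))
}

#' Fraction of fragment counts in peaks
#'
#' @param frags Fragment table.
#' @param peaks data.frame(chrom, start, end).
#' @return Scalar FRiP (fragment-overlap based).
#' @export
frip <- function(frags, peaks) {
  validate_fragments(frags)
  inpk <- rep(FALSE, nrow(frags))
  for (i in seq_len(nrow(peaks))) {
    inpk <- inpk | (frags$chrom == peaks$chrom[i] &
                      frags$end > peaks$start[i] & frags$start < peaks$end[i])
  }
  sum(frags$count[inpk]) / sum(frags$count)
}

#' Cluster genes by their joint mark profiles
#'
#' k-means (fixed seed) on row-scaled gene profiles, e.g. binned H3K27ac
#' and H3K27me3 signal around each TSS.
#'
#' @param tss_signal Numeric gene x feature matrix.
#' @param k Number of clusters (<= number of genes).
#' @param seed RNG seed for the k-means initialization.
#' @param scale_rows Center/scale each gene profile first.
#' @return List with \code{labels} (named by gene) and \code{centers}.
#' @export
cluster_genes_by_marks <- function(tss_signal, k = 10, seed = 1,
                                   scale_rows = TRUE) {
  tss_signal <- as.matrix(tss_signal)
  if (k > nrow(tss_signal)) stop("k must not exceed the number of genes")
  x <- tss_signal
  if (scale_rows) {
    mu <- rowMeans(x)
    sd <- apply(x, 1, stats::sd)
    sd[sd == 0] <- 1
    x <- (x - mu) / sd
  }
  if (k == nrow(x)) {  # degenerate: every gene its own cluster
    return(list(labels = stats::setNames(seq_len(k), rownames(tss_signal)),
                centers = x))
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 10, iter.max = 100)
  list(labels = stats::setNames(km$cluster, rownames(tss_signal)),
       centers = km$centers)
}
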