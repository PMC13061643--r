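# Within-cell joint-mark analysis: per-cell regional signal for two
# modalities sharing one cell barcode, an H3K27me3-based two-group split,
# and a permutation test of H3K27ac equality between the groups.

#' Per-cell depth-normalized signal in a region
#'
#' Counts fragments overlapping the region per cell and modality, and
#' normalizes by the cell's total fragment count in that modality (counts
#' per thousand). Cells with zero total depth are flagged.
#'
#' @param fragments Named list of fragment tables (one per modality,
#'   sharing cell barcodes).
#' @param chrom Chromosome of the region.
#' @param region c(start, end), 0-based half-open.
#' @param barcodes Barcodes to report (shared across modalities).
#' @return data.frame(barcode, modality, raw, total, norm, flagged).
#' @export
percell_region_signal <- function(fragments, chrom, region, barcodes) {
  stopifnot(length(region) == 2, region[1] < region[2])
  out <- lapply(names(fragments), function(mod) {
    f <- fragments[[mod]]
    validate_fragments(f)
    f <- f[f$barcode %in% barcodes, , drop = FALSE]
    bc <- factor(f$barcode, levels = barcodes)
    total <- tapply(f$count, bc, sum, default = 0)
    total[is.na(total)] <- 0
    inr <- f$chrom == chrom & f$end > region[1] & f$start < region[2]
    raw <- tapply(f$count[inr], bc[inr], sum, default = 0)
    raw[is.na(raw)] <- 0
    flagged <- total == 0
    data.frame(barcode = barcodes, modality = mod,
               raw = as.numeric(raw), total = as.numeric(total),
               norm = ifelse(flagged, 0, 1000 * raw / total),
               flagged = flagged)
  })
  do.call(rbind, out)
}

#' Split cells into two groups by a mark's regional signal
#'
#' One-dimensional 2-means with deterministic initialization at the 10th
#' and 90th percentiles. Group 1 is the higher-signal group. When the
#' values admit no split (all identical, or the clusters collapse), the
#' split is refused and a single group is returned with a diagnostic.
#' The mean silhouette width is reported as a separation diagnostic.
#'
#' @param values Named numeric vector (e.g. per-cell normalized H3K27me3).
#' @return List with \code{labels} (named, "group1"/"group2"),
#'   \code{centers}, \code{silhouette}, \code{refused}, \code{diagnostic}.
#' @export
split_groups_by_mark <- function(values) {
  if (length(values) < 4) stop("need at least 4 cells")
  x <- as.numeric(values)
  nm <- names(values)
  refuse <- function(msg) {
    list(labels = stats::setNames(rep("group1", length(x)), nm),
         centers = c(group1 = mean(x), group2 = NA_real_),
         silhouette = NA_real_, refused = TRUE, diagnostic = msg)
  }
  if (diff(range(x)) == 0) return(refuse("all values identical"))
  ctr <- unname(stats::quantile(x, c(0.9, 0.1), type = 7))
  if (ctr[1] == ctr[2]) ctr <- range(x)[2:1]
  for (it in 1:100) {
    lab <- ifelse(abs(x - ctr[1]) <= abs(x - ctr[2]), 1L, 2L)
    if (length(unique(lab)) < 2) return(refuse("clusters collapsed"))
    new <- c(mean(x[lab == 1]), mean(x[lab == 2]))
    if (isTRUE(all.equal(new, ctr))) break
    ctr <- new
  }
  if (ctr[1] < ctr[2]) {  # ensure group1 = higher mean
    lab <- 3L - lab
    ctr <- rev(ctr)
  }
  # mean silhouette width (1D, exact pairwise distances)
  n <- length(x)
  sil <- vapply(seq_len(n), function(i) {
    own <- x[lab == lab[i]]
    oth <- x[lab != lab[i]]
    a <- if (length(own) > 1) sum(abs(x[i] - own)) / (length(own) - 1) else 0
    b <- mean(abs(x[i] - oth))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  list(labels = stats::setNames(c("group1", "group2")[lab], nm),
       centers = c(group1 = ctr[1], group2 = ctr[2]),
       silhouette = mean(sil), refused = FALSE, diagnostic = "ok")
}

#' Permutation test of mark equality between two cell groups
#'
#' Two-sided permutation test of the difference in group means under a
#' label-shuffling null; p = (1 + #{|T_perm| >= |T_obs|}) / (1 + n_perm).
#'
#' @param values Numeric per-cell signal (e.g. normalized H3K27ac).
#' @param groups Group labels, two levels, same length as values.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return List with \code{observed} mean difference, \code{p_value} and
#'   \code{n_perm}.
#' @export
test_mark_uniformity <- function(values, groups, n_perm = 10000, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) == 0)) {
    stop("need two non-empty groups")
  }
  x <- as.numeric(values)
  n <- length(x)
  n1 <- sum(groups == levels(groups)[1])
  n2 <- n - n1
  tot <- sum(x)
  obs <- mean(x[groups == levels(groups)[1]]) -
    mean(x[groups == levels(groups)[2]])
  set.seed(seed)
  tperm <- vapply(seq_len(n_perm), function(i) {
    s <- sum(x[sample.int(n, n1)])
    s / n1 - (tot - s) / n2
  }, 0)
  p <- (1 + sum(abs(tperm) >= abs(obs))) / (1 + n_perm)
  list(observed = obs, p_value = p, n_perm = n_perm)
}
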