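# Gene-activity matrix around promoters, metagene cell-type scoring, and
# differential accessibility (Welch t on log1p-CPM, Benjamini-Hochberg).

#' Gene activity from a binned count matrix
#'
#' Per gene, sums counts of all bins overlapping the promoter window
#' [TSS - flank, TSS + flank); with \code{promoter_flank = 0} the single
#' bin containing the TSS is used. Optional k-NN smoothing averages each
#' cell's activity over its nearest neighbors in PC space.
#'
#' @param mat Cell-by-bin count matrix.
#' @param scheme The \code{bin_scheme} of the matrix columns.
#' @param genes data.frame with name, tss and (optionally) chrom columns;
#'   tss is the strand-resolved transcription start.
#' @param promoter_flank Promoter half-width in bp.
#' @param knn Number of neighbors for smoothing (0 = off).
#' @return Dense cell x gene activity matrix.
#' @export
gene_activity <- function(mat, scheme, genes, promoter_flank = 5000,
                          knn = 0) {
  chroms <- if ("chrom" %in% names(genes)) genes$chrom else
    rep(names(scheme$n_bins)[1], nrow(genes))
  act <- matrix(0, nrow(mat), nrow(genes),
                dimnames = list(rownames(mat), genes$name))
  for (i in seq_len(nrow(genes))) {
    tss <- genes$tss[i]
    if (promoter_flank == 0) {
      lo <- tss
      hi <- tss + 1
    } else {
      lo <- max(0, tss - promoter_flank)
      hi <- min(scheme$chrom_lengths[[chroms[i]]], tss + promoter_flank)
    }
    if (lo >= hi) next
    b0 <- bin_index(scheme, chroms[i], lo)
    b1 <- bin_index(scheme, chroms[i], hi - 1)
    act[, i] <- Matrix::rowSums(mat[, b0:b1, drop = FALSE])
  }
  if (knn > 0) {
    lp <- log1p(1e6 * act / pmax(1, rowSums(act)))
    pcs <- stats::prcomp(lp, rank. = min(10, ncol(lp), nrow(lp) - 1))$x
    d <- as.matrix(stats::dist(pcs))
    sm <- act
    for (i in seq_len(nrow(act))) {
      nb <- order(d[i, ])[seq_len(min(knn + 1, nrow(act)))]
      sm[i, ] <- colMeans(act[nb, , drop = FALSE])
    }
    act <- sm
  }
  act
}

#' Metagene cell-type scores and labels
#'
#' Per-cell CPM-normalized activities are z-scored per gene; a cell's
#' score for a marker set is the mean z over the set's genes, and its
#' label the argmax set. Ties and all-zero cells are left unlabeled and
#' flagged; marker-set overlaps are reported as an attribute.
#'
#' @param activity Cell x gene activity matrix.
#' @param marker_sets Named list of marker gene vectors.
#' @return data.frame with one score column per set plus label, margin
#'   and flagged columns; rownames are the cells.
#' @export
metagene_score <- function(activity, marker_sets) {
  missing <- lapply(marker_sets, setdiff, y = colnames(activity))
  if (any(lengths(missing) > 0)) {
    stop("marker genes absent from activity matrix: ",
         paste(unlist(missing), collapse = ", "))
  }
  overlaps <- outer(names(marker_sets), names(marker_sets),
                    Vectorize(function(a, b) {
                      length(intersect(marker_sets[[a]], marker_sets[[b]]))
                    }))
  depth <- rowSums(activity)
  zero <- depth == 0
  cpm <- 1e6 * activity / ifelse(depth == 0, 1, depth)
  z <- scale(cpm)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z[!is.finite(z)] <- 0
  scores <- vapply(marker_sets, function(gs) {
    rowMeans(z[, gs, drop = FALSE])
  }, numeric(nrow(activity)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  top <- apply(scores, 1, function(s) {
    o <- order(-s)
    tie <- sum(s == s[o[1]]) > 1
    c(which_max = unname(o[1]), margin = unname(s[o[1]] - s[o[2]]),
      tie = unname(tie))
  })
  label <- colnames(scores)[top["which_max", ]]
  label[top["tie", ] == 1 | zero] <- NA_character_
  out <- as.data.frame(scores)
  out$label <- label
  out$margin <- top["margin", ]
  out$flagged <- zero | top["tie", ] == 1
  rownames(out) <- rownames(activity)
  attr(out, "set_overlap") <- overlaps
  out
}

#' Differential accessibility between two cell groups
#'
#' CPM-normalizes per cell, applies a two-sided Welch t-test on log1p
#' values per feature (vectorized), adjusts p-values with
#' Benjamini-Hochberg, and reports log2 fold changes of mean normalized
#' counts (pseudocount 1). Features are significant when the adjusted p
#' is at most \code{alpha} and |logFC| at least \code{lfc_min}.
#'
#' @param mat Cell-by-feature count matrix.
#' @param groupA,groupB Barcode vectors (rownames of mat), >= 3 cells each.
#' @param alpha Adjusted-p significance threshold.
#' @param lfc_min Minimum |log2 fold change|.
#' @return data.frame(feature, logFC, p, padj, significant).
#' @export
differential_accessibility <- function(mat, groupA, groupB,
                                       alpha = 0.001, lfc_min = 1.5) {
  if (length(groupA) < 3 || length(groupB) < 3) {
    stop("need at least 3 cells per group")
  }
  sub <- mat[c(groupA, groupB), , drop = FALSE]
  depth <- Matrix::rowSums(sub)
  cpm <- as.matrix(sub) * (1e6 / ifelse(depth == 0, 1, depth))
  lg <- log1p(cpm)
  ia <- seq_along(groupA)
  ib <- length(groupA) + seq_along(groupB)
  na <- length(ia)
  nb <- length(ib)
  ma <- colMeans(lg[ia, , drop = FALSE])
  mb <- colMeans(lg[ib, , drop = FALSE])
  va <- (colSums(lg[ia, , drop = FALSE]^2) - na * ma^2) / (na - 1)
  vb <- (colSums(lg[ib, , drop = FALSE]^2) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0)
  vb <- pmax(vb, 0)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1  # zero variance in both groups, equal means
  padj <- bh_adjust(p)
  lfc <- log2((colMeans(cpm[ia, , drop = FALSE]) + 1) /
                (colMeans(cpm[ib, , drop = FALSE]) + 1))
  feat <- colnames(mat)
  if (is.null(feat)) feat <- as.character(seq_len(ncol(mat)))
  data.frame(feature = feat, logFC = lfc, p = p, padj = padj,
             significant = padj <= alpha & abs(lfc) >= lfc_min,
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement,
#' capped at 1; invariant to input order, identity for a single p-value.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
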