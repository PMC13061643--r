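# Contact-matrix analytics: iterative-correction balancing,
# distance-decay expected and observed/expected transform, compartment
# eigenvector, diamond insulation with boundary calls, virtual 4C and
# aggregate loop pileup. Masked bins are excluded from every statistic.

.cm_mat <- function(cm) if (!is.null(cm$balanced)) cm$balanced else cm$counts

#' Iterative-correction (ICE) balancing
#'
#' Alternately divides the matrix by its row sums until every unmasked row
#' sums to the same value; weights are normalized to mean 1. Rows with
#' fewer than \code{min_nnz_frac} nonzero entries are masked before
#' balancing. On non-convergence the best iterate is returned with a
#' warning reporting the residual.
#'
#' @param cm A \code{contact_matrix}.
#' @param max_iter,tol Iteration cap and relative row-sum tolerance.
#' @param min_nnz_frac Minimum nonzero fraction per row.
#' @return The \code{contact_matrix} with \code{weights},
#'   \code{balanced} (NA on masked rows/cols) and an updated mask.
#' @export
ice_balance <- function(cm, max_iter = 200, tol = 1e-5,
                        min_nnz_frac = 0.02) {
  m <- cm$counts
  n <- nrow(m)
  mask <- cm$mask | rowMeans(m > 0) < min_nnz_frac
  live <- which(!mask)
  if (length(live) < 2) stop("fewer than 2 unmasked bins")
  sub <- m[live, live, drop = FALSE]
  w <- rep(1, length(live))
  best_w <- w
  best_res <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    b <- w * sub %*% diag(w, length(live))
    s <- rowSums(b)
    res <- max(abs(s / mean(s) - 1))
    if (res < best_res) {
      best_res <- res
      best_w <- w
    }
    if (res < tol) {
      converged <- TRUE
      break
    }
    w <- w / (s / mean(s))
  }
  if (!converged) {
    warning(sprintf("ICE did not converge in %d iterations (residual %.3g)",
                    max_iter, best_res))
    w <- best_w
  }
  w <- w / mean(w)
  weights <- rep(NA_real_, n)
  weights[live] <- w
  balanced <- matrix(NA_real_, n, n)
  balanced[live, live] <- outer(w, w) * sub
  cm$weights <- weights
  cm$balanced <- balanced
  cm$mask <- mask
  cm$ice_residual <- best_res
  cm
}

#' Mean contact per diagonal (distance-decay expected profile)
#'
#' @param cm A balanced \code{contact_matrix}.
#' @return Numeric vector: mean over unmasked pixels of each diagonal
#'   (distance 0..n-1 in bins).
#' @export
expected_by_distance <- function(cm) {
  m <- .cm_mat(cm)
  n <- nrow(m)
  live <- !cm$mask
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  ok <- outer(live, live, "&")
  vapply(0:(n - 1), function(k) {
    sel <- d == k & ok
    if (!any(sel)) NA_real_ else mean(m[sel])
  }, 0)
}

#' Observed/expected transform
#'
#' @param cm A balanced \code{contact_matrix}.
#' @return O/E matrix (NA at masked pixels).
#' @export
obs_exp <- function(cm) {
  m <- .cm_mat(cm)
  n <- nrow(m)
  ex <- expected_by_distance(cm)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  oe <- m / matrix(ex[d + 1], n, n)
  oe[cm$mask, ] <- NA
  oe[, cm$mask] <- NA
  oe
}

#' Compartment eigenvector from an O/E matrix
#'
#' Leading eigenvector of the Pearson correlation matrix of log O/E,
#' sign-anchored so that it correlates positively with a supplied
#' reference track (e.g. accessibility). Degenerate (constant) input is
#' reported as undefined.
#'
#' @param oe O/E matrix (NA at masked pixels).
#' @param reference Optional per-bin reference values for the sign
#'   convention.
#' @return List with \code{pc1} (per-bin, NA at masked bins) and
#'   \code{defined}.
#' @export
compartment_eigenvector <- function(oe, reference = NULL) {
  n <- nrow(oe)
  live <- which(colSums(!is.na(oe)) > 0)
  if (length(live) < 10) stop("need at least 10 unmasked bins")
  loe <- log(oe[live, live])
  loe[!is.finite(loe)] <- NA
  sds <- apply(loe, 2, stats::sd, na.rm = TRUE)
  if (all(!is.finite(sds)) || all(sds[is.finite(sds)] < 1e-12)) {
    return(list(pc1 = rep(NA_real_, n), defined = FALSE))
  }
  cc <- suppressWarnings(stats::cor(loe, use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  ev <- eigen(cc, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (!is.null(reference)) {
    r <- stats::cor(v, reference[live])
    if (is.finite(r) && r < 0) v <- -v
  }
  pc1 <- rep(NA_real_, n)
  pc1[live] <- v
  list(pc1 = pc1, defined = TRUE)
}

#' Diamond insulation profile and boundary calls
#'
#' For each bin, sums contacts in the w x w window just off the diagonal
#' (rows b-w..b-1, columns b+1..b+w, w = window/bin), takes log2 of the
#' sum over its chromosome-wide mean, and calls boundaries at local
#' minima with prominence at least \code{prominence}. The score is
#' undefined within w bins of the matrix edges or of masked bins.
#'
#' @param cm A balanced \code{contact_matrix}.
#' @param window Window size in bp (multiple of the bin width).
#' @param prominence Minimum boundary prominence (log2 units).
#' @return List with \code{score}, \code{window}, \code{w_bins} and
#'   \code{boundaries} (data.frame bin, position, score, prominence).
#' @export
insulation <- function(cm, window = 100000, prominence = 0.2) {
  binw <- cm$bins$end[1] - cm$bins$start[1]
  if (window %% binw != 0) stop("window must be a multiple of the bin width")
  m <- .cm_mat(cm)
  n <- nrow(m)
  w <- window %/% binw
  if (w >= n) stop("window larger than the matrix span")
  sums <- rep(NA_real_, n)
  for (b in (w + 1):(n - w)) {
    ri <- (b - w):(b - 1)
    ci <- (b + 1):(b + w)
    if (any(cm$mask[c(ri, b, ci)])) next
    sums[b] <- sum(m[ri, ci])
  }
  mu <- mean(sums, na.rm = TRUE)
  score <- log2(sums / mu)
  bounds <- .local_min_prominence(score, prominence)
  boundaries <- data.frame(bin = bounds$idx,
                           position = cm$bins$start[bounds$idx],
                           score = score[bounds$idx],
                           prominence = bounds$prominence)
  list(score = score, window = window, w_bins = w, boundaries = boundaries)
}

# local minima of a profile (NA tolerated) with topographic prominence
.local_min_prominence <- function(v, threshold) {
  n <- length(v)
  idx <- integer()
  prom <- numeric()
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    lv <- if (i > 1) v[i - 1] else NA
    rv <- if (i < n) v[i + 1] else NA
    if (!is.na(lv) && lv <= v[i]) next
    if (!is.na(rv) && rv < v[i]) next
    if (is.na(lv) || is.na(rv)) next  # edges of the defined range excluded
    # walk outwards until a lower point or the defined edge; track maxima
    maxl <- -Inf
    j <- i - 1
    while (j >= 1 && !is.na(v[j]) && v[j] >= v[i]) {
      maxl <- max(maxl, v[j])
      j <- j - 1
    }
    maxr <- -Inf
    j <- i + 1
    while (j <= n && !is.na(v[j]) && v[j] >= v[i]) {
      maxr <- max(maxr, v[j])
      j <- j + 1
    }
    p <- min(maxl, maxr) - v[i]
    if (is.finite(p) && p >= threshold) {
      idx <- c(idx, i)
      prom <- c(prom, p)
    }
  }
  list(idx = idx, prominence = prom)
}

#' Virtual 4C profile from a viewpoint bin
#'
#' The balanced matrix row of the viewpoint, optionally smoothed with a
#' centered running mean. The viewpoint self-bin is reported but flagged.
#'
#' @param cm A balanced \code{contact_matrix}.
#' @param viewpoint_bin 1-based bin index (must be unmasked).
#' @param smooth_bins Half-width of the running-mean smoother (0 = none).
#' @return data.frame(bin, position, value, is_viewpoint).
#' @export
virtual_4c <- function(cm, viewpoint_bin, smooth_bins = 0) {
  if (cm$mask[viewpoint_bin]) stop("viewpoint bin is masked")
  m <- .cm_mat(cm)
  v <- m[viewpoint_bin, ]
  if (smooth_bins > 0) {
    n <- length(v)
    v <- vapply(seq_len(n), function(i) {
      j <- max(1, i - smooth_bins):min(n, i + smooth_bins)
      mean(v[j], na.rm = TRUE)
    }, 0)
  }
  data.frame(bin = seq_along(v), position = cm$bins$start,
             value = v, is_viewpoint = seq_along(v) == viewpoint_bin)
}

#' Aggregate O/E pileup at loop anchors
#'
#' Averages the (2 flank + 1)^2 O/E windows centered on each anchor pair
#' elementwise (ignoring NAs). Central enrichment is the center pixel
#' divided by the mean of the four corner quadrants.
#'
#' @param oe O/E matrix.
#' @param anchors data.frame(bin_a, bin_b) of 1-based anchor bins; each
#'   pair must be separated by more than \code{flank_bins} and lie at
#'   least \code{flank_bins} from the matrix edge.
#' @param flank_bins Window half-width in bins.
#' @return List with \code{pileup} matrix, \code{enrichment} and
#'   \code{n_anchors}.
#' @export
loop_pileup <- function(oe, anchors, flank_bins = 10) {
  n <- nrow(oe)
  f <- flank_bins
  ok <- anchors$bin_a - f >= 1 & anchors$bin_a + f <= n &
    anchors$bin_b - f >= 1 & anchors$bin_b + f <= n
  if (any(!ok)) stop("anchor window extends outside the matrix")
  if (any(abs(anchors$bin_b - anchors$bin_a) <= f)) {
    stop("anchors must be separated by more than flank_bins")
  }
  k <- 2L * f + 1L
  acc <- matrix(0, k, k)
  cnt <- matrix(0, k, k)
  for (i in seq_len(nrow(anchors))) {
    wnd <- oe[(anchors$bin_a[i] - f):(anchors$bin_a[i] + f),
              (anchors$bin_b[i] - f):(anchors$bin_b[i] + f)]
    fin <- is.finite(wnd)
    acc[fin] <- acc[fin] + wnd[fin]
    cnt <- cnt + fin
  }
  pile <- acc / cnt
  ctr <- pile[f + 1L, f + 1L]
  q <- max(1L, f %/% 2L)
  corners <- c(pile[1:q, 1:q], pile[1:q, (k - q + 1):k],
               pile[(k - q + 1):k, 1:q], pile[(k - q + 1):k, (k - q + 1):k])
  list(pileup = pile, enrichment = ctr / mean(corners, na.rm = TRUE),
       n_anchors = nrow(anchors))
}
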