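#' @importFrom data.table fread fwrite data.table as.data.table setorder :=
#' @importFrom Matrix sparseMatrix rowSums colSums t
NULL

# All coordinates in this package are 0-based half-open (BED dialect).
# A fragment record is one row of a data.frame with columns
# chrom, start, end, barcode, count; its two Tn5 insertion events sit at
# `start` and `end - 1`.

#' Validate a fragment table
#'
#' @param frags data.frame with columns chrom, start, end, barcode, count.
#' @return The validated data.frame (invisibly unchanged).
#' @keywords internal
validate_fragments <- function(frags) {
  need <- c("chrom", "start", "end", "barcode", "count")
  if (!all(need %in% names(frags))) {
    stop("fragment table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(frags)) {
    if (any(frags$start >= frags$end)) {
      bad <- which(frags$start >= frags$end)[1]
      stop("fragment row ", bad, ": start >= end")
    }
    if (any(frags$count < 1)) stop("fragment counts must be >= 1")
  }
  frags
}

#' Read a 10x-style fragments TSV
#'
#' Five tab-separated columns (chrom, start, end, barcode, count), 0-based
#' half-open coordinates. Lines starting with '#' are ignored. Malformed
#' lines raise errors that name the offending line number.
#'
#' @param path Path to a plain-text fragments file.
#' @return data.frame of fragment records.
#' @export
read_fragments <- function(path) {
  lines <- readLines(path)
  ln <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  ln <- ln[keep]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      barcode = character(), count = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 5)) {
    stop("line ", ln[which(nf < 5)[1]], ": expected >= 5 tab-separated fields")
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:5)), ncol = 5, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  count <- suppressWarnings(as.integer(m[, 5]))
  for (col in list(start, end, count)) {
    if (anyNA(col)) stop("line ", ln[which(is.na(col))[1]], ": non-integer field")
  }
  bad <- which(start >= end)
  if (length(bad)) stop("line ", ln[bad[1]], ": start >= end")
  if (any(count < 1)) stop("line ", ln[which(count < 1)[1]], ": count < 1")
  data.frame(chrom = m[, 1], start = start, end = end,
             barcode = m[, 4], count = count)
}

#' Write a fragments TSV
#'
#' Records are sorted by (chrom, start, end, barcode). A header comment
#' declares the coordinate convention.
#'
#' @param frags Fragment table.
#' @param path Output path.
#' @export
write_fragments <- function(frags, path) {
  validate_fragments(frags)
  dt <- as.data.table(frags)
  setorder(dt, chrom, start, end, barcode)
  writeLines("# chrom\tstart\tend\tbarcode\tcount (0-based half-open)", path)
  fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Define a fixed-width binning scheme
#'
#' Position-to-bin mapping is \code{floor(pos / width)}; the last bin of each
#' chromosome may be truncated. Bins are indexed 1..total across chromosomes.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param width Bin width in bp.
#' @return A \code{bin_scheme} object.
#' @export
bin_scheme <- function(chrom_lengths, width) {
  if (width <= 0) stop("bin width must be > 0")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be named")
  }
  n_bins <- as.integer(ceiling(chrom_lengths / width))
  offset <- c(0L, cumsum(n_bins))[seq_along(n_bins)]
  names(n_bins) <- names(offset) <- names(chrom_lengths)
  structure(list(width = as.integer(width), chrom_lengths = chrom_lengths,
                 n_bins = n_bins, offset = offset,
                 total_bins = sum(n_bins)),
            class = "bin_scheme")
}

#' Bin table for a scheme
#' @param scheme A \code{bin_scheme}.
#' @return data.frame(chrom, start, end, bin) with 0-based half-open bins.
#' @export
bins_table <- function(scheme) {
  out <- lapply(names(scheme$n_bins), function(ch) {
    n <- scheme$n_bins[[ch]]
    start <- (seq_len(n) - 1L) * scheme$width
    data.frame(chrom = ch, start = start,
               end = pmin(start + scheme$width, scheme$chrom_lengths[[ch]]),
               bin = scheme$offset[[ch]] + seq_len(n))
  })
  do.call(rbind, out)
}

#' Map genomic positions to global bin indices
#' @param scheme A \code{bin_scheme}.
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return Integer global bin indices (1-based).
#' @export
bin_index <- function(scheme, chrom, pos) {
  if (!all(chrom %in% names(scheme$n_bins))) {
    stop("chromosome not in scheme: ",
         paste(unique(setdiff(chrom, names(scheme$n_bins))), collapse = ", "))
  }
  ok <- pos >= 0 & pos < scheme$chrom_lengths[chrom]
  if (any(!ok)) stop("position outside chromosome bounds")
  as.integer(scheme$offset[chrom] + pos %/% scheme$width + 1L)
}

#' Build a cell-by-bin insertion count matrix
#'
#' Each fragment contributes its count to the bin of each of its two Tn5
#' insertion termini (\code{start} and \code{end - 1}), so total matrix mass
#' is twice the summed counts of retained barcodes. Barcodes absent from
#' \code{cells} are dropped and tallied in \code{attr(., "dropped")}.
#'
#' @param frags Fragment table.
#' @param scheme A \code{bin_scheme} covering all fragment chromosomes.
#' @param cells Character vector of barcodes to retain (matrix row order).
#' @return Sparse dgCMatrix, cells x bins.
#' @export
bin_counts <- function(frags, scheme, cells) {
  validate_fragments(frags)
  keep <- frags$barcode %in% cells
  dropped <- frags$barcode[!keep]
  drop_tab <- if (length(dropped)) table(dropped) else table(character())
  frags <- frags[keep, , drop = FALSE]
  if (!nrow(frags)) {
    m <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                      dims = c(length(cells), scheme$total_bins))
  } else {
    ci <- match(frags$barcode, cells)
    j1 <- bin_index(scheme, frags$chrom, frags$start)
    j2 <- bin_index(scheme, frags$chrom, frags$end - 1L)
    m <- sparseMatrix(i = c(ci, ci), j = c(j1, j2),
                      x = as.numeric(c(frags$count, frags$count)),
                      dims = c(length(cells), scheme$total_bins))
  }
  rownames(m) <- cells
  attr(m, "dropped") <- drop_tab
  m
}

#' Construct a binned signal track
#'
#' A track covers one chromosome (or a contiguous slice of it) in fixed-width
#' bins starting at \code{start} (a multiple of \code{width}).
#'
#' @param chrom Chromosome name.
#' @param width Bin width (bp).
#' @param values Numeric vector, one value per bin.
#' @param start 0-based start of the first bin.
#' @param normalization "raw" or "CPM".
#' @param group Optional group label (cell type / modality).
#' @return A \code{binned_track} object.
#' @export
binned_track <- function(chrom, width, values, start = 0L,
                         normalization = "raw", group = NA_character_) {
  stopifnot(width > 0, start %% width == 0, all(is.finite(values)))
  structure(list(chrom = chrom, width = as.integer(width),
                 start = as.integer(start), values = as.numeric(values),
                 normalization = normalization, group = group),
            class = "binned_track")
}

#' Bin start positions of a track
#' @param track A \code{binned_track}.
#' @return Integer vector of 0-based bin starts.
#' @export
track_positions <- function(track) {
  track$start + (seq_along(track$values) - 1L) * track$width
}

#' Extract the slice of a track overlapping an interval
#' @param track A \code{binned_track}.
#' @param start,end 0-based half-open interval.
#' @return A \code{binned_track} over the bins intersecting [start, end).
#' @export
track_subset <- function(track, start, end) {
  pos <- track_positions(track)
  keep <- pos + track$width > start & pos < end
  if (!any(keep)) stop("interval overlaps no track bins")
  binned_track(track$chrom, track$width, track$values[keep],
               start = pos[which(keep)[1]],
               normalization = track$normalization, group = track$group)
}

#' Write a track as bedGraph
#'
#' Adjacent bins with equal values are merged into one interval.
#'
#' @param track A \code{binned_track}.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$values)
  ends0 <- cumsum(r$lengths)
  starts0 <- c(0L, ends0[-length(ends0)])
  lines <- sprintf("%s\t%d\t%d\t%.10g", track$chrom,
                   track$start + starts0 * track$width,
                   track$start + ends0 * track$width, r$values)
  writeLines(c("# bedGraph, 0-based half-open", lines), path)
  invisible(path)
}

#' Read a bedGraph into a binned track
#'
#' Intervals must be non-overlapping and aligned to \code{width}; runs of
#' merged bins are re-expanded, gaps are filled with 0.
#'
#' @param path bedGraph path.
#' @param width Bin width used to re-expand merged runs.
#' @return A \code{binned_track}.
#' @export
read_bedgraph <- function(path, width) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(chrom = vapply(parts, `[`, "", 1),
                   start = as.integer(vapply(parts, `[`, "", 2)),
                   end = as.integer(vapply(parts, `[`, "", 3)),
                   value = as.numeric(vapply(parts, `[`, "", 4)))
  if (length(unique(df$chrom)) != 1) stop("track must cover one chromosome")
  df <- df[order(df$start), ]
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)])) {
    stop("overlapping intervals in bedGraph")
  }
  if (any(df$start %% width != 0)) stop("intervals not aligned to bin width")
  lo <- df$start[1]
  hi <- max(df$end)
  n <- ceiling((hi - lo) / width)
  values <- numeric(n)
  for (i in seq_len(nrow(df))) {
    b0 <- (df$start[i] - lo) %/% width + 1
    b1 <- ceiling((df$end[i] - lo) / width)
    values[b0:b1] <- df$value[i]
  }
  binned_track(df$chrom[1], width, values, start = lo)
}

#' Construct a contact matrix
#'
#' @param bins data.frame(chrom, start, end) of matrix bins, in order.
#' @param counts Symmetric numeric matrix of contact counts.
#' @param weights Optional per-bin balancing weights.
#' @param mask Optional logical vector of excluded bins; defaults to bins
#'   with zero coverage.
#' @return A \code{contact_matrix} object.
#' @export
contact_matrix <- function(bins, counts, weights = NULL, mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) != nrow(bins)) {
    stop("counts must be square and match the bin table")
  }
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-12))) {
    stop("counts must be symmetric")
  }
  if (is.null(mask)) mask <- rowSums(counts) == 0
  structure(list(bins = bins, counts = counts, weights = weights,
                 mask = as.logical(mask)),
            class = "contact_matrix")
}

#' Read COO contact triplets plus a bin table
#'
#' The bin table is a TSV (chrom, start, end, bin_id); triplets are
#' (bin_i, bin_j, count). Upper-triangle storage is accepted and
#' symmetrized; duplicate symmetric entries with conflicting values raise
#' an error. Zero-coverage bins are masked.
#'
#' @param triplets_path,bins_path Input paths.
#' @return A \code{contact_matrix}.
#' @export
read_contacts <- function(triplets_path, bins_path) {
  bins <- as.data.frame(fread(bins_path, header = TRUE))
  names(bins)[1:4] <- c("chrom", "start", "end", "bin_id")
  n <- nrow(bins)
  idx <- match(seq_len(n) - 1L, bins$bin_id)
  if (anyNA(idx)) stop("bin_id must cover 0..n-1")
  bins <- bins[idx, c("chrom", "start", "end")]
  trip <- as.data.frame(fread(triplets_path, header = TRUE))
  names(trip)[1:3] <- c("bin_i", "bin_j", "count")
  if (any(trip$bin_i < 0 | trip$bin_i >= n | trip$bin_j < 0 | trip$bin_j >= n)) {
    stop("triplet references bin id outside the bin table")
  }
  m <- matrix(NA_real_, n, n)
  for (k in seq_len(nrow(trip))) {
    i <- trip$bin_i[k] + 1L
    j <- trip$bin_j[k] + 1L
    v <- trip$count[k]
    for (pr in list(c(i, j), c(j, i))) {
      old <- m[pr[1], pr[2]]
      if (!is.na(old) && old != v) {
        stop("conflicting duplicate entries for bin pair (",
             trip$bin_i[k], ", ", trip$bin_j[k], ")")
      }
      m[pr[1], pr[2]] <- v
    }
  }
  m[is.na(m)] <- 0
  contact_matrix(bins, m)
}

#' Write a contact matrix as COO triplets plus a bin table
#' @param cm A \code{contact_matrix}.
#' @param triplets_path,bins_path Output paths.
#' @export
write_contacts <- function(cm, triplets_path, bins_path) {
  n <- nrow(cm$counts)
  bins <- data.table(chrom = cm$bins$chrom, start = cm$bins$start,
                     end = cm$bins$end, bin_id = seq_len(n) - 1L)
  fwrite(bins, bins_path, sep = "\t")
  ut <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
              arr.ind = TRUE)
  trip <- data.table(bin_i = ut[, 1] - 1L, bin_j = ut[, 2] - 1L,
                     count = cm$counts[ut])
  setorder(trip, bin_i, bin_j)
  fwrite(trip, triplets_path, sep = "\t")
  invisible(triplets_path)
}

#' Write intervals as BED
#' @param df data.frame with chrom, start, end and optional name, score.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(df))
  writeLines("# BED, 0-based half-open", path)
  fwrite(as.data.table(df)[, cols, with = FALSE], path, sep = "\t",
         col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a BED file
#' @param path BED path.
#' @return data.frame with chrom, start, end (+ name, score when present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    start = as.integer(vapply(parts, `[`, "", 2)),
                    end = as.integer(vapply(parts, `[`, "", 3)))
  nf <- min(lengths(parts))
  if (nf >= 4) out$name <- vapply(parts, `[`, "", 4)
  if (nf >= 5) out$score <- as.numeric(vapply(parts, `[`, "", 5))
  out
}
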