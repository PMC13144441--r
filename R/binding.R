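#' Read a bedGraph signal track
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @return A `signal_track`: list of per-chromosome sorted interval tables.
#' @export
read_bedgraph <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  signal_track(data.frame(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
                          value = tab[[4]], stringsAsFactors = FALSE))
}

#' Construct a signal track from an interval table
#'
#' @param df Data frame with chrom, start, end, value; intervals on a
#'   chromosome must not overlap. Uncovered positions have value 0.
#' @return A `signal_track` object.
#' @export
signal_track <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  if (any(df$end <= df$start)) stop("intervals must have end > start")
  if (any(df$value < 0)) stop("signal values must be >= 0")
  per_chrom <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1] < d$end[-nrow(d)])) {
      stop(sprintf("overlapping intervals on %s", d$chrom[1]))
    }
    rownames(d) <- NULL
    d
  })
  structure(list(per_chrom = per_chrom), class = "signal_track")
}

## Per-base signal values over [start, end) (0-based); positions outside the
## track (including negative coordinates) are 0.
track_values <- function(track, chrom, start, end) {
  out <- numeric(end - start)
  d <- track$per_chrom[[chrom]]
  if (is.null(d)) return(out)
  for (i in seq_len(nrow(d))) {
    lo <- max(d$start[i], start)
    hi <- min(d$end[i], end)
    if (hi > lo) out[(lo - start + 1L):(hi - start)] <- d$value[i]
  }
  out
}

#' Scale-regions signal matrix
#'
#' deeptools-style geometry: each interval body is resampled to `body_bins`
#' equal sub-intervals (length-weighted per-base means, fractional overlap
#' at bin edges), with fixed-width flank bins of `flank_bp / flank_bins` bp
#' on each side. Minus-strand rows are reversed so bins read 5' to 3'. Rows
#' are ordered by descending row sum (stable in input order for ties).
#'
#' @param track A [signal_track()].
#' @param intervals Data frame with chrom, start, end, strand (and
#'   optionally a `name` used as row label).
#' @param body_bins Number of body bins.
#' @param flank_bp Flank width in bp each side.
#' @param flank_bins Number of bins per flank.
#' @return A `binding_matrix`: list with `matrix` (rows sorted by descending
#'   sum), `intervals` (reordered to match), `body_bins`, `flank_bins`.
#' @export
matrix_scale_regions <- function(track, intervals, body_bins = 10L,
                                 flank_bp = 1000L, flank_bins = 10L) {
  if (body_bins < 1L || flank_bins < 1L) stop("bins must be >= 1")
  n <- nrow(intervals)
  if (n == 0L) stop("no intervals")
  rows <- matrix(0, nrow = n, ncol = flank_bins + body_bins + flank_bins)
  for (i in seq_len(n)) {
    s <- intervals$start[i]
    e <- intervals$end[i]
    ch <- intervals$chrom[i]
    up <- bin_mean(track_values(track, ch, s - flank_bp, s), flank_bins)
    body <- bin_mean(track_values(track, ch, s, e), body_bins)
    down <- bin_mean(track_values(track, ch, e, e + flank_bp), flank_bins)
    row <- c(up, body, down)
    if (!is.null(intervals$strand) && intervals$strand[i] == "-") {
      row <- rev(row)
    }
    rows[i, ] <- row
  }
  labels <- if ("name" %in% names(intervals)) intervals$name else
    sprintf("%s:%d-%d", intervals$chrom, intervals$start, intervals$end)
  ord <- order(-rowSums(rows))   # stable: ties keep input order
  structure(list(matrix = rows[ord, , drop = FALSE],
                 intervals = intervals[ord, , drop = FALSE],
                 labels = labels[ord],
                 body_bins = body_bins, flank_bins = flank_bins),
            class = "binding_matrix")
}

#' Reference-point signal matrix
#'
#' Fixed window around each reference point (e.g. a TSS), `upstream_bp`
#' before to `downstream_bp` after, in `bin_bp` bins, strand-aware (minus
#' strand rows reversed). Bins extending past the chromosome start are
#' filled with 0 and the row flagged. Rows are ordered by descending sum.
#'
#' @param track A [signal_track()].
#' @param points Data frame with chrom, pos (0-based), strand (and
#'   optionally `name`).
#' @param upstream_bp,downstream_bp Window extents; `bin_bp` must divide
#'   both.
#' @param bin_bp Bin width in bp.
#' @return A `binding_matrix` with an additional `edge_flag` logical vector.
#' @export
matrix_reference_point <- function(track, points, upstream_bp = 1000L,
                                   downstream_bp = 1000L, bin_bp = 10L) {
  if (upstream_bp %% bin_bp != 0L || downstream_bp %% bin_bp != 0L) {
    stop("bin_bp must divide upstream_bp and downstream_bp")
  }
  n <- nrow(points)
  if (n == 0L) stop("no points")
  nbins <- (upstream_bp + downstream_bp) %/% bin_bp
  rows <- matrix(0, nrow = n, ncol = nbins)
  edge <- logical(n)
  for (i in seq_len(n)) {
    s <- points$pos[i] - upstream_bp
    e <- points$pos[i] + downstream_bp
    edge[i] <- s < 0L
    vals <- numeric(e - s)
    lo <- max(s, 0L)
    if (e > lo) {
      vals[(lo - s + 1L):(e - s)] <- track_values(track, points$chrom[i], lo, e)
    }
    row <- bin_mean(vals, nbins)
    if (!is.null(points$strand) && points$strand[i] == "-") row <- rev(row)
    rows[i, ] <- row
  }
  labels <- if ("name" %in% names(points)) points$name else
    sprintf("%s:%d", points$chrom, points$pos)
  ord <- order(-rowSums(rows))
  structure(list(matrix = rows[ord, , drop = FALSE],
                 intervals = points[ord, , drop = FALSE],
                 labels = labels[ord], edge_flag = edge[ord],
                 bin_bp = bin_bp),
            class = "binding_matrix")
}

#' Top-fraction bound intervals
#'
#' Ranks rows by row sum (ties keep original order) and returns the top
#' `ceiling(fraction * n)` rows' source intervals as the "bound" set.
#'
#' @param bm A `binding_matrix`.
#' @param fraction Fraction in (0, 1]; default 0.25 (top quartile).
#' @return The bound subset of the matrix's interval table, with a
#'   `row_sum` column.
#' @export
top_quartile_bound <- function(bm, fraction = 0.25) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  n <- nrow(bm$matrix)
  if (n == 0L) stop("empty matrix")
  sums <- rowSums(bm$matrix)
  ord <- order(-sums)             # stable for ties
  k <- ceiling(fraction * n)
  sel <- ord[seq_len(k)]
  out <- bm$intervals[sel, , drop = FALSE]
  out$row_sum <- sums[sel]
  rownames(out) <- NULL
  out
}

#' Genes whose TSS lies near an insertion
#'
#' A gene is included when the minimum distance from its TSS to any
#' insertion interval is at most `window_bp` (0 when the TSS falls inside an
#' insertion); the boundary is inclusive. Each gene is counted once.
#'
#' @param genes Data frame with gene, chrom, tss (0-based position) and any
#'   further columns (e.g. lfc, padj).
#' @param insertions Data frame with chrom, start, end (0-based half-open).
#' @param window_bp Maximum TSS-to-insertion distance (default 10 kb).
#' @return The subset of `genes` within the window, with a `distance`
#'   column.
#' @export
genes_near_insertions <- function(genes, insertions, window_bp = 10000L) {
  dist <- rep(Inf, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ins <- insertions[insertions$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(ins) == 0L) next
    p <- genes$tss[i]
    d <- ifelse(p < ins$start, ins$start - p,
                ifelse(p >= ins$end, p - (ins$end - 1L), 0L))
    dist[i] <- min(d)
  }
  out <- genes[dist <= window_bp, , drop = FALSE]
  out$distance <- dist[dist <= window_bp]
  rownames(out) <- NULL
  out
}

#' Compare log fold changes of two gene groups
#'
#' Two-sample, two-sided unpaired t-test of the log2 fold changes of genes
#' near bound insertions versus genes near any insertion. Welch
#' (unequal-variance) by default; `var_equal = TRUE` gives pooled-variance
#' Student's t.
#'
#' @param lfc_bound,lfc_all Numeric vectors (each >= 2 values with positive
#'   variance).
#' @param var_equal Use the pooled-variance test.
#' @return List with `t`, `df`, `p`.
#' @export
compare_lfc_groups <- function(lfc_bound, lfc_all, var_equal = FALSE) {
  for (g in list(lfc_bound, lfc_all)) {
    if (length(g) < 2L || stats::var(g) <= 0) {
      stop("each group needs >= 2 values with positive variance")
    }
  }
  tt <- t.test(lfc_bound, lfc_all, var.equal = var_equal,
               alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
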