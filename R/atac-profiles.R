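#' Construct an insertion track
#'
#' A per-stage table of single-base Tn5 cut sites plus the genome-wide
#' library size used for per-million normalisation.
#'
#' @param stage Stage label.
#' @param events Data frame with columns chrom, pos (0-based cut position)
#'   and optionally strand.
#' @param library_size Total genome-wide insertions; defaults to the number
#'   of stored events and must be at least that.
#' @return An `insertion_track` object.
#' @export
insertion_track <- function(stage, events, library_size = nrow(events)) {
  if (!all(c("chrom", "pos") %in% names(events))) {
    stop("events must have chrom and pos columns")
  }
  if (nrow(events) > 0L && any(events$pos < 0)) stop("positions must be >= 0")
  if (library_size < nrow(events)) {
    stop("library_size must be >= number of stored events")
  }
  structure(list(stage = stage, events = events,
                 library_size = as.numeric(library_size)),
            class = "insertion_track")
}

#' Convert fragments to Tn5 insertion sites
#'
#' Each fragment yields two cut events, `start + shift_plus` and
#' `end - 1 - shift_minus`. The default (+4, -5) shift is the standard ATAC
#' correction for the 9-bp Tn5 duplication. Library size is twice the
#' number of valid fragments.
#'
#' @param fragments Data frame with chrom, start, end (0-based half-open).
#' @param shift_plus Shift applied to the fragment start cut.
#' @param shift_minus Shift applied to the fragment end cut.
#' @param stage Stage label for the resulting track.
#' @return An [insertion_track()]. Fragments with `end <= start` are skipped
#'   with a warning reporting the count.
#' @export
fragments_to_insertions <- function(fragments, shift_plus = 4L,
                                    shift_minus = 5L, stage = "unknown") {
  bad <- fragments$end <= fragments$start
  if (any(bad)) {
    warning(sprintf("%d fragment(s) with end <= start skipped", sum(bad)))
    fragments <- fragments[!bad, , drop = FALSE]
  }
  n <- nrow(fragments)
  events <- data.frame(
    chrom = rep(fragments$chrom, 2L),
    pos = c(fragments$start + shift_plus,
            fragments$end - 1L - shift_minus),
    strand = rep(c("+", "-"), each = n),
    stringsAsFactors = FALSE)
  insertion_track(stage, events, library_size = 2L * n)
}

#' Read a fragment table
#'
#' @param path BED3 (`chrom start end`) or BEDPE
#'   (`chrom1 start1 end1 chrom2 start2 end2 ...`) file. For BEDPE the
#'   fragment spans from the leftmost start to the rightmost end of the two
#'   read blocks.
#' @param format `"bed3"` or `"bedpe"`.
#' @return Data frame with chrom, start, end.
#' @export
read_fragments <- function(path, format = c("bed3", "bedpe")) {
  format <- match.arg(format)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (format == "bed3") {
    data.frame(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
               stringsAsFactors = FALSE)
  } else {
    if (any(tab[[1]] != tab[[4]])) stop("interchromosomal BEDPE unsupported")
    data.frame(chrom = tab[[1]], start = pmin(tab[[2]], tab[[5]]),
               end = pmax(tab[[3]], tab[[6]]), stringsAsFactors = FALSE)
  }
}

#' Build a per-family insertion meta-profile in consensus coordinates
#'
#' Every cut falling within a length-intact copy of the family (half-open
#' containment) increments its projected consensus position; plus- and
#' minus-strand copies contribute through the strand-aware projection. The
#' raw count vector is normalised to insertions per million genome-wide
#' library insertions.
#'
#' @param track An [insertion_track()].
#' @param intact An `intact_set` from [select_intact()].
#' @param family Family name.
#' @param library A [consensus_library()] providing the consensus length.
#' @return A `meta_profile`: list with family, stage, `raw` (counts),
#'   `normalized` (per million), `n_copies`, `library_size`.
#' @export
build_meta_profile <- function(track, intact, family, library) {
  stopifnot(inherits(track, "insertion_track"), inherits(intact, "intact_set"))
  copies <- intact$copies[intact$copies$family == family, , drop = FALSE]
  if (nrow(copies) == 0L) {
    stop(sprintf("no intact copies of family '%s'", family))
  }
  clen <- consensus_length(library, family)
  raw <- numeric(clen)
  ev <- track$events
  for (chrom in unique(copies$chrom)) {
    cc <- copies[copies$chrom == chrom, , drop = FALSE]
    pos <- ev$pos[ev$chrom == chrom]
    if (length(pos) == 0L) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(pos + 1L, width = 1L),
      IRanges::IRanges(cc$start + 1L, cc$end))
    if (length(hit) == 0L) next
    qp <- pos[S4Vectors::queryHits(hit)]
    ci <- S4Vectors::subjectHits(hit)
    cpos <- ifelse(cc$strand[ci] == "+",
                   qp - cc$start[ci],
                   (cc$end[ci] - 1L) - qp)
    cpos <- cpos[cpos >= 0L & cpos < clen]  # copies within tolerance > 0
    tab <- tabulate(cpos + 1L, nbins = clen)
    raw <- raw + tab
  }
  structure(list(family = family, stage = track$stage, raw = raw,
                 normalized = raw * 1e6 / track$library_size,
                 n_copies = nrow(copies),
                 library_size = track$library_size),
            class = "meta_profile")
}

#' Centred moving-average smoothing with edge truncation
#'
#' Windows are truncated at the profile boundaries (shorter means at the
#' edges); `window = 1` is the identity.
#'
#' @param x Numeric vector, or a `meta_profile` (its normalised vector is
#'   smoothed).
#' @param window Odd window width, >= 1, <= length of the vector.
#' @return Smoothed numeric vector.
#' @export
smooth_profile <- function(x, window) {
  if (inherits(x, "meta_profile")) x <- x$normalized
  stopifnot_scalar_int(window, "window", min = 1)
  if (window %% 2L == 0L) stop("window must be odd")
  n <- length(x)
  if (window > n) stop("window exceeds profile length")
  h <- (window - 1L) %/% 2L
  if (h == 0L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Write a meta-profile as TSV
#'
#' Columns: position (0-based consensus coordinate), raw count, insertions
#' per million.
#'
#' @param profile A `meta_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(position = seq_along(profile$raw) - 1L,
                   raw = profile$raw, per_million = profile$normalized)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
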