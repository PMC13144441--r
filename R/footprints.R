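#' Footprint-calling parameters
#'
#' Formalises the visual footprint rule (a local depletion of Tn5 insertion
#' signal relative to higher flanking signal) as an explicit statistic.
#' Defaults: smoothing window 3 bp, flank width 25 bp, width range 6-30 bp
#' (the span of typical TF binding sites), depletion threshold 0.3, minimum
#' flank signal 0.5 insertions per million.
#'
#' @param window Odd smoothing window (bp) applied before calling.
#' @param flank_bp Flank width F over which local background is averaged.
#' @param w_min,w_max Minimum/maximum footprint width (bp).
#' @param d_min Minimum depletion score for a call (and for a stage to be
#'   scored as "present").
#' @param c_min Minimum flank signal (per million) for a call.
#' @param pad Padding (bp) added to each side when extracting footprint
#'   sequences.
#' @return A `footprint_params` object.
#' @export
footprint_params <- function(window = 3L, flank_bp = 25L, w_min = 6L,
                             w_max = 30L, d_min = 0.3, c_min = 0.5,
                             pad = 3L) {
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (flank_bp < 1L || w_min < 1L || w_max < w_min) {
    stop("flank_bp/w_min/w_max must be positive with w_min <= w_max")
  }
  if (d_min <= 0 || c_min < 0) stop("d_min must be > 0 and c_min >= 0")
  structure(list(window = as.integer(window), flank_bp = as.integer(flank_bp),
                 w_min = as.integer(w_min), w_max = as.integer(w_max),
                 d_min = d_min, c_min = c_min, pad = as.integer(pad)),
            class = "footprint_params")
}

#' Depletion score of an interval
#'
#' `D = (m_flank - m_center) / m_flank`, where `m_center` is the mean
#' profile value over the interval and `m_flank` the mean over up to
#' `flank_bp` positions on each side (truncated at the profile edges). By
#' convention `D = 0` when `m_flank = 0`. D is 1 for complete depletion,
#' 0 for no depletion, negative for enrichment.
#'
#' @param x Numeric profile vector.
#' @param start,end 0-based half-open interval within the profile.
#' @param flank_bp Flank width F.
#' @return List with `D`, `m_center`, `m_flank`.
#' @export
depletion_score <- function(x, start, end, flank_bp = 25L) {
  n <- length(x)
  if (end <= start || start < 0 || end > n) stop("empty or out-of-range interval")
  center <- x[(start + 1L):end]
  left <- if (start == 0L) numeric(0) else
    x[seq.int(max(1L, start - flank_bp + 1L), start)]
  right <- if (end >= n) numeric(0) else
    x[seq.int(end + 1L, min(n, end + flank_bp))]
  fl <- c(left, right)
  if (length(fl) == 0L) stop("flanks are empty")
  m_center <- mean(center)
  m_flank <- mean(fl)
  D <- if (m_flank == 0) 0 else (m_flank - m_center) / m_flank
  list(D = D, m_center = m_center, m_flank = m_flank)
}

## Position-wise local background: mean of the profile over the two windows
## of width `flank_bp` starting just outside an exclusion zone of
## floor(w_min/2) on each side of the position, truncated at the edges.
local_background <- function(x, flank_bp, w_min) {
  n <- length(x)
  excl <- w_min %/% 2L
  vapply(seq_len(n), function(i) {
    li <- seq.int(i - excl - flank_bp, i - excl - 1L)
    ri <- seq.int(i + excl + 1L, i + excl + flank_bp)
    idx <- c(li[li >= 1L], ri[ri <= n])
    if (length(idx) == 0L) NA_real_ else mean(x[idx])
  }, numeric(1))
}

#' Call footprints on a meta-profile
#'
#' On the smoothed profile, positions whose value falls below
#' `(1 - d_min)` times the local flanking background are marked depleted;
#' maximal runs of depleted positions are found, runs separated by less than
#' `w_min / 2` positions are merged, and runs are retained when their width
#' lies in `[w_min, w_max]` and the flank mean of the interval is at least
#' `c_min`. Retained intervals are scored with [depletion_score()] on the
#' smoothed profile and numbered left to right from 1.
#'
#' @param profile A `meta_profile` or a plain numeric vector (already in
#'   per-million units).
#' @param params A [footprint_params()].
#' @return Data frame with columns index, start, end (0-based half-open
#'   consensus interval), D, m_center, m_flank; zero rows when nothing is
#'   called.
#' @export
call_footprints <- function(profile, params = footprint_params()) {
  v <- if (inherits(profile, "meta_profile")) profile$normalized else profile
  if (length(v) == 0L) stop("empty profile")
  sm <- smooth_profile(v, min(params$window,
                              if (length(v) %% 2L == 0L) length(v) - 1L
                              else length(v)))
  bg <- local_background(sm, params$flank_bp, params$w_min)
  depleted <- !is.na(bg) & bg > 0 & sm < (1 - params$d_min) * bg
  empty <- data.frame(index = integer(0), start = integer(0),
                      end = integer(0), D = numeric(0),
                      m_center = numeric(0), m_flank = numeric(0))
  if (!any(depleted)) return(empty)
  r <- rle(depleted)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  ## merge runs separated by a gap < w_min / 2
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap < params$w_min / 2) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  out <- list()
  for (i in seq_len(nrow(merged))) {
    s0 <- merged$start[i] - 1L              # to 0-based
    e0 <- merged$end[i]
    w <- e0 - s0
    if (w < params$w_min || w > params$w_max) next
    ds <- depletion_score(sm, s0, e0, params$flank_bp)
    if (ds$m_flank < params$c_min) next
    out[[length(out) + 1L]] <- data.frame(start = s0, end = e0, D = ds$D,
                                          m_center = ds$m_center,
                                          m_flank = ds$m_flank)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  res$index <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("index", "start", "end", "D", "m_center", "m_flank")]
}

#' Classify the stage specificity of a footprint interval
#'
#' Computes the depletion score of one consensus interval on each stage's
#' profile and labels the footprint with the set of stages where
#' `D >= d_min`.
#'
#' @param profiles Named list of per-stage profiles (vectors or
#'   `meta_profile`s) for one family; all stages must be present.
#' @param start,end Footprint interval (0-based half-open).
#' @param params A [footprint_params()] (uses `d_min`, `flank_bp`,
#'   `window`).
#' @return List with `D` (named per-stage scores), `present` (named
#'   logicals) and `label` (stage names joined with "+"; "none" if absent
#'   everywhere).
#' @export
classify_stages <- function(profiles, start, end,
                            params = footprint_params()) {
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    stop("profiles must be a named per-stage list")
  }
  D <- vapply(profiles, function(p) {
    v <- if (inherits(p, "meta_profile")) p$normalized else p
    if (is.null(v)) stop("stage missing a profile")
    sm <- smooth_profile(v, params$window)
    depletion_score(sm, start, end, params$flank_bp)$D
  }, numeric(1))
  present <- D >= params$d_min
  label <- if (any(present)) paste(names(D)[present], collapse = "+") else
    "none"
  list(D = D, present = present, label = label)
}

## Merge intervals across stages: any pair with >= 50% reciprocal overlap is
## replaced by its union, iterated to a fixed point.
merge_stage_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- unique(iv[, c("start", "end")])
  repeat {
    n <- nrow(iv)
    merged <- FALSE
    for (i in seq_len(n - 1L)) {
      if (merged) break
      for (j in seq.int(i + 1L, n)) {
        ov <- min(iv$end[i], iv$end[j]) - max(iv$start[i], iv$start[j])
        if (ov > 0 &&
            ov >= 0.5 * (iv$end[i] - iv$start[i]) &&
            ov >= 0.5 * (iv$end[j] - iv$start[j])) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  iv <- iv[order(iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

#' Call and stage-classify footprints for one family across stages
#'
#' Footprints are called per stage, unified across stages by interval union
#' (pairs with at least 50% reciprocal overlap merge), then each unified
#' interval is scored on every stage and classified with
#' [classify_stages()]. Intervals absent at every stage after unification
#' are dropped.
#'
#' @param profiles Named list of per-stage `meta_profile`s for one family.
#' @param params A [footprint_params()].
#' @return Data frame with family, index, start, end, one `D_<stage>`
#'   column per stage, and label.
#' @export
call_family_footprints <- function(profiles, params = footprint_params()) {
  fam <- if (inherits(profiles[[1]], "meta_profile")) profiles[[1]]$family else
    NA_character_
  per_stage <- lapply(profiles, call_footprints, params = params)
  iv <- do.call(rbind, lapply(per_stage, function(d) d[, c("start", "end")]))
  if (is.null(iv) || nrow(iv) == 0L) {
    out <- data.frame(family = character(0), index = integer(0),
                      start = integer(0), end = integer(0),
                      label = character(0))
    for (s in names(profiles)) out[[paste0("D_", s)]] <- numeric(0)
    return(out)
  }
  iv <- merge_stage_intervals(iv)
  rows <- list()
  for (i in seq_len(nrow(iv))) {
    cl <- classify_stages(profiles, iv$start[i], iv$end[i], params)
    if (cl$label == "none") next
    row <- data.frame(family = fam, start = iv$start[i], end = iv$end[i],
                      label = cl$label, stringsAsFactors = FALSE)
    for (s in names(cl$D)) row[[paste0("D_", s)]] <- cl$D[[s]]
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) {
    out <- data.frame(family = character(0), index = integer(0),
                      start = integer(0), end = integer(0),
                      label = character(0))
    for (s in names(profiles)) out[[paste0("D_", s)]] <- numeric(0)
    return(out)
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$start), , drop = FALSE]
  res$index <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("family", "index", "start", "end",
          paste0("D_", names(profiles)), "label")]
}

#' Extract the consensus sequence under a footprint
#'
#' Returns the consensus substring over the padded interval together with
#' its reverse complement; motif matching searches both strands. Padding is
#' clipped at the consensus boundaries.
#'
#' @param library A [consensus_library()].
#' @param family Family name.
#' @param start,end Footprint interval (0-based half-open).
#' @param pad Padding in bp added to each side.
#' @return Named character vector `c(forward = , reverse = )`.
#' @export
extract_footprint_sequence <- function(library, family, start, end,
                                       pad = 0L) {
  clen <- consensus_length(library, family)
  s <- max(0L, start - pad)
  e <- min(clen, end + pad)
  fwd <- substr(library$sequences[[family]], s + 1L, e)
  c(forward = fwd, reverse = reverse_complement(fwd))
}
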