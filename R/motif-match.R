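#' Convert a DNA sequence to a PWM-shaped query
#'
#' Each position becomes a smoothed one-hot probability column:
#' `(one_hot + pseudocount) / (1 + 4 * pseudocount)`. Ambiguity codes (N and
#' friends) become the uniform column (0.25 each) with a warning.
#'
#' @param sequence DNA string (length >= 4).
#' @param pseudocount Non-negative smoothing constant.
#' @return 4 x width probability matrix (rows A,C,G,T).
#' @export
sequence_to_pfm <- function(sequence, pseudocount = 0.1) {
  if (!is_string(sequence) || nchar(sequence) < 4L) {
    stop("sequence must be a single string of length >= 4")
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  bases <- strsplit(toupper(sequence), "")[[1]]
  W <- length(bases)
  m <- matrix(pseudocount / (1 + 4 * pseudocount), nrow = 4, ncol = W,
              dimnames = list(DNA_BASES, NULL))
  amb <- !(bases %in% DNA_BASES)
  if (any(amb)) {
    warning(sprintf("%d ambiguous base(s) set to uniform columns", sum(amb)))
    m[, amb] <- 0.25
  }
  for (j in which(!amb)) {
    m[bases[j], j] <- (1 + pseudocount) / (1 + 4 * pseudocount)
  }
  m
}

UNIFORM_COL <- rep(0.25, 4)

## Distance of each query column to the uniform background column.
dist_to_uniform <- function(q) {
  sqrt(colSums((q - UNIFORM_COL)^2))
}

## Alignment score of query vs target at a single offset: mean over ALL
## query columns of the Euclidean distance to the aligned target column,
## with unaligned (overhanging) query columns scored against the uniform
## column. Returns NA when fewer than min_overlap columns align.
offset_score <- function(q, t, offset, min_overlap, u = dist_to_uniform(q)) {
  Wq <- ncol(q)
  Wt <- ncol(t)
  j <- seq_len(Wq)
  tj <- offset + j
  al <- tj >= 1L & tj <= Wt
  if (sum(al) < min_overlap) return(NA_real_)
  d_al <- sqrt(colSums((q[, al, drop = FALSE] - t[, tj[al], drop = FALSE])^2))
  (sum(d_al) + sum(u[!al])) / Wq
}

#' Ungapped Euclidean alignment of two motifs
#'
#' Slides the query over the target at every integer offset with at least
#' `min_overlap` aligned columns and, optionally, over the target's reverse
#' complement. The score at an offset is the mean over all query columns of
#' the Euclidean distance between probability columns; query columns hanging
#' over the target edge are scored against the uniform column (0.25 each),
#' penalising spurious partial overlaps. Ties are broken by forward
#' orientation first, then smaller absolute offset, then the negative
#' offset.
#'
#' @param query,target 4 x width probability matrices (or [pwm()] objects).
#' @param min_overlap Minimum aligned columns (>= 1, <= both widths).
#' @param orientations `"both"` (default) also scans the target's reverse
#'   complement; `"forward"` scans the given orientation only (used when the
#'   caller already enumerates strands).
#' @return List with `distance`, `offset` (query position relative to the
#'   target: query column j aligns target column offset + j), and
#'   `orientation` (`"+"` or `"-"`).
#' @export
align_motifs <- function(query, target, min_overlap = 4L,
                         orientations = c("both", "forward")) {
  orientations <- match.arg(orientations)
  if (inherits(query, "pwm")) query <- query$matrix
  if (inherits(target, "pwm")) target <- target$matrix
  Wq <- ncol(query)
  Wt <- ncol(target)
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (Wq < min_overlap || Wt < min_overlap) {
    stop("motif widths must be >= min_overlap")
  }
  u <- dist_to_uniform(query)
  targets <- list(`+` = target)
  if (orientations == "both") targets$`-` <- revcomp_pwm(target)
  best <- list(distance = Inf, offset = NA_integer_, orientation = NA_character_)
  offsets <- seq.int(-(Wq - min_overlap), Wt - min_overlap)
  for (ori in names(targets)) {
    tt <- targets[[ori]]
    for (o in offsets) {
      d <- offset_score(query, tt, o, min_overlap, u)
      if (is.na(d)) next
      better <- d < best$distance - 1e-12
      tie <- abs(d - best$distance) <= 1e-12
      if (tie) {
        ## forward before reverse; then smaller |offset|; then negative first
        if (ori == best$orientation) {
          better <- abs(o) < abs(best$offset) ||
            (abs(o) == abs(best$offset) && o < best$offset)
        }
      }
      if (better) best <- list(distance = d, offset = o, orientation = ori)
    }
  }
  best
}

## Null alignment distances for a query against n_perm pseudo-targets of a
## given width whose columns are drawn with replacement from the pooled
## library columns. Vectorised over permutations.
null_distances <- function(query, width, pool, n_perm, seed,
                           min_overlap = 4L,
                           orientations = c("both", "forward")) {
  orientations <- match.arg(orientations)
  if (ncol(pool) == 0L) stop("empty library column pool")
  Wq <- ncol(query)
  u <- dist_to_uniform(query)
  idx <- with_seed(seed, sample.int(ncol(pool), width * n_perm,
                                    replace = TRUE))
  targ <- array(pool[, idx], dim = c(4L, width, n_perm))
  queries <- list(query)
  if (orientations == "both") queries[[2]] <- revcomp_pwm(query)
  best <- rep(Inf, n_perm)
  offsets <- seq.int(-(Wq - min_overlap), width - min_overlap)
  for (q in queries) {
    uq <- dist_to_uniform(q)
    for (o in offsets) {
      j <- seq_len(Wq)
      tj <- o + j
      al <- tj >= 1L & tj <= width
      if (sum(al) < min_overlap) next
      qa <- q[, al, drop = FALSE]
      ta <- targ[, tj[al], , drop = FALSE]
      diff2 <- (as.vector(qa) - matrix(ta, nrow = 4L * sum(al)))^2
      dim(diff2) <- c(4L, sum(al), n_perm)
      dsum <- colSums(sqrt(colSums(diff2)))   # per permutation
      sc <- (dsum + sum(uq[!al])) / Wq
      best <- pmin(best, sc)
    }
  }
  best
}

#' Permutation p-value of a motif match
#'
#' The null distribution re-draws, for each permutation, a pseudo-target of
#' the target's width with columns sampled with replacement from the pooled
#' columns of the whole library, aligns the query against it with
#' [align_motifs()]'s scoring, and estimates
#' `p = (1 + #\{null <= d\}) / (n_perm + 1)`.
#'
#' @param query 4 x W query matrix.
#' @param target 4 x W target matrix (only its width is used for the null).
#' @param d_star Observed best alignment distance.
#' @param pool 4 x N matrix of pooled library columns.
#' @param n_perm Number of permutations (>= 99).
#' @param seed RNG seed (deterministic given seed).
#' @param min_overlap,orientations Passed through to the alignment rule;
#'   must match how `d_star` was computed.
#' @return p-value in (0, 1].
#' @export
match_pvalue <- function(query, target, d_star, pool, n_perm = 999L,
                         seed = 1L, min_overlap = 4L,
                         orientations = c("both", "forward")) {
  orientations <- match.arg(orientations)
  if (n_perm < 99L) stop("n_perm must be >= 99")
  if (inherits(query, "pwm")) query <- query$matrix
  if (inherits(target, "pwm")) target <- target$matrix
  nulls <- null_distances(query, ncol(target), pool, n_perm, seed,
                          min_overlap, orientations)
  (1 + sum(nulls <= d_star + 1e-12)) / (n_perm + 1)
}

## Pooled columns of a motif library.
library_column_pool <- function(motifs) {
  do.call(cbind, lapply(motifs, function(m) {
    if (inherits(m, "pwm")) m$matrix else m
  }))
}

#' Scan footprint sequences against a motif library
#'
#' Every (footprint strand, motif) pair is aligned with [align_motifs()]
#' (forward orientation only: the two footprint strands already cover both
#' orientations), given a permutation p-value against the pooled library
#' null, and an E-value `p * library size`. Matches with `E < e_threshold`
#' are retained. Null distributions are cached per (query content, target
#' width), with sub-seeds derived from the query sequence so results do not
#' depend on scan order.
#'
#' @param footprints Data frame with columns family, index, strand
#'   (`"+"`/`"-"`) and seq (one row per footprint strand), e.g. from
#'   [footprint_sequence_table()].
#' @param library A `motif_library` (or named list of [pwm()]).
#' @param tf_map Named character vector motif id -> TF name; motifs missing
#'   from the map keep their library name.
#' @param e_threshold E-value retention threshold (default 30).
#' @param n_perm Permutations for the p-value null.
#' @param seed Master seed.
#' @param pseudocount Passed to [sequence_to_pfm()].
#' @param min_overlap Minimum aligned columns.
#' @return Data frame of matches: family, footprint_index, strand, motif_id,
#'   tf, offset, distance, p, evalue.
#' @export
scan_footprints <- function(footprints, library, tf_map = character(0),
                            e_threshold = 30, n_perm = 999L, seed = 1L,
                            pseudocount = 0.1, min_overlap = 4L) {
  motifs <- if (inherits(library, "motif_library")) library$motifs else library
  if (length(motifs) == 0L) stop("empty motif library")
  pool <- library_column_pool(motifs)
  nlib <- length(motifs)
  widths <- sort(unique(vapply(motifs, function(m) m$width, integer(1))))
  rows <- list()
  for (i in seq_len(nrow(footprints))) {
    fpseq <- footprints$seq[i]
    query <- suppressWarnings(sequence_to_pfm(fpseq, pseudocount))
    ## cache null distributions per target width for this query
    nulls <- lapply(widths, function(w) {
      null_distances(query, w, pool, n_perm,
                     seed = derive_seed(seed, seq_hash(fpseq) * 7L + w * 131L),
                     min_overlap = min_overlap, orientations = "forward")
    })
    names(nulls) <- as.character(widths)
    for (mid in names(motifs)) {
      mot <- motifs[[mid]]
      al <- align_motifs(query, mot$matrix, min_overlap = min_overlap,
                         orientations = "forward")
      nl <- nulls[[as.character(mot$width)]]
      p <- (1 + sum(nl <= al$distance + 1e-12)) / (n_perm + 1)
      E <- p * nlib
      if (E < e_threshold) {
        tf <- if (mid %in% names(tf_map)) unname(tf_map[mid]) else mot$name
        rows[[length(rows) + 1L]] <- data.frame(
          family = footprints$family[i],
          footprint_index = footprints$index[i],
          strand = footprints$strand[i], motif_id = mid, tf = tf,
          offset = al$offset, distance = al$distance, p = p, evalue = E,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(family = character(0), footprint_index = integer(0),
                      strand = character(0), motif_id = character(0),
                      tf = character(0), offset = integer(0),
                      distance = numeric(0), p = numeric(0),
                      evalue = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Footprint sequence table for scanning
#'
#' Expands a footprint call table into one row per footprint strand, with
#' the padded consensus sequence on the forward strand and its reverse
#' complement on the minus strand.
#'
#' @param calls Footprint table from [call_family_footprints()].
#' @param library A [consensus_library()].
#' @param pad Padding in bp.
#' @return Data frame with family, index, strand, seq.
#' @export
footprint_sequence_table <- function(calls, library, pad = 3L) {
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    seqs <- extract_footprint_sequence(library, calls$family[i],
                                       calls$start[i], calls$end[i], pad)
    rows[[length(rows) + 1L]] <- data.frame(
      family = calls$family[i], index = calls$index[i],
      strand = c("+", "-"), seq = unname(seqs), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(family = character(0), index = integer(0),
                      strand = character(0), seq = character(0)))
  }
  do.call(rbind, rows)
}
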