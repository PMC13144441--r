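#' Simulate per-stage Tn5 insertion events
#'
#' Draws single-base Tn5 cut sites independently per position from a Poisson
#' model. Relative insertion rates are 1 at background positions,
#' `background_rate_ratio` inside TE copies, and additionally multiplied by
#' `protection_factor` (rho) at positions inside a planted site whose
#' occupied stages include the current stage. Rates are scaled so the
#' expected genome-wide total per stage equals `depth_per_stage`.
#'
#' @param truth Truth bundle from [make_te_genome()] (components `copies`
#'   and `genomic_sites`).
#' @param config The [sim_config()] used to build the genome.
#' @return Named list (one element per stage) of [insertion_track()]
#'   objects.
#' @export
simulate_atac <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  rel0 <- rep(1, L)
  cp <- truth$copies
  for (i in seq_len(nrow(cp))) {
    rel0[seq.int(cp$start[i] + 1L, cp$end[i])] <- config$background_rate_ratio
  }
  gs <- truth$genomic_sites
  out <- vector("list", length(config$stages))
  names(out) <- config$stages
  for (k in seq_along(config$stages)) {
    stage <- config$stages[k]
    rel <- rel0
    if (!is.null(gs)) {
      for (i in seq_len(nrow(gs))) {
        occ <- strsplit(gs$occupied[i], ",", fixed = TRUE)[[1]]
        if (stage %in% occ) {
          idx <- seq.int(gs$start[i] + 1L, gs$end[i])
          rel[idx] <- rel[idx] * config$protection_factor
        }
      }
    }
    lambda <- rel * (config$depth_per_stage / sum(rel))
    counts <- with_seed(derive_seed(config$seed, 101L + k), rpois(L, lambda))
    pos <- rep.int(which(counts > 0L) - 1L, counts[counts > 0L])
    strand <- with_seed(derive_seed(config$seed, 201L + k),
                        sample(c("+", "-"), length(pos), replace = TRUE))
    events <- data.frame(chrom = rep("chrS", length(pos)), pos = pos,
                         strand = strand, stringsAsFactors = FALSE)
    out[[k]] <- insertion_track(stage, events, library_size = nrow(events))
  }
  out
}

#' Pair successive cut sites into pseudo-fragments
#'
#' Converts an insertion track back into a BEDPE-style fragment table by
#' pairing successive cut positions on each chromosome: a pair (c1, c2)
#' becomes the fragment \[c1, c2 + 1), whose two cut sites under zero Tn5
#' shift are exactly c1 and c2. This lets the fragment-input path of the
#' profile builder be exercised against cut sites generated directly.
#'
#' @param track An [insertion_track()].
#' @return Data frame with columns chrom, start, end (0-based half-open).
#'   An odd trailing event per chromosome is dropped with a warning.
#' @export
cuts_to_fragments <- function(track) {
  stopifnot(inherits(track, "insertion_track"))
  ev <- track$events
  frs <- lapply(split(ev$pos, ev$chrom), sort)
  dropped <- 0L
  rows <- list()
  for (chrom in names(frs)) {
    p <- frs[[chrom]]
    n <- length(p)
    if (n %% 2L == 1L) {
      dropped <- dropped + 1L
      p <- p[-n]
      n <- n - 1L
    }
    if (n == 0L) next
    c1 <- p[seq(1L, n, by = 2L)]
    c2 <- p[seq(2L, n, by = 2L)]
    rows[[chrom]] <- data.frame(chrom = chrom, start = c1, end = c2 + 1L,
                                stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    warning(sprintf("%d unpaired cut(s) dropped", dropped))
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
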