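#' Specify a simulated TE family
#'
#' Describes one transposable-element family to plant in a synthetic genome:
#' its consensus sequence, how many length-intact and 3'-truncated copies to
#' place, and which consensus intervals carry planted transcription-factor
#' binding sites (with the developmental stages at which each site is
#' occupied, i.e. protected from Tn5 insertion).
#'
#' @param name Family identifier (goes in the BED name column).
#' @param consensus Uppercase ACGT consensus sequence.
#' @param n_intact Number of copies of exactly consensus length.
#' @param n_truncated Number of copies truncated from the 3' end.
#' @param planted_sites List of sites, each a list with elements `start`,
#'   `end` (0-based half-open consensus interval), `motif_id`, and `occupied`
#'   (character vector of stage names at which the site is bound).
#' @return A `family_spec` object.
#' @export
family_spec <- function(name, consensus, n_intact, n_truncated = 0L,
                        planted_sites = list()) {
  if (!is_string(name)) stop("family name must be a single string")
  if (!is_string(consensus) || nchar(consensus) == 0L) {
    stop("consensus must be a non-empty string")
  }
  if (grepl("[^ACGT]", consensus)) {
    stop(sprintf("family '%s': consensus must be uppercase ACGT", name))
  }
  stopifnot_scalar_int(n_intact, "n_intact", min = 0)
  stopifnot_scalar_int(n_truncated, "n_truncated", min = 0)
  len <- nchar(consensus)
  if (length(planted_sites) > 0L) {
    iv <- t(vapply(planted_sites, function(s) {
      c(as.numeric(s$start), as.numeric(s$end))
    }, numeric(2)))
    if (any(iv[, 1] < 0 | iv[, 2] > len | iv[, 1] >= iv[, 2])) {
      stop(sprintf("family '%s': planted sites must lie within [0, %d)",
                   name, len))
    }
    o <- order(iv[, 1])
    if (any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)])) {
      stop(sprintf("family '%s': planted sites overlap", name))
    }
    ids <- vapply(planted_sites, function(s) s$motif_id, character(1))
    if (anyDuplicated(ids)) {
      stop(sprintf("family '%s': duplicate motif ids in planted sites", name))
    }
  }
  structure(list(name = name, consensus = consensus,
                 n_intact = as.integer(n_intact),
                 n_truncated = as.integer(n_truncated),
                 planted_sites = planted_sites),
            class = "family_spec")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic dataset: the toy genome, the planted
#' TE families, the per-stage ATAC sequencing depth and footprint protection,
#' and the expression matrix used by the candidate filter.
#'
#' @param seed Master seed; identical configurations produce byte-identical
#'   outputs.
#' @param genome_length Toy genome length in bp (single chromosome `chrS`).
#' @param families List of [family_spec()] objects.
#' @param stages Ordered character vector of stage names.
#' @param depth_per_stage Expected total Tn5 insertions per stage, genome
#'   wide.
#' @param protection_factor Multiplicative insertion-rate factor (rho, in
#'   \[0, 1\]) applied inside an occupied planted site: 0 means complete
#'   protection, 1 means no footprint.
#' @param background_rate_ratio Insertion-rate ratio of accessible TE
#'   element positions over non-element background positions.
#' @param copy_mutation_rate Per-base substitution probability applied to
#'   each planted copy (planted-site positions are never mutated).
#' @param n_cells_per_stage Cells per stage in the expression matrix.
#' @param tf_count_high Expected per-cell count for planted TFs in mid/late
#'   2-cell cells; must make `P(count < 2)` negligible (< 1e-3 requires
#'   lambda >= 9.3) since counts below 2 are rejection-resampled.
#' @param tf_count_low Expected per-cell count for decoy TFs.
#' @param planted_motifs Named list of PWMs (4 x width probability matrices,
#'   rows A,C,G,T), one per planted motif id.
#' @param tf_map Named character vector mapping motif id to TF name.
#' @param n_decoys Number of random decoy motifs in the emitted library.
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed, genome_length, families, stages,
                       depth_per_stage = 18000,
                       protection_factor = 0.15,
                       background_rate_ratio = 10,
                       copy_mutation_rate = 0.02,
                       n_cells_per_stage = 8L,
                       tf_count_high = 30,
                       tf_count_low = 1,
                       planted_motifs = list(),
                       tf_map = character(0),
                       n_decoys = 25L) {
  stopifnot_scalar_int(seed, "seed")
  stopifnot_scalar_int(genome_length, "genome_length", min = 1)
  if (!is.list(families) || length(families) == 0L ||
      !all(vapply(families, inherits, logical(1), "family_spec"))) {
    stop("families must be a non-empty list of family_spec objects")
  }
  if (!is.character(stages) || length(stages) == 0L || anyDuplicated(stages)) {
    stop("stages must be a character vector of distinct stage names")
  }
  if (protection_factor < 0 || protection_factor > 1) {
    stop("protection_factor must lie in [0, 1]")
  }
  if (background_rate_ratio <= 0) stop("background_rate_ratio must be > 0")
  if (copy_mutation_rate < 0 || copy_mutation_rate > 1) {
    stop("copy_mutation_rate must lie in [0, 1]")
  }
  stopifnot_scalar_int(n_cells_per_stage, "n_cells_per_stage", min = 2)
  if (tf_count_high < 2) stop("tf_count_high must be >= 2")
  total_copy_bp <- sum(vapply(families, function(f) {
    nchar(f$consensus) * (f$n_intact + f$n_truncated)
  }, numeric(1)))
  if (genome_length < total_copy_bp) {
    stop("genome too small: genome_length is less than the total planted copy length")
  }
  for (f in families) {
    for (s in f$planted_sites) {
      if (!all(s$occupied %in% stages)) {
        stop(sprintf("family '%s': occupied stages must be a subset of config stages",
                     f$name))
      }
      if (!s$motif_id %in% names(planted_motifs)) {
        stop(sprintf("planted site motif '%s' has no PWM in planted_motifs",
                     s$motif_id))
      }
    }
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 families = families, stages = stages,
                 depth_per_stage = depth_per_stage,
                 protection_factor = protection_factor,
                 background_rate_ratio = background_rate_ratio,
                 copy_mutation_rate = copy_mutation_rate,
                 n_cells_per_stage = as.integer(n_cells_per_stage),
                 tf_count_high = tf_count_high,
                 tf_count_low = tf_count_low,
                 planted_motifs = planted_motifs,
                 tf_map = tf_map,
                 n_decoys = as.integer(n_decoys)),
            class = "sim_config")
}

## Sharp PWM whose modal sequence is `seq`: probability `peak` on the
## sequence base, the remainder split evenly, rounded so columns sum to 1
## exactly at 6 decimals.
sharp_pwm <- function(seq, peak = 0.85) {
  bases <- strsplit(seq, "")[[1]]
  m <- matrix((1 - peak) / 3, nrow = 4, ncol = length(bases),
              dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- peak
  normalize_pwm_columns(m)
}

#' Default simulation configuration
#'
#' The reference study conditions used throughout the package's tests and
#' worked examples: two 300-bp TE families with 50 intact and 10 truncated
#' copies each, five planted 10-bp motifs (three sites in family one, two in
#' family two) occupied at 2-cell stages, rho = 0.15 protection, aggregated
#' insertion depth of about 20 insertions/bp over the 50 intact copies of a
#' family, and a motif library of 5 planted plus 25 decoy motifs. Planted
#' TFs are expressed high in mid/late 2-cell cells; decoys are not.
#'
#' @param seed Master seed.
#' @return A `sim_config` object.
#' @export
default_sim_config <- function(seed = 42L) {
  with_seed(derive_seed(seed, 11L), {
    stages <- c("early2C", "mid2C", "late2C", "8C")
    motif_w <- 10L
    tf_names <- paste0("Tfp", 1:5)
    motif_ids <- paste0("M_", tf_names)
    motif_seqs <- vapply(motif_ids, function(i) random_dna(motif_w),
                         character(1))
    planted <- lapply(motif_seqs, sharp_pwm)
    names(planted) <- motif_ids

    ## site layout: 15-bp sites, motif centred, sites well separated
    site <- function(start, id, occ) {
      list(start = start, end = start + 15L, motif_id = id, occupied = occ)
    }
    sites1 <- list(site(60L, motif_ids[1], c("early2C", "late2C")),
                   site(140L, motif_ids[2], "late2C"),
                   site(220L, motif_ids[3], c("early2C", "late2C")))
    sites2 <- list(site(80L, motif_ids[4], c("early2C", "late2C")),
                   site(190L, motif_ids[5], "late2C"))

    make_consensus <- function(len, sites) {
      s <- strsplit(random_dna(len), "")[[1]]
      for (st in sites) {
        mseq <- strsplit(motif_seqs[[st$motif_id]], "")[[1]]
        off <- st$start + floor((st$end - st$start - motif_w) / 2)
        s[(off + 1):(off + motif_w)] <- mseq
      }
      paste(s, collapse = "")
    }
    fam1 <- family_spec("simTE1", make_consensus(300L, sites1), 50L, 10L,
                        sites1)
    fam2 <- family_spec("simTE2", make_consensus(300L, sites2), 50L, 10L,
                        sites2)
    tf_map <- stats::setNames(tf_names, motif_ids)
    sim_config(seed = seed, genome_length = 150000L,
               families = list(fam1, fam2), stages = stages,
               planted_motifs = planted, tf_map = tf_map)
  })
}
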