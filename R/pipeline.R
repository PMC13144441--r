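#' Run the full footprint-to-candidate pipeline
#'
#' Ties the analysis modules together on an in-memory dataset (typically
#' from [simulate_te_dataset()], but any components with the same shapes
#' work): select length-intact copies, build per-stage insertion
#' meta-profiles per family, call and stage-classify footprints, extract and
#' scan the underlying consensus sequences against the motif library, apply
#' the embryonic expression filter, and merge candidates across families.
#'
#' @param sim List with `annotation`, `consensus`, `tracks`, `library`,
#'   `tf_map`, `expression` (see [simulate_te_dataset()]).
#' @param params A [footprint_params()].
#' @param e_threshold Motif-match E-value threshold (default 30).
#' @param n_perm Permutations for motif p-values.
#' @param seed Seed for the permutation null.
#' @param filter_stages Stages used by the expression filter.
#' @param min_reads Minimum raw reads per cell in the filter.
#' @param intact_tolerance_bp Length tolerance for intact-copy selection.
#' @return List with `intact`, `profiles` (family -> stage ->
#'   `meta_profile`), `footprints` (per-family call table), `matches`,
#'   `filtered_tfs`, `candidates` (a `candidate_set`).
#' @export
run_footprint_pipeline <- function(sim, params = footprint_params(),
                                   e_threshold = 30, n_perm = 999L,
                                   seed = 1L,
                                   filter_stages = c("mid2C", "late2C"),
                                   min_reads = 2L,
                                   intact_tolerance_bp = 0L) {
  intact <- select_intact(sim$annotation, sim$consensus, intact_tolerance_bp)
  families <- intersect(consensus_families(sim$consensus),
                        unique(intact$copies$family))
  profiles <- lapply(families, function(fam) {
    lapply(sim$tracks, build_meta_profile, intact = intact, family = fam,
           library = sim$consensus)
  })
  names(profiles) <- families

  calls <- do.call(rbind, lapply(families, function(fam) {
    call_family_footprints(profiles[[fam]], params)
  }))
  if (is.null(calls) || nrow(calls) == 0L) {
    return(list(intact = intact, profiles = profiles, footprints = calls,
                matches = NULL, filtered_tfs = character(0),
                candidates = merge_candidates(NULL)))
  }
  fp_seqs <- footprint_sequence_table(calls, sim$consensus, params$pad)
  matches <- scan_footprints(fp_seqs, sim$library, sim$tf_map,
                             e_threshold = e_threshold, n_perm = n_perm,
                             seed = seed)
  filtered <- expression_filter(sim$expression, unique(matches$tf),
                                stages = filter_stages, min_reads = min_reads)
  candidates <- merge_candidates(matches[matches$tf %in% filtered, ,
                                         drop = FALSE])
  list(intact = intact, profiles = profiles, footprints = calls,
       matches = matches, filtered_tfs = filtered, candidates = candidates)
}
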