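#' Build a motif library of planted PWMs plus random decoys
#'
#' Decoy motifs have columns drawn independently from a flat Dirichlet
#' (Gamma(1) normalisation) and widths sampled uniformly from 6-12 bp.
#' Columns are rounded so they sum to exactly 1 at the 6-decimal precision
#' used by the MEME writer, making write/read round trips exact.
#'
#' @param planted Named list of 4 x width probability matrices (or [pwm()]
#'   objects); names are motif ids.
#' @param n_decoys Number of decoy motifs.
#' @param seed RNG seed; output is deterministic given the seed.
#' @param tf_map Optional named character vector motif id -> TF name used
#'   for the planted motifs' alternate names.
#' @return A `motif_library`: list with `motifs` (named list of [pwm()]),
#'   `planted_ids`, `decoy_ids`.
#' @export
make_motif_library <- function(planted, n_decoys, seed,
                               tf_map = character(0)) {
  if (length(planted) > 0L && is.null(names(planted))) {
    stop("planted motifs must be named by motif id")
  }
  stopifnot_scalar_int(n_decoys, "n_decoys", min = 0)
  motifs <- list()
  for (id in names(planted)) {
    m <- planted[[id]]
    if (inherits(m, "pwm")) m <- m$matrix
    nm <- if (id %in% names(tf_map)) unname(tf_map[id]) else id
    motifs[[id]] <- pwm(id, normalize_pwm_columns(m), nm)
  }
  with_seed(derive_seed(seed, 53L), {
    for (k in seq_len(n_decoys)) {
      id <- sprintf("decoy%02d", k)
      if (id %in% names(motifs)) stop(sprintf("duplicate motif id '%s'", id))
      w <- sample(6:12, 1L)
      m <- matrix(rgamma(4L * w, shape = 1), nrow = 4L)
      motifs[[id]] <- pwm(id, normalize_pwm_columns(m), paste0("Dcy", k))
    }
  })
  structure(list(motifs = motifs,
                 planted_ids = names(planted),
                 decoy_ids = setdiff(names(motifs), names(planted))),
            class = "motif_library")
}

#' Simulate a single-cell expression count matrix
#'
#' Emits Poisson counts for planted and decoy TFs across
#' `n_cells_per_stage` cells per stage. Planted TFs draw from
#' Poisson(`tf_count_high`) and, in cells of the filter stages (mid and
#' late 2-cell by default), counts below 2 are rejection-resampled so every
#' planted TF is guaranteed to pass the two-or-more-reads-in-all-cells
#' filter. Decoy TFs draw from Poisson(`tf_count_low`) everywhere, so with
#' the default rate of 1 they essentially never pass it.
#'
#' @param planted_tfs Character vector of planted TF names.
#' @param decoy_tfs Character vector of decoy TF names.
#' @param config A [sim_config()].
#' @param filter_stages Stages in which planted counts are forced >= 2.
#' @return An [expression_matrix()] (TFs x cells, with per-column stage
#'   labels).
#' @export
simulate_expression <- function(planted_tfs, decoy_tfs, config,
                                filter_stages = c("mid2C", "late2C")) {
  stopifnot(inherits(config, "sim_config"))
  if (config$tf_count_high < 2) stop("tf_count_high must be >= 2")
  stages <- config$stages
  ncell <- config$n_cells_per_stage
  cells <- as.vector(vapply(stages, function(s) paste0(s, "_c", seq_len(ncell)),
                            character(ncell)))
  cell_stage <- rep(stages, each = ncell)
  tfs <- c(planted_tfs, decoy_tfs)
  with_seed(derive_seed(config$seed, 303L), {
    counts <- matrix(0L, nrow = length(tfs), ncol = length(cells),
                     dimnames = list(tfs, cells))
    for (i in seq_along(tfs)) {
      lambda <- if (tfs[i] %in% planted_tfs) config$tf_count_high else
        config$tf_count_low
      counts[i, ] <- rpois(length(cells), lambda)
    }
    guard <- cell_stage %in% filter_stages
    for (tf in planted_tfs) {
      low <- which(guard & counts[tf, ] < 2L)
      while (length(low) > 0L) {
        counts[tf, low] <- rpois(length(low), config$tf_count_high)
        low <- which(guard & counts[tf, ] < 2L)
      }
    }
    expression_matrix(counts, cell_stage)
  })
}

#' Simulate a complete synthetic TE footprinting dataset
#'
#' Convenience wrapper tying the generator stages together: genome and
#' annotation with planted copies, per-stage Tn5 insertion tracks, the motif
#' library (planted plus decoys), the motif-to-TF map, and the expression
#' matrix, with ground truth throughout.
#'
#' @param config A [sim_config()], e.g. [default_sim_config()].
#' @return List with `config`, `genome`, `annotation`, `truth`, `tracks`,
#'   `library`, `tf_map`, `expression`, `consensus` (a [consensus_library()]).
#' @export
simulate_te_dataset <- function(config) {
  gen <- make_te_genome(config)
  tracks <- simulate_atac(gen$truth, config)
  lib <- make_motif_library(config$planted_motifs, config$n_decoys,
                            seed = derive_seed(config$seed, 77L),
                            tf_map = config$tf_map)
  decoy_tfs <- vapply(lib$motifs[lib$decoy_ids], `[[`, character(1), "name")
  tf_map <- c(config$tf_map,
              stats::setNames(decoy_tfs, lib$decoy_ids))
  expr <- simulate_expression(gen$truth$planted_tfs, unname(decoy_tfs), config)
  cons <- consensus_library(stats::setNames(
    lapply(config$families, `[[`, "consensus"),
    vapply(config$families, `[[`, character(1), "name")))
  gen$truth$decoy_tfs <- unname(decoy_tfs)
  list(config = config, genome = gen$genome, annotation = gen$annotation,
       truth = gen$truth, tracks = tracks, library = lib, tf_map = tf_map,
       expression = expr, consensus = cons)
}

#' Write a simulated dataset to disk
#'
#' Emits the on-disk form of a simulated dataset: `genome.fa`,
#' `te_annotation.bed` (BED6), per-stage `insertions.<stage>.bed` (BED3 plus
#' strand) and `fragments.<stage>.bedpe`, `motifs.meme`, `expression.tsv`
#' (stage header row), `tf_map.tsv` and `truth/*.tsv`.
#'
#' @param sim Output of [simulate_te_dataset()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_te_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(outdir, "genome.fa"))
  write_annotation_bed(sim$annotation, file.path(outdir, "te_annotation.bed"))
  for (stage in names(sim$tracks)) {
    tr <- sim$tracks[[stage]]
    ev <- tr$events
    bed <- data.frame(ev$chrom, ev$pos, ev$pos + 1L, ".", 0L, ev$strand)
    write.table(bed, file.path(outdir, sprintf("insertions.%s.bed", stage)),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    fr <- suppressWarnings(cuts_to_fragments(tr))
    bedpe <- data.frame(fr$chrom, fr$start, fr$start + 1L,
                        fr$chrom, fr$end - 1L, fr$end)
    write.table(bedpe, file.path(outdir, sprintf("fragments.%s.bedpe", stage)),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  write_meme(sim$library$motifs, file.path(outdir, "motifs.meme"))
  write_expression_tsv(sim$expression, file.path(outdir, "expression.tsv"))
  write.table(data.frame(motif_id = names(sim$tf_map), tf = unname(sim$tf_map)),
              file.path(outdir, "tf_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$copies, file.path(outdir, "truth", "copies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$sites, file.path(outdir, "truth", "sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$planted_tfs,
             file.path(outdir, "truth", "planted_tfs.txt"))
  writeLines(sim$truth$decoy_tfs,
             file.path(outdir, "truth", "decoy_tfs.txt"))
  invisible(outdir)
}
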