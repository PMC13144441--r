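## Small fixtures shared across test files, built in code.

## One-family configuration, light enough for module tests.
tiny_config <- function(seed = 7L, mutation = 0, n_intact = 5L,
                        n_truncated = 0L, rho = 0.15, depth = 4000,
                        sites = TRUE) {
  motif <- tefoot::pwm("M_toy", matrix(c(.85, .05, .05, .05), 4, 10,
                                       dimnames = list(c("A","C","G","T"),
                                                       NULL)))
  cons <- paste(rep("ACGT", 75), collapse = "")  # 300 bp, deterministic
  cons <- paste0(substr(cons, 1, 120), "AAAAAAAAAACGCGT",
                 substr(cons, 136, 300))          # site [120,135) with A10 run
  planted <- if (sites) {
    list(list(start = 120L, end = 135L, motif_id = "M_toy",
              occupied = c("early2C", "late2C")))
  } else list()
  fam <- tefoot::family_spec("toyTE", cons, n_intact, n_truncated, planted)
  tefoot::sim_config(seed = seed, genome_length = 60000L,
                     families = list(fam),
                     stages = c("early2C", "mid2C", "late2C", "8C"),
                     depth_per_stage = depth, protection_factor = rho,
                     copy_mutation_rate = mutation,
                     planted_motifs = list(M_toy = motif$matrix),
                     tf_map = c(M_toy = "ToyTF"), n_decoys = 3L)
}

## Extract the sequence of each annotated copy from the genome, oriented to
## the consensus strand.
copy_sequences <- function(genome, annotation) {
  g <- as.character(genome[[1]])
  vapply(seq_len(nrow(annotation)), function(i) {
    s <- substr(g, annotation$start[i] + 1, annotation$end[i])
    if (annotation$strand[i] == "-") revcomp_chr(s) else s
  }, character(1))
}

random_profile <- function(n, lambda = 8) {
  as.numeric(rpois(n, lambda))
}

## Random step bedGraph-style track used by the matrix-builder tests.
make_random_track <- function(L, step = 50L, seed = 1L) {
  set.seed(seed)
  starts <- seq(0L, L - step, by = step)
  data.frame(chrom = "chr1", start = starts, end = starts + step,
             value = round(rgamma(length(starts), 2, 0.5), 3))
}
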