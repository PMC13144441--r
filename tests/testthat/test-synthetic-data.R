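test_that("mutation-free copies reproduce the consensus exactly", {
  cfg <- tiny_config(seed = 1L, mutation = 0, n_intact = 5L)
  gen <- make_te_genome(cfg)
  expect_equal(nrow(gen$annotation), 5L)
  expect_true(all(gen$annotation$end - gen$annotation$start == 300L))
  seqs <- copy_sequences(gen$genome, gen$annotation)
  expect_true(all(seqs == cfg$families[[1]]$consensus))
})

test_that("identical seed gives byte-identical genome, annotation and tracks", {
  cfg <- tiny_config(seed = 1L)
  a <- make_te_genome(cfg)
  b <- make_te_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$annotation, b$annotation)
  ta <- simulate_atac(a$truth, cfg)
  tb <- simulate_atac(b$truth, cfg)
  expect_identical(lapply(ta, `[[`, "events"), lapply(tb, `[[`, "events"))
  ## and the generator actually depends on the seed
  c2 <- make_te_genome(tiny_config(seed = 2L))
  expect_false(identical(as.character(a$genome), as.character(c2$genome)))
})

test_that("per-copy mismatch fraction matches the configured mutation rate", {
  cfg <- tiny_config(seed = 7L, mutation = 0.02, n_intact = 50L,
                     sites = FALSE)
  gen <- make_te_genome(cfg)
  seqs <- copy_sequences(gen$genome, gen$annotation)
  cons <- strsplit(cfg$families[[1]]$consensus, "")[[1]]
  mismatch <- vapply(seqs, function(s) {
    mean(strsplit(s, "")[[1]] != cons)
  }, numeric(1))
  expect_lt(abs(mean(mismatch) - 0.02), 0.01)
})

test_that("truncated copies are shorter and cut from the 3' end", {
  cfg <- tiny_config(seed = 3L, mutation = 0, n_intact = 2L, n_truncated = 4L)
  gen <- make_te_genome(cfg)
  tr <- gen$truth$copies[!gen$truth$copies$intact, ]
  expect_equal(nrow(tr), 4L)
  expect_true(all(tr$end - tr$start < 300L))
  g <- as.character(gen$genome[[1]])
  for (i in seq_len(nrow(tr))) {
    s <- substr(g, tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") s <- revcomp_chr(s)
    expect_identical(s, substr(cfg$families[[1]]$consensus, 1,
                               tr$end[i] - tr$start[i]))
  }
})

test_that("placement failure in a too-small genome raises an error", {
  fam <- family_spec("big", paste(rep("ACGT", 100), collapse = ""), 20L)
  expect_error(sim_config(seed = 1L, genome_length = 5000L,
                          families = list(fam), stages = "s1"),
               "genome too small")
})

test_that("rho = 1 leaves no footprint at planted sites", {
  cfg <- tiny_config(seed = 5L, rho = 1, n_intact = 50L, depth = 20000)
  gen <- make_te_genome(cfg)
  tracks <- simulate_atac(gen$truth, cfg)
  intact <- select_intact(gen$annotation,
                          consensus_library(list(toyTE = cfg$families[[1]]$consensus)))
  lib <- consensus_library(list(toyTE = cfg$families[[1]]$consensus))
  prof <- build_meta_profile(tracks$early2C, intact, "toyTE", lib)
  site <- 121:135                      # 1-based indices of [120,135)
  flank <- c(96:120, 136:160)
  m_in <- mean(prof$raw[site])
  m_fl <- mean(prof$raw[flank])
  se <- sqrt(m_fl / length(site) + m_fl / length(flank))
  expect_lt(abs(m_in - m_fl), 3 * se + 1e-9)
})

test_that("rho = 0 gives zero insertions inside occupied sites at that stage", {
  cfg <- tiny_config(seed = 5L, rho = 0, n_intact = 20L, depth = 20000)
  gen <- make_te_genome(cfg)
  tracks <- simulate_atac(gen$truth, cfg)
  gs <- gen$truth$genomic_sites
  for (stage in c("early2C", "late2C")) {       # occupied stages of the site
    ev <- tracks[[stage]]$events
    for (i in seq_len(nrow(gs))) {
      expect_equal(sum(ev$pos >= gs$start[i] & ev$pos < gs$end[i]), 0L)
    }
  }
  ## unoccupied stage keeps signal inside the sites
  ev8 <- tracks[["8C"]]$events
  inside8 <- sum(vapply(seq_len(nrow(gs)), function(i) {
    sum(ev8$pos >= gs$start[i] & ev8$pos < gs$end[i])
  }, numeric(1)))
  expect_gt(inside8, 0)
})

test_that("rho = 0.2 yields an in-site/flank rate ratio near 0.2", {
  cfg <- tiny_config(seed = 9L, rho = 0.2, n_intact = 50L, depth = 20000)
  gen <- make_te_genome(cfg)
  tracks <- simulate_atac(gen$truth, cfg)
  lib <- consensus_library(list(toyTE = cfg$families[[1]]$consensus))
  intact <- select_intact(gen$annotation, lib)
  prof <- build_meta_profile(tracks$early2C, intact, "toyTE", lib)
  ratio <- mean(prof$raw[121:135]) / mean(prof$raw[c(96:120, 136:160)])
  expect_gt(ratio, 0.1)
  expect_lt(ratio, 0.3)
})

test_that("total emitted insertions are Poisson-consistent with the depth", {
  cfg <- tiny_config(seed = 11L, depth = 10000)
  gen <- make_te_genome(cfg)
  tracks <- simulate_atac(gen$truth, cfg)
  for (tr in tracks) {
    expect_lt(abs(nrow(tr$events) - 10000), 4 * sqrt(10000))
  }
})

test_that("motif library round-trips through MEME format deterministically", {
  cfg <- tiny_config()
  lib <- make_motif_library(cfg$planted_motifs, 3L, seed = 21L,
                            tf_map = cfg$tf_map)
  expect_length(lib$motifs, 4L)
  f1 <- tempfile(fileext = ".meme")
  f2 <- tempfile(fileext = ".meme")
  write_meme(lib$motifs, f1)
  back <- read_meme(f1)
  expect_length(back, 4L)
  for (m in back) {
    expect_true(all(abs(colSums(m$matrix) - 1) < 1e-9))
  }
  write_meme(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## determinism of generation
  lib2 <- make_motif_library(cfg$planted_motifs, 3L, seed = 21L,
                             tf_map = cfg$tf_map)
  write_meme(lib2$motifs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("decoys differ from every planted motif column-wise", {
  cfg <- default_sim_config(42L)
  lib <- make_motif_library(cfg$planted_motifs, 25L, seed = 1L)
  for (d in lib$decoy_ids) {
    dm <- lib$motifs[[d]]$matrix
    for (p in lib$planted_ids) {
      pm <- lib$motifs[[p]]$matrix
      mind <- min(vapply(seq_len(ncol(dm)), function(j) {
        min(sqrt(colSums((pm - dm[, j])^2)))
      }, numeric(1)))
      expect_gt(mind, 0)
    }
  }
})

test_that("duplicate planted motif ids are rejected", {
  m <- matrix(0.25, 4, 6)
  expect_error(write_meme(list(pwm("a", m), pwm("a", m)), tempfile()),
               "duplicate")
})

test_that("simulated expression guarantees the planted-TF filter and shape", {
  cfg <- tiny_config(seed = 13L)
  expr <- simulate_expression(paste0("P", 1:2), paste0("D", 1:2), cfg)
  expect_equal(dim(expr$counts), c(4L, 4L * cfg$n_cells_per_stage))
  filt_cols <- expr$stages %in% c("mid2C", "late2C")
  expect_true(all(expr$counts[c("P1", "P2"), filt_cols] >= 2))
  ## decoys at rate 1 essentially always fail somewhere
  expect_true(any(expr$counts[c("D1", "D2"), filt_cols] < 2))
  ## the downstream filter recovers exactly the planted set
  kept <- expression_filter(expr, c("P1", "P2", "D1", "D2"))
  expect_identical(kept, c("P1", "P2"))
})

test_that("fragment conversion round-trips cut sites under zero shift", {
  cfg <- tiny_config(seed = 17L, depth = 2000)
  gen <- make_te_genome(cfg)
  tr <- simulate_atac(gen$truth, cfg)$early2C
  frags <- suppressWarnings(cuts_to_fragments(tr))
  back <- fragments_to_insertions(frags, shift_plus = 0L, shift_minus = 0L)
  n <- 2L * nrow(frags)
  expect_identical(sort(back$events$pos),
                   sort(tr$events$pos)[seq_len(n)])
})
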