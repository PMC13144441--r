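test_that("depletion score follows its definition and conventions", {
  flat <- rep(4, 50)
  expect_equal(depletion_score(flat, 10L, 20L)$D, 0)
  v <- c(rep(10, 20), rep(2, 4), rep(10, 20))
  ds <- depletion_score(v, 20L, 24L, flank_bp = 10L)
  expect_equal(ds$m_flank, 10)
  expect_equal(ds$m_center, 2)
  expect_equal(ds$D, 0.8)
  expect_equal(depletion_score(rep(0, 30), 10L, 15L)$D, 0)
  expect_error(depletion_score(flat, 10L, 10L), "empty")
})

test_that("the worked single-footprint profile is called exactly", {
  v <- rep(10, 20)
  v[9:12] <- 2                               # 0-based [8,12)
  p <- footprint_params(window = 1L, flank_bp = 5L, w_min = 3L, w_max = 12L,
                        d_min = 0.5, c_min = 1)
  calls <- call_footprints(v, p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 8L)
  expect_equal(calls$end, 12L)
  expect_equal(calls$D, 0.8)
  expect_equal(nrow(call_footprints(rep(7, 20), p)), 0L)
  expect_equal(nrow(call_footprints(rep(0, 20), p)), 0L)
})

test_that("calls are invariant to positive rescaling of the profile", {
  set.seed(41)
  p <- footprint_params(window = 3L, flank_bp = 10L, w_min = 4L, w_max = 20L,
                        d_min = 0.4, c_min = 0)
  for (rep_i in 1:20) {
    v <- rpois(60, 10)
    v[25:32] <- rpois(8, 1)
    base <- call_footprints(v, p)
    for (k in c(0.01, 3, 1e4)) {
      sc <- call_footprints(v * k, p)
      expect_equal(sc$start, base$start)
      expect_equal(sc$end, base$end)
      expect_equal(sc$D, base$D, tolerance = 1e-12)
    }
  }
})

test_that("calls mirror under profile reversal", {
  set.seed(43)
  p <- footprint_params(window = 3L, flank_bp = 10L, w_min = 4L, w_max = 20L,
                        d_min = 0.4, c_min = 0)
  for (rep_i in 1:20) {
    v <- as.numeric(rpois(60, 10))
    v[15:22] <- 0
    fwd <- call_footprints(v, p)
    rev_calls <- call_footprints(rev(v), p)
    n <- length(v)
    mirrored <- data.frame(start = n - rev_calls$end,
                           end = n - rev_calls$start)
    mirrored <- mirrored[order(mirrored$start), ]
    expect_equal(fwd$start, mirrored$start)
    expect_equal(fwd$end, mirrored$end)
  }
})

test_that("caller equals the exhaustive reference on random short profiles", {
  set.seed(101)
  p <- footprint_params(window = 3L, flank_bp = 8L, w_min = 4L, w_max = 15L,
                        d_min = 0.3, c_min = 0.5)
  for (rep_i in 1:60) {
    n <- sample(20:50, 1)
    v <- as.numeric(rpois(n, 8))
    if (rep_i %% 2 == 0) {
      s <- sample(5:(n - 10), 1)
      v[s:(s + 5)] <- rpois(6, 1)
    }
    got <- call_footprints(v, p)
    want <- oracle_call_footprints(v, p)
    expect_equal(got$start, want$start, info = paste("rep", rep_i))
    expect_equal(got$end, want$end)
    expect_equal(got$D, want$D, tolerance = 1e-12)
  }
})

test_that("stage classification thresholds the per-stage depletion", {
  profs <- list(early2C = c(rep(10, 20), rep(1, 8), rep(10, 20)),
                late2C = rep(10, 48))
  p <- footprint_params(window = 1L, flank_bp = 10L, d_min = 0.3)
  cl <- classify_stages(profs, 20L, 28L, p)
  expect_true(cl$present[["early2C"]])
  expect_false(cl$present[["late2C"]])
  expect_equal(cl$label, "early2C")
  ## equal depletion at both stages labels both
  profs$late2C <- profs$early2C
  expect_equal(classify_stages(profs, 20L, 28L, p)$label, "early2C+late2C")
})

test_that("synthetic stage-specific occupancy gives stage-specific labels", {
  motif <- matrix(c(.85, .05, .05, .05), 4, 10,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- paste(rep("ACGT", 75), collapse = "")
  sites <- list(list(start = 120L, end = 135L, motif_id = "M_toy",
                     occupied = "late2C"))
  fam <- family_spec("toyTE", cons, 50L, 0L, sites)
  cfg <- sim_config(seed = 19L, genome_length = 60000L,
                    families = list(fam),
                    stages = c("early2C", "late2C", "8C"),
                    depth_per_stage = 20000, protection_factor = 0.1,
                    copy_mutation_rate = 0,
                    planted_motifs = list(M_toy = motif),
                    tf_map = c(M_toy = "ToyTF"))
  gen <- make_te_genome(cfg)
  tracks <- simulate_atac(gen$truth, cfg)
  lib <- consensus_library(list(toyTE = cons))
  intact <- select_intact(gen$annotation, lib)
  profs <- lapply(tracks, build_meta_profile, intact = intact,
                  family = "toyTE", library = lib)
  calls <- call_family_footprints(profs)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$label, "late2C")
  ## >= 80% reciprocal overlap with the planted interval
  ov <- min(calls$end, 135) - max(calls$start, 120)
  expect_gte(ov / (calls$end - calls$start), 0.8)
  expect_gte(ov / 15, 0.8)
})

test_that("two planted sites are both recovered with no extra calls", {
  cfg <- default_sim_config(42L)
  cfg$protection_factor <- 0.1
  sim_truth <- make_te_genome(cfg)
  tracks <- simulate_atac(sim_truth$truth, cfg)
  lib <- consensus_library(stats::setNames(
    lapply(cfg$families, `[[`, "consensus"),
    vapply(cfg$families, `[[`, character(1), "name")))
  intact <- select_intact(sim_truth$annotation, lib)
  for (famspec in cfg$families) {
    fam <- famspec$name
    profs <- lapply(tracks, build_meta_profile, intact = intact,
                    family = fam, library = lib)
    calls <- call_family_footprints(profs)
    truth_sites <- sim_truth$truth$sites[sim_truth$truth$sites$family == fam, ]
    expect_equal(nrow(calls), nrow(truth_sites))
    for (i in seq_len(nrow(truth_sites))) {
      ov <- pmin(calls$end, truth_sites$end[i]) -
        pmax(calls$start, truth_sites$start[i])
      j <- which.max(ov)
      expect_gte(ov[j] / (calls$end[j] - calls$start[j]), 0.8)
      expect_gte(ov[j] / (truth_sites$end[i] - truth_sites$start[i]), 0.8)
    }
  }
})

test_that("footprint sequences extract with padding and clipping", {
  lib <- consensus_library(list(fam = "ACGTACGTAC"))
  seqs <- extract_footprint_sequence(lib, "fam", 2L, 7L, pad = 0L)
  expect_equal(unname(seqs["forward"]), "GTACG")
  expect_equal(unname(seqs["reverse"]), "CGTAC")
  clipped <- extract_footprint_sequence(lib, "fam", 1L, 4L, pad = 5L)
  expect_equal(unname(clipped["forward"]), "ACGTACGTA")
  ## planted-site sequence contains the planted motif consensus exactly
  cfg <- tiny_config(seed = 3L, mutation = 0.05)
  clib <- consensus_library(list(toyTE = cfg$families[[1]]$consensus))
  fp <- extract_footprint_sequence(clib, "toyTE", 120L, 135L, pad = 0L)
  expect_true(grepl("AAAAAAAAAA", fp["forward"]))
})
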