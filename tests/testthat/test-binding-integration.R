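test_that("constant tracks give constant matrices in both geometries", {
  tr <- signal_track(data.frame(chrom = "chr1", start = 0L, end = 100000L,
                                value = 5))
  iv <- data.frame(chrom = "chr1", start = c(10000L, 30000L),
                   end = c(10300L, 30450L), strand = c("+", "-"))
  bm <- matrix_scale_regions(tr, iv, body_bins = 10L, flank_bp = 1000L,
                             flank_bins = 10L)
  expect_true(all(bm$matrix == 5))
  pts <- data.frame(chrom = "chr1", pos = c(20000L, 50000L),
                    strand = c("+", "-"))
  rp <- matrix_reference_point(tr, pts)
  expect_true(all(rp$matrix == 5))
  expect_equal(ncol(rp$matrix), 200L)
})

test_that("body-only signal fills body bins and mirrors on the minus strand", {
  tr <- signal_track(data.frame(chrom = "chr1", start = 10000L, end = 10300L,
                                value = 10))
  iv <- data.frame(chrom = "chr1", start = 10000L, end = 10300L,
                   strand = "+", name = "elt")
  bm <- matrix_scale_regions(tr, iv, body_bins = 6L, flank_bp = 300L,
                             flank_bins = 3L)
  expect_equal(unname(bm$matrix[1, ]), c(rep(0, 3), rep(10, 6), rep(0, 3)))
  ## asymmetric signal mirrors for a minus-strand row
  tr2 <- signal_track(data.frame(chrom = "chr1", start = 10000L,
                                 end = 10150L, value = 8))
  ivp <- data.frame(chrom = "chr1", start = 10000L, end = 10300L, strand = "+")
  ivm <- transform(ivp, strand = "-")
  rp <- matrix_scale_regions(tr2, ivp, 6L, 300L, 3L)$matrix[1, ]
  rm_ <- matrix_scale_regions(tr2, ivm, 6L, 300L, 3L)$matrix[1, ]
  expect_equal(rm_, rev(rp))
})

test_that("a delta signal at the TSS lands in the central bin only", {
  tr <- signal_track(data.frame(chrom = "chr1", start = 5000L, end = 5001L,
                                value = 100))
  pts <- data.frame(chrom = "chr1", pos = 5000L, strand = "+")
  rp <- matrix_reference_point(tr, pts, upstream_bp = 100L,
                               downstream_bp = 100L, bin_bp = 10L)
  expect_equal(which(rp$matrix[1, ] > 0), 11L)    # first downstream bin
  expect_equal(rp$matrix[1, 11], 100 / 10)
  ## near-edge points flag and zero-fill the missing bins
  edge <- matrix_reference_point(tr, data.frame(chrom = "chr1", pos = 40L,
                                                strand = "+"),
                                 upstream_bp = 100L, downstream_bp = 100L,
                                 bin_bp = 10L)
  expect_true(edge$edge_flag[1])
  expect_true(all(edge$matrix[1, 1:6] == 0))
})

test_that("scale-regions equals the per-base brute-force reference", {
  df <- make_random_track(100000L, seed = 11L)
  tr <- signal_track(df)
  vals <- expand_track(df, 100000L)
  set.seed(12)
  iv <- data.frame(chrom = "chr1",
                   start = sample(5000:80000, 20L))
  iv$end <- iv$start + sample(c(120L, 300L, 777L), 20L, replace = TRUE)
  iv$strand <- sample(c("+", "-"), 20L, replace = TRUE)
  bm <- matrix_scale_regions(tr, iv, body_bins = 7L, flank_bp = 500L,
                             flank_bins = 5L)
  for (r in seq_len(nrow(iv))) {
    i <- which(bm$intervals$start == iv$start[r])[1]
    want <- oracle_scale_row(vals, iv$start[r], iv$end[r], 500L, 7L, 5L,
                             minus = iv$strand[r] == "-")
    expect_equal(unname(bm$matrix[i, ]), want, tolerance = 1e-9)
  }
})

test_that("reference-point equals the per-base brute-force reference", {
  df <- make_random_track(60000L, seed = 21L)
  tr <- signal_track(df)
  vals <- expand_track(df, 60000L)
  set.seed(22)
  pts <- data.frame(chrom = "chr1", pos = sample(2000:50000, 15L),
                    strand = sample(c("+", "-"), 15L, replace = TRUE))
  rp <- matrix_reference_point(tr, pts, upstream_bp = 500L,
                               downstream_bp = 500L, bin_bp = 20L)
  for (r in seq_len(nrow(pts))) {
    i <- which(rp$intervals$pos == pts$pos[r])[1]
    window <- vals[(pts$pos[r] - 500 + 1):(pts$pos[r] + 500)]
    want <- vapply(seq_len(50), function(b) {
      mean(window[((b - 1) * 20 + 1):(b * 20)])
    }, numeric(1))
    if (pts$strand[r] == "-") want <- rev(want)
    expect_equal(unname(rp$matrix[i, ]), want, tolerance = 1e-9)
  }
})

test_that("top-quartile selection ranks by row sum with stable ties", {
  m <- structure(list(matrix = matrix(c(8:1), nrow = 8, ncol = 4),
                      intervals = data.frame(id = paste0("r", 1:8))),
                 class = "binding_matrix")
  top <- top_quartile_bound(m, 0.25)
  expect_equal(nrow(top), 2L)
  expect_equal(top$id, c("r1", "r2"))
  expect_equal(nrow(top_quartile_bound(m, 1.0)), 8L)
  ties <- structure(list(matrix = matrix(1, nrow = 8, ncol = 4),
                         intervals = data.frame(id = paste0("r", 1:8))),
                    class = "binding_matrix")
  expect_equal(top_quartile_bound(ties, 0.25)$id, c("r1", "r2"))
  ## monotone nesting over fractions
  for (f in c(0.1, 0.25, 0.5, 0.9)) {
    expect_true(all(top_quartile_bound(m, f)$id %in%
                      top_quartile_bound(m, min(1, f + 0.25))$id))
  }
})

test_that("TSS-to-insertion distance honours the 10 kb boundary inclusively", {
  genes <- data.frame(gene = c("gA", "gB", "gC", "gD"),
                      chrom = "chr1",
                      tss = c(5000L, 1000L, 12100L, 2000L),
                      lfc = c(-1, 0.5, -2, 3))
  ins <- data.frame(chrom = "chr1", start = 12000L, end = 12300L)
  near <- genes_near_insertions(genes, ins, 10000L)
  expect_setequal(near$gene, c("gA", "gC", "gD"))
  expect_equal(near$distance[near$gene == "gA"], 7000)
  expect_equal(near$distance[near$gene == "gC"], 0)       # TSS inside
  expect_equal(near$distance[near$gene == "gD"], 10000)   # exactly 10 kb: in
  ## one bp further is out
  far <- data.frame(gene = "gE", chrom = "chr1", tss = 1999L, lfc = 0)
  expect_equal(nrow(genes_near_insertions(far, ins, 10000L)), 0L)
  ## monotone in window
  for (w in c(0L, 5000L, 10000L, 20000L)) {
    expect_true(all(genes_near_insertions(genes, ins, w)$gene %in%
                      genes_near_insertions(genes, ins, w + 5000L)$gene))
  }
})

test_that("the group comparison matches the closed-form Welch t-test", {
  bound <- c(-1.2, -0.8, -1.5, -0.3, -1.0)
  all_g <- c(-0.2, 0.1, -0.4, 0.3, 0.0, -0.1, 0.2)
  res <- compare_lfc_groups(bound, all_g)
  ## closed-form Welch
  n1 <- length(bound); n2 <- length(all_g)
  v1 <- var(bound); v2 <- var(all_g)
  t_hand <- (mean(bound) - mean(all_g)) / sqrt(v1 / n1 + v2 / n2)
  df_hand <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  ## identical groups: t = 0, p = 1
  same <- c(1, 2, 3, 4)
  res0 <- compare_lfc_groups(same, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  ## clearly separated means
  res1 <- compare_lfc_groups(c(0, 0.01, -0.01, 0.005),
                             c(1, 1.01, 0.99, 1.02))
  expect_lt(res1$p, 0.01)
  expect_error(compare_lfc_groups(c(1, 1), c(1, 2)), "variance")
  ## pooled-variance flag reproduces Student's t
  st <- compare_lfc_groups(bound, all_g, var_equal = TRUE)
  expect_equal(st$df, n1 + n2 - 2)
})

test_that("bedGraph tracks round-trip through the reader", {
  df <- make_random_track(5000L, seed = 31L)
  f <- tempfile(fileext = ".bedgraph")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  tr <- read_bedgraph(f)
  expect_equal(tr$per_chrom$chr1$value, df$value)
  expect_error(signal_track(data.frame(chrom = "c", start = 0L, end = 10L,
                                       value = -1)), ">= 0")
})
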