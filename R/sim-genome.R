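#' Generate a toy genome with planted TE copies
#'
#' Builds a random single-chromosome genome (`chrS`) and plants, per family,
#' `n_intact` copies of exactly consensus length plus `n_truncated` copies
#' truncated from the 3' end. Copies are placed non-overlapping at uniform
#' random positions with uniform random strand; each copy is the consensus
#' (reverse-complemented on the minus strand) with i.i.d. substitutions at
#' `copy_mutation_rate`, except that planted-site positions are never
#' mutated. The annotation is BED6-style with the family name in the name
#' column.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genome` (a named
#'   [Biostrings::DNAStringSet]), `annotation` (a BED6-style data frame with
#'   columns chrom, start, end, name, score, strand plus `copy_id`), and
#'   `truth` (ground-truth tables: `copies`, `sites`, `genomic_sites`,
#'   `planted_tfs`).
#' @export
make_te_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 0L), {
    L <- config$genome_length
    genome <- sample(DNA_BASES, L, replace = TRUE)

    ## plan copy lengths
    plan <- do.call(rbind, lapply(config$families, function(f) {
      clen <- nchar(f$consensus)
      n <- f$n_intact + f$n_truncated
      if (n == 0L) return(NULL)
      trunc_len <- if (f$n_truncated > 0L) {
        pmax(1L, as.integer(floor(clen * runif(f$n_truncated, 0.3, 0.8))))
      } else integer(0)
      data.frame(family = f$name,
                 copy_id = sprintf("%s_%03d", f$name, seq_len(n)),
                 length = c(rep(clen, f$n_intact), trunc_len),
                 intact = rep(c(TRUE, FALSE), c(f$n_intact, f$n_truncated)),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(plan)) stop("no copies requested in any family")

    ## non-overlapping uniform placement with bounded retries
    placed <- IRanges::IRanges()
    starts <- integer(nrow(plan))
    for (i in seq_len(nrow(plan))) {
      w <- plan$length[i]
      ok <- FALSE
      for (try in seq_len(200L)) {
        s <- sample.int(L - w + 1L, 1L) - 1L          # 0-based start
        cand <- IRanges::IRanges(s + 1L, s + w)
        if (length(IRanges::findOverlaps(cand, placed)) == 0L) {
          placed <- c(placed, cand)
          starts[i] <- s
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("genome too small: failed to place copies without overlap")
    }
    plan$start <- starts
    plan$end <- starts + plan$length
    plan$strand <- sample(c("+", "-"), nrow(plan), replace = TRUE)

    fam_by_name <- stats::setNames(config$families,
                                   vapply(config$families, `[[`, character(1),
                                          "name"))

    ## per-copy sequence: consensus prefix, mutated outside planted sites
    gsites <- list()
    for (i in seq_len(nrow(plan))) {
      f <- fam_by_name[[plan$family[i]]]
      cons <- strsplit(f$consensus, "")[[1]]
      w <- plan$length[i]
      seq <- cons[seq_len(w)]
      protected <- logical(w)
      for (s in f$planted_sites) {
        idx <- seq.int(s$start + 1L, s$end)
        idx <- idx[idx <= w]
        protected[idx] <- TRUE
        if (length(idx) == (s$end - s$start)) {
          ## full site present in this copy: record genomic interval
          if (plan$strand[i] == "+") {
            gs <- plan$start[i] + s$start
            ge <- plan$start[i] + s$end
          } else {
            gs <- plan$end[i] - s$end
            ge <- plan$end[i] - s$start
          }
          gsites[[length(gsites) + 1L]] <-
            data.frame(copy_id = plan$copy_id[i], family = f$name,
                       chrom = "chrS", start = gs, end = ge,
                       motif_id = s$motif_id,
                       occupied = paste(s$occupied, collapse = ","),
                       stringsAsFactors = FALSE)
        }
      }
      if (config$copy_mutation_rate > 0) {
        hit <- which(runif(w) < config$copy_mutation_rate & !protected)
        for (j in hit) {
          seq[j] <- sample(setdiff(DNA_BASES, seq[j]), 1L)
        }
      }
      if (plan$strand[i] == "-") {
        seq <- rev(chartr("ACGT", "TGCA", seq))
      }
      genome[seq.int(plan$start[i] + 1L, plan$end[i])] <- seq
    }

    genome_str <- paste(genome, collapse = "")
    genome_set <- Biostrings::DNAStringSet(genome_str)
    names(genome_set) <- "chrS"

    annotation <- data.frame(chrom = "chrS", start = plan$start,
                             end = plan$end, name = plan$family,
                             score = 0L, strand = plan$strand,
                             copy_id = plan$copy_id,
                             stringsAsFactors = FALSE)
    sites <- do.call(rbind, lapply(config$families, function(f) {
      if (length(f$planted_sites) == 0L) return(NULL)
      do.call(rbind, lapply(f$planted_sites, function(s) {
        data.frame(family = f$name, start = s$start, end = s$end,
                   motif_id = s$motif_id,
                   occupied = paste(s$occupied, collapse = ","),
                   stringsAsFactors = FALSE)
      }))
    }))
    truth <- list(
      copies = data.frame(copy_id = plan$copy_id, chrom = "chrS",
                          start = plan$start, end = plan$end,
                          strand = plan$strand, family = plan$family,
                          intact = plan$intact, stringsAsFactors = FALSE),
      sites = sites,
      genomic_sites = if (length(gsites)) do.call(rbind, gsites) else NULL,
      planted_tfs = if (is.null(sites)) character(0) else
        unname(config$tf_map[unique(sites$motif_id)]))
    list(genome = genome_set, annotation = annotation, truth = truth)
  })
}
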