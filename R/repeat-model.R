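#' Consensus sequence library
#'
#' Maps each TE family name to its Repbase-style consensus sequence. The
#' consensus defines the coordinate frame onto which all intact genomic
#' copies are projected.
#'
#' @param sequences Named list or named character vector of uppercase ACGTN
#'   sequences (names are family names).
#' @return A `consensus_library` object.
#' @export
consensus_library <- function(sequences) {
  sequences <- as.list(sequences)
  if (length(sequences) == 0L || is.null(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("sequences must be a non-empty named list")
  }
  seqs <- vapply(sequences, as.character, character(1))
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("consensus sequences must be uppercase ACGTN")
  }
  structure(list(sequences = as.list(seqs), lengths = nchar(seqs)),
            class = "consensus_library")
}

#' Families in a consensus library
#' @param library A [consensus_library()].
#' @return Character vector of family names.
#' @export
consensus_families <- function(library) names(library$sequences)

#' Consensus length of a family
#' @param library A [consensus_library()].
#' @param family Family name.
#' @return Consensus length in bp.
#' @export
consensus_length <- function(library, family) {
  if (!family %in% names(library$sequences)) {
    stop(sprintf("family '%s' not in consensus library", family))
  }
  unname(library$lengths[family])
}

#' Read a TE annotation
#'
#' Reads TE copies from a BED6 file or a RepeatMasker `.out` file and
#' normalises coordinates to 0-based half-open (RepeatMasker coordinates are
#' 1-based inclusive and are shifted). Records whose family is absent from
#' an optional consensus library are retained but flagged
#' (`known_family = FALSE`).
#'
#' @param path Annotation file.
#' @param dialect `"bed6"` or `"repeatmasker_out"`.
#' @param library Optional [consensus_library()] used to flag families.
#' @return Data frame of TE copies: copy_id, chrom, start, end, strand,
#'   family, length, known_family.
#' @export
load_annotation <- function(path, dialect = c("bed6", "repeatmasker_out"),
                            library = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  if (dialect == "bed6") {
    keep <- which(nzchar(trimws(lines)))
    recs <- lapply(keep, function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 6L) stop(sprintf("malformed BED line %d in %s", i, path))
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end) || end <= start) {
        stop(sprintf("malformed BED line %d in %s", i, path))
      }
      data.frame(chrom = f[1], start = start, end = end, family = f[4],
                 strand = f[6], stringsAsFactors = FALSE)
    })
  } else {
    ## RepeatMasker .out: 3 header lines, whitespace-separated columns;
    ## cols 5-7 = query chrom, begin (1-based), end (inclusive); 9 = strand
    ## (+ or C); 10 = repeat name
    body <- lines[nzchar(trimws(lines))]
    body <- body[!grepl("^\\s*(SW|score|perc)", body)]
    recs <- lapply(seq_along(body), function(i) {
      f <- strsplit(trimws(body[i]), "\\s+")[[1]]
      if (length(f) < 10L) {
        stop(sprintf("malformed RepeatMasker line %d in %s", i, path))
      }
      begin <- suppressWarnings(as.integer(f[6]))
      end <- suppressWarnings(as.integer(f[7]))
      if (is.na(begin) || is.na(end) || end < begin) {
        stop(sprintf("malformed RepeatMasker line %d in %s", i, path))
      }
      data.frame(chrom = f[5], start = begin - 1L, end = end,
                 family = f[10],
                 strand = if (f[9] == "C") "-" else f[9],
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, recs)
  dot <- out$strand == "."
  if (any(dot)) {
    warning(sprintf("%d record(s) with strand '.'; treated as '+'", sum(dot)))
    out$strand[dot] <- "+"
  }
  if (!all(out$strand %in% c("+", "-"))) stop("invalid strand field")
  out$length <- out$end - out$start
  out$copy_id <- sprintf("%s_%06d", out$family, seq_len(nrow(out)))
  out$known_family <- if (is.null(library)) TRUE else
    out$family %in% consensus_families(library)
  out[, c("copy_id", "chrom", "start", "end", "strand", "family", "length",
          "known_family")]
}

#' Write TE copies as BED6
#'
#' @param copies Data frame with chrom, start, end, name (or family),
#'   strand columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(copies, path) {
  name <- if ("name" %in% names(copies)) copies$name else copies$family
  bed <- data.frame(copies$chrom, copies$start, copies$end, name,
                    if ("score" %in% names(copies)) copies$score else 0L,
                    copies$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Select length-intact TE copies
#'
#' A copy is intact when its length matches the family consensus length
#' within `tolerance_bp` (default 0: the copy corresponds exactly to the
#' consensus length). Copies of families missing from the library are
#' skipped with a warning.
#'
#' @param copies Data frame from [load_annotation()] (or the simulator
#'   annotation with a `family` or `name` column).
#' @param library A [consensus_library()].
#' @param tolerance_bp Non-negative length tolerance in bp.
#' @return An `intact_set`: list with `copies` (retained data frame),
#'   `tolerance_bp`, and per-family retained/discarded `counts`.
#' @export
select_intact <- function(copies, library, tolerance_bp = 0L) {
  stopifnot_scalar_int(tolerance_bp, "tolerance_bp", min = 0)
  if (!"family" %in% names(copies) && "name" %in% names(copies)) {
    copies$family <- copies$name
  }
  copies$length <- copies$end - copies$start
  known <- copies$family %in% consensus_families(library)
  if (any(!known)) {
    warning(sprintf("%d cop(ies) of families absent from the library skipped",
                    sum(!known)))
  }
  cc <- copies[known, , drop = FALSE]
  clen <- library$lengths[cc$family]
  keep <- abs(cc$length - clen) <= tolerance_bp
  counts <- do.call(rbind, lapply(split(keep, cc$family), function(k) {
    data.frame(retained = sum(k), discarded = sum(!k))
  }))
  structure(list(copies = cc[keep, , drop = FALSE],
                 tolerance_bp = as.integer(tolerance_bp),
                 counts = counts),
            class = "intact_set")
}

#' Place monomer copies by Hamming-distance scan
#'
#' Reports every genomic window of monomer length, on both strands, within
#' `max_mismatches` substitutions of the monomer consensus (no gaps).
#' Overlapping hits on the same strand are resolved by keeping the
#' lower-distance hit, ties going to the leftmost. Used for L1-style 5'UTR
#' monomers, which are annotated by sequence match rather than RepeatMasker.
#'
#' @param genome A named [Biostrings::DNAStringSet] (or single sequence).
#' @param monomer Monomer consensus sequence (>= 15 bp).
#' @param max_mismatches Maximum substitutions per hit.
#' @param family Family name to assign to the hits.
#' @return Data frame of TE copies (copy_id, chrom, start, end, strand,
#'   family, length, mismatches).
#' @export
place_monomers <- function(genome, monomer, max_mismatches = 2L,
                           family = "monomer") {
  if (nchar(monomer) < 15L) stop("monomer length must be >= 15 bp")
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(genome)
    if (is.null(names(genome))) names(genome) <- "chr1"
  }
  pat_f <- Biostrings::DNAString(monomer)
  pat_r <- Biostrings::reverseComplement(pat_f)
  hits <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    for (str in c("+", "-")) {
      pat <- if (str == "+") pat_f else pat_r
      mt <- Biostrings::matchPattern(pat, subj,
                                     max.mismatch = max_mismatches,
                                     with.indels = FALSE)
      if (length(mt) == 0L) next
      mm <- Biostrings::neditStartingAt(pat, subj,
                                        starting.at = IRanges::start(mt))
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = IRanges::start(mt) - 1L,
        end = IRanges::end(mt), strand = str, mismatches = as.integer(mm),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(copy_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), family = character(0),
                      length = integer(0), mismatches = integer(0)))
  }
  df <- do.call(rbind, hits)
  ## same-strand overlap resolution: best (fewest mismatches), ties leftmost
  keep <- rep(TRUE, nrow(df))
  for (grp in split(seq_len(nrow(df)), paste(df$chrom, df$strand))) {
    sub <- df[grp, ]
    ord <- grp[order(sub$mismatches, sub$start)]
    taken <- IRanges::IRanges()
    for (i in ord) {
      cand <- IRanges::IRanges(df$start[i] + 1L, df$end[i])
      if (length(IRanges::findOverlaps(cand, taken)) > 0L) {
        keep[i] <- FALSE
      } else {
        taken <- c(taken, cand)
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
  df$family <- family
  df$length <- df$end - df$start
  df$copy_id <- sprintf("%s_%06d", family, seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("copy_id", "chrom", "start", "end", "strand", "family", "length",
         "mismatches")]
}

#' Project a genomic position onto consensus coordinates
#'
#' For a length-intact copy, the projection is a linear offset: on the plus
#' strand `pos - start`, on the minus strand `(end - 1) - pos`. The result
#' indexes the family consensus (0-based).
#'
#' @param copy One-row data frame (or list) with start, end, strand, and
#'   optionally family/length.
#' @param genomic_position 0-based genomic position(s) within the copy.
#' @param consensus_len Consensus length; when supplied the copy must match
#'   it exactly (projection is defined only for intact copies).
#' @return Integer consensus position(s) in `[0, consensus length)`.
#' @export
project_to_consensus <- function(copy, genomic_position,
                                 consensus_len = NULL) {
  start <- copy$start
  end <- copy$end
  if (!is.null(consensus_len) && (end - start) != consensus_len) {
    stop("projection requires an intact copy (length equal to consensus)")
  }
  if (any(genomic_position < start | genomic_position >= end)) {
    stop("genomic position outside the copy interval")
  }
  if (copy$strand == "+") {
    as.integer(genomic_position - start)
  } else {
    as.integer((end - 1L) - genomic_position)
  }
}

#' Inverse of [project_to_consensus()]
#'
#' @param copy One-row data frame (or list) with start, end, strand.
#' @param consensus_position 0-based consensus position(s).
#' @return 0-based genomic position(s).
#' @export
consensus_to_genomic <- function(copy, consensus_position) {
  len <- copy$end - copy$start
  if (any(consensus_position < 0 | consensus_position >= len)) {
    stop("consensus position outside [0, copy length)")
  }
  if (copy$strand == "+") {
    as.integer(copy$start + consensus_position)
  } else {
    as.integer((copy$end - 1L) - consensus_position)
  }
}
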