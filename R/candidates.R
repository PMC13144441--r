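#' Expression matrix with stage labels
#'
#' Genes/TFs in rows, cells (or embryos) in columns, non-negative integer
#' counts, with one stage label per column.
#'
#' @param counts Matrix with row names (genes) and column names (cells).
#' @param stages Character vector of stage labels, one per column.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(counts, stages) {
  if (!is.matrix(counts) || is.null(rownames(counts))) {
    stop("counts must be a matrix with row names")
  }
  if (length(stages) != ncol(counts)) {
    stop("one stage label per column is required")
  }
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(list(counts = counts, stages = as.character(stages)),
            class = "expression_matrix")
}

#' Write/read an expression matrix as TSV with a stage header row
#'
#' The first row after the header carries the stage label of each column.
#'
#' @param expr An [expression_matrix()].
#' @param path File path.
#' @return `path` (write) or an [expression_matrix()] (read).
#' @export
write_expression_tsv <- function(expr, path) {
  hdr <- c("gene", colnames(expr$counts))
  stage_row <- c("stage", expr$stages)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  writeLines(paste(stage_row, collapse = "\t"), con)
  for (i in seq_len(nrow(expr$counts))) {
    writeLines(paste(c(rownames(expr$counts)[i], expr$counts[i, ]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  stage_row <- strsplit(lines[2], "\t")[[1]]
  if (stage_row[1] != "stage") stop("second row must be the stage label row")
  body <- strsplit(lines[-(1:2)], "\t")
  genes <- vapply(body, `[[`, character(1), 1L)
  counts <- t(vapply(body, function(f) as.numeric(f[-1]),
                     numeric(length(hdr) - 1L)))
  rownames(counts) <- genes
  colnames(counts) <- hdr[-1]
  expression_matrix(counts, stage_row[-1])
}

#' Library-size (rpm) normalisation
#'
#' Divides each column by its total count over detected genes and scales to
#' reads per million.
#'
#' @param expr An [expression_matrix()] or a plain matrix.
#' @return Matrix of rpm values (columns sum to 1e6).
#' @export
rpm_normalize <- function(expr) {
  counts <- if (inherits(expr, "expression_matrix")) expr$counts else expr
  cs <- colSums(counts)
  zero <- which(cs == 0)
  if (length(zero) > 0L) {
    nm <- colnames(counts)[zero[1]]
    stop(sprintf("column '%s' has zero total count",
                 if (is.null(nm)) as.character(zero[1]) else nm))
  }
  sweep(counts, 2, cs, "/") * 1e6
}

#' Filter candidate TFs by embryonic expression
#'
#' A TF is retained when its raw count is at least `min_reads` in every cell
#' of the given stages (by default mid and late 2-cell). TFs absent from the
#' matrix are dropped with a warning.
#'
#' @param expr An [expression_matrix()].
#' @param tf_list Character vector of TF names to test.
#' @param stages Stages whose cells must all pass.
#' @param min_reads Minimum raw count per cell.
#' @return Character vector of retained TF names (input order).
#' @export
expression_filter <- function(expr, tf_list, stages = c("mid2C", "late2C"),
                              min_reads = 2L) {
  stopifnot(inherits(expr, "expression_matrix"))
  for (s in stages) {
    if (!s %in% expr$stages) stop(sprintf("no columns labelled stage '%s'", s))
  }
  cols <- expr$stages %in% stages
  missing <- setdiff(tf_list, rownames(expr$counts))
  if (length(missing) > 0L) {
    warning(sprintf("%d TF(s) absent from the expression matrix dropped: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }
  present <- tf_list[tf_list %in% rownames(expr$counts)]
  keep <- vapply(present, function(tf) {
    all(expr$counts[tf, cols] >= min_reads)
  }, logical(1))
  present[keep]
}

#' Merge per-family candidate TFs
#'
#' Groups motif matches across all footprints and strands within each
#' family (unique, sorted TF names) and takes the union across families.
#' Per TF and family the best (smallest) E-value and its supporting
#' footprint/strand are kept as provenance.
#'
#' @param matches Match table from [scan_footprints()] (columns family, tf,
#'   footprint_index, strand, evalue), typically already restricted to
#'   expression-filtered TFs.
#' @return A `candidate_set`: list with `per_family` (named list of sorted
#'   TF vectors), `merged` (sorted union), `provenance` (data frame).
#' @export
merge_candidates <- function(matches) {
  if (is.null(matches) || nrow(matches) == 0L) {
    return(structure(list(per_family = list(), merged = character(0),
                          provenance = data.frame()),
                     class = "candidate_set"))
  }
  per_family <- lapply(split(matches$tf, matches$family),
                       function(x) sort(unique(x)))
  prov <- do.call(rbind, lapply(
    split(matches, list(matches$family, matches$tf), drop = TRUE),
    function(d) d[which.min(d$evalue), c("family", "tf", "footprint_index",
                                         "strand", "evalue")]))
  prov <- prov[order(prov$family, prov$tf), , drop = FALSE]
  rownames(prov) <- NULL
  structure(list(per_family = per_family,
                 merged = sort(unique(matches$tf)),
                 provenance = prov),
            class = "candidate_set")
}

#' Venn region sizes of per-family candidate sets
#'
#' Sizes of every exclusive intersection region (inclusion-exclusion
#' consistent: region sizes sum to the size of the union).
#'
#' @param candidates A `candidate_set` with at least 2 families.
#' @return Data frame with columns `region` (family names joined with "&")
#'   and `count`.
#' @export
venn_counts <- function(candidates) {
  sets <- candidates$per_family
  k <- length(sets)
  if (k < 2L) stop("venn_counts needs at least 2 families")
  fams <- names(sets)
  all_tfs <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_tfs %in% s,
                       logical(length(all_tfs)))
  if (length(all_tfs) == 1L) membership <- matrix(membership, nrow = 1L,
                                                  dimnames = list(NULL, fams))
  pattern <- apply(membership, 1L, function(r) paste(fams[r], collapse = "&"))
  regions <- unlist(lapply(seq_len(k), function(m) {
    apply(utils::combn(fams, m), 2L, paste, collapse = "&")
  }))
  counts <- vapply(regions, function(r) sum(pattern == r), integer(1))
  data.frame(region = regions, count = unname(counts),
             stringsAsFactors = FALSE)
}

#' Per-embryo family expression profile
#'
#' Sums, per embryo, the rpm of all insertions belonging to one TE family,
#' optionally divides by a per-embryo ERCC normalisation factor, and returns
#' per-stage means (the trend line across stages).
#'
#' @param insertions Data frame with columns embryo, stage, family, rpm
#'   (one row per insertion per embryo).
#' @param family Family name.
#' @param ercc_factors Optional named numeric vector of per-embryo ERCC
#'   factors (rpm is divided by the factor).
#' @return List with `per_embryo` (embryo, stage, total) and `stage_means`
#'   (stage, mean_total), stages ordered as first encountered.
#' @export
family_expression_profile <- function(insertions, family,
                                      ercc_factors = NULL) {
  if (!family %in% insertions$family) {
    stop(sprintf("unknown family '%s'", family))
  }
  sub <- insertions[insertions$family == family, , drop = FALSE]
  emb <- unique(sub[, c("embryo", "stage")])
  total <- vapply(seq_len(nrow(emb)), function(i) {
    sum(sub$rpm[sub$embryo == emb$embryo[i]])
  }, numeric(1))
  if (!is.null(ercc_factors)) {
    if (!all(emb$embryo %in% names(ercc_factors))) {
      stop("ercc_factors must cover every embryo")
    }
    total <- total / unname(ercc_factors[emb$embryo])
  }
  per_embryo <- data.frame(embryo = emb$embryo, stage = emb$stage,
                           total = total, stringsAsFactors = FALSE)
  stages <- unique(per_embryo$stage)
  stage_means <- data.frame(
    stage = stages,
    mean_total = vapply(stages, function(s) {
      mean(per_embryo$total[per_embryo$stage == s])
    }, numeric(1)), stringsAsFactors = FALSE)
  list(per_embryo = per_embryo, stage_means = stage_means)
}
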