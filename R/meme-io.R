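## MEME minimal-format motif input/output and PWM constructors.

#' Construct a PWM object
#'
#' @param id Motif identifier (unique within a library).
#' @param matrix 4 x width matrix of column probabilities, rows in A,C,G,T
#'   order; each column must sum to 1 within 1e-6.
#' @param name TF (alternate) name; defaults to the id.
#' @return A `pwm` object.
#' @export
pwm <- function(id, matrix, name = id) {
  if (!is_string(id)) stop("motif id must be a single string")
  if (!is.matrix(matrix) || nrow(matrix) != 4L) {
    stop(sprintf("motif '%s': matrix must have 4 rows (A,C,G,T)", id))
  }
  if (ncol(matrix) < 1L) stop(sprintf("motif '%s': empty matrix", id))
  if (any(matrix < 0)) stop(sprintf("motif '%s': negative probabilities", id))
  if (any(abs(colSums(matrix) - 1) > 1e-6)) {
    stop(sprintf("motif '%s': columns must sum to 1", id))
  }
  rownames(matrix) <- DNA_BASES
  structure(list(id = id, name = name, matrix = matrix,
                 width = ncol(matrix)), class = "pwm")
}

## Round columns to 6 decimals, absorbing the residual into the largest
## entry so each column sums to exactly 1 at the printed precision.
normalize_pwm_columns <- function(m) {
  m <- sweep(m, 2, colSums(m), "/")
  for (j in seq_len(ncol(m))) {
    col <- round(m[, j], 6)
    k <- which.max(col)
    col[k] <- round(col[k] + (1 - sum(col)), 6)
    m[, j] <- col
  }
  m
}

#' Reverse-complement a PWM matrix
#'
#' Reverses the column order and swaps complementary base rows.
#'
#' @param m 4 x W probability matrix (rows A,C,G,T).
#' @return The reverse-complement matrix.
#' @export
revcomp_pwm <- function(m) {
  out <- m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

#' Write motifs in MEME minimal format
#'
#' @param motifs List of [pwm()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  ids <- vapply(motifs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate motif id in library")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m$id, m$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       m$width), con)
    for (j in seq_len(m$width)) {
      writeLines(paste(sprintf("%.6f", m$matrix[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal-format motif file
#'
#' Parses `letter-probability matrix` blocks; the alphabet must be ACGT.
#'
#' @param path MEME minimal file.
#' @return Named list of [pwm()] objects (names are motif ids).
#' @export
read_meme <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  alpha <- grep("^ALPHABET=", lines, value = TRUE)
  if (length(alpha) > 0L && !grepl("ACGT", alpha[1])) {
    stop("alphabet must be ACGT")
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) stop("no MOTIF blocks found")
  motifs <- list()
  for (s in starts) {
    toks <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    id <- toks[2]
    name <- if (length(toks) >= 3L) toks[3] else id
    h <- s + 1L
    while (h <= length(lines) && !grepl("^letter-probability matrix", lines[h])) {
      h <- h + 1L
    }
    if (h > length(lines)) stop(sprintf("motif '%s': missing matrix header", id))
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1L):(h + w)]
    m <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4), USE.NAMES = FALSE))
    m <- t(m)  # back to 4 x w
    bad <- which(abs(colSums(m) - 1) > 1e-3)
    if (length(bad) > 0L) {
      stop(sprintf("motif '%s': column %d is not stochastic", id, bad[1]))
    }
    m <- sweep(m, 2, colSums(m), "/")  # absorb printed-precision rounding
    motifs[[id]] <- pwm(id, m, name)
  }
  motifs
}
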