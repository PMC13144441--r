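## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic sub-seed derivation; stays within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483587)
}

## Stable content hash of a character string (for content-keyed sub-seeds).
seq_hash <- function(x) {
  codes <- utf8ToInt(x)
  as.integer(sum(codes * (seq_along(codes) %% 97 + 1)) %% 1000003)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stopifnot_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x)) {
    stop(sprintf("%s must be a single integer", name))
  }
  if (!is.null(min) && x < min) {
    stop(sprintf("%s must be >= %s", name, min))
  }
  invisible(TRUE)
}

## Mean of `values` over `nbins` equal-width bins with proportional
## (fractional) overlap at bin boundaries. Length-weighted per-base mean.
bin_mean <- function(values, nbins) {
  L <- length(values)
  if (nbins < 1L) stop("nbins must be >= 1")
  if (L == 0L) return(rep(0, nbins))
  edges <- seq(0, L, length.out = nbins + 1L)
  out <- numeric(nbins)
  for (j in seq_len(nbins)) {
    a <- edges[j]
    b <- edges[j + 1L]
    lo <- floor(a)
    hi <- ceiling(b)
    tot <- 0
    for (i in seq.int(lo, hi - 1L)) {
      ov <- min(b, i + 1) - max(a, i)
      if (ov > 0) tot <- tot + values[i + 1L] * ov
    }
    out[j] <- tot / (b - a)
  }
  out
}
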