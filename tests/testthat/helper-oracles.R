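## Independent reference implementations used as oracles. These are written
## as plain loops, deliberately sharing no code with the package internals.

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

## Naive centred moving average with edge truncation.
oracle_smooth <- function(x, window) {
  h <- (window - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - h):min(n, i + h)
    out[i] <- mean(x[idx])
  }
  out
}

## Naive footprint caller implementing the published rule step by step.
oracle_call_footprints <- function(v, params) {
  n <- length(v)
  sm <- oracle_smooth(v, params$window)
  excl <- floor(params$w_min / 2)
  depleted <- logical(n)
  for (i in seq_len(n)) {
    idx <- integer(0)
    for (j in seq_len(n)) {
      d <- abs(j - i)
      if (d > excl && d <= excl + params$flank_bp) idx <- c(idx, j)
    }
    if (length(idx) == 0) next
    b <- mean(sm[idx])
    depleted[i] <- b > 0 && sm[i] < (1 - params$d_min) * b
  }
  ## maximal runs
  runs <- list()
  i <- 1
  while (i <= n) {
    if (depleted[i]) {
      j <- i
      while (j < n && depleted[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  ## merge runs separated by gap < w_min/2
  if (length(runs) > 1) {
    merged <- list(runs[[1]])
    for (k in 2:length(runs)) {
      last <- merged[[length(merged)]]
      gap <- runs[[k]][1] - last[2] - 1
      if (gap < params$w_min / 2) {
        merged[[length(merged)]] <- c(last[1], runs[[k]][2])
      } else merged[[length(merged) + 1]] <- runs[[k]]
    }
    runs <- merged
  }
  out <- data.frame(index = integer(0), start = integer(0), end = integer(0),
                    D = numeric(0))
  for (r in runs) {
    w <- r[2] - r[1] + 1
    if (w < params$w_min || w > params$w_max) next
    left <- sm[seq_len(n) < r[1] & seq_len(n) >= r[1] - params$flank_bp]
    right <- sm[seq_len(n) > r[2] & seq_len(n) <= r[2] + params$flank_bp]
    fl <- c(left, right)
    if (length(fl) == 0) next
    m_flank <- mean(fl)
    if (m_flank < params$c_min) next
    m_center <- mean(sm[r[1]:r[2]])
    D <- if (m_flank == 0) 0 else (m_flank - m_center) / m_flank
    out <- rbind(out, data.frame(index = NA, start = r[1] - 1, end = r[2],
                                 D = D))
  }
  if (nrow(out) > 0) out$index <- seq_len(nrow(out))
  out
}

## Naive column distance and brute-force motif alignment over every offset
## and both orientations, mirroring the documented tie-break.
oracle_align <- function(query, target, min_overlap = 4,
                         orientations = "both") {
  coldist <- function(a, b) sqrt(sum((a - b)^2))
  rc <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  Wq <- ncol(query)
  Wt <- ncol(target)
  cand <- list()
  oris <- if (orientations == "both") c("+", "-") else "+"
  for (ori in oris) {
    tt <- if (ori == "+") target else rc(target)
    for (o in (-Wq + min_overlap):(Wt - min_overlap)) {
      tot <- 0
      n_al <- 0
      for (j in seq_len(Wq)) {
        tj <- o + j
        if (tj >= 1 && tj <= Wt) {
          tot <- tot + coldist(query[, j], tt[, tj])
          n_al <- n_al + 1
        } else {
          tot <- tot + coldist(query[, j], rep(0.25, 4))
        }
      }
      if (n_al < min_overlap) next
      cand[[length(cand) + 1]] <- list(d = tot / Wq, o = o, ori = ori)
    }
  }
  ## pick min d; ties: "+" before "-", then smaller |o|, then negative o
  best <- cand[[1]]
  for (c2 in cand[-1]) {
    if (c2$d < best$d - 1e-12) best <- c2
    else if (abs(c2$d - best$d) <= 1e-12 && c2$ori == best$ori &&
             (abs(c2$o) < abs(best$o) ||
              (abs(c2$o) == abs(best$o) && c2$o < best$o))) best <- c2
  }
  best
}

## Brute-force Hamming scan over both strands of a genome string.
oracle_hamming_hits <- function(genome, monomer, max_mm) {
  g <- strsplit(genome, "")[[1]]
  w <- nchar(monomer)
  hits <- data.frame(start = integer(0), end = integer(0),
                     strand = character(0), mismatches = integer(0))
  for (strand in c("+", "-")) {
    pat <- strsplit(if (strand == "+") monomer else revcomp_chr(monomer),
                    "")[[1]]
    for (s in 0:(length(g) - w)) {
      mm <- sum(g[(s + 1):(s + w)] != pat)
      if (mm <= max_mm) {
        hits <- rbind(hits, data.frame(start = s, end = s + w,
                                       strand = strand, mismatches = mm))
      }
    }
  }
  hits
}

## Per-base reference for the scale-regions matrix geometry.
oracle_scale_row <- function(values_by_pos, s, e, flank_bp, body_bins,
                             flank_bins, minus = FALSE) {
  val <- function(p) if (p >= 0 && p < length(values_by_pos))
    values_by_pos[p + 1] else 0
  seg_mean_bins <- function(a, b, nb) {
    L <- b - a
    out <- numeric(nb)
    for (k in seq_len(nb)) {
      lo <- a + (k - 1) * L / nb
      hi <- a + k * L / nb
      tot <- 0
      p <- floor(lo)
      while (p < hi) {
        ov <- min(hi, p + 1) - max(lo, p)
        if (ov > 0) tot <- tot + val(p) * ov
        p <- p + 1
      }
      out[k] <- tot / (L / nb)
    }
    out
  }
  row <- c(seg_mean_bins(s - flank_bp, s, flank_bins),
           seg_mean_bins(s, e, body_bins),
           seg_mean_bins(e, e + flank_bp, flank_bins))
  if (minus) rev(row) else row
}

## Expand a bedGraph-style data frame to a per-base vector over [0, L).
expand_track <- function(df, L) {
  v <- numeric(L)
  for (i in seq_len(nrow(df))) {
    v[(df$start[i] + 1):df$end[i]] <- df$value[i]
  }
  v
}
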