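# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive algorithms distinct from the package's code
# paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# O(n^2) repeated-pass interval union with gap tolerance, on (start, end)
# 1-based closed pairs
bruteMerge <- function(starts, ends, maxGap = 0L) {
  repeat {
    n <- length(starts)
    mergedAny <- FALSE
    i <- 1L
    while (i <= length(starts)) {
      j <- i + 1L
      while (j <= length(starts)) {
        gap <- max(starts[i], starts[j]) - min(ends[i], ends[j]) - 1L
        if (gap <= maxGap) {
          starts[i] <- min(starts[i], starts[j])
          ends[i] <- max(ends[i], ends[j])
          starts <- starts[-j]; ends <- ends[-j]
          mergedAny <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!mergedAny) break
  }
  ord <- order(starts)
  list(starts = starts[ord], ends = ends[ord])
}

# all-pairs bp overlap between two sets of 1-based closed intervals
brutePairBp <- function(s1, e1, s2, e2) {
  total <- 0L
  for (i in seq_along(s1)) {
    for (j in seq_along(s2)) {
      ov <- min(e1[i], e2[j]) - max(s1[i], s2[j]) + 1L
      if (ov > 0L) total <- total + ov
    }
  }
  total
}

# brute-force BH from the step-up definition q_(i) = min_{j>=i} m p_(j) / j
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[ord] <- q
  out
}

# hypergeometric upper tail by direct combinatorial enumeration
bruteHyperUpper <- function(k, n, K, N) {
  iMax <- min(n, K)
  if (k > iMax) return(0)
  sum(vapply(k:iMax, function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

# G4Hunter per-base scoring by explicit character-by-character run scanning
bruteG4Base <- function(seqChar) {
  ch <- strsplit(seqChar, "")[[1]]
  n <- length(ch)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    b <- ch[i]
    j <- i
    while (j < n && ch[j + 1L] == b) j <- j + 1L
    runLen <- j - i + 1L
    val <- if (b == "G") min(runLen, 4L) else if (b == "C") -min(runLen, 4L) else 0
    out[i:j] <- val
    i <- j + 1L
  }
  out
}

# per-window mean of the brute per-base scores
bruteG4Window <- function(seqChar, window) {
  base <- bruteG4Base(seqChar)
  n <- length(base) - window + 1L
  vapply(seq_len(n), function(i) mean(base[i:(i + window - 1L)]), numeric(1))
}

randomDna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}
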