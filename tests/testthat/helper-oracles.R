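# Independent brute-force oracles, deliberately written without the package
# (or base helpers the package itself calls) on the checked path.

# Poisson upper tail P(X >= x | lambda) by direct term summation in log space
pois_tail_oracle <- function(x, lambda) {
  if (x <= 0) return(1)
  k <- x:(x + 3000)
  sum(exp(-lambda + k * log(lambda) - lgamma(k + 1)))
}

# Benjamini-Hochberg step-up by hand: sort, scale by m/rank, enforce
# monotonicity from the largest rank down, restore input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  pmin(q_sorted, 1)[order(o)]
}

# hypergeometric upper tail from the factorial formula
hyper_oracle <- function(fg_with, fg_n, bg_with, bg_n) {
  K <- fg_with + bg_with   # motif-containing sequences in the pool
  N <- fg_n + bg_n
  j <- fg_with:min(fg_n, K)
  sum(choose(K, j) * choose(N - K, fg_n - j)) / choose(N, fg_n)
}

# two-sample KS statistic by enumerating empirical CDF steps
ks_D_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# transcript-level FE sums by explicit looping
fe_sum_oracle <- function(peaks, transcript_ids) {
  out <- data.frame(transcript_id = transcript_ids, n_peaks = 0L,
                    fe_sum = 0, stringsAsFactors = FALSE)
  for (i in seq_along(transcript_ids)) {
    hit <- peaks$transcript_id == transcript_ids[i]
    out$n_peaks[i] <- sum(hit)
    out$fe_sum[i] <- sum(peaks$fe[hit])
  }
  out
}

# ZOOPS by explicit position-by-position scanning
zoops_oracle <- function(sequences, kmer) {
  k <- nchar(kmer)
  hits <- 0L
  for (s in toupper(sequences)) {
    found <- FALSE
    if (nchar(s) >= k) {
      for (i in seq_len(nchar(s) - k + 1)) {
        if (substr(s, i, i + k - 1) == kmer) { found <- TRUE; break }
      }
    }
    hits <- hits + found
  }
  hits
}
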