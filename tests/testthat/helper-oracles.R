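# Independent oracles used across the suite. These deliberately do not share
# code with the package: the transform oracle is a dense matrix construction,
# and the outlier-elimination oracle is a literal step-by-step trace.

# Dense one-level periodic analysis matrix for a filter pair: row k holds the
# filter placed at circular offset 2(k-1). Stacking lowpass rows over highpass
# rows gives the orthogonal analysis operator.
analysis_matrix <- function(n, lowpass, highpass) {
  nh <- n %/% 2L
  A <- matrix(0, nrow = n, ncol = n)
  for (k in seq_len(nh)) {
    for (m in seq_along(lowpass)) {
      col <- (2L * (k - 1L) + (m - 1L)) %% n + 1L
      A[k, col] <- A[k, col] + lowpass[m]
      A[nh + k, col] <- A[nh + k, col] + highpass[m]
    }
  }
  A
}

# Full J-level DWT by explicit matrix multiplication; returns the
# concatenated coefficient vector ordered (approx_J, detail_J, ..., detail_1).
matrix_dwt <- function(x, lowpass, highpass, levels) {
  n <- length(x)
  out <- x
  pos <- n # boundary between the part still being analysed and stored details
  for (j in seq_len(levels)) {
    A <- analysis_matrix(pos, lowpass, highpass)
    y <- as.numeric(A %*% out[seq_len(pos)])
    out[seq_len(pos)] <- y
    pos <- pos %/% 2L
  }
  out
}

# Literal trace of the recursive sqrt-range outlier elimination: round 1
# centres on the median, later rounds on the mean, closed intervals,
# stop when the survivor set is stable or a single ratio remains.
trace_outlier_elimination <- function(ratios) {
  survivors <- ratios
  first <- TRUE
  repeat {
    if (length(survivors) <= 1L) break
    centre <- if (first) median(survivors) else mean(survivors)
    first <- FALSE
    keep <- survivors[survivors >= centre - sqrt(centre) &
      survivors <= centre + sqrt(centre)]
    if (length(keep) == 0L) break
    if (length(keep) == length(survivors)) {
      survivors <- keep
      # one confirming mean-centred pass
      centre2 <- mean(survivors)
      keep2 <- survivors[survivors >= centre2 - sqrt(centre2) &
        survivors <= centre2 + sqrt(centre2)]
      if (length(keep2) == length(survivors) || length(keep2) == 0L) break
      survivors <- keep2
      next
    }
    survivors <- keep
  }
  mean(survivors)
}

# Clean Gaussian elution peak on a scan grid
gauss_peak <- function(n = 256, apex = n / 2, amplitude = 100, sigma = 5) {
  s <- seq_len(n)
  amplitude * exp(-(s - apex)^2 / (2 * sigma^2))
}
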