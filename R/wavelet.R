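#' Orthonormal wavelet filter banks
#'
#' Returns the analysis filter pair (lowpass/scaling, highpass/wavelet) of a
#' compactly supported orthonormal wavelet. Orthonormality is the property the
#' de-noiser relies on: the transform preserves signal energy exactly (sum of
#' squared coefficients equals sum of squared samples), so thresholding in the
#' coefficient domain has a direct energy interpretation in the signal domain.
#'
#' Supported families: `"haar"` (synonym `"db1"`) and Daubechies extremal-phase
#' wavelets `"db2"`, `"db3"`, `"db4"` (the name is the number of vanishing
#' moments; `"db4"` has 8 taps). The highpass filter is the quadrature mirror
#' of the lowpass: `g[k] = (-1)^k h[L-1-k]`.
#'
#' @param name Wavelet name, e.g. `"db4"`.
#' @return An object of class `wavelet_filter`: a list with elements `name`,
#'   `lowpass` and `highpass` (numeric vectors of equal length).
#' @examples
#' wf <- wavelet_filter("haar")
#' sum(wf$lowpass^2) # 1: orthonormal
#' @export
wavelet_filter <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- switch(tolower(name),
    "haar" = ,
    "db1" = rep(1 / sqrt(2), 2L),
    "db2" = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    # db3/db4 taps: standard extremal-phase Daubechies coefficients
    "db3" = c(
      0.332670552950957, 0.806891509313339, 0.459877502119331,
      -0.135011020010391, -0.085441273882241, 0.035226291882101
    ),
    "db4" = c(
      0.230377813308855, 0.714846570552542, 0.630880767929590,
      -0.027983769416984, -0.187034811718881, 0.030841381835987,
      0.032883011666983, -0.010597401784997
    ),
    stop("unsupported wavelet: '", name, "' (supported: haar/db1, db2, db3, db4)",
      call. = FALSE
    )
  )
  # renormalise against rounding in the printed taps
  h <- h / sqrt(sum(h^2))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)
  structure(
    list(name = tolower(name), lowpass = h, highpass = g),
    class = "wavelet_filter"
  )
}

#' @export
print.wavelet_filter <- function(x, ...) {
  cat("<wavelet_filter> ", x$name, " (", length(x$lowpass), " taps)\n", sep = "")
  invisible(x)
}

# one periodic analysis step: x (even length) -> list(approx, detail)
.dwt_step <- function(x, h, g) {
  n <- length(x)
  nh <- n %/% 2L
  a <- numeric(nh)
  d <- numeric(nh)
  base <- 2L * (seq_len(nh) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L)) %% n + 1L
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(approx = a, detail = d)
}

# inverse of .dwt_step (transpose of the orthogonal analysis operator)
.idwt_step <- function(a, d, h, g) {
  nh <- length(a)
  n <- 2L * nh
  x <- numeric(n)
  base <- 2L * (seq_len(nh) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L)) %% n + 1L
    contrib <- h[m] * a + g[m] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Discrete wavelet transform of a finite signal
#'
#' Decimated orthonormal DWT. The signal is analysed through `levels` stages of
#' the two-channel filter bank; each stage halves the length. Scale 1 is the
#' finest detail (first analysis step) and carries most of the white-noise
#' energy, which is where the noise level is estimated downstream.
#'
#' Boundary handling: `"periodic"` (default) treats the signal as circular and
#' gives exact energy conservation and perfect reconstruction;
#' `"reflect"` first mirrors the signal to twice its length and then applies
#' the periodic transform, avoiding wrap-around artefacts at the cost of
#' doubled coefficient counts. Signals whose length is not a multiple of
#' `2^levels` are padded by edge replication to the next multiple; the padding
#' is recorded and stripped by [idwt()].
#'
#' @param x Numeric signal.
#' @param wavelet Wavelet name (see [wavelet_filter()]) or a `wavelet_filter`.
#' @param levels Decomposition depth J (>= 1). The padded length must be at
#'   least `2^levels`.
#' @param boundary `"periodic"` or `"reflect"`.
#' @return An object of class `wavelet_dwt`: list with `approx` (coarsest
#'   approximation), `details` (list of length `levels`, element 1 = finest),
#'   `levels`, `filter`, `original_length`, `boundary`, `n_pad`.
#' @seealso [idwt()], [denoise_signal()]
#' @examples
#' w <- dwt(sin(seq_len(64) / 4), "db4", levels = 3)
#' length(w$details)
#' max(abs(idwt(w) - sin(seq_len(64) / 4)))
#' @export
dwt <- function(x, wavelet = "db4", levels = 4L, boundary = c("periodic", "reflect")) {
  boundary <- match.arg(boundary)
  if (inherits(wavelet, "wavelet_filter")) wf <- wavelet else wf <- wavelet_filter(wavelet)
  stopifnot(is.numeric(x), length(x) >= 1L)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  n0 <- length(x)
  if (n0 < 2L^levels) {
    stop("decomposition too deep: length ", n0, " < 2^", levels, call. = FALSE)
  }

  y <- x
  if (boundary == "reflect") y <- c(y, rev(y))

  block <- 2L^levels
  n_pad <- (block - length(y) %% block) %% block
  if (n_pad > 0L) y <- c(y, rep(y[length(y)], n_pad))

  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    st <- .dwt_step(y, wf$lowpass, wf$highpass)
    details[[j]] <- st$detail
    y <- st$approx
  }
  structure(
    list(
      approx = y, details = details, levels = levels, filter = wf,
      original_length = n0, boundary = boundary, n_pad = n_pad
    ),
    class = "wavelet_dwt"
  )
}

#' @export
print.wavelet_dwt <- function(x, ...) {
  cat(
    "<wavelet_dwt> N =", x$original_length, "| J =", x$levels,
    "|", x$filter$name, "|", x$boundary, "boundary\n"
  )
  cat(
    " detail lengths:", paste(vapply(x$details, length, 1L), collapse = ", "),
    "| approx:", length(x$approx), "\n"
  )
  invisible(x)
}

# internal consistency check for a decomposition
.check_dwt <- function(w) {
  if (!inherits(w, "wavelet_dwt")) stop("not a wavelet_dwt object", call. = FALSE)
  if (length(w$details) != w$levels) {
    stop("malformed decomposition: expected ", w$levels, " detail scales", call. = FALSE)
  }
  n <- length(w$approx) * 2L^w$levels
  expect_len <- n / 2L^seq_len(w$levels)
  got_len <- vapply(w$details, length, 1L)
  if (!all(got_len == expect_len)) {
    stop("malformed decomposition: detail lengths (",
      paste(got_len, collapse = ","), ") do not match cascade (",
      paste(expect_len, collapse = ","), ")",
      call. = FALSE
    )
  }
  base_len <- w$original_length * (if (w$boundary == "reflect") 2L else 1L)
  if (n != base_len + w$n_pad) {
    stop("malformed decomposition: coefficient count inconsistent with original_length",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Inverse discrete wavelet transform
#'
#' Exact inverse of [dwt()]: reconstructs the signal from the approximation and
#' detail coefficients, strips any padding and reflection, and returns a vector
#' of the original length. For an unmodified decomposition the round trip is
#' exact to floating-point precision (perfect reconstruction).
#'
#' @param w A `wavelet_dwt` object (possibly with modified coefficients).
#' @return Numeric vector of length `w$original_length`.
#' @export
idwt <- function(w) {
  .check_dwt(w)
  y <- w$approx
  for (j in rev(seq_len(w$levels))) {
    y <- .idwt_step(y, w$details[[j]], w$filter$lowpass, w$filter$highpass)
  }
  if (w$n_pad > 0L) y <- y[seq_len(length(y) - w$n_pad)]
  if (w$boundary == "reflect") y <- y[seq_len(length(y) %/% 2L)]
  y
}

#' Coefficient energy of a decomposition
#'
#' Sum of squared coefficients over the approximation and all detail scales.
#' For the periodic transform with no padding this equals the signal energy
#' exactly (Parseval), which is the reason an orthogonal wavelet is used here.
#'
#' @param w A `wavelet_dwt` object.
#' @return Scalar energy.
#' @export
dwt_energy <- function(w) {
  sum(w$approx^2) + sum(vapply(w$details, function(d) sum(d^2), 0))
}
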