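#' Construct a single-ion chromatogram
#'
#' A chromatogram is a tibble with one row per scan: `scan` (strictly
#' increasing integer scan numbers), `rt` (retention time, seconds) and
#' `intensity` (non-negative). The m/z window it was extracted over is kept
#' as attributes `mz_center` / `mz_tolerance`.
#'
#' @param scan Integer scan numbers, strictly increasing.
#' @param rt Retention times in seconds, same length.
#' @param intensity Non-negative intensities, same length.
#' @param mz_center,mz_tolerance Optional m/z window metadata.
#' @return A tibble of class `chromatogram`.
#' @export
chromatogram <- function(scan, rt, intensity, mz_center = NA_real_,
                         mz_tolerance = NA_real_) {
  scan <- as.integer(scan)
  n <- length(scan)
  if (n < 1L || length(rt) != n || length(intensity) != n) {
    stop("scan, rt and intensity must have equal length >= 1", call. = FALSE)
  }
  if (any(diff(scan) <= 0L)) stop("scan numbers must be strictly increasing", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  out <- tibble::tibble(scan = scan, rt = as.numeric(rt), intensity = as.numeric(intensity))
  attr(out, "mz_center") <- mz_center
  attr(out, "mz_tolerance") <- mz_tolerance
  class(out) <- c("chromatogram", class(out))
  out
}

#' Extract a single-ion chromatogram from spectra
#'
#' Reconstructs the intensity-versus-retention-time trace of one ion species:
#' for every scan, the intensities of all spectral peaks within
#' `mz_tolerance` of `mz_center` are summed; scans without a matching peak get
#' intensity 0, so the trace is defined on every scan of the window.
#'
#' @param spectra A spectra table as returned by [read_mzml()] or
#'   [generate_spectra()]: a tibble with columns `scan`, `rt`, and list
#'   columns `mz`, `intensity`.
#' @param mz_center Target m/z.
#' @param mz_tolerance Half-width of the extraction window; absolute (Th) by
#'   default, parts-per-million when `ppm = TRUE`. Default 0.5 Th.
#' @param scan_range Optional `c(first, last)` scan-number window.
#' @param ppm Interpret `mz_tolerance` in ppm.
#' @return A [chromatogram()].
#' @export
extract_xic <- function(spectra, mz_center, mz_tolerance = 0.5,
                        scan_range = NULL, ppm = FALSE) {
  if (is.null(spectra) || nrow(spectra) == 0L) {
    stop("empty input: no spectra to extract from", call. = FALSE)
  }
  stopifnot(mz_tolerance > 0)
  if (!is.null(scan_range)) {
    spectra <- dplyr::filter(
      spectra, .data$scan >= scan_range[1L], .data$scan <= scan_range[2L]
    )
    if (nrow(spectra) == 0L) stop("empty input: scan window contains no spectra", call. = FALSE)
  }
  tol <- if (ppm) mz_center * mz_tolerance * 1e-6 else mz_tolerance
  ints <- purrr::map2_dbl(spectra$mz, spectra$intensity, function(mz, it) {
    keep <- abs(mz - mz_center) <= tol
    if (any(keep)) sum(it[keep]) else 0
  })
  chromatogram(spectra$scan, spectra$rt, ints,
    mz_center = mz_center, mz_tolerance = tol
  )
}

# one-row tibble describing a peak region
.peak_region <- function(start_scan, end_scan, apex_scan,
                         background = NA_real_, area = NA_real_,
                         split_from_overlap = FALSE, valley_scan = NA_integer_) {
  stopifnot(start_scan <= apex_scan, apex_scan <= end_scan)
  tibble::tibble(
    start_scan = as.integer(start_scan), end_scan = as.integer(end_scan),
    apex_scan = as.integer(apex_scan), background = background, area = area,
    split_from_overlap = split_from_overlap,
    valley_scan = as.integer(valley_scan)
  )
}

#' Locate the elution peak region around a seed scan
#'
#' The apex is the maximum of the de-noised trace inside a search window
#' around `seed_scan` (ties break to the earlier scan). Boundaries extend
#' outward from the apex until the trace decays to
#' `background + boundary_factor * (apex - background)` or a local minimum
#' below that level — whichever comes first — so a shoulder that never quite
#' reaches baseline still terminates the region.
#'
#' @param chrom A [chromatogram()].
#' @param seed_scan Scan number near the expected apex (e.g. the MS/MS
#'   identification scan).
#' @param denoised De-noised intensity trace, same length as the
#'   chromatogram; defaults to [denoise_signal()] of the raw trace.
#' @param background Baseline level used for the decay test; default is the
#'   lower decile of the de-noised trace (a provisional value — the definitive
#'   background comes from [estimate_background()] afterwards).
#' @param boundary_factor Fraction of the background-subtracted apex height at
#'   which the region ends (default 0.05).
#' @param search_window Half-width, in scans, of the apex search around
#'   `seed_scan` (default 25).
#' @return A one-row peak-region tibble (`start_scan`, `end_scan`,
#'   `apex_scan`, `background`, `area`, `split_from_overlap`).
#' @export
find_peak_region <- function(chrom, seed_scan, denoised = NULL,
                             background = NULL, boundary_factor = 0.05,
                             search_window = 25L) {
  if (is.null(denoised)) denoised <- denoise_signal(chrom$intensity)
  stopifnot(length(denoised) == nrow(chrom))
  if (seed_scan < min(chrom$scan) || seed_scan > max(chrom$scan)) {
    stop("seed scan ", seed_scan, " outside chromatogram range", call. = FALSE)
  }
  if (is.null(background)) {
    background <- as.numeric(stats::quantile(denoised, 0.1, names = FALSE))
  }
  background <- max(background, 0)

  seed_idx <- which.min(abs(chrom$scan - seed_scan))
  win <- which(abs(chrom$scan - chrom$scan[seed_idx]) <= search_window)
  if (all(denoised[win] <= background) || max(denoised[win]) <= 0) {
    stop("no peak found near scan ", seed_scan, call. = FALSE)
  }
  apex_idx <- win[which.max(denoised[win])] # which.max: earlier index on ties
  apex_val <- denoised[apex_idx]
  cut <- background + boundary_factor * (apex_val - background)

  lo <- apex_idx
  while (lo > 1L) {
    if (denoised[lo - 1L] <= cut) break
    if (denoised[lo - 1L] > denoised[lo] && denoised[lo] <= cut) break
    lo <- lo - 1L
  }
  if (lo > 1L && denoised[lo - 1L] <= cut) lo <- lo - 1L
  hi <- apex_idx
  n <- length(denoised)
  while (hi < n) {
    if (denoised[hi + 1L] <= cut) break
    if (denoised[hi + 1L] > denoised[hi] && denoised[hi] <= cut) break
    hi <- hi + 1L
  }
  if (hi < n && denoised[hi + 1L] <= cut) hi <- hi + 1L

  .peak_region(chrom$scan[lo], chrom$scan[hi], chrom$scan[apex_idx],
    background = background
  )
}

# index range of a region inside a chromatogram
.region_idx <- function(chrom, region) {
  which(chrom$scan >= region$start_scan & chrom$scan <= region$end_scan)
}

#' Split an overlapping double peak and keep the expected one
#'
#' Co-eluting species can merge into one apparent region; treating them as one
#' peak inflates the integrated area (the classic failure mode this engine is
#' designed to avoid). If the de-noised trace inside `region` has a valley
#' whose depth below the smaller of its two flanking apexes exceeds
#' `valley_fraction` of that apex's height above background, the region is cut
#' at the valley minimum and the sub-region whose apex retention time is
#' closest to `expected_rt` is returned with `split_from_overlap = TRUE`.
#' Otherwise the region is returned unchanged.
#'
#' @param chrom A [chromatogram()].
#' @param region A peak-region row from [find_peak_region()].
#' @param denoised De-noised trace, same length as `chrom`.
#' @param expected_rt Retention time (seconds) where the true peak is
#'   expected, e.g. the identification scan's RT or the partner's apex RT.
#' @param valley_fraction Minimum relative valley depth to qualify as a split
#'   point (default 0.5).
#' @param background Background level; defaults to `region$background`.
#' @return A one-row peak-region tibble, never extending beyond `region`.
#' @export
split_overlap <- function(chrom, region, denoised, expected_rt,
                          valley_fraction = 0.5, background = NULL) {
  stopifnot(length(denoised) == nrow(chrom))
  if (is.null(background)) background <- region$background
  if (is.na(background)) background <- 0
  idx <- .region_idx(chrom, region)
  y <- denoised[idx]
  m <- length(y)
  if (m < 5L) return(region)

  # interior local maxima / minima of the de-noised trace
  d <- diff(y)
  s <- sign(d)
  s[s == 0] <- 1 # plateaus lean rising so the earlier apex wins ties
  turns <- diff(s)
  maxima <- which(turns < 0) + 1L
  minima <- which(turns > 0) + 1L
  if (length(maxima) < 2L) return(region)

  best <- NULL
  best_depth <- -Inf
  for (v in minima) {
    left <- maxima[maxima < v]
    right <- maxima[maxima > v]
    if (!length(left) || !length(right)) next
    a_left <- max(y[left])
    a_right <- max(y[right])
    smaller <- min(a_left, a_right)
    depth <- smaller - y[v]
    if (depth > valley_fraction * (smaller - background) && depth > best_depth) {
      best <- v
      best_depth <- depth
    }
  }
  if (is.null(best)) return(region)

  cut_idx <- idx[best]
  left_idx <- idx[seq_len(best)]
  right_idx <- idx[seq(best, m)]
  apex_l <- left_idx[which.max(denoised[left_idx])]
  apex_r <- right_idx[which.max(denoised[right_idx])]
  pick_left <- abs(chrom$rt[apex_l] - expected_rt) <= abs(chrom$rt[apex_r] - expected_rt)
  if (pick_left) {
    .peak_region(chrom$scan[left_idx[1L]], chrom$scan[cut_idx], chrom$scan[apex_l],
      background = region$background, split_from_overlap = TRUE,
      valley_scan = chrom$scan[cut_idx]
    )
  } else {
    .peak_region(chrom$scan[cut_idx], chrom$scan[right_idx[length(right_idx)]],
      chrom$scan[apex_r],
      background = region$background, split_from_overlap = TRUE,
      valley_scan = chrom$scan[cut_idx]
    )
  }
}

#' Estimate the chromatographic background level
#'
#' Median of the de-noised intensities in flanking windows just outside the
#' peak region (default 10 scans each side). When the region touches both ends
#' of the chromatogram and no flanks exist, falls back to the lower decile of
#' the in-region intensities.
#'
#' @param chrom A [chromatogram()].
#' @param region A peak-region row.
#' @param denoised De-noised trace, same length as `chrom`.
#' @param flank Flank width in scans (default 10).
#' @return Non-negative background intensity.
#' @export
estimate_background <- function(chrom, region, denoised, flank = 10L) {
  stopifnot(length(denoised) == nrow(chrom))
  left <- which(chrom$scan < region$start_scan & chrom$scan >= region$start_scan - flank)
  right <- which(chrom$scan > region$end_scan & chrom$scan <= region$end_scan + flank)
  # a flank on the valley side of a split region sits on the co-eluting
  # species, not on baseline: use only the outer flank there
  if ("valley_scan" %in% names(region) && !is.na(region$valley_scan)) {
    if (region$valley_scan == region$end_scan) right <- integer(0)
    if (region$valley_scan == region$start_scan) left <- integer(0)
  }
  vals <- denoised[c(left, right)]
  if (length(vals) == 0L) {
    vals <- denoised[.region_idx(chrom, region)]
    return(max(0, as.numeric(stats::quantile(vals, 0.1, names = FALSE))))
  }
  max(0, stats::median(vals))
}

#' Integrate the background-subtracted peak area
#'
#' Trapezoidal integral over retention time (seconds) of
#' `max(denoised - background, 0)` across the region, so the area carries
#' physical units (intensity x seconds) and is robust to uneven scan spacing.
#'
#' @param chrom A [chromatogram()].
#' @param region A peak-region row.
#' @param denoised De-noised trace, same length as `chrom`.
#' @param background Background level; defaults to `region$background`.
#' @return Non-negative area; 0 when the trace never exceeds background.
#' @export
peak_area <- function(chrom, region, denoised, background = NULL) {
  stopifnot(length(denoised) == nrow(chrom))
  if (is.null(background)) background <- region$background
  if (is.na(background)) background <- 0
  idx <- .region_idx(chrom, region)
  if (length(idx) < 2L) return(0)
  y <- pmax(denoised[idx] - background, 0)
  t <- chrom$rt[idx]
  sum(diff(t) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' De-noise, locate, split and integrate one chromatogram
#'
#' Convenience wrapper chaining [denoise_signal()], [find_peak_region()],
#' [split_overlap()], [estimate_background()] and [peak_area()]; this is the
#' per-partner unit of work of the quantification pipeline.
#'
#' @param chrom A [chromatogram()].
#' @param seed_scan Seed scan number.
#' @param expected_rt Expected apex retention time for overlap resolution;
#'   defaults to the RT at the seed scan.
#' @param config A [denoise_config()].
#' @param boundary_factor,valley_fraction,search_window,flank Tuning
#'   parameters, see the individual steps.
#' @return A one-row peak-region tibble with `background` and `area` filled
#'   in, plus a `denoised` list column carrying the full de-noised trace.
#' @export
quantify_chromatogram <- function(chrom, seed_scan, expected_rt = NULL,
                                  config = denoise_config(),
                                  boundary_factor = 0.05, valley_fraction = 0.5,
                                  search_window = 25L, flank = 10L) {
  den <- denoise_signal(chrom$intensity, config)
  if (is.null(expected_rt)) {
    expected_rt <- chrom$rt[which.min(abs(chrom$scan - seed_scan))]
  }
  region <- find_peak_region(chrom, seed_scan, den,
    boundary_factor = boundary_factor, search_window = search_window
  )
  region <- split_overlap(chrom, region, den, expected_rt,
    valley_fraction = valley_fraction
  )
  region$background <- estimate_background(chrom, region, den, flank = flank)
  region$area <- peak_area(chrom, region, den)
  region$denoised <- list(den)
  region
}
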