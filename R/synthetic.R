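#' Specification of a synthetic light/heavy chromatogram pair
#'
#' Describes a stated world with analytic ground truth: Gaussian elution
#' peaks on a flat baseline with additive Gaussian white noise, mirroring the
#' additive signal-plus-noise model the de-noiser assumes. The heavy partner
#' carries the peaks as given; the light partner has identical geometry with
#' amplitudes scaled by `mixing_ratio` (light:heavy) and independent noise.
#'
#' Defaults describe a realistic ion-trap elution trace: 256 scans at 1 s,
#' one peak of amplitude 100 and width 5 scans (FWHM about 12 s), noise sigma
#' 5 (5% of the apex), baseline 15 (kept >= 3 x noise sigma so clipping at
#' zero is negligible).
#'
#' @param n_scans Number of scans.
#' @param scan_interval Seconds between scans.
#' @param peaks Tibble/data frame with columns `apex_scan`, `amplitude`,
#'   `sigma_scans` (one row per Gaussian peak).
#' @param baseline Flat baseline intensity.
#' @param noise_sigma Standard deviation of the additive white noise.
#' @param mixing_ratio Light:heavy amplitude ratio (> 0).
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_scans = 256L, scan_interval = 1,
                           peaks = tibble::tibble(
                             apex_scan = 128, amplitude = 100, sigma_scans = 5
                           ),
                           baseline = 15, noise_sigma = 5,
                           mixing_ratio = 1, seed = 1L) {
  stopifnot(
    n_scans >= 8L, scan_interval > 0, is.data.frame(peaks),
    all(c("apex_scan", "amplitude", "sigma_scans") %in% names(peaks)),
    nrow(peaks) >= 1L
  )
  if (any(peaks$amplitude <= 0) || any(peaks$sigma_scans <= 0)) {
    stop("peak amplitudes and widths must be positive", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (baseline < 0) stop("baseline must be >= 0", call. = FALSE)
  if (mixing_ratio <= 0) stop("mixing_ratio must be > 0", call. = FALSE)
  structure(
    list(
      n_scans = as.integer(n_scans), scan_interval = scan_interval,
      peaks = tibble::as_tibble(peaks), baseline = baseline,
      noise_sigma = noise_sigma, mixing_ratio = mixing_ratio,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# clean Gaussian mixture trace (no baseline, no noise)
.clean_trace <- function(spec, amplitude_scale = 1) {
  s <- seq_len(spec$n_scans)
  y <- numeric(spec$n_scans)
  for (i in seq_len(nrow(spec$peaks))) {
    p <- spec$peaks[i, ]
    y <- y + amplitude_scale * p$amplitude *
      exp(-(s - p$apex_scan)^2 / (2 * p$sigma_scans^2))
  }
  y
}

#' Generate one synthetic chromatogram with known peak areas
#'
#' Intensities are `baseline + sum of Gaussians + N(0, noise_sigma^2)`,
#' clipped at zero. True areas are the closed-form Gaussian integrals
#' `amplitude * sigma_seconds * sqrt(2 * pi)` (background excluded), one per
#' peak.
#'
#' @param spec A [synthetic_spec()].
#' @param amplitude_scale Internal amplitude multiplier (used for the light
#'   partner).
#' @param seed Seed override; defaults to `spec$seed`.
#' @return List with `chrom` (a [chromatogram()]), `clean` (noise-free trace
#'   including baseline) and `true_areas` (numeric, one per peak).
#' @export
generate_chromatogram <- function(spec, amplitude_scale = 1, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  clean <- spec$baseline + .clean_trace(spec, amplitude_scale)
  noise <- withr::with_seed(seed, stats::rnorm(spec$n_scans, sd = spec$noise_sigma))
  y <- pmax(clean + noise, 0)
  scans <- seq_len(spec$n_scans)
  list(
    chrom = chromatogram(scans, (scans - 1L) * spec$scan_interval, y),
    clean = clean,
    true_areas = amplitude_scale * spec$peaks$amplitude *
      spec$peaks$sigma_scans * spec$scan_interval * sqrt(2 * pi)
  )
}

#' Generate a light/heavy chromatogram pair with known mixing ratio
#'
#' The heavy partner follows the spec as given; the light partner has the
#' same peak geometry with amplitudes scaled by `spec$mixing_ratio` and an
#' independent noise realisation.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `light`, `heavy` (each as from
#'   [generate_chromatogram()]) and `true_ratio = spec$mixing_ratio`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  heavy <- generate_chromatogram(spec, amplitude_scale = 1, seed = spec$seed)
  light <- generate_chromatogram(spec,
    amplitude_scale = spec$mixing_ratio,
    seed = spec$seed + 1000003L
  )
  list(light = light, heavy = heavy, true_ratio = spec$mixing_ratio)
}

#' Build toy spectra tracing a light/heavy pair
#'
#' One centroid spectrum per scan with two peaks, at `mz_light` and
#' `mz_heavy`, whose intensities follow the generated light and heavy
#' chromatograms. Extracting an XIC at either m/z reproduces the
#' corresponding chromatogram exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param mz_light,mz_heavy Distinct m/z positions for the two partners.
#' @param pair Optional pre-generated [generate_pair()] result (so the same
#'   realisation can be reused).
#' @return A spectra tibble (`scan`, `rt`, list columns `mz`, `intensity`)
#'   compatible with [extract_xic()] and [write_mzml()].
#' @export
generate_spectra <- function(spec, mz_light = 500.0, mz_heavy = 504.0,
                             pair = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), mz_light != mz_heavy)
  if (is.null(pair)) pair <- generate_pair(spec)
  li <- pair$light$chrom
  he <- pair$heavy$chrom
  tibble::tibble(
    scan = li$scan,
    rt = li$rt,
    mz = purrr::map(seq_len(nrow(li)), ~ c(mz_light, mz_heavy)),
    intensity = purrr::map(
      seq_len(nrow(li)),
      ~ c(li$intensity[.x], he$intensity[.x])
    )
  )
}

# ---- minimal mzML I/O -------------------------------------------------------
# A deliberately small mzML subset: MS1 centroid spectra, 64-bit uncompressed
# base64 binary arrays, scan start times in seconds. Enough for the full
# pipeline to round-trip; not a general-purpose reader.

.encode_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L, endian = "little"))
}

.decode_doubles <- function(txt) {
  raw <- jsonlite::base64_dec(gsub("[\r\n ]", "", txt))
  readBin(raw, "numeric", n = length(raw) %/% 8L, size = 8L, endian = "little")
}

#' Write spectra to a minimal mzML file
#'
#' Emits a small but standard-conformant mzML document (MS1 centroid spectra,
#' uncompressed 64-bit little-endian base64 arrays, scan start time in
#' seconds) that [read_mzml()] — and any mzML-aware reader supporting
#' uncompressed 64-bit arrays — can parse. Values round-trip exactly.
#'
#' @param spectra A spectra tibble (`scan`, `rt`, list columns `mz`,
#'   `intensity`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  stopifnot(is.data.frame(spectra), all(c("scan", "rt", "mz", "intensity") %in% names(spectra)))
  n <- nrow(spectra)
  doc <- xml2::xml_new_root("mzML",
    xmlns = "http://psi.hupo.org/ms/mzml", version = "1.1.0"
  )
  run <- xml2::xml_add_child(doc, "run", id = "run1")
  slist <- xml2::xml_add_child(run, "spectrumList", count = as.character(n))
  for (i in seq_len(n)) {
    sp <- xml2::xml_add_child(slist, "spectrum",
      index = as.character(i - 1L),
      id = paste0("scan=", spectra$scan[i]),
      defaultArrayLength = as.character(length(spectra$mz[[i]]))
    )
    xml2::xml_add_child(sp, "cvParam",
      cvRef = "MS", accession = "MS:1000511",
      name = "ms level", value = "1"
    )
    scl <- xml2::xml_add_child(sp, "scanList", count = "1")
    sc <- xml2::xml_add_child(scl, "scan")
    xml2::xml_add_child(sc, "cvParam",
      cvRef = "MS", accession = "MS:1000016",
      name = "scan start time",
      value = format(spectra$rt[i], digits = 17),
      unitName = "second"
    )
    bal <- xml2::xml_add_child(sp, "binaryDataArrayList", count = "2")
    for (kind in c("mz", "intensity")) {
      vals <- spectra[[kind]][[i]]
      enc <- .encode_doubles(vals)
      ba <- xml2::xml_add_child(bal, "binaryDataArray",
        encodedLength = as.character(nchar(enc))
      )
      xml2::xml_add_child(ba, "cvParam",
        cvRef = "MS", accession = "MS:1000523",
        name = "64-bit float", value = ""
      )
      xml2::xml_add_child(ba, "cvParam",
        cvRef = "MS", accession = "MS:1000576",
        name = "no compression", value = ""
      )
      acc <- if (kind == "mz") c("MS:1000514", "m/z array") else c("MS:1000515", "intensity array")
      xml2::xml_add_child(ba, "cvParam",
        cvRef = "MS", accession = acc[1L], name = acc[2L], value = ""
      )
      xml2::xml_add_child(ba, "binary", enc)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a minimal mzML file into a spectra table
#'
#' Parses the mzML subset written by [write_mzml()]: uncompressed 64-bit
#' binary arrays, scan start times (minutes are converted to seconds). Scan
#' numbers are taken from the `scan=` field of the spectrum id when present,
#' otherwise `index + 1`.
#'
#' @param path Path to an mzML file.
#' @return A spectra tibble (`scan`, `rt`, list columns `mz`, `intensity`).
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  specs <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(specs) == 0L) stop("no spectra found in '", path, "'", call. = FALSE)
  rows <- purrr::map(specs, function(sp) {
    id <- xml2::xml_attr(sp, "id")
    scan <- if (grepl("scan=", id %||% "")) {
      as.integer(sub(".*scan=([0-9]+).*", "\\1", id))
    } else {
      as.integer(xml2::xml_attr(sp, "index")) + 1L
    }
    rt_node <- xml2::xml_find_first(sp, ".//cvParam[@accession='MS:1000016']")
    rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
    if (identical(xml2::xml_attr(rt_node, "unitName"), "minute")) rt <- rt * 60
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- intensity <- numeric(0)
    for (ba in arrays) {
      if (!is.na(xml2::xml_find_first(ba, ".//cvParam[@accession='MS:1000574']"))) {
        stop("compressed binary arrays are not supported by this reader", call. = FALSE)
      }
      vals <- .decode_doubles(xml2::xml_text(xml2::xml_find_first(ba, ".//binary")))
      if (!is.na(xml2::xml_find_first(ba, ".//cvParam[@accession='MS:1000514']"))) {
        mz <- vals
      } else if (!is.na(xml2::xml_find_first(ba, ".//cvParam[@accession='MS:1000515']"))) {
        intensity <- vals
      }
    }
    list(scan = scan, rt = rt, mz = mz, intensity = intensity)
  })
  out <- tibble::tibble(
    scan = purrr::map_int(rows, "scan"),
    rt = purrr::map_dbl(rows, "rt"),
    mz = purrr::map(rows, "mz"),
    intensity = purrr::map(rows, "intensity")
  )
  dplyr::arrange(out, .data$scan)
}

#' Read / write a peptide target table
#'
#' Tab-separated with header columns `peptide`, `protein`, `charge`,
#' `mz_light`, `mz_heavy`, `seed_scan` — one row per charge state to
#' quantify.
#'
#' @param path File path.
#' @return A tibble (for the reader); `path` invisibly (for the writer).
#' @export
read_targets <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("peptide", "protein", "charge", "mz_light", "mz_heavy", "seed_scan")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop("target table missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' @rdname read_targets
#' @param targets Target tibble to write.
#' @export
write_targets <- function(targets, path) {
  readr::write_tsv(targets, path)
  invisible(path)
}
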