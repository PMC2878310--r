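#' Pipeline run configuration
#'
#' Collects every tunable of the quantification pipeline in one place; the
#' command-line tool's flags mirror these keys.
#'
#' @param denoise A [denoise_config()].
#' @param mz_tolerance XIC extraction half-window (Th, or ppm if `ppm`).
#' @param ppm Interpret `mz_tolerance` in ppm.
#' @param scan_halfwidth Half-width, in scans, of the extraction window
#'   around each target's seed scan (default 60).
#' @param search_window Apex search half-width in scans.
#' @param boundary_factor,valley_fraction,flank Peak-region tuning, see
#'   [find_peak_region()], [split_overlap()], [estimate_background()].
#' @param min_weight Charge states with `light_area + heavy_area` below this
#'   are rejected (default 0).
#' @return A list of class `run_config`.
#' @export
run_config <- function(denoise = denoise_config(), mz_tolerance = 0.5,
                       ppm = FALSE, scan_halfwidth = 60L, search_window = 25L,
                       boundary_factor = 0.05, valley_fraction = 0.5,
                       flank = 10L, min_weight = 0) {
  structure(
    list(
      denoise = denoise, mz_tolerance = mz_tolerance, ppm = ppm,
      scan_halfwidth = as.integer(scan_halfwidth),
      search_window = as.integer(search_window),
      boundary_factor = boundary_factor, valley_fraction = valley_fraction,
      flank = as.integer(flank), min_weight = min_weight
    ),
    class = "run_config"
  )
}

# quantify one isotopic partner of one target row; NULL on failure
.quantify_partner <- function(spectra, mz, target, config) {
  tryCatch(
    {
      chrom <- extract_xic(spectra, mz,
        mz_tolerance = config$mz_tolerance, ppm = config$ppm,
        scan_range = c(
          target$seed_scan - config$scan_halfwidth,
          target$seed_scan + config$scan_halfwidth
        )
      )
      quantify_chromatogram(chrom, target$seed_scan,
        config = config$denoise,
        boundary_factor = config$boundary_factor,
        valley_fraction = config$valley_fraction,
        search_window = config$search_window, flank = config$flank
      )
    },
    error = function(e) NULL
  )
}

#' Quantify a labelled LC-MS run against a peptide target table
#'
#' The end-to-end pipeline: for every target row (one charge state of one
#' peptide), the light and heavy extracted-ion chromatograms are built,
#' wavelet de-noised, their peak regions located (splitting overlapped
#' double peaks), backgrounds estimated and areas integrated; the
#' light/heavy area ratio and its weight (total area) are recorded. Charge
#' states of the same peptide are merged by weighted mean, and each
#' protein's unique-peptide ratios are aggregated by recursive
#' square-root-range outlier elimination.
#'
#' A malformed or unquantifiable target never aborts the run: the row is
#' flagged and processing continues.
#'
#' @param spectra Spectra tibble (see [read_mzml()]) or a path to an mzML
#'   file.
#' @param targets Target tibble (see [read_targets()]) or a path to a TSV.
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, `peptides.tsv`,
#'   `proteins.tsv` and `charge_states.tsv` are written there.
#' @return An object of class `quant_run`: list with tibbles
#'   `charge_states` (per target row: areas, ratio, weight, region bounds,
#'   flags), `peptides` (per peptide: combined ratio) and `proteins` (per
#'   protein: `n_peptides`, `n_survivors`, `n_rounds`, `final_ratio`), plus
#'   `protein_fits` (the underlying `protein_quant` objects) and `config`.
#' @export
quantify_run <- function(spectra, targets, config = run_config(),
                         output_dir = NULL) {
  if (is.character(spectra)) spectra <- read_mzml(spectra)
  if (is.character(targets)) targets <- read_targets(targets)
  stopifnot(is.data.frame(targets))

  if (nrow(targets) == 0L) {
    warning("empty target table: nothing to quantify", call. = FALSE)
    empty <- list(
      charge_states = tibble::tibble(),
      peptides = tibble::tibble(),
      proteins = tibble::tibble(),
      protein_fits = list(), config = config
    )
    class(empty) <- "quant_run"
    return(empty)
  }

  rows <- purrr::map(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    base <- tibble::tibble(
      peptide = as.character(tg$peptide), protein = as.character(tg$protein),
      charge = as.integer(tg$charge),
      light_area = NA_real_, heavy_area = NA_real_,
      ratio = NA_real_, weight = 0,
      light_start = NA_integer_, light_end = NA_integer_,
      heavy_start = NA_integer_, heavy_end = NA_integer_,
      split_light = NA, split_heavy = NA,
      flag = ""
    )
    ok <- tryCatch(
      {
        stopifnot(
          !is.na(tg$mz_light), !is.na(tg$mz_heavy),
          !is.na(tg$seed_scan), tg$mz_light > 0, tg$mz_heavy > 0
        )
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) {
      base$flag <- "malformed_target"
      return(base)
    }
    li <- .quantify_partner(spectra, tg$mz_light, tg, config)
    he <- .quantify_partner(spectra, tg$mz_heavy, tg, config)
    if (is.null(li) || is.null(he)) {
      base$flag <- "unquantifiable"
      return(base)
    }
    base$light_area <- li$area
    base$heavy_area <- he$area
    base$ratio <- peptide_ratio(li$area, he$area)
    base$weight <- li$area + he$area
    base$light_start <- li$start_scan
    base$light_end <- li$end_scan
    base$heavy_start <- he$start_scan
    base$heavy_end <- he$end_scan
    base$split_light <- li$split_from_overlap
    base$split_heavy <- he$split_from_overlap
    if (is.na(base$ratio)) base$flag <- "zero_heavy_area"
    if (base$weight < config$min_weight) base$flag <- "low_weight"
    base
  })
  charge_states <- dplyr::bind_rows(rows)

  peptides <- charge_states |>
    dplyr::mutate(accepted = .data$flag == "") |>
    dplyr::group_by(.data$peptide, .data$protein) |>
    dplyr::summarise(
      n_charge_states = dplyr::n(),
      combined_ratio = combine_charge_states(
        dplyr::pick("ratio", "weight", "accepted")
      ),
      total_weight = sum(.data$weight),
      .groups = "drop"
    )

  quant_peps <- dplyr::filter(
    peptides, !is.na(.data$combined_ratio), .data$combined_ratio > 0
  )
  protein_fits <- list()
  if (nrow(quant_peps) > 0L) {
    protein_fits <- quant_peps |>
      dplyr::group_by(.data$protein) |>
      dplyr::group_map(~ protein_ratio(.x$combined_ratio, protein = .y$protein))
    names(protein_fits) <- vapply(protein_fits, function(f) f$protein, "")
  }
  proteins <- if (length(protein_fits)) {
    dplyr::bind_rows(lapply(protein_fits, glance))
  } else {
    tibble::tibble(
      protein = character(), n_peptides = integer(), n_survivors = integer(),
      n_rounds = integer(), final_ratio = numeric()
    )
  }

  out <- structure(
    list(
      charge_states = charge_states, peptides = peptides,
      proteins = proteins, protein_fits = protein_fits, config = config
    ),
    class = "quant_run"
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(charge_states, file.path(output_dir, "charge_states.tsv"))
    readr::write_tsv(peptides, file.path(output_dir, "peptides.tsv"))
    readr::write_tsv(proteins, file.path(output_dir, "proteins.tsv"))
  }
  out
}

#' @export
print.quant_run <- function(x, ...) {
  cat(
    "<quant_run>", nrow(x$charge_states), "charge states |",
    nrow(x$peptides), "peptides |", nrow(x$proteins), "proteins\n"
  )
  if (nrow(x$proteins)) print(x$proteins)
  invisible(x)
}

#' Protein-level summary of a quantification run
#'
#' @param x A `quant_run` object.
#' @param ... Unused.
#' @return The protein table (one row per protein).
#' @export
tidy.quant_run <- function(x, ...) x$proteins

#' One-row summary of a quantification run
#'
#' @param x A `quant_run` object.
#' @param ... Unused.
#' @return Tibble with run-level counts.
#' @export
glance.quant_run <- function(x, ...) {
  tibble::tibble(
    n_targets = nrow(x$charge_states),
    n_peptides = nrow(x$peptides),
    n_quantified_peptides = sum(!is.na(x$peptides$combined_ratio)),
    n_proteins = nrow(x$proteins)
  )
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits an mzML file, a matching target table and a ground-truth sidecar
#' (TSV with the true mixing ratio and analytic areas) for a synthetic
#' light/heavy pair — [quantify_run()] on the two files closes the loop.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param mz_light,mz_heavy m/z positions of the two partners.
#' @param peptide,protein Identifiers used in the target table.
#' @param charge Charge state recorded in the target table.
#' @return Named character vector of the three file paths, invisibly.
#' @export
simulate_run <- function(spec, dir, mz_light = 500.0, mz_heavy = 504.0,
                         peptide = "SYNTHPEPTIDEK", protein = "SYN_PROT",
                         charge = 2L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pair <- generate_pair(spec)
  spectra <- generate_spectra(spec, mz_light, mz_heavy, pair = pair)
  paths <- c(
    mzml = file.path(dir, "run.mzML"),
    targets = file.path(dir, "targets.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_mzml(spectra, paths[["mzml"]])
  main_peak <- which.max(spec$peaks$amplitude)
  write_targets(tibble::tibble(
    peptide = peptide, protein = protein, charge = charge,
    mz_light = mz_light, mz_heavy = mz_heavy,
    seed_scan = as.integer(round(spec$peaks$apex_scan[main_peak]))
  ), paths[["targets"]])
  readr::write_tsv(tibble::tibble(
    peptide = peptide, protein = protein,
    true_ratio = pair$true_ratio,
    true_light_area = pair$light$true_areas[main_peak],
    true_heavy_area = pair$heavy$true_areas[main_peak]
  ), paths[["truth"]])
  invisible(paths)
}
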