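#' Light/heavy abundance ratio of one charge state
#'
#' Ratio of the light-partner area to the heavy-partner area. When the heavy
#' area is zero the ratio is undefined and returned as `NA` (never coerced to
#' zero or infinity): such charge states are flagged and excluded from
#' aggregation rather than imputed.
#'
#' @param light_area,heavy_area Non-negative integrated areas (vectorised).
#' @return `light_area / heavy_area`, or `NA` where `heavy_area == 0`.
#' @export
peptide_ratio <- function(light_area, heavy_area) {
  if (any(light_area < 0, na.rm = TRUE) || any(heavy_area < 0, na.rm = TRUE)) {
    stop("invalid area: areas must be non-negative", call. = FALSE)
  }
  out <- ifelse(heavy_area > 0, light_area / heavy_area, NA_real_)
  as.numeric(out)
}

#' Merge charge-state ratios into one peptide ratio
#'
#' Weighted arithmetic mean of the per-charge-state ratios over entries that
#' are accepted, have a defined ratio and positive weight. The default weight
#' of a charge state is its total ion current, `light_area + heavy_area`: a
#' larger combined signal gives a more reliable ratio. Returns `NA` when no
#' entry is usable (an unquantifiable peptide, recorded rather than thrown).
#'
#' @param entries A tibble/data frame with columns `ratio`, `weight` and
#'   optionally `accepted` (default all TRUE).
#' @return Scalar combined ratio, or `NA`.
#' @examples
#' combine_charge_states(tibble::tibble(ratio = c(1, 3), weight = c(3, 1)))
#' @export
combine_charge_states <- function(entries) {
  stopifnot(is.data.frame(entries), all(c("ratio", "weight") %in% names(entries)))
  acc <- if ("accepted" %in% names(entries)) entries$accepted else rep(TRUE, nrow(entries))
  use <- acc & !is.na(entries$ratio) & !is.na(entries$weight) & entries$weight > 0
  if (!any(use)) return(NA_real_)
  sum(entries$ratio[use] * entries$weight[use]) / sum(entries$weight[use])
}

#' Protein ratio by recursive square-root-range outlier elimination
#'
#' Aggregates the ratios of a protein's unique peptides into one protein
#' ratio. Outliers are eliminated recursively: in the first round the centre
#' is the median `m` and ratios outside the closed interval
#' `[m - sqrt(m), m + sqrt(m)]` are dropped; in every later round the centre
#' is the mean `A` of the current survivors with interval
#' `[A - sqrt(A), A + sqrt(A)]`. Rounds repeat until the survivor set stops
#' changing or one ratio remains. The final protein ratio is the arithmetic
#' mean of the survivors. The square-root width adapts to the magnitude of
#' the ratio, mirroring the roughly Poisson growth of ion-count variance.
#'
#' At least one ratio always survives: in the degenerate case where a round's
#' interval contains no ratio, the ratio(s) closest to that round's centre are
#' kept and elimination stops.
#'
#' @param ratios Positive, defined peptide ratios (one per unique peptide).
#' @param protein Optional protein accession carried into the result.
#' @return An object of class `protein_quant`: list with `protein`, `ratios`,
#'   `surviving` (logical), `final_ratio`, and `rounds` — a per-round audit
#'   tibble (`round`, `center_type`, `center`, `lower`, `upper`, `n_before`,
#'   `n_after`). Use [tidy()] for the audit trail and [glance()] for the
#'   one-row summary.
#' @examples
#' pq <- protein_ratio(c(1.0, 1.1, 0.9, 1.05, 5.0))
#' pq$final_ratio # 1.0125: the 5.0 outlier is dropped in round 1
#' @export
protein_ratio <- function(ratios, protein = NA_character_) {
  ratios <- as.numeric(ratios)
  if (length(ratios) == 0L) {
    stop("insufficient peptides: no ratios to aggregate", call. = FALSE)
  }
  if (any(is.na(ratios)) || any(ratios <= 0)) {
    stop("ratios must be defined and > 0 (filter undefined ratios upstream)",
      call. = FALSE
    )
  }
  surviving <- rep(TRUE, length(ratios))
  audit <- list()
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    cur <- ratios[surviving]
    if (length(cur) <= 1L) break
    if (round_i == 1L) {
      center <- stats::median(cur)
      ctype <- "median"
    } else {
      center <- mean(cur)
      ctype <- "mean"
    }
    lower <- center - sqrt(center)
    upper <- center + sqrt(center)
    keep <- ratios >= lower & ratios <= upper & surviving
    if (!any(keep)) {
      # degenerate spread: keep the ratio(s) nearest the centre, stop
      dist <- abs(ratios - center)
      dist[!surviving] <- Inf
      keep <- dist == min(dist) & surviving
      audit[[round_i]] <- tibble::tibble(
        round = round_i, center_type = ctype, center = center,
        lower = lower, upper = upper,
        n_before = sum(surviving), n_after = sum(keep)
      )
      surviving <- keep
      break
    }
    audit[[round_i]] <- tibble::tibble(
      round = round_i, center_type = ctype, center = center,
      lower = lower, upper = upper,
      n_before = sum(surviving), n_after = sum(keep)
    )
    no_change <- identical(keep, surviving)
    surviving <- keep
    if (no_change && round_i > 1L) break
    if (no_change && round_i == 1L) {
      # still run one mean-centred round to confirm stability
      next
    }
  }
  structure(
    list(
      protein = protein, ratios = ratios, surviving = surviving,
      final_ratio = mean(ratios[surviving]),
      rounds = if (length(audit)) dplyr::bind_rows(audit) else tibble::tibble(
        round = integer(), center_type = character(), center = numeric(),
        lower = numeric(), upper = numeric(), n_before = integer(),
        n_after = integer()
      )
    ),
    class = "protein_quant"
  )
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("<protein_quant>",
    if (!is.na(x$protein)) x$protein else "", "\n",
    " peptides:", length(x$ratios), "| survivors:", sum(x$surviving),
    "| ratio:", signif(x$final_ratio, 4), "\n"
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-round audit trail of the outlier elimination
#'
#' @param x A `protein_quant` object.
#' @param ... Unused.
#' @return A tibble with one row per elimination round.
#' @export
tidy.protein_quant <- function(x, ...) {
  x$rounds
}

#' One-row summary of a protein quantification
#'
#' @param x A `protein_quant` object.
#' @param ... Unused.
#' @return A tibble with `protein`, `n_peptides`, `n_survivors`, `n_rounds`
#'   and `final_ratio`.
#' @export
glance.protein_quant <- function(x, ...) {
  tibble::tibble(
    protein = x$protein, n_peptides = length(x$ratios),
    n_survivors = sum(x$surviving), n_rounds = nrow(x$rounds),
    final_ratio = x$final_ratio
  )
}

#' Relative quantification error in percent
#'
#' `100 * |estimated - expected| / expected`, the standard accuracy metric
#' for known-mixture benchmarks.
#'
#' @param estimated Estimated ratio(s).
#' @param expected True ratio(s), > 0.
#' @return Percent error (vectorised).
#' @export
relative_error <- function(estimated, expected) {
  stopifnot(all(expected > 0))
  100 * abs(estimated - expected) / expected
}
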