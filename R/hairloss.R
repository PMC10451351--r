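#' Derive zone surface weights from grid-cell counts
#'
#' The body diagram used for hair-loss scoring is divided into zones under
#' a 100 x 100 grid overlay; a zone's weight is the number of grid cells it
#' occupies divided by the total cells in the pictured body (typically
#' hairless parts — fronts of hands, soles, ears, parts of the face — are
#' excluded when the grid mask is drawn, not at runtime).
#'
#' @param grid_counts Named positive integer vector, zone code -> cell count.
#' @return Tibble of class `zone_map`: `zone`, `cells`, `weight`
#'   (weights sum to 1).
#' @export
#' @examples
#' zone_weights_from_grid(c(A = 500, B = 300, C = 200))
zone_weights_from_grid <- function(grid_counts) {
  if (length(grid_counts) == 0 || is.null(names(grid_counts))) {
    abort("grid_counts must be a named vector of cell counts")
  }
  if (any(grid_counts <= 0) || any(grid_counts != as.integer(grid_counts))) {
    abort("grid cell counts must be positive integers")
  }
  out <- tibble::tibble(
    zone = names(grid_counts),
    cells = as.integer(grid_counts),
    weight = as.numeric(grid_counts) / sum(grid_counts)
  )
  class(out) <- c("zone_map", class(out))
  out
}

#' Packaged default seven-zone body map
#'
#' Zones A (head), B (torso front), C (back), D/E (arms), F/G (legs) with
#' grid-cell counts from this package's reference body mask; the published
#' diagram shows the zones graphically without printing per-zone
#' percentages, so these weights are a documented, fully configurable
#' default rather than a transcription. Weights sum to 1.
#'
#' @return A `zone_map` tibble with 7 rows.
#' @export
default_zone_map <- function() {
  zone_weights_from_grid(c(
    A = 500L, B = 1000L, C = 850L, D = 600L, E = 600L, F = 725L, G = 725L
  ))
}

#' Snap observed zone scores to the five-point scale
#'
#' Observers estimate per-zone hair loss to one of {0, 25, 50, 75, 100}
#' percent. Values recorded off-scale are snapped to the nearest scale
#' point; exact midpoints round up, toward concern.
#'
#' @param x Numeric vector of per-zone percentages in \[0, 100\].
#' @return Vector with every value in {0, 25, 50, 75, 100}.
#' @export
#' @examples
#' snap_zone_scores(c(10, 12.5, 60, 88))
snap_zone_scores <- function(x) {
  if (any(!is.na(x) & (x < 0 | x > 100))) {
    abort("zone scores must lie in [0, 100]")
  }
  25 * floor(x / 25 + 0.5)
}

#' Zone-weighted total body hair loss
#'
#' Each zone's five-point hair-loss score is scaled by the zone's share of
#' ideal hair surface area and the scaled scores are summed, giving the
#' percent of total body hair lost. Totals of 25% or more are flagged
#' significant and escalate the monitoring schedule.
#'
#' @param surveys Tibble with `chimp_id`, `date`, `observer` and one column
#'   per zone of `zone_map` (percent lost in that zone).
#' @param zone_map A [zone_weights_from_grid()] result; default
#'   [default_zone_map()].
#' @param snap Snap off-scale zone scores on ingestion (default `TRUE`)?
#' @return Tibble of class `hairloss_result`: `chimp_id`, `date`,
#'   `total_pct`, `significant`.
#' @export
total_hair_loss <- function(surveys, zone_map = default_zone_map(), snap = TRUE) {
  surveys <- tibble::as_tibble(surveys)
  miss <- setdiff(zone_map$zone, names(surveys))
  if (length(miss) > 0) {
    abort(paste0(
      "survey is missing zone column(s): ", paste(miss, collapse = ", ")
    ))
  }
  scores <- as.matrix(surveys[, zone_map$zone])
  if (anyNA(scores)) abort("every zone of the active zone map must be scored")
  if (snap) scores <- snap_zone_scores(scores)
  if (!all(scores %in% c(0, 25, 50, 75, 100))) {
    abort("zone scores must be on the scale {0, 25, 50, 75, 100}")
  }
  total <- drop(scores %*% zone_map$weight)
  out <- tibble::tibble(
    chimp_id = surveys$chimp_id,
    date = as.Date(surveys$date),
    total_pct = total,
    significant = flag_significant(total)
  )
  class(out) <- c("hairloss_result", class(out))
  out
}

#' Significance flag for total body hair loss
#'
#' An animal that has lost 25% or more of its estimated cumulative total
#' body hair is monitored at higher frequency.
#'
#' @param total_pct Numeric vector in \[0, 100\].
#' @return Logical vector, `TRUE` iff `total_pct >= 25`.
#' @export
flag_significant <- function(total_pct) {
  if (any(is.na(total_pct)) || any(total_pct < 0 | total_pct > 100)) {
    abort("total_pct must lie in [0, 100]")
  }
  total_pct >= 25
}

#' Plan hair-loss monitoring
#'
#' Colony-wide hair-loss surveys run once every 15 months. Animals with
#' significant loss (>= 25%) are instead observed every 4 months by three
#' different behavior-team members per occasion. Roster members with no
#' survey on file (new arrivals) are scheduled immediately for a baseline.
#'
#' @param significance Tibble with `chimp_id`, `significant` — typically the
#'   latest row per chimp of a [total_hair_loss()] result.
#' @param roster A [chimp_roster()].
#' @param start_date First day of the planning horizon.
#' @param horizon_months Planning horizon length in months (default 12).
#' @return Tibble: `chimp_id`, `planned_date`, `occasion`, `observer_slot`,
#'   `reason` (`"routine"`, `"escalated"`, `"baseline"`).
#' @export
schedule_hairloss <- function(significance, roster, start_date = Sys.Date(),
                              horizon_months = 12) {
  start_date <- as.Date(start_date)
  empty <- tibble::tibble(
    chimp_id = character(), planned_date = as.Date(character()),
    occasion = integer(), observer_slot = integer(), reason = character()
  )
  if (nrow(roster) == 0) {
    return(empty)
  }
  significance <- tibble::as_tibble(significance)
  add_months <- function(d, m) seq(d, by = paste(m, "months"), length.out = 2)[2]
  plan_one <- function(chimp) {
    known <- chimp %in% significance$chimp_id
    if (!known) {
      return(tibble::tibble(
        chimp_id = chimp, planned_date = start_date, occasion = 1L,
        observer_slot = 1L, reason = "baseline"
      ))
    }
    sig <- any(significance$significant[significance$chimp_id == chimp])
    if (sig) {
      n_occ <- max(1L, floor(horizon_months / 4))
      purrr::map_dfr(seq_len(n_occ), function(k) {
        tibble::tibble(
          chimp_id = chimp,
          planned_date = add_months(start_date, 4 * (k - 1)),
          occasion = k, observer_slot = 1:3, reason = "escalated"
        )
      })
    } else {
      n_occ <- max(1L, ceiling(horizon_months / 15))
      purrr::map_dfr(seq_len(n_occ), function(k) {
        tibble::tibble(
          chimp_id = chimp,
          planned_date = add_months(start_date, 15 * (k - 1)),
          occasion = k, observer_slot = 1L, reason = "routine"
        )
      })
    }
  }
  purrr::map_dfr(roster$chimp_id, plan_one)
}

#' Hair-loss trajectory for one chimpanzee
#'
#' Chronologically ordered totals with the change since the previous
#' survey, for tracking whether an intervention (extra forage, enrichment)
#' is associated with regrowth.
#'
#' @param results A [total_hair_loss()] tibble.
#' @param chimp Chimp id.
#' @return Tibble: `chimp_id`, `date`, `total_pct`, `delta` (`NA` for the
#'   first survey).
#' @export
hairloss_trajectory <- function(results, chimp) {
  out <- tibble::as_tibble(results) |>
    dplyr::filter(.data$chimp_id == chimp) |>
    dplyr::arrange(.data$date) |>
    dplyr::mutate(delta = .data$total_pct - dplyr::lag(.data$total_pct))
  if (nrow(out) == 0) abort(paste0("no hair-loss results for ", chimp))
  out[, c("chimp_id", "date", "total_pct", "delta")]
}
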