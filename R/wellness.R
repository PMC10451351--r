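#' The ten wellness survey parameters
#'
#' Parameter codes of the composite wellness survey: abnormal behavior
#' (ABN), locomotion (LOC), access to food/water (ACS), human-animal
#' interaction (HAI), coat appearance (COT), self-aggression (SAG), social
#' interaction (SIA), staff concern (SCO), enrichment/medication/reinforcer
#' acceptance (ENR) and wounds (WOU). Each assessor scores every parameter
#' on a raw 0-3 scale (0 = no concern).
#'
#' @return Character vector of the ten parameter codes.
#' @export
wellness_parameters <- function() {
  c("ABN", "LOC", "ACS", "HAI", "COT", "SAG", "SIA", "SCO", "ENR", "WOU")
}

#' Default wellness parameter weights
#'
#' Unit weights on all ten parameters, giving the documented scale maximum
#' of 30 (ten parameters x raw maximum 3). Facilities weighting parameters
#' by level of concern can pass their own named vector; [score_survey()]
#' warns when the attainable maximum differs from 30.
#'
#' @return Named numeric vector over [wellness_parameters()].
#' @export
default_wellness_weights <- function() {
  setNames(rep(1, 10), wellness_parameters())
}

#' Score one chimpanzee's wellness survey
#'
#' Multiple assessors (ideally one per animal-care department) each score
#' the ten parameters 0-3. Scores are averaged per parameter across
#' assessors, multiplied by the parameter weight, and the weighted means
#' are summed into the total wellness score. Under default unit weights the
#' total lies in \[0, 30\]; lower is better.
#'
#' @param responses Tibble of survey responses for one chimpanzee at one
#'   timepoint: columns `chimp_id`, `observer`, `date`, and the ten
#'   parameter columns.
#' @param weights Named positive weights over all ten parameters.
#' @return One-row tibble of class `wellness_score`: `chimp_id`, `date`,
#'   `n_assessors`, the ten weighted per-parameter means, `total`, `band`.
#' @export
#' @examples
#' r <- data.frame(
#'   chimp_id = "c1", observer = c("a", "b"), date = "2022-03-01",
#'   ABN = c(1, 2), LOC = 0, ACS = 0, HAI = 0, COT = 0,
#'   SAG = 0, SIA = 0, SCO = 0, ENR = 0, WOU = 0
#' )
#' score_survey(r)$total # 1.5
score_survey <- function(responses, weights = default_wellness_weights()) {
  responses <- tibble::as_tibble(responses)
  if (nrow(responses) == 0) abort("no responses to score")
  params <- wellness_parameters()
  miss <- setdiff(params, names(responses))
  if (length(miss) > 0) {
    abort(paste0("responses missing parameter(s): ", paste(miss, collapse = ", ")))
  }
  miss_w <- setdiff(params, names(weights))
  if (length(miss_w) > 0) {
    abort(paste0("weights missing parameter(s): ", paste(miss_w, collapse = ", ")))
  }
  if (any(weights[params] <= 0)) abort("weights must be positive")
  if (dplyr::n_distinct(responses$chimp_id) != 1) {
    abort("score_survey() scores one chimpanzee; see score_surveys()")
  }
  vals <- as.matrix(responses[, params])
  if (anyNA(vals) || !all(vals %in% 0:3)) {
    abort("raw parameter scores must all be in {0, 1, 2, 3}")
  }
  max_total <- sum(weights[params] * 3)
  if (abs(max_total - 30) > 1e-9) {
    warn(paste0(
      "attainable maximum under these weights is ", format(max_total),
      ", not the standard 30"
    ))
  }
  means <- colMeans(vals) * weights[params]
  total <- sum(means)
  out <- tibble::tibble(
    chimp_id = responses$chimp_id[1],
    date = as.Date(max(as.Date(responses$date))),
    n_assessors = nrow(responses)
  )
  out[params] <- as.list(means)
  out$total <- total
  out$band <- classify_wellness(total)
  class(out) <- c("wellness_score", class(out))
  out
}

#' Score many surveys at once
#'
#' Applies [score_survey()] to each (chimp, date) cell of a response table.
#'
#' @inheritParams score_survey
#' @return Tibble of class `wellness_score`, one row per chimp-date.
#' @export
score_surveys <- function(responses, weights = default_wellness_weights()) {
  responses <- tibble::as_tibble(responses)
  responses$date <- as.Date(responses$date)
  out <- responses |>
    dplyr::group_by(.data$chimp_id, .data$date) |>
    dplyr::group_modify(function(d, key) {
      d$chimp_id <- key$chimp_id
      d$date <- key$date
      s <- suppressWarnings(score_survey(d, weights))
      s[, setdiff(names(s), c("chimp_id", "date"))]
    }) |>
    dplyr::ungroup()
  class(out) <- c("wellness_score", class(out))
  out
}

#' Classify a total wellness score into an action band
#'
#' Bands follow the protocol's published cutpoints: scores below 12 continue
#' routine quarterly monitoring ("routine"); scores from 12 through 29 may
#' require additional observation or intervention ("elevated"); scores above
#' 29 are reported immediately to the veterinarian and behaviorist
#' ("critical"). The published band edges overlap at 12 and leave a gap
#' below the scale maximum; this implementation resolves both toward
#' concern: 12 itself is elevated, and everything above 29 is critical.
#'
#' @param total Numeric vector of total scores (>= 0).
#' @return Character vector: `"routine"`, `"elevated"` or `"critical"`.
#' @export
#' @examples
#' classify_wellness(c(0, 1.52, 12, 29, 29.5))
classify_wellness <- function(total) {
  if (any(is.na(total)) || any(total < 0)) {
    abort("total wellness scores must be non-negative")
  }
  dplyr::case_when(
    total < 12 ~ "routine",
    total <= 29 ~ "elevated",
    TRUE ~ "critical"
  )
}

#' Fraction of chimpanzees of concern per wellness parameter
#'
#' A chimpanzee is "of concern" on a parameter when any of its scores in
#' the period has a weighted per-parameter mean at or above the concern
#' cutoff (default 1.0 — at least one assessor-average step above "no
#' concern").
#'
#' @param scores A `wellness_score` tibble (from [score_surveys()]).
#' @param period Length-2 date vector (inclusive); defaults to all scores.
#' @param cutoff Concern cutoff on the weighted parameter mean.
#' @return Tibble: `parameter`, `n_concern`, `n_chimps`, `fraction`.
#' @export
parameter_concern_summary <- function(scores, period = NULL, cutoff = 1) {
  scores <- tibble::as_tibble(scores)
  if (!is.null(period)) {
    period <- as.Date(period)
    scores <- dplyr::filter(
      scores,
      .data$date >= period[1], .data$date <= period[2]
    )
  }
  n_chimps <- dplyr::n_distinct(scores$chimp_id)
  long <- tidyr::pivot_longer(
    scores[, c("chimp_id", wellness_parameters())],
    -"chimp_id",
    names_to = "parameter", values_to = "value"
  )
  long |>
    dplyr::group_by(parameter = factor(.data$parameter, wellness_parameters())) |>
    dplyr::summarise(
      n_concern = dplyr::n_distinct(.data$chimp_id[.data$value >= cutoff]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      parameter = as.character(.data$parameter),
      n_chimps = n_chimps,
      fraction = ifelse(n_chimps == 0, 0, .data$n_concern / n_chimps)
    )
}

#' Plan quarterly wellness surveys
#'
#' Every animal is surveyed once per quarter, four times a year, so each is
#' seen across the seasons. Surveys are planned mid-quarter.
#'
#' @param roster A [chimp_roster()] (or any table with `chimp_id`).
#' @param year Calendar year.
#' @return Tibble: `chimp_id`, `quarter`, `planned_date` (4 rows per chimp).
#' @export
schedule_wellness <- function(roster, year) {
  if (nrow(roster) == 0) {
    return(tibble::tibble(
      chimp_id = character(), quarter = integer(),
      planned_date = as.Date(character())
    ))
  }
  mid <- as.Date(paste0(year, c("-02-15", "-05-15", "-08-15", "-11-15")))
  tidyr::expand_grid(
    chimp_id = roster$chimp_id,
    quarter = 1:4
  ) |>
    dplyr::mutate(planned_date = mid[.data$quarter])
}
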