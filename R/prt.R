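#' Deterministic positive-reinforcement-training session key
#'
#' A session is uniquely identified by its date, time of day, trainer and
#' chimpanzee; the key is deterministic and injective over distinct
#' component tuples (a length-prefixed encoding prevents collisions from
#' delimiter characters inside components).
#'
#' @param date,time,trainer,chimp Session components; all required.
#' @return Character vector of opaque session keys.
#' @export
#' @examples
#' prt_session_id("2022-03-01", "09:30", "rl", "Tessa")
prt_session_id <- function(date, time, trainer, chimp) {
  parts <- list(as.character(date), as.character(time), as.character(trainer), as.character(chimp))
  if (any(vapply(parts, function(p) any(is.na(p) | p == ""), logical(1)))) {
    abort("session id requires date, time, trainer and chimp")
  }
  enc <- lapply(parts, function(p) paste0(nchar(p), ":", p))
  paste(enc[[1]], enc[[2]], enc[[3]], enc[[4]], sep = "|")
}

#' Colony training-engagement summary
#'
#' Session counts and colony coverage for a period: distinct sessions (by
#' session key), sessions per month, distinct animals trained, and the
#' fraction of the roster with at least one session.
#'
#' @param sessions PRT log tibble (`date`, `time_of_day`, `trainer`,
#'   `chimp_id`, `cue`, `response`, one row per cue-response).
#' @param roster A [chimp_roster()].
#' @param period Optional length-2 inclusive date range; defaults to the
#'   span of the sessions.
#' @return One-row tibble: `n_sessions`, `sessions_per_month`,
#'   `n_chimps_trained`, `fraction_colony`.
#' @export
engagement_summary <- function(sessions, roster, period = NULL) {
  if (nrow(roster) == 0) abort("roster must be non-empty")
  sessions <- tibble::as_tibble(sessions)
  sessions$date <- as.Date(sessions$date)
  if (!is.null(period)) {
    period <- as.Date(period)
    sessions <- dplyr::filter(
      sessions, .data$date >= period[1], .data$date <= period[2]
    )
  }
  if (nrow(sessions) == 0) {
    return(tibble::tibble(
      n_sessions = 0L, sessions_per_month = 0,
      n_chimps_trained = 0L, fraction_colony = 0
    ))
  }
  keys <- prt_session_id(
    sessions$date, sessions$time_of_day, sessions$trainer, sessions$chimp_id
  )
  span <- if (!is.null(period)) period else range(sessions$date)
  months <- max(1, as.numeric(span[2] - span[1] + 1) / 30.44)
  trained <- intersect(unique(sessions$chimp_id), roster$chimp_id)
  tibble::tibble(
    n_sessions = dplyr::n_distinct(keys),
    sessions_per_month = dplyr::n_distinct(keys) / months,
    n_chimps_trained = length(trained),
    fraction_colony = length(trained) / nrow(roster)
  )
}

#' Shifting compliance
#'
#' Percent of eligible asked-days on which an animal complied with the
#' shift goal. Days excluded for weather and days with an alternate goal
#' are removed from the denominator; with no eligible days the result is
#' undefined (`NA`), which is distinct from 0%.
#'
#' @param records Long shift log: one row per (shift day, chimp) with
#'   `date`, `chimp_id`, `weather_excluded`, `alternate_goal`, `complied`.
#' @param chimp Optional chimp id(s) to restrict to.
#' @param period Optional length-2 inclusive date range (e.g. one month).
#' @return Tibble per chimp: `chimp_id`, `eligible_days`, `complied_days`,
#'   `compliance_pct` (`NA` when no eligible days).
#' @export
shifting_compliance <- function(records, chimp = NULL, period = NULL) {
  records <- tibble::as_tibble(records)
  records$date <- as.Date(records$date)
  if (!is.null(chimp)) {
    records <- dplyr::filter(records, .data$chimp_id %in% chimp)
  }
  if (!is.null(period)) {
    period <- as.Date(period)
    records <- dplyr::filter(
      records, .data$date >= period[1], .data$date <= period[2]
    )
  }
  records |>
    dplyr::group_by(.data$chimp_id) |>
    dplyr::summarise(
      eligible_days = dplyr::n_distinct(
        .data$date[!.data$weather_excluded & !.data$alternate_goal]
      ),
      complied_days = dplyr::n_distinct(
        .data$date[!.data$weather_excluded & !.data$alternate_goal &
          .data$complied]
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      compliance_pct = ifelse(
        .data$eligible_days == 0, NA_real_,
        100 * .data$complied_days / .data$eligible_days
      )
    )
}

#' Cue-response trend for one chimpanzee
#'
#' Chronological series of 1-3 response scores for a training cue with
#' per-period means (3 = correct response most of the time; 1 = seldom or
#' never responded).
#'
#' @param sessions PRT log tibble.
#' @param chimp Chimp id.
#' @param cue Behavior cue name; must appear in at least one session.
#' @param period_unit `"month"` or `"week"` for the mean aggregation.
#' @return Tibble: `period`, `n`, `mean_score` (means lie in \[1, 3\]).
#' @export
response_trend <- function(sessions, chimp, cue, period_unit = c("month", "week")) {
  period_unit <- match.arg(period_unit)
  sessions <- tibble::as_tibble(sessions)
  sessions$date <- as.Date(sessions$date)
  sel <- dplyr::filter(sessions, .data$chimp_id == chimp, .data$cue == .env$cue)
  if (nrow(sel) == 0) {
    abort(paste0("cue '", cue, "' never recorded for ", chimp))
  }
  if (!all(sel$response %in% 1:3)) {
    abort("response scores must be in {1, 2, 3}")
  }
  sel$period <- if (period_unit == "month") {
    format(sel$date, "%Y-%m")
  } else {
    format(sel$date - (as.integer(format(sel$date, "%u")) - 1L), "%Y-%m-%d")
  }
  sel |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_score = mean(.data$response),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$period)
}
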