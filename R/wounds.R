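#' Default rolling-window wound concern criteria
#'
#' The counts of wounds within any 14-day period that place an individual
#' at a higher level of concern: 10 wounds of any grade, 4 wounds of grade
#' 3, 3 wounds of grade 4, or a single grade-5 wound. Grade-specific
#' criteria count wounds of exactly that grade; higher grades carry their
#' own stricter criteria.
#'
#' @return Named integer vector of thresholds.
#' @export
default_wound_criteria <- function() {
  c(any_grade_total = 10L, grade3_count = 4L, grade4_count = 3L, grade5_count = 1L)
}

window_days <- 14L

#' Effective wounds inside a 14-day window
#'
#' The wound log records only initial occurrences and severity escalations,
#' so one wound can appear several times. Within a window a wound counts
#' once, graded at its maximum grade among in-window events; events dated
#' outside the window are ignored even when the same wound has events
#' inside it.
#'
#' @param log Wound event tibble (see [validate_wounds()]).
#' @param chimp Chimp id.
#' @param window_start First day of the 14-day window (inclusive; the
#'   window ends 13 days later).
#' @return Tibble: `wound_id`, `grade` (max in-window grade), `first_date`.
#' @export
effective_wounds_in_window <- function(log, chimp, window_start) {
  log <- tibble::as_tibble(log)
  window_start <- as.Date(window_start)
  window_end <- window_start + (window_days - 1L)
  inw <- log |>
    dplyr::filter(
      .data$chimp_id == chimp,
      as.Date(.data$date) >= window_start,
      as.Date(.data$date) <= window_end
    )
  if (nrow(inw) == 0) {
    return(tibble::tibble(
      wound_id = character(), grade = integer(),
      first_date = as.Date(character())
    ))
  }
  inw |>
    dplyr::group_by(.data$wound_id) |>
    dplyr::summarise(
      grade = max(.data$grade),
      first_date = min(as.Date(.data$date)),
      .groups = "drop"
    )
}

criterion_counts <- function(wounds, criteria) {
  vapply(names(criteria), function(cr) {
    if (cr == "any_grade_total") {
      nrow(wounds)
    } else {
      g <- as.integer(sub("^grade(\\d)_count$", "\\1", cr))
      sum(wounds$grade == g)
    }
  }, integer(1))
}

#' Raise wound concern flags from rolling 14-day windows
#'
#' For every chimpanzee, every 14-day window anchored at one of its event
#' dates is evaluated against each criterion. Anchoring windows at event
#' dates is sufficient: any real-valued window can be slid until its start
#' coincides with the earliest event it contains without losing events.
#' Per (chimp, criterion), overlapping satisfying windows are collapsed to
#' one flag at the earliest window of each contiguous episode, so a single
#' wounding bout yields a single alert rather than one per day.
#'
#' @param log Wound event tibble.
#' @param criteria Named positive thresholds, as [default_wound_criteria()].
#' @return Tibble of class `concern_flags`: `chimp_id`, `window_start`,
#'   `window_end`, `criterion`, `count`.
#' @export
#' @examples
#' log <- data.frame(
#'   wound_id = "w1", chimp_id = "c1", date = as.Date("2022-05-01"),
#'   grade = 5L, event_kind = "initial"
#' )
#' wound_concern_flags(log)
wound_concern_flags <- function(log, criteria = default_wound_criteria()) {
  if (any(criteria <= 0) || any(criteria != as.integer(criteria))) {
    abort("wound criteria thresholds must be positive integers")
  }
  log <- tibble::as_tibble(log)
  log$date <- as.Date(log$date)
  empty <- tibble::tibble(
    chimp_id = character(), window_start = as.Date(character()),
    window_end = as.Date(character()), criterion = character(),
    count = integer()
  )
  if (nrow(log) == 0) {
    class(empty) <- c("concern_flags", class(empty))
    return(empty)
  }
  hits <- purrr::map_dfr(unique(log$chimp_id), function(ch) {
    anchors <- sort(unique(log$date[log$chimp_id == ch]))
    purrr::map_dfr(anchors, function(d) {
      wounds <- effective_wounds_in_window(log, ch, d)
      counts <- criterion_counts(wounds, criteria)
      met <- counts >= criteria
      if (!any(met)) {
        return(NULL)
      }
      tibble::tibble(
        chimp_id = ch, window_start = d, window_end = d + (window_days - 1L),
        criterion = names(criteria)[met], count = as.integer(counts[met])
      )
    })
  })
  if (nrow(hits) == 0) {
    class(empty) <- c("concern_flags", class(empty))
    return(empty)
  }
  out <- hits |>
    dplyr::arrange(.data$chimp_id, .data$criterion, .data$window_start) |>
    dplyr::group_by(.data$chimp_id, .data$criterion) |>
    dplyr::mutate(
      episode = cumsum(c(
        1L,
        as.integer(diff(as.numeric(.data$window_start)) >= window_days)
      ))
    ) |>
    dplyr::group_by(.data$chimp_id, .data$criterion, .data$episode) |>
    dplyr::slice_min(.data$window_start, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"episode") |>
    dplyr::relocate("chimp_id", "window_start", "window_end", "criterion", "count") |>
    dplyr::arrange(.data$chimp_id, .data$window_start, .data$criterion)
  class(out) <- c("concern_flags", class(out))
  out
}

#' Severity distribution of effective wounds
#'
#' Proportions of deduplicated wounds by severity grade over a period, each
#' wound graded at its maximum recorded grade in the period.
#'
#' @param log Wound event tibble.
#' @param period Optional length-2 inclusive date range.
#' @return Tibble: `grade` (1-5), `n`, `proportion` (sums to 1).
#' @export
severity_distribution <- function(log, period = NULL) {
  log <- tibble::as_tibble(log)
  log$date <- as.Date(log$date)
  if (!is.null(period)) {
    period <- as.Date(period)
    log <- dplyr::filter(log, .data$date >= period[1], .data$date <= period[2])
  }
  if (nrow(log) == 0) {
    abort("no effective wounds in the period; distribution undefined")
  }
  eff <- log |>
    dplyr::group_by(.data$wound_id) |>
    dplyr::summarise(grade = max(.data$grade), .groups = "drop")
  tibble::tibble(grade = 1:5) |>
    dplyr::left_join(dplyr::count(eff, .data$grade), by = "grade") |>
    dplyr::mutate(
      n = tidyr::replace_na(.data$n, 0L),
      proportion = .data$n / sum(.data$n)
    )
}

#' Wound frequency-by-severity time series
#'
#' Bins effective wounds (deduplicated to their first in-bin event, graded
#' at the running maximum at that time) by day, week or month, per
#' individual, per group or for the whole colony.
#'
#' @param log Wound event tibble.
#' @param roster Optional [chimp_roster()], required for `grouping = "group"`.
#' @param grouping `"individual"`, `"group"` or `"colony"`.
#' @param bin `"day"`, `"week"` or `"month"`.
#' @return Tibble: `subject`, `bin_start`, `grade`, `n`; the grand total of
#'   `n` equals the number of effective wounds.
#' @export
wound_timeline <- function(log, roster = NULL,
                           grouping = c("colony", "group", "individual"),
                           bin = c("day", "week", "month")) {
  grouping <- match.arg(grouping)
  bin <- match.arg(bin)
  log <- tibble::as_tibble(log)
  log$date <- as.Date(log$date)
  eff <- log |>
    dplyr::group_by(.data$wound_id) |>
    dplyr::summarise(
      chimp_id = dplyr::first(.data$chimp_id),
      date = min(.data$date),
      grade = max(.data$grade),
      .groups = "drop"
    )
  subject <- switch(grouping,
    colony = rep("colony", nrow(eff)),
    individual = eff$chimp_id,
    group = {
      if (is.null(roster)) abort("grouping = 'group' requires a roster")
      idx <- match(eff$chimp_id, roster$chimp_id)
      if (anyNA(idx)) {
        abort(paste0(
          "chimp id(s) not in roster: ",
          paste(unique(eff$chimp_id[is.na(idx)]), collapse = ", ")
        ))
      }
      roster$group_id[idx]
    }
  )
  bin_start <- switch(bin,
    day = eff$date,
    week = eff$date - (as.integer(format(eff$date, "%u")) - 1L),
    month = as.Date(format(eff$date, "%Y-%m-01"))
  )
  tibble::tibble(subject = subject, bin_start = bin_start, grade = eff$grade) |>
    dplyr::count(.data$subject, .data$bin_start, .data$grade, name = "n") |>
    dplyr::arrange(.data$subject, .data$bin_start, .data$grade)
}
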