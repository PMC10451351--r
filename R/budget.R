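new_time_budget <- function(pct, n_samples, subject, period, basis) {
  out <- tibble::tibble(
    category = behavior_categories(),
    pct = as.numeric(pct[behavior_categories()])
  )
  attr(out, "subject") <- subject
  attr(out, "period") <- period
  attr(out, "n_samples") <- n_samples
  attr(out, "basis") <- basis
  class(out) <- c("time_budget", class(out))
  out
}

filter_scope <- function(records, subject, period, id_col) {
  records <- tibble::as_tibble(records)
  if (!is.null(subject)) {
    records <- records[records[[id_col]] %in% subject, , drop = FALSE]
  }
  if (!is.null(period)) {
    period <- as.Date(period)
    d <- as.Date(records$timestamp)
    records <- records[d >= period[1] & d <= period[2], , drop = FALSE]
  }
  records
}

#' Activity budget from instantaneous scans
#'
#' The fraction of sampled instants spent in each behavior category,
#' expressed as percent of observation time. All-occurrence and continuous
#' records are excluded from both numerator and denominator; categories
#' with no scans report 0 so budgets always cover the full category set
#' and sum to 100.
#'
#' @param records Observation records (see [read_records()] schema
#'   `"observation"`).
#' @param ethogram An [ethogram()] governing the records.
#' @param subject Optional chimp id(s) to restrict to; `NULL` = all
#'   (pooled, e.g. a group or the colony).
#' @param period Optional length-2 inclusive date range.
#' @return A `time_budget` tibble: `category`, `pct`, with attributes
#'   `subject`, `period`, `n_samples`, `basis`.
#' @export
budget_from_scans <- function(records, ethogram = default_ethogram(),
                              subject = NULL, period = NULL) {
  records <- filter_scope(records, subject, period, "focal_id")
  scans <- records[records$sampling == "instantaneous", , drop = FALSE]
  if (nrow(scans) == 0) abort("no instantaneous scans in scope")
  idx <- match(scans$behavior_code, ethogram$code)
  if (anyNA(idx)) {
    abort(paste0(
      "behavior code(s) not in ethogram: ",
      paste(unique(scans$behavior_code[is.na(idx)]), collapse = ", ")
    ))
  }
  cat <- ethogram$category[idx]
  counts <- table(factor(cat, behavior_categories()))
  pct <- 100 * as.numeric(counts) / nrow(scans)
  new_time_budget(setNames(pct, names(counts)), nrow(scans),
    subject %||% "all", period, "scans"
  )
}

#' Activity budget from continuous focal sessions
#'
#' Duration-weighted budget from continuous focal-follow records (e.g. the
#' daily 15-min Targeted Individual Assessment follows): percent of
#' observed seconds per behavior category. Records within one session
#' (same focal, observer, date) must not overlap in time.
#'
#' @inheritParams budget_from_scans
#' @param chimp Chimp id the sessions belong to.
#' @return A `time_budget` tibble; `n_samples` is total observed seconds.
#' @export
budget_from_focal <- function(records, ethogram = default_ethogram(),
                              chimp = NULL, period = NULL) {
  records <- filter_scope(records, chimp, period, "focal_id")
  foc <- records[records$sampling == "continuous", , drop = FALSE]
  if (nrow(foc) == 0) abort("no continuous focal records in scope")
  if (anyNA(foc$duration_s) || any(foc$duration_s <= 0)) {
    abort("continuous records require positive duration_s")
  }
  overlap <- foc |>
    dplyr::mutate(day = as.Date(.data$timestamp)) |>
    dplyr::group_by(.data$focal_id, .data$observer, .data$day) |>
    dplyr::arrange(.data$timestamp, .by_group = TRUE) |>
    dplyr::summarise(
      ok = dplyr::n() == 1 || all(diff(as.numeric(.data$timestamp)) >=
        .data$duration_s[-dplyr::n()]),
      .groups = "drop"
    )
  if (!all(overlap$ok)) {
    abort("overlapping intervals within a focal session")
  }
  idx <- match(foc$behavior_code, ethogram$code)
  if (anyNA(idx)) {
    abort(paste0(
      "behavior code(s) not in ethogram: ",
      paste(unique(foc$behavior_code[is.na(idx)]), collapse = ", ")
    ))
  }
  secs <- tapply(foc$duration_s, factor(ethogram$category[idx], behavior_categories()), sum)
  secs[is.na(secs)] <- 0
  pct <- 100 * secs / sum(foc$duration_s)
  new_time_budget(pct, sum(foc$duration_s), chimp %||% "all", period, "focal")
}

#' Event rates for all-occurrence behaviors
#'
#' All-occurrence sampling tallies every event of selected rare behaviors;
#' dividing by observed time gives events per observation hour.
#'
#' @inheritParams budget_from_scans
#' @param hours_observed Total observation time in hours (> 0).
#' @return Tibble: `behavior_code`, `n`, `rate_per_hour`, covering every
#'   all-occurrence code of the ethogram.
#' @export
all_occurrence_rates <- function(records, hours_observed,
                                 ethogram = default_ethogram(),
                                 subject = NULL, period = NULL) {
  if (is.na(hours_observed) || hours_observed <= 0) {
    abort("hours_observed must be positive")
  }
  records <- filter_scope(records, subject, period, "focal_id")
  ao_codes <- ethogram$code[ethogram$sampling == "all_occurrence"]
  ev <- records[records$sampling == "all_occurrence", , drop = FALSE]
  bad <- setdiff(unique(ev$behavior_code), ao_codes)
  if (length(bad) > 0) {
    abort(paste0(
      "not an all-occurrence code: ", paste(bad, collapse = ", ")
    ))
  }
  counts <- table(factor(ev$behavior_code, ao_codes))
  tibble::tibble(
    behavior_code = ao_codes,
    n = as.integer(counts),
    rate_per_hour = as.numeric(counts) / hours_observed
  )
}

#' Social Monitoring System observation schedule table
#'
#' The fixed mapping from the reason an animal is placed on social
#' monitoring to the span of the observation period and the number of
#' 10-min focal follows per chimpanzee.
#'
#' @return Tibble with 13 rows: `reason`, `duration`, `duration_days`,
#'   `n_observations`.
#' @export
sms_schedule_table <- function() {
  tibble::tribble(
    ~reason, ~duration, ~n_observations,
    "Post-Social Integration", "3 months", 13L,
    "Separation from Group", "3 months", 13L,
    "Yearly Check-In", "6 weeks", 6L,
    "Wounding/Aggression/Welfare", "6 weeks", 6L,
    "Considered for Integration", "6 weeks", 6L,
    "Release to Novel Area", "4 weeks", 4L,
    "New Arrival", "3 months", 13L,
    "Pre-Social Integration", "6 weeks", 6L,
    "Wounding/Aggression Check-In", "6 weeks", 6L,
    "New Arrival 6 Month Check In", "4 weeks", 4L,
    "Integration Check In 6 Months", "4 weeks", 4L,
    "Integration Check-In 1 Year", "4 weeks", 4L,
    "Death of a Group Member", "6 weeks", 6L
  ) |>
    dplyr::mutate(
      duration_days = dplyr::case_when(
        .data$duration == "3 months" ~ 91L,
        .data$duration == "6 weeks" ~ 42L,
        .data$duration == "4 weeks" ~ 28L
      ),
      .after = "duration"
    )
}

#' Look up the observation schedule for a monitoring reason
#'
#' @param reason One of the 13 reasons in [sms_schedule_table()].
#' @return One-row tibble: `reason`, `duration`, `duration_days`,
#'   `n_observations`.
#' @export
#' @examples
#' sms_schedule("Post-Social Integration")
sms_schedule <- function(reason) {
  tab <- sms_schedule_table()
  hit <- tab[tab$reason == reason, , drop = FALSE]
  if (nrow(hit) == 0) {
    abort(paste0(
      "unknown SMS reason '", reason, "'; valid reasons: ",
      paste(tab$reason, collapse = "; ")
    ))
  }
  hit
}

#' Assign dated, time-blocked observation slots
#'
#' Spreads the scheduled number of observations evenly across the
#' observation span and assigns each, uniformly at random, to one of the
#' three daily observation blocks (07:30-10:30, 10:30-12:30, 13:30-15:30).
#' Deterministic given the seed.
#'
#' @param schedule One-row schedule from [sms_schedule()].
#' @param chimp Chimp id.
#' @param start_date First day of the observation span.
#' @param seed Integer seed for block assignment.
#' @return Tibble: `chimp_id`, `date`, `block` (`"07:30-10:30"` etc.),
#'   `slot`.
#' @export
assign_observation_slots <- function(schedule, chimp, start_date, seed = 1L) {
  start_date <- as.Date(start_date)
  n <- schedule$n_observations[1]
  span <- schedule$duration_days[1]
  if (n < 1) abort("n_observations must be >= 1")
  if (span < n) abort("observation span shorter than the number of slots")
  blocks <- c("07:30-10:30", "10:30-12:30", "13:30-15:30")
  offsets <- round(seq(0, span - 1, length.out = n))
  picks <- with_seed(seed, sample(blocks, n, replace = TRUE))
  tibble::tibble(
    chimp_id = chimp,
    date = start_date + offsets,
    block = picks,
    slot = seq_len(n)
  )
}

#' Evaluate Targeted Individual Assessment triggers
#'
#' A Targeted Individual Assessment (TIA) — intensive daily focal follows
#' on one animal — is triggered by any of four causes: a high-priority
#' abnormal-behavior report; wound concern criteria met on the rolling
#' wound surveillance; an abnormal-behavior share of the activity budget
#' strictly greater than the threshold (default 10%); or an externally
#' reported notable behavioral change (eating habits, locomotion).
#'
#' @param chimp Chimp id.
#' @param budget Optional `time_budget` for the chimp.
#' @param reports Optional tibble of abnormal-behavior reports: `chimp_id`,
#'   `date`, `kind` (`"high_priority"`, `"notable_change"`, other kinds are
#'   kept on file but trigger nothing).
#' @param wound_flags Optional [wound_concern_flags()] result.
#' @param threshold_pct Budget trigger threshold in percent (strict `>`).
#' @param as_of Date stamped on budget-driven triggers.
#' @return Tibble: `chimp_id`, `date`, `cause`, `evidence`.
#' @export
evaluate_tia_triggers <- function(chimp, budget = NULL, reports = NULL,
                                  wound_flags = NULL, threshold_pct = 10,
                                  as_of = Sys.Date()) {
  out <- list()
  if (!is.null(reports) && nrow(reports) > 0) {
    rep_c <- dplyr::filter(tibble::as_tibble(reports), .data$chimp_id == chimp)
    hp <- dplyr::filter(rep_c, .data$kind == "high_priority")
    if (nrow(hp) > 0) {
      out$hp <- tibble::tibble(
        chimp_id = chimp, date = as.Date(min(hp$date)),
        cause = "high_priority_report",
        evidence = paste0(nrow(hp), " high-priority report(s)")
      )
    }
    nc <- dplyr::filter(rep_c, .data$kind == "notable_change")
    if (nrow(nc) > 0) {
      out$nc <- tibble::tibble(
        chimp_id = chimp, date = as.Date(min(nc$date)),
        cause = "notable_change_report",
        evidence = paste0(nrow(nc), " notable-change report(s)")
      )
    }
  }
  if (!is.null(wound_flags) && nrow(wound_flags) > 0) {
    wf <- dplyr::filter(tibble::as_tibble(wound_flags), .data$chimp_id == chimp)
    if (nrow(wf) > 0) {
      out$wf <- tibble::tibble(
        chimp_id = chimp, date = as.Date(min(wf$window_start)),
        cause = "wound_criteria",
        evidence = paste0(
          "criteria met: ", paste(unique(wf$criterion), collapse = ", ")
        )
      )
    }
  }
  if (!is.null(budget)) {
    ab <- budget$pct[budget$category == "abnormal"]
    if (length(ab) == 1 && ab > threshold_pct) {
      out$ab <- tibble::tibble(
        chimp_id = chimp, date = as.Date(as_of),
        cause = "abnormal_budget_exceeds",
        evidence = sprintf(
          "abnormal %.2f%% of budget > %.1f%%", ab, threshold_pct
        )
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      chimp_id = character(), date = as.Date(character()),
      cause = character(), evidence = character()
    ))
  }
  dplyr::bind_rows(out)
}

#' Compare activity budgets before and after an intervention
#'
#' Per-category change in percentage points between a pre-intervention and
#' a post-intervention budget over the same ethogram. Because both budgets
#' sum to 100, deltas sum to zero.
#'
#' @param pre,post `time_budget` tibbles.
#' @return Tibble: `category`, `pre_pct`, `post_pct`, `delta`.
#' @export
pre_post_comparison <- function(pre, post) {
  if (!identical(sort(pre$category), sort(post$category))) {
    abort("pre and post budgets cover different category sets")
  }
  idx <- match(pre$category, post$category)
  tibble::tibble(
    category = pre$category,
    pre_pct = pre$pct,
    post_pct = post$pct[idx],
    delta = post$pct[idx] - pre$pct
  )
}
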