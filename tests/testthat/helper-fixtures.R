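# Small in-code fixtures and independent brute-force oracles shared by the
# test files.

tiny_roster <- function() {
  chimp_roster(tibble::tibble(
    chimp_id = c("Kasey", "Latoya", "Tessa", "Blue"),
    name = c("Kasey", "Latoya", "Tessa", "Blue"),
    sex = c("M", "F", "F", "M"),
    birth_date = as.Date(c("1988-01-01", "1995-06-01", "1998-09-01", "1985-02-01")),
    group_id = c("g1", "g1", "g2", "g2")
  ))
}

# One wellness response row, all parameters at `value` unless overridden.
wellness_row <- function(chimp_id = "Kasey", observer = "a",
                         date = "2022-03-01", value = 0, ...) {
  row <- tibble::tibble(
    chimp_id = chimp_id, observer = observer,
    department = "behavior", date = as.Date(date)
  )
  row[wellness_parameters()] <- value
  over <- list(...)
  row[names(over)] <- over
  row
}

wound_event <- function(wound_id, chimp_id, date, grade, kind = "initial") {
  tibble::tibble(
    wound_id = wound_id, chimp_id = chimp_id, date = as.Date(date),
    grade = as.integer(grade), event_kind = kind
  )
}

# k grade-`grade` wounds on consecutive days for one chimp
consecutive_wounds <- function(k, grade = 1, chimp = "Kasey",
                               start = as.Date("2022-05-01")) {
  purrr::map_dfr(seq_len(k), function(i) {
    wound_event(paste0("w", i), chimp, start + i - 1, grade)
  })
}

# Independent oracle: enumerate every 14-day window over every anchor date
# (not just event-anchored ones) and report which (chimp, criterion) pairs
# have a satisfying window, with the criterion counts per window computed
# from first principles.
brute_force_flagged <- function(log, criteria = default_wound_criteria()) {
  log <- tibble::as_tibble(log)
  log$date <- as.Date(log$date)
  out <- list()
  for (ch in unique(log$chimp_id)) {
    sub <- log[log$chimp_id == ch, ]
    starts <- seq(min(sub$date) - 13, max(sub$date), by = "day")
    for (s in as.list(starts)) {
      inw <- sub[sub$date >= s & sub$date <= s + 13, ]
      if (nrow(inw) == 0) next
      grades <- vapply(
        split(inw$grade, inw$wound_id), max, numeric(1)
      )
      counts <- c(
        any_grade_total = length(grades),
        grade3_count = sum(grades == 3),
        grade4_count = sum(grades == 4),
        grade5_count = sum(grades == 5)
      )
      for (cr in names(criteria)) {
        if (counts[[cr]] >= criteria[[cr]]) {
          out[[paste(ch, cr)]] <- tibble::tibble(
            chimp_id = ch, criterion = cr,
            first_start = min(
              out[[paste(ch, cr)]]$first_start %||% as.Date(s), as.Date(s)
            )
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      chimp_id = character(), criterion = character(),
      first_start = as.Date(character())
    ))
  }
  dplyr::arrange(dplyr::bind_rows(out), chimp_id, criterion)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random valid wound log (initial events only) for oracle-equivalence runs.
random_wound_log <- function(n_events, n_chimps = 3, span_days = 40,
                             start = as.Date("2022-01-01")) {
  tibble::tibble(
    wound_id = paste0("w", seq_len(n_events)),
    chimp_id = paste0("c", sample.int(n_chimps, n_events, replace = TRUE)),
    date = start + sample.int(span_days, n_events, replace = TRUE) - 1L,
    grade = sample(1:5, n_events, replace = TRUE, prob = c(.4, .3, .2, .07, .03)),
    event_kind = "initial"
  )
}

# Independent oracle: per-night pair enumeration for the sociogram matrix.
brute_force_pair_counts <- function(obs, group, classes) {
  m <- matrix(0L, length(group), length(group), dimnames = list(group, group))
  for (d in unique(obs$date)) {
    night <- obs[obs$date == d & obs$proximity %in% classes, ]
    seen <- character()
    for (i in seq_len(nrow(night))) {
      a <- night$chimp_id[i]
      b <- night$neighbor_id[i]
      key <- paste(min(a, b), max(a, b))
      if (!key %in% seen) {
        m[a, b] <- m[a, b] + 1L
        m[b, a] <- m[b, a] + 1L
        seen <- c(seen, key)
      }
    }
  }
  m
}

# Random valid night-observation table over a fixed group.
random_nights <- function(group, n_nights, p_alone = 0.2,
                          start = as.Date("2022-03-01")) {
  purrr::map_dfr(seq_len(n_nights), function(d) {
    purrr::map_dfr(group, function(ch) {
      alone <- runif(1) < p_alone
      tibble::tibble(
        chimp_id = ch,
        date = start + d - 1L,
        location = sample(c("indoor", "outdoor"), 1, prob = c(.9, .1)),
        proximity = if (alone) "no_neighbor" else sample(
          c("contact", "arms_reach", "within_3m", "outside_3m"), 1
        ),
        neighbor_id = if (alone) NA_character_ else sample(setdiff(group, ch), 1)
      )
    })
  })
}

simple_scan <- function(code, focal = "Kasey", sampling = "instantaneous",
                        duration = NA_real_, day = "2022-06-01") {
  tibble::tibble(
    timestamp = as.POSIXct(paste(day, "09:00:00"), tz = "UTC"),
    observer = "obs1", focal_id = focal, behavior_code = code,
    sampling = sampling, duration_s = duration,
    neighbors_within_1m = NA_character_
  )
}
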