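test_that("a wound counts once per window at its maximum in-window grade", {
  log <- dplyr::bind_rows(
    wound_event("w", "c1", "2022-05-01", 2, "initial"),
    wound_event("w", "c1", "2022-05-05", 4, "escalation")
  )
  # window covering both events: counted once at grade 4
  eff <- effective_wounds_in_window(log, "c1", "2022-05-01")
  expect_equal(nrow(eff), 1)
  expect_equal(eff$grade, 4)
  # escalation outside the window: counted at the initial grade
  log2 <- dplyr::bind_rows(
    wound_event("w", "c1", "2022-05-01", 2, "initial"),
    wound_event("w", "c1", "2022-05-20", 4, "escalation")
  )
  eff2 <- effective_wounds_in_window(log2, "c1", "2022-05-01")
  expect_equal(eff2$grade, 2)
  expect_equal(nrow(effective_wounds_in_window(log[0, ], "c1", "2022-05-01")), 0)
})

test_that("the any-grade criterion first fires at 10 wounds in a 14-day window", {
  for (k in 1:9) {
    expect_equal(nrow(wound_concern_flags(consecutive_wounds(k))), 0)
  }
  flags <- wound_concern_flags(consecutive_wounds(10))
  expect_equal(flags$criterion, "any_grade_total")
  expect_equal(flags$count, 10L)
  expect_equal(as.integer(flags$window_end - flags$window_start), 13L)
})

test_that("grade-specific criteria fire at their published thresholds", {
  # a single grade-5 wound is already of concern
  f5 <- wound_concern_flags(wound_event("w1", "c1", "2022-05-01", 5))
  expect_equal(f5$criterion, "grade5_count")
  expect_equal(f5$count, 1L)
  # 4 grade-3 wounds in-window fire; 3 do not
  expect_equal(nrow(wound_concern_flags(consecutive_wounds(3, grade = 3))), 0)
  f3 <- wound_concern_flags(consecutive_wounds(4, grade = 3))
  expect_equal(f3$criterion, "grade3_count")
  # grade-4 wounds do NOT count toward the grade-3 criterion
  mixed <- dplyr::bind_rows(
    consecutive_wounds(3, grade = 3),
    wound_event("w9", "Kasey", "2022-05-04", 4)
  )
  expect_equal(nrow(wound_concern_flags(mixed)), 0)
  # 4 grade-3 wounds spread so no 14-day window holds more than 3: no flag
  spread <- purrr::map_dfr(1:4, function(i) {
    wound_event(paste0("w", i), "c1", as.Date("2022-05-01") + (i - 1) * 7, 3)
  })
  expect_equal(nrow(wound_concern_flags(spread)), 0)
  expect_error(
    wound_concern_flags(consecutive_wounds(2), criteria = c(any_grade_total = 0L)),
    "positive"
  )
})

test_that("a wound escalating within one window contributes one count, and flags dedup per episode", {
  # 9 wounds + the 10th escalating twice in-window: any-grade count is 10, not 11
  log <- dplyr::bind_rows(
    consecutive_wounds(9),
    wound_event("w10", "Kasey", "2022-05-10", 1),
    wound_event("w10", "Kasey", "2022-05-11", 3, "escalation")
  )
  flags <- wound_concern_flags(log)
  any_flag <- flags[flags$criterion == "any_grade_total", ]
  expect_equal(nrow(any_flag), 1)
  expect_equal(any_flag$count, 10L)
  # overlapping satisfying windows collapse to the earliest of the episode
  long <- consecutive_wounds(14)
  af <- wound_concern_flags(long)
  af <- af[af$criterion == "any_grade_total", ]
  expect_equal(nrow(af), 1)
  expect_equal(af$window_start, as.Date("2022-05-01"))
})

test_that("flag emission matches brute-force window enumeration on random logs", {
  withr::local_seed(2207)
  for (i in 1:25) {
    log <- random_wound_log(sample(5:50, 1))
    flags <- wound_concern_flags(log)
    oracle <- brute_force_flagged(log)
    expect_equal(
      dplyr::arrange(
        unique(flags[, c("chimp_id", "criterion")]), chimp_id, criterion
      ),
      oracle[, c("chimp_id", "criterion")],
      ignore_attr = TRUE
    )
    # every reported flag is a genuinely satisfying window on recount
    for (r in seq_len(nrow(flags))) {
      eff <- effective_wounds_in_window(
        log, flags$chimp_id[r], flags$window_start[r]
      )
      n <- switch(flags$criterion[r],
        any_grade_total = nrow(eff),
        grade3_count = sum(eff$grade == 3),
        grade4_count = sum(eff$grade == 4),
        grade5_count = sum(eff$grade == 5)
      )
      expect_gte(n, default_wound_criteria()[[flags$criterion[r]]])
      expect_equal(n, flags$count[r])
    }
  }
})

test_that("adding a wound event never removes an existing flag", {
  withr::local_seed(31)
  for (i in 1:10) {
    log <- random_wound_log(sample(10:40, 1))
    before <- unique(wound_concern_flags(log)[, c("chimp_id", "criterion")])
    extra <- random_wound_log(1)
    extra$wound_id <- "wx"
    after <- unique(
      wound_concern_flags(dplyr::bind_rows(log, extra))[, c("chimp_id", "criterion")]
    )
    expect_equal(nrow(dplyr::anti_join(before, after, by = c("chimp_id", "criterion"))), 0)
  }
})

test_that("severity distribution is over deduplicated max-grade wounds and sums to 1", {
  log <- dplyr::bind_rows(
    wound_event("w1", "c1", "2022-01-01", 1),
    wound_event("w2", "c1", "2022-01-02", 1),
    wound_event("w3", "c2", "2022-01-03", 3),
    wound_event("w4", "c2", "2022-01-04", 3)
  )
  d <- severity_distribution(log)
  expect_equal(d$proportion[d$grade == 1], 0.5)
  expect_equal(d$proportion[d$grade == 3], 0.5)
  expect_equal(sum(d$proportion), 1)
  # escalation merges into one wound at max grade
  esc <- dplyr::bind_rows(
    wound_event("w1", "c1", "2022-01-01", 2),
    wound_event("w1", "c1", "2022-01-05", 4, "escalation")
  )
  d2 <- severity_distribution(esc)
  expect_equal(d2$n[d2$grade == 4], 1L)
  expect_equal(sum(d2$n), 1L)
  expect_error(severity_distribution(log[0, ]), "undefined")
  expect_error(
    severity_distribution(log, period = as.Date(c("2023-01-01", "2023-02-01"))),
    "undefined"
  )
})

test_that("wound timelines conserve totals across rebinning and groupings", {
  withr::local_seed(99)
  log <- random_wound_log(40, n_chimps = 4, span_days = 80)
  n_eff <- dplyr::n_distinct(log$wound_id)
  for (bin in c("day", "week", "month")) {
    tl <- wound_timeline(log, bin = bin)
    expect_equal(sum(tl$n), n_eff)
  }
  roster <- chimp_roster(tibble::tibble(
    chimp_id = paste0("c", 1:4), name = paste0("c", 1:4), sex = "F",
    birth_date = as.Date("2000-01-01"), group_id = c("g1", "g1", "g2", "g2")
  ))
  by_group <- wound_timeline(log, roster, grouping = "group", bin = "month")
  expect_equal(sum(by_group$n), n_eff)
  expect_setequal(unique(by_group$subject), c("g1", "g2"))
  # two same-day wounds of grades 1 and 5 land in one bin with separate counts
  two <- dplyr::bind_rows(
    wound_event("a", "c1", "2022-02-01", 1),
    wound_event("b", "c1", "2022-02-01", 5)
  )
  tl2 <- wound_timeline(two, bin = "day")
  expect_equal(nrow(tl2), 2)
  expect_equal(tl2$n, c(1L, 1L))
  expect_error(wound_timeline(log, grouping = "group"), "roster")
})
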