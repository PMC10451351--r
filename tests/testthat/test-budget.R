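test_that("scan budgets normalize to 100 over the full category set", {
  scans <- dplyr::bind_rows(
    simple_scan("rest"), simple_scan("feed"),
    simple_scan("walk"), simple_scan("groom_other")
  )
  b <- budget_from_scans(scans)
  expect_s3_class(b, "time_budget")
  expect_equal(sum(b$pct), 100, tolerance = 1e-6)
  expect_equal(sort(b$pct[b$pct > 0]), rep(25, 4))
  one <- budget_from_scans(dplyr::bind_rows(simple_scan("rest"), simple_scan("sleep")))
  expect_equal(one$pct[one$category == "inactive"], 100)
  # all-occurrence records are excluded from the denominator
  mixed <- dplyr::bind_rows(
    simple_scan("rest"),
    simple_scan("attack", sampling = "all_occurrence")
  )
  b2 <- budget_from_scans(mixed)
  expect_equal(attr(b2, "n_samples"), 1)
  expect_equal(b2$pct[b2$category == "inactive"], 100)
  expect_error(budget_from_scans(mixed[2, ]), "no instantaneous")
  expect_error(budget_from_scans(simple_scan("made_up_code")), "not in ethogram")
  # permutation invariance
  expect_equal(budget_from_scans(scans[sample(4), ])$pct, b$pct)
})

test_that("focal budgets weight by duration and reject overlapping intervals", {
  t0 <- as.POSIXct("2022-06-01 09:00:00", tz = "UTC")
  sess <- tibble::tibble(
    timestamp = t0 + c(0, 90, 810),
    observer = "obs1", focal_id = "Kasey",
    behavior_code = c("rest", "wound_pick_i", "rest"),
    sampling = "continuous",
    duration_s = c(90, 90, 90),
    neighbors_within_1m = NA_character_
  )
  eth <- ethogram(
    data.frame(
      code = c("rest", "wound_pick_i"),
      category = c("inactive", "abnormal")
    )
  )
  # 900 s total with 90 s wound picking -> abnormal 10%
  sess$duration_s <- c(450, 90, 360)
  sess$timestamp <- t0 + c(0, 450, 540)
  b <- budget_from_focal(sess, eth, chimp = "Kasey")
  expect_equal(b$pct[b$category == "abnormal"], 10)
  expect_equal(sum(b$pct), 100, tolerance = 1e-6)
  expect_equal(attr(b, "n_samples"), 900)
  # concatenating two sessions equals the duration-weighted average of budgets
  sess2 <- sess
  sess2$timestamp <- sess$timestamp + 86400
  both <- budget_from_focal(dplyr::bind_rows(sess, sess2), eth, chimp = "Kasey")
  expect_equal(both$pct, b$pct)
  # overlap within one session is a validation error
  bad <- sess
  bad$timestamp <- t0 + c(0, 100, 540)
  expect_error(budget_from_focal(bad, eth), "overlapping")
  expect_error(
    budget_from_focal(dplyr::mutate(sess, duration_s = 0), eth),
    "positive duration"
  )
})

test_that("all-occurrence rates are events per observed hour and scale invariant", {
  ev <- dplyr::bind_rows(
    simple_scan("attack", sampling = "all_occurrence"),
    simple_scan("attack", sampling = "all_occurrence"),
    simple_scan("display", sampling = "all_occurrence")
  )
  r <- all_occurrence_rates(ev, hours_observed = 1.5)
  expect_equal(r$rate_per_hour[r$behavior_code == "attack"], 2 / 1.5)
  expect_equal(r$rate_per_hour[r$behavior_code == "display"], 1 / 1.5)
  expect_equal(sum(r$n), 3)
  # doubling both events and time leaves rates unchanged
  r2 <- all_occurrence_rates(dplyr::bind_rows(ev, ev), hours_observed = 3)
  expect_equal(r2$rate_per_hour, r$rate_per_hour)
  # no events -> all-zero rates over the six configured codes
  r0 <- all_occurrence_rates(ev[0, ], hours_observed = 2)
  expect_equal(nrow(r0), 6)
  expect_equal(r0$rate_per_hour, rep(0, 6))
  expect_error(all_occurrence_rates(ev, hours_observed = 0), "positive")
  expect_error(
    all_occurrence_rates(simple_scan("rest", sampling = "all_occurrence"), 1),
    "not an all-occurrence code"
  )
})

test_that("the observation scheduler reproduces all 13 reason rows and rejects others", {
  tab <- sms_schedule_table()
  expect_equal(nrow(tab), 13)
  expect_equal(
    sms_schedule("Post-Social Integration")$n_observations, 13L
  )
  expect_equal(sms_schedule("Post-Social Integration")$duration, "3 months")
  expect_equal(sms_schedule("Yearly Check-In")$n_observations, 6L)
  expect_equal(sms_schedule("Yearly Check-In")$duration, "6 weeks")
  expect_equal(sms_schedule("Release to Novel Area")$n_observations, 4L)
  expect_equal(sms_schedule("Release to Novel Area")$duration, "4 weeks")
  expect_equal(sms_schedule("New Arrival")$n_observations, 13L)
  expect_equal(sms_schedule("Death of a Group Member")$n_observations, 6L)
  expect_error(sms_schedule("Vacation"), "unknown SMS reason")
})

test_that("observation slots are deterministic per seed and spread over the span", {
  sched <- sms_schedule("Yearly Check-In")
  a <- assign_observation_slots(sched, "Kasey", "2022-04-01", seed = 7)
  b <- assign_observation_slots(sched, "Kasey", "2022-04-01", seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 6)
  expect_true(all(a$date >= as.Date("2022-04-01")))
  expect_true(all(a$date <= as.Date("2022-04-01") + sched$duration_days))
  expect_true(all(a$block %in% c("07:30-10:30", "10:30-12:30", "13:30-15:30")))
  expect_false(identical(
    a$block,
    assign_observation_slots(sched, "Kasey", "2022-04-01", seed = 8)$block
  ))
  short <- sched
  short$duration_days <- 3L
  expect_error(assign_observation_slots(short, "Kasey", "2022-04-01"), "shorter")
})

test_that("block assignment is uniform over the three daily windows", {
  sched <- sms_schedule("Release to Novel Area") # 4 slots
  blocks <- unlist(lapply(1:750, function(s) {
    assign_observation_slots(sched, "Kasey", "2022-04-01", seed = s)$block
  }))
  counts <- table(blocks)
  expect_equal(length(counts), 3)
  # chi-square goodness of fit against uniform thirds at alpha = 0.01
  p <- stats::chisq.test(counts, p = rep(1 / 3, 3))$p.value
  expect_gt(p, 0.01)
})

test_that("TIA triggers fire strictly above 10% abnormal budget and per independent cause", {
  mk_budget <- function(abn) {
    scans <- dplyr::bind_rows(
      purrr::map_dfr(seq_len(1000 - abn), ~ simple_scan("rest")),
      purrr::map_dfr(seq_len(abn), ~ simple_scan("rock"))
    )
    budget_from_scans(scans, subject = "Kasey")
  }
  # 10.0% exactly: no trigger; 10.1%: trigger
  expect_equal(nrow(evaluate_tia_triggers("Kasey", budget = mk_budget(100))), 0)
  tr <- evaluate_tia_triggers("Kasey", budget = mk_budget(101))
  expect_equal(tr$cause, "abnormal_budget_exceeds")
  # a grade-5 wound flag raises the wound-criteria cause
  flags <- wound_concern_flags(wound_event("w1", "Kasey", "2022-05-01", 5))
  tr2 <- evaluate_tia_triggers("Kasey", wound_flags = flags)
  expect_equal(tr2$cause, "wound_criteria")
  # a high-priority report alone triggers only that cause
  rep <- tibble::tibble(
    chimp_id = "Kasey", date = as.Date("2022-05-02"), kind = "high_priority"
  )
  tr3 <- evaluate_tia_triggers("Kasey", reports = rep)
  expect_equal(tr3$cause, "high_priority_report")
  # independent causes combine
  tr4 <- evaluate_tia_triggers(
    "Kasey",
    budget = mk_budget(200), reports = rep, wound_flags = flags
  )
  expect_setequal(
    tr4$cause,
    c("abnormal_budget_exceeds", "high_priority_report", "wound_criteria")
  )
  # reports for other chimps do not leak
  expect_equal(
    nrow(evaluate_tia_triggers("Blue", reports = rep, wound_flags = flags)), 0
  )
})

test_that("pre/post comparison differences categories and deltas sum to zero", {
  pre <- budget_from_scans(dplyr::bind_rows(
    purrr::map_dfr(1:80, ~ simple_scan("rest")),
    purrr::map_dfr(1:20, ~ simple_scan("rock"))
  ))
  post <- budget_from_scans(dplyr::bind_rows(
    purrr::map_dfr(1:95, ~ simple_scan("rest")),
    purrr::map_dfr(1:5, ~ simple_scan("rock"))
  ))
  cmp <- pre_post_comparison(pre, post)
  expect_equal(cmp$delta[cmp$category == "abnormal"], -15)
  expect_equal(sum(cmp$delta), 0, tolerance = 1e-6)
  # identical budgets -> all deltas zero
  same <- pre_post_comparison(pre, pre)
  expect_equal(same$delta, rep(0, 9))
  broken <- pre[-1, ]
  expect_error(pre_post_comparison(pre, broken), "category sets")
})
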