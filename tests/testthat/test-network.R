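night_obs <- function(chimp, date, neighbor, proximity = "contact",
                      location = "indoor") {
  tibble::tibble(
    chimp_id = chimp, date = as.Date(date), location = location,
    proximity = proximity,
    neighbor_id = if (proximity == "no_neighbor") NA_character_ else neighbor
  )
}

test_that("pair counts are per-night, deduplicated across mutual naming", {
  # three nights of A naming B in contact -> count 3 in 'all' and 'contact'
  obs <- purrr::map_dfr(1:3, ~ night_obs("A", as.Date("2022-03-01") + .x, "B"))
  for (stratum in c("all", "contact")) {
    m <- pair_matrix(obs, group = c("A", "B"), stratum = stratum)
    expect_equal(m["A", "B"], 3)
    expect_equal(m["B", "A"], 3)
    expect_equal(diag(unclass(m)), c(A = 0, B = 0))
  }
  # mutual naming on one night counts once, not twice
  mutual <- dplyr::bind_rows(
    night_obs("A", "2022-03-01", "B"),
    night_obs("B", "2022-03-01", "A")
  )
  expect_equal(pair_matrix(mutual, group = c("A", "B"))["A", "B"], 1)
  # outside_3m contributes to 'all' but to no stratified matrix
  far <- night_obs("A", "2022-03-02", "B", proximity = "outside_3m")
  expect_equal(pair_matrix(far, group = c("A", "B"), stratum = "all")["A", "B"], 1)
  for (stratum in c("contact", "arms_reach", "within_3m")) {
    expect_equal(
      pair_matrix(far, group = c("A", "B"), stratum = stratum)["A", "B"], 0
    )
  }
})

test_that("night observation validation enforces the record invariants", {
  expect_error(
    pair_matrix(night_obs("A", "2022-03-01", "A")),
    "own nearest neighbor"
  )
  bad_nb <- night_obs("A", "2022-03-01", "Z")
  expect_error(pair_matrix(bad_nb, group = c("A", "B")), "outside the group")
  dup <- dplyr::bind_rows(
    night_obs("A", "2022-03-01", "B"),
    night_obs("A", "2022-03-01", "B", proximity = "arms_reach")
  )
  expect_error(pair_matrix(dup, group = c("A", "B")), "one night observation")
  miss <- night_obs("A", "2022-03-01", NA_character_)
  miss$neighbor_id <- NA_character_
  expect_error(pair_matrix(miss, group = c("A", "B")), "neighbor_id")
})

test_that("stratified matrices nest cumulatively and per-class matrices sum to 'all'", {
  withr::local_seed(41)
  group <- paste0("c", 1:6)
  obs <- random_nights(group, 25)
  # make mutual mentions of a pair agree on the proximity class so that the
  # per-class matrices exactly partition the 'all' matrix
  named <- obs$proximity != "no_neighbor"
  pair_key <- paste(
    pmin(obs$chimp_id, obs$neighbor_id),
    pmax(obs$chimp_id, obs$neighbor_id), obs$date
  )
  classes4 <- c("contact", "arms_reach", "within_3m", "outside_3m")
  obs$proximity[named] <-
    classes4[1 + (as.integer(factor(pair_key)) %% 4)][named]
  all_m <- pair_matrix(obs, group, "all")
  per_class <- lapply(
    c("contact", "arms_reach", "within_3m"),
    function(s) unclass(pair_matrix(obs, group, s))
  )
  outside <- brute_force_pair_counts(obs, group, "outside_3m")
  expect_equal(
    Reduce(`+`, per_class) + outside, unclass(all_m),
    ignore_attr = TRUE
  )
  # cumulative strata are elementwise monotone
  contact <- unclass(pair_matrix(obs, group, "contact", cumulative = TRUE))
  arms <- unclass(pair_matrix(obs, group, "arms_reach", cumulative = TRUE))
  within <- unclass(pair_matrix(obs, group, "within_3m", cumulative = TRUE))
  expect_true(all(contact <= arms))
  expect_true(all(arms <= within))
  expect_true(all(within <= unclass(all_m)))
})

test_that("pair matrices match brute-force per-night enumeration on random colonies", {
  withr::local_seed(73)
  for (i in 1:20) {
    group <- paste0("c", seq_len(sample(3:10, 1)))
    obs <- random_nights(group, sample(5:30, 1))
    for (stratum in c("all", "contact", "within_3m")) {
      classes <- switch(stratum,
        all = c("contact", "arms_reach", "within_3m", "outside_3m"),
        stratum
      )
      expect_equal(
        unclass(pair_matrix(obs, group, stratum)),
        brute_force_pair_counts(obs, group, classes),
        ignore_attr = TRUE
      )
    }
  }
})

test_that("no-neighbor and location tallies partition observed nights", {
  group <- c("A", "B")
  obs <- dplyr::bind_rows(
    purrr::map_dfr(1:5, ~ night_obs("A", as.Date("2022-03-01") + .x, NA,
      proximity = "no_neighbor"
    )),
    purrr::map_dfr(6:10, ~ night_obs("A", as.Date("2022-03-01") + .x, "B")),
    purrr::map_dfr(1:10, ~ night_obs("B", as.Date("2022-03-01") + .x, "A",
      location = if (.x == 1) "outdoor" else "indoor"
    ))
  )
  nn <- no_neighbor_counts(obs, group)
  expect_equal(nn$nights_alone[nn$chimp_id == "A"], 5)
  expect_equal(nn$nights_alone[nn$chimp_id == "B"], 0)
  expect_equal(nn$nights_observed, c(10, 10))
  # 19 indoor + 1 outdoor style split conserves totals
  loc <- location_tally(obs, group)
  expect_equal(loc$indoor + loc$outdoor, loc$nights_observed)
  expect_equal(loc$outdoor[loc$chimp_id == "B"], 1)
  expect_equal(loc$indoor[loc$chimp_id == "B"], 9)
  # record order does not matter
  shuffled <- obs[sample(nrow(obs)), ]
  expect_equal(no_neighbor_counts(shuffled, group), nn)
})

test_that("sociogram layout is seeded-deterministic and pulls heavy pairs closer", {
  obs <- dplyr::bind_rows(
    purrr::map_dfr(1:10, ~ night_obs("A", as.Date("2022-03-01") + .x, "B")),
    night_obs("C", "2022-03-02", "B")
  )
  m <- pair_matrix(obs, group = c("A", "B", "C"))
  l1 <- sociogram_layout(m, seed = 3)
  l2 <- sociogram_layout(m, seed = 3)
  expect_identical(l1, l2)
  expect_equal(nrow(l1$nodes), 3)
  expect_equal(sort(l1$edges$weight), c(1, 10))
  # the weight-10 pair ends up closer than the weight-1 pair
  dist_of <- function(l, a, b) {
    pa <- l$nodes[l$nodes$chimp_id == a, ]
    pb <- l$nodes[l$nodes$chimp_id == b, ]
    sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2)
  }
  expect_lt(dist_of(l1, "A", "B"), dist_of(l1, "B", "C"))
  # an all-zero matrix still lays out isolated nodes
  empty <- pair_matrix(
    night_obs("A", "2022-03-01", NA, proximity = "no_neighbor"),
    group = c("A", "B")
  )
  l0 <- sociogram_layout(empty, seed = 1)
  expect_equal(nrow(l0$nodes), 2)
  expect_equal(nrow(l0$edges), 0)
  expect_error(sociogram_layout(m[1, 1, drop = FALSE]), "at least two")
})

test_that("tidy and glance summarize pair matrices", {
  obs <- dplyr::bind_rows(
    purrr::map_dfr(1:4, ~ night_obs("A", as.Date("2022-03-01") + .x, "B")),
    night_obs("C", "2022-03-02", "A")
  )
  m <- pair_matrix(obs, group = c("A", "B", "C"))
  edges <- tidy(m)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$nights[edges$a == "A" & edges$b == "B"], 4)
  g <- glance(m)
  expect_equal(g$top_pair, "A--B")
  expect_equal(g$n_nights, 4)
})
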