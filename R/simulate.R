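#' Configure a synthetic colony
#'
#' Parameters of the seeded colony simulator. Defaults emulate the shape of
#' data a sanctuary colony produces — an inactive-dominant behavior
#' mixture, mostly superficial wounds arriving as a sparse Poisson process,
#' low and slowly drifting hair loss, stable nightly sleeping preferences,
#' and high but imperfect shifting compliance. They are illustrative
#' defaults for testing metric recovery, not fitted estimates.
#'
#' @param n_chimps Number of animals.
#' @param n_groups Number of social groups (animals split evenly).
#' @param days Simulated span in days.
#' @param start_date First simulated day.
#' @param scans_per_chimp Instantaneous scans per animal over the span.
#' @param focal_sessions_per_chimp 15-min continuous focal sessions per
#'   animal.
#' @param behavior_mixture Named probability vector over
#'   [behavior_categories()] (shared by all animals), or a matrix with one
#'   row per animal.
#' @param wound_rate Expected wounds per chimp-day (Poisson).
#' @param severity_probs Probability of severity grades 1-5 for a new wound.
#' @param p_escalate Probability a wound below grade 5 later escalates one
#'   grade.
#' @param hairloss_mean Mean of the latent starting total hair-loss percent.
#' @param hairloss_drift Per-survey drift (percentage points) of latent
#'   hair loss.
#' @param preference_concentration Spread of random pairwise
#'   nearest-neighbor preference weights (larger = more even).
#' @param planted_pair_boost Multiplier on the preference weight of one
#'   planted strongest pair per group (ground truth for recovery tests).
#' @param p_no_neighbor Nightly probability of sleeping with no neighbor in
#'   shared space.
#' @param p_indoor Nightly probability of sleeping indoors.
#' @param p_comply Per-animal shift-compliance probability (scalar or
#'   length `n_chimps`).
#' @param p_weather Probability a shift day is weather-excluded.
#' @param p_alternate Probability a shift day has an alternate goal.
#' @param prt_sessions_per_month Training sessions per animal per month.
#' @param n_assessors Wellness assessors per survey (one per department,
#'   cycling through husbandry/behavior/veterinary).
#' @param survey_noise SD of assessor noise around the latent parameter
#'   score (0 = all assessors agree exactly).
#' @param seed Master seed; every record stream derives its own stream
#'   seed from it.
#' @return List of class `colony_config`.
#' @export
colony_config <- function(n_chimps = 12,
                          n_groups = 2,
                          days = 90,
                          start_date = as.Date("2022-01-01"),
                          scans_per_chimp = 120,
                          focal_sessions_per_chimp = 3,
                          behavior_mixture = default_behavior_mixture(),
                          wound_rate = 0.015,
                          severity_probs = c(0.5162, 0.3006, 0.1361, 0.035, 0.0121),
                          p_escalate = 0.05,
                          hairloss_mean = 8,
                          hairloss_drift = -1,
                          preference_concentration = 1,
                          planted_pair_boost = 4,
                          p_no_neighbor = 0.1,
                          p_indoor = 0.9,
                          p_comply = 0.8,
                          p_weather = 0.08,
                          p_alternate = 0.04,
                          prt_sessions_per_month = 4,
                          n_assessors = 3,
                          survey_noise = 0.3,
                          seed = 1L) {
  cats <- behavior_categories()
  if (is.matrix(behavior_mixture)) {
    if (ncol(behavior_mixture) != length(cats) || nrow(behavior_mixture) != n_chimps) {
      abort("behavior_mixture matrix must be n_chimps x 9")
    }
    mix <- behavior_mixture
    colnames(mix) <- cats
  } else {
    if (!all(cats %in% names(behavior_mixture))) {
      abort("behavior_mixture must be named over all nine categories")
    }
    mix <- matrix(behavior_mixture[cats],
      nrow = n_chimps, ncol = length(cats),
      byrow = TRUE, dimnames = list(NULL, cats)
    )
  }
  if (any(mix < 0) || any(abs(rowSums(mix) - 1) > 1e-8)) {
    abort("behavior mixtures must be probability vectors summing to 1")
  }
  if (wound_rate < 0) abort("wound_rate must be non-negative")
  if (length(severity_probs) != 5 || any(severity_probs < 0) ||
    abs(sum(severity_probs) - 1) > 1e-8) {
    abort("severity_probs must be 5 non-negative probabilities summing to 1")
  }
  p_comply <- rep_len(p_comply, n_chimps)
  if (any(p_comply < 0 | p_comply > 1)) abort("p_comply must lie in [0, 1]")
  cfg <- list(
    n_chimps = as.integer(n_chimps), n_groups = as.integer(n_groups),
    days = as.integer(days), start_date = as.Date(start_date),
    scans_per_chimp = as.integer(scans_per_chimp),
    focal_sessions_per_chimp = as.integer(focal_sessions_per_chimp),
    mixtures = mix, wound_rate = wound_rate,
    severity_probs = severity_probs, p_escalate = p_escalate,
    hairloss_mean = hairloss_mean, hairloss_drift = hairloss_drift,
    preference_concentration = preference_concentration,
    planted_pair_boost = planted_pair_boost,
    p_no_neighbor = p_no_neighbor, p_indoor = p_indoor,
    p_comply = p_comply, p_weather = p_weather, p_alternate = p_alternate,
    prt_sessions_per_month = prt_sessions_per_month,
    n_assessors = as.integer(n_assessors), survey_noise = survey_noise,
    seed = as.integer(seed)
  )
  class(cfg) <- "colony_config"
  cfg
}

#' Default colony behavior mixture
#'
#' Inactive-dominant mixture typical of a sanctuary colony budget:
#' inactivity around half of observation time, feeding next, abnormal and
#' aggressive behavior rare.
#'
#' @return Named probability vector over [behavior_categories()].
#' @export
default_behavior_mixture <- function() {
  c(
    inactive = 0.5117, food_drink = 0.1624, self_directed = 0.1057,
    locomotion = 0.0907, affiliative = 0.0668, abnormal = 0.018,
    aggressive = 0.015, sexual = 0.010, other = 0.0197
  )
}

sim_roster <- function(cfg) {
  ids <- sprintf("CH%03d", seq_len(cfg$n_chimps))
  groups <- sprintf("G%02d", rep_len(seq_len(cfg$n_groups), cfg$n_chimps))
  with_seed(stream_seed(cfg$seed, "roster"), {
    chimp_roster(tibble::tibble(
      chimp_id = ids,
      name = ids,
      sex = sample(c("M", "F"), cfg$n_chimps, replace = TRUE),
      birth_date = cfg$start_date - round(runif(cfg$n_chimps, 4, 55) * 365.25),
      group_id = sort(groups)
    ))
  })
}

sim_scans <- function(cfg, roster, eth) {
  cats <- behavior_categories()
  codes_by_cat <- split(
    eth$code[eth$sampling == "instantaneous"],
    eth$category[eth$sampling == "instantaneous"]
  )
  blocks <- c("08:30:00", "11:30:00", "14:30:00")
  with_seed(stream_seed(cfg$seed, "scans"), {
    purrr::map_dfr(seq_len(nrow(roster)), function(i) {
      n <- cfg$scans_per_chimp
      cat_draw <- sample(cats, n, replace = TRUE, prob = cfg$mixtures[i, ])
      code <- vapply(cat_draw, function(cc) {
        pool <- codes_by_cat[[cc]]
        pool[sample.int(length(pool), 1)]
      }, character(1))
      day <- sample.int(cfg$days, n, replace = TRUE) - 1L
      tibble::tibble(
        timestamp = as.POSIXct(
          paste(cfg$start_date + day, sample(blocks, n, replace = TRUE)),
          tz = "UTC"
        ),
        observer = sample(paste0("obs", 1:6), n, replace = TRUE),
        focal_id = roster$chimp_id[i],
        behavior_code = code,
        sampling = "instantaneous",
        duration_s = NA_real_,
        neighbors_within_1m = NA_character_
      )
    })
  })
}

sim_focals <- function(cfg, roster, eth) {
  if (cfg$focal_sessions_per_chimp == 0) {
    return(tibble::tibble(
      timestamp = as.POSIXct(character(), tz = "UTC"), observer = character(),
      focal_id = character(), behavior_code = character(),
      sampling = character(), duration_s = numeric(),
      neighbors_within_1m = character()
    ))
  }
  cats <- behavior_categories()
  codes_by_cat <- split(
    eth$code[eth$sampling == "instantaneous"],
    eth$category[eth$sampling == "instantaneous"]
  )
  with_seed(stream_seed(cfg$seed, "focals"), {
    purrr::map_dfr(seq_len(nrow(roster)), function(i) {
      purrr::map_dfr(seq_len(cfg$focal_sessions_per_chimp), function(s) {
        day <- sample.int(cfg$days, 1) - 1L
        t0 <- as.POSIXct(paste(cfg$start_date + day, "09:00:00"), tz = "UTC")
        # a 15-min session recorded as 15 consecutive 60-s bouts
        cat_draw <- sample(cats, 15, replace = TRUE, prob = cfg$mixtures[i, ])
        code <- vapply(cat_draw, function(cc) {
          pool <- codes_by_cat[[cc]]
          pool[sample.int(length(pool), 1)]
        }, character(1))
        tibble::tibble(
          timestamp = t0 + 60 * (0:14),
          observer = paste0("obs", 1 + (s %% 6)),
          focal_id = roster$chimp_id[i],
          behavior_code = code,
          sampling = "continuous",
          duration_s = 60,
          neighbors_within_1m = NA_character_
        )
      })
    })
  })
}

sim_wounds <- function(cfg, roster) {
  with_seed(stream_seed(cfg$seed, "wounds"), {
    out <- purrr::map_dfr(roster$chimp_id, function(ch) {
      n <- rpois(1, cfg$wound_rate * cfg$days)
      if (n == 0) {
        return(NULL)
      }
      day <- sort(sample.int(cfg$days, n, replace = TRUE)) - 1L
      grade <- sample(1:5, n, replace = TRUE, prob = cfg$severity_probs)
      tibble::tibble(
        chimp_id = ch, date = cfg$start_date + day, grade = as.integer(grade)
      )
    })
    if (nrow(out) == 0) {
      return(tibble::tibble(
        wound_id = character(), chimp_id = character(),
        date = as.Date(character()), grade = integer(),
        event_kind = character()
      ))
    }
    out$wound_id <- sprintf("W%04d", seq_len(nrow(out)))
    out$event_kind <- "initial"
    esc <- which(out$grade < 5 & runif(nrow(out)) < cfg$p_escalate)
    if (length(esc) > 0) {
      esc_rows <- out[esc, , drop = FALSE]
      esc_rows$date <- esc_rows$date + sample(1:7, length(esc), replace = TRUE)
      esc_rows$grade <- esc_rows$grade + 1L
      esc_rows$event_kind <- "escalation"
      out <- dplyr::bind_rows(out, esc_rows)
    }
    out <- dplyr::arrange(out, .data$date, .data$wound_id)
    out[, c("wound_id", "chimp_id", "date", "grade", "event_kind")]
  })
}

sim_wellness <- function(cfg, roster) {
  params <- wellness_parameters()
  departments <- c("husbandry", "behavior", "veterinary")
  survey_days <- seq(7, cfg$days, by = 91)
  with_seed(stream_seed(cfg$seed, "wellness"), {
    # latent per-chimp concern level per parameter, mostly zero
    latent <- matrix(
      sample(0:3, cfg$n_chimps * 10,
        replace = TRUE,
        prob = c(0.85, 0.12, 0.025, 0.005)
      ),
      nrow = cfg$n_chimps, dimnames = list(roster$chimp_id, params)
    )
    out <- purrr::map_dfr(seq_len(nrow(roster)), function(i) {
      purrr::map_dfr(survey_days, function(d) {
        purrr::map_dfr(seq_len(cfg$n_assessors), function(a) {
          noise <- round(rnorm(10, 0, cfg$survey_noise))
          raw <- pmin(3, pmax(0, latent[i, ] + noise))
          row <- tibble::tibble(
            chimp_id = roster$chimp_id[i],
            observer = paste0("assessor", a),
            department = departments[1 + (a - 1) %% 3],
            date = cfg$start_date + d
          )
          row[params] <- as.list(as.integer(raw))
          row
        })
      })
    })
    attr(out, "latent") <- latent
    out
  })
}

sim_hairloss <- function(cfg, roster, zone_map) {
  survey_days <- seq(0, cfg$days - 1, by = 120)
  with_seed(stream_seed(cfg$seed, "hairloss"), {
    start <- pmax(0, pmin(95, rnorm(cfg$n_chimps, cfg$hairloss_mean, 10)))
    purrr::map_dfr(seq_len(nrow(roster)), function(i) {
      purrr::map_dfr(seq_along(survey_days), function(k) {
        latent_total <- pmax(0, pmin(
          100,
          start[i] + cfg$hairloss_drift * (k - 1)
        ))
        # spread the latent total over zones, then snap to the 5-point scale
        raw <- pmax(0, pmin(100, rnorm(
          nrow(zone_map), latent_total, 8
        )))
        scores <- snap_zone_scores(raw)
        row <- tibble::tibble(
          chimp_id = roster$chimp_id[i],
          date = cfg$start_date + survey_days[k],
          observer = paste0("obs", 1 + (k %% 3))
        )
        row[zone_map$zone] <- as.list(scores)
        row
      })
    })
  })
}

sim_preferences <- function(cfg, roster) {
  ids <- roster$chimp_id
  pref <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  planted <- list()
  with_seed(stream_seed(cfg$seed, "nights"), {
    for (g in unique(roster$group_id)) {
      members <- ids[roster$group_id == g]
      if (length(members) < 2) next
      for (i in seq_along(members)) {
        for (j in seq_along(members)) {
          if (i < j) {
            w <- stats::rgamma(1, shape = cfg$preference_concentration, rate = 1)
            pref[members[i], members[j]] <- w
            pref[members[j], members[i]] <- w
          }
        }
      }
      pair <- sort(sample(members, 2))
      pref[pair[1], pair[2]] <- max(pref[ids %in% members, ids %in% members]) *
        cfg$planted_pair_boost
      pref[pair[2], pair[1]] <- pref[pair[1], pair[2]]
      planted[[g]] <- pair
    }
    list(pref = pref, planted = planted)
  })
}

sim_nights <- function(cfg, roster, pref) {
  ids <- roster$chimp_id
  n <- cfg$days
  with_seed(stream_seed(cfg$seed, "nights") + 1L, {
    out <- purrr::map_dfr(seq_along(ids), function(i) {
      ch <- ids[i]
      members <- ids[roster$group_id == roster$group_id[i] & ids != ch]
      alone <- if (length(members) == 0) {
        rep(TRUE, n)
      } else {
        runif(n) < cfg$p_no_neighbor
      }
      nb <- rep(NA_character_, n)
      prox <- rep("no_neighbor", n)
      k <- sum(!alone)
      if (k > 0) {
        w <- pref[ch, members]
        if (sum(w) == 0) w <- rep(1, length(members))
        nb[!alone] <- if (length(members) == 1) {
          members
        } else {
          sample(members, k, replace = TRUE, prob = w)
        }
        prox[!alone] <- sample(
          c("contact", "arms_reach", "within_3m", "outside_3m"), k,
          replace = TRUE, prob = c(0.35, 0.3, 0.2, 0.15)
        )
      }
      tibble::tibble(
        chimp_id = ch, date = cfg$start_date + seq_len(n) - 1L,
        location = ifelse(runif(n) < cfg$p_indoor, "indoor", "outdoor"),
        proximity = prox, neighbor_id = nb
      )
    })
    dplyr::arrange(out, .data$date, .data$chimp_id)
  })
}

sim_prt <- function(cfg, roster) {
  cues <- c("target", "present_arm", "open_mouth", "station", "shift_in")
  months <- max(1, round(cfg$days / 30.44))
  with_seed(stream_seed(cfg$seed, "prt"), {
    purrr::map_dfr(roster$chimp_id, function(ch) {
      n_sessions <- rpois(1, cfg$prt_sessions_per_month * months)
      if (n_sessions == 0) {
        return(NULL)
      }
      purrr::map_dfr(seq_len(n_sessions), function(s) {
        day <- sample.int(cfg$days, 1) - 1L
        n_cues <- sample(1:3, 1)
        tibble::tibble(
          date = cfg$start_date + day,
          time_of_day = sprintf("%02d:%02d", sample(8:15, 1), sample(0:59, 1)),
          trainer = sample(paste0("trainer", 1:5), 1),
          chimp_id = ch,
          cue = sample(cues, n_cues),
          response = sample(1:3, n_cues, replace = TRUE, prob = c(0.1, 0.2, 0.7)),
          reinforcers = "juice",
          co_trainers = NA_character_,
          notes = NA_character_
        )
      })
    })
  })
}

sim_shifts <- function(cfg, roster) {
  n <- cfg$days
  with_seed(stream_seed(cfg$seed, "shifts"), {
    out <- purrr::map_dfr(unique(roster$group_id), function(g) {
      members <- roster$chimp_id[roster$group_id == g]
      m <- length(members)
      weather <- runif(n) < cfg$p_weather
      alternate <- !weather & runif(n) < cfg$p_alternate
      p <- cfg$p_comply[match(members, roster$chimp_id)]
      tibble::tibble(
        date = rep(cfg$start_date + seq_len(n) - 1L, each = m),
        group_id = g,
        shifter = rep(
          sample(paste0("shifter", 1:4), n, replace = TRUE),
          each = m
        ),
        goal = "shift outside",
        weather_excluded = rep(weather, each = m),
        alternate_goal = rep(alternate, each = m),
        chimp_id = rep(members, n),
        complied = as.logical(rbinom(n * m, 1, rep(p, n))),
        notes = NA_character_
      )
    })
    dplyr::arrange(out, .data$date, .data$group_id, .data$chimp_id)
  })
}

#' Simulate a full colony record bundle
#'
#' Generates every record stream the metric modules consume — roster,
#' instantaneous scans, continuous focal sessions, wound events, wellness
#' responses, hair-loss surveys, nightly nearest-neighbor records, training
#' logs and shifting logs — from known ground truth, deterministically for
#' a given seed. Each stream has its own RNG stream derived from the master
#' seed, so regenerating one stream never perturbs the others.
#'
#' @param config A [colony_config()].
#' @return List of class `colony_bundle` with elements `roster`,
#'   `ethogram`, `zone_map`, `scans`, `focals`, `wounds`, `wellness`,
#'   `hairloss`, `nights`, `prt`, `shifts`, and `manifest` (the generating
#'   ground truth: mixtures, severity distribution, preference matrix,
#'   planted strongest pairs, compliance probabilities, ...).
#' @export
#' @examples
#' bundle <- simulate_colony(colony_config(n_chimps = 4, days = 30, seed = 7))
#' names(bundle)
simulate_colony <- function(config) {
  stopifnot(inherits(config, "colony_config"))
  roster <- sim_roster(config)
  eth <- default_ethogram()
  zone_map <- default_zone_map()
  prefs <- sim_preferences(config, roster)
  wellness <- sim_wellness(config, roster)
  bundle <- list(
    roster = roster,
    ethogram = eth,
    zone_map = zone_map,
    scans = sim_scans(config, roster, eth),
    focals = sim_focals(config, roster, eth),
    wounds = sim_wounds(config, roster),
    wellness = wellness,
    hairloss = sim_hairloss(config, roster, zone_map),
    nights = sim_nights(config, roster, prefs$pref),
    prt = sim_prt(config, roster),
    shifts = sim_shifts(config, roster),
    manifest = list(
      seed = config$seed,
      mixtures = config$mixtures,
      wound_rate = config$wound_rate,
      severity_probs = config$severity_probs,
      preference = prefs$pref,
      planted_pairs = prefs$planted,
      p_comply = setNames(config$p_comply, roster$chimp_id),
      p_no_neighbor = config$p_no_neighbor,
      p_indoor = config$p_indoor,
      wellness_latent = attr(wellness, "latent")
    ),
    config = config
  )
  attr(bundle$wellness, "latent") <- NULL
  class(bundle) <- "colony_bundle"
  bundle
}

#' @export
print.colony_bundle <- function(x, ...) {
  cat(
    "<colony_bundle> ", nrow(x$roster), " chimps, ",
    nrow(x$scans), " scans, ", nrow(x$wounds), " wound events, ",
    nrow(x$nights), " night records (seed ", x$manifest$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Estimate-versus-truth recovery report for a simulated bundle
#'
#' Runs the metric modules on a simulated bundle and compares their
#' estimates with the generating ground truth: colony activity budget
#' versus the generating mixture, wound severity distribution versus the
#' generating grade probabilities, per-animal shifting compliance versus
#' the generating probability, and whether each group's top sociogram edge
#' recovers the planted strongest pair.
#'
#' @param bundle A [simulate_colony()] result.
#' @return Tibble: `metric`, `detail`, `estimate`, `truth`, `abs_error`
#'   (for the planted pair, `abs_error` is 0 when recovered, 1 when not).
#' @export
recovery_report <- function(bundle) {
  stopifnot(inherits(bundle, "colony_bundle"))
  man <- bundle$manifest
  rows <- list()
  # colony budget vs mean generating mixture
  budget <- budget_from_scans(bundle$scans, bundle$ethogram)
  truth_mix <- 100 * colMeans(man$mixtures)
  truth_b <- as.numeric(truth_mix[budget$category])
  rows$budget <- tibble::tibble(
    metric = "budget_pct", detail = budget$category,
    estimate = budget$pct, truth = truth_b,
    abs_error = abs(budget$pct - truth_b)
  )
  # wound severity distribution
  if (nrow(bundle$wounds) > 0) {
    sev <- severity_distribution(bundle$wounds)
    rows$severity <- tibble::tibble(
      metric = "severity_proportion", detail = paste0("grade", sev$grade),
      estimate = sev$proportion, truth = man$severity_probs,
      abs_error = abs(sev$proportion - man$severity_probs)
    )
  }
  # shifting compliance
  comp <- shifting_compliance(bundle$shifts)
  truth_comp <- as.numeric(100 * man$p_comply[comp$chimp_id])
  rows$compliance <- tibble::tibble(
    metric = "compliance_pct", detail = comp$chimp_id,
    estimate = comp$compliance_pct, truth = truth_comp,
    abs_error = abs(comp$compliance_pct - truth_comp)
  )
  # planted strongest pair per group
  rows$pairs <- purrr::map_dfr(names(man$planted_pairs), function(g) {
    members <- bundle$roster$chimp_id[bundle$roster$group_id == g]
    m <- pair_matrix(
      bundle$nights[bundle$nights$chimp_id %in% members, ],
      group = members, stratum = "all"
    )
    top <- which(m == max(m), arr.ind = TRUE)[1, ]
    found <- sort(c(rownames(m)[top[1]], colnames(m)[top[2]]))
    planted <- man$planted_pairs[[g]]
    tibble::tibble(
      metric = "top_pair", detail = g,
      estimate = NA_real_, truth = NA_real_,
      abs_error = as.numeric(!identical(found, planted))
    )
  })
  dplyr::bind_rows(rows)
}
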