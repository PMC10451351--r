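section_or_empty <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return("no data in period")
  }
  x
}

#' Build an Integrated Welfare Report
#'
#' Assembles every behavioral metric for one animal (or a whole group) over
#' a period into a single structured report: wellness scores and band,
#' wound concern flags and severity distribution, hair-loss totals and
#' significance, the current activity budget with any Targeted Individual
#' Assessment triggers (wound flags are cross-referenced into the TIA
#' section), nightly social summary (top partners, nights alone, location
#' split) and training engagement with shifting compliance. Sections with
#' no records are explicitly marked `"no data in period"`. The report is a
#' pure function of its inputs.
#'
#' @param subject A chimp id present in the roster, or a group id.
#' @param period Length-2 inclusive date range.
#' @param stores Named list of validated record tables — any of `roster`
#'   (required), `ethogram`, `scans`, `focals`, `wounds`, `wellness`,
#'   `hairloss`, `zone_map`, `nights`, `prt`, `shifts`, `reports` — e.g. a
#'   [simulate_colony()] bundle.
#' @param tia_threshold_pct Budget percentage (strict) for the abnormal
#'   budget trigger.
#' @return List of class `welfare_report` with `subject`, `period`,
#'   `sections`, and an audit `log` of every flag and trigger with the rule
#'   that fired.
#' @export
build_report <- function(subject, period, stores, tia_threshold_pct = 10) {
  roster <- stores$roster
  if (is.null(roster)) abort("stores must include a roster")
  period <- as.Date(period)
  is_group <- subject %in% roster$group_id
  if (!is_group && !subject %in% roster$chimp_id) {
    abort(paste0("unknown subject '", subject, "'"))
  }
  chimps <- if (is_group) {
    roster$chimp_id[roster$group_id == subject]
  } else {
    subject
  }
  eth <- stores$ethogram %||% default_ethogram()
  in_period <- function(d) as.Date(d) >= period[1] & as.Date(d) <= period[2]
  audit <- list()

  # wellness
  wellness <- NULL
  if (!is.null(stores$wellness) && nrow(stores$wellness) > 0) {
    w <- stores$wellness[stores$wellness$chimp_id %in% chimps &
      in_period(stores$wellness$date), , drop = FALSE]
    if (nrow(w) > 0) {
      wellness <- score_surveys(w)
      ele <- wellness[wellness$band != "routine", , drop = FALSE]
      if (nrow(ele) > 0) {
        audit$wellness <- tibble::tibble(
          rule = "wellness_band", chimp_id = ele$chimp_id,
          detail = paste0(ele$band, " (total ", round(ele$total, 2), ")")
        )
      }
    }
  }

  # wounds
  wound_flags <- NULL
  wounds_section <- NULL
  if (!is.null(stores$wounds) && nrow(stores$wounds) > 0) {
    wd <- stores$wounds[stores$wounds$chimp_id %in% chimps &
      in_period(stores$wounds$date), , drop = FALSE]
    if (nrow(wd) > 0) {
      wound_flags <- wound_concern_flags(wd)
      wounds_section <- list(
        flags = wound_flags,
        severity = severity_distribution(wd)
      )
      if (nrow(wound_flags) > 0) {
        audit$wounds <- tibble::tibble(
          rule = paste0("wound_", wound_flags$criterion),
          chimp_id = wound_flags$chimp_id,
          detail = paste0(
            wound_flags$count, " wound(s) in window starting ",
            wound_flags$window_start
          )
        )
      }
    }
  }

  # hair loss
  hairloss <- NULL
  if (!is.null(stores$hairloss) && nrow(stores$hairloss) > 0) {
    h <- stores$hairloss[stores$hairloss$chimp_id %in% chimps &
      in_period(stores$hairloss$date), , drop = FALSE]
    if (nrow(h) > 0) {
      hairloss <- total_hair_loss(h, stores$zone_map %||% default_zone_map())
      sig <- hairloss[hairloss$significant, , drop = FALSE]
      if (nrow(sig) > 0) {
        audit$hairloss <- tibble::tibble(
          rule = "hairloss_significant", chimp_id = sig$chimp_id,
          detail = paste0(round(sig$total_pct, 2), "% total hair loss")
        )
      }
    }
  }

  # activity budget + TIA triggers
  budget <- NULL
  triggers <- NULL
  if (!is.null(stores$scans) && nrow(stores$scans) > 0) {
    sc <- stores$scans[stores$scans$focal_id %in% chimps &
      in_period(as.Date(stores$scans$timestamp)), , drop = FALSE]
    if (nrow(sc) > 0) {
      budget <- budget_from_scans(sc, eth)
    }
  }
  if (!is_group) {
    triggers <- evaluate_tia_triggers(
      subject,
      budget = budget, reports = stores$reports,
      wound_flags = wound_flags, threshold_pct = tia_threshold_pct,
      as_of = period[2]
    )
    if (nrow(triggers) > 0) {
      audit$tia <- tibble::tibble(
        rule = paste0("tia_", triggers$cause),
        chimp_id = triggers$chimp_id, detail = triggers$evidence
      )
    }
  }

  # social
  social <- NULL
  if (!is.null(stores$nights) && nrow(stores$nights) > 0) {
    nt <- stores$nights[stores$nights$chimp_id %in% chimps &
      in_period(stores$nights$date), , drop = FALSE]
    if (nrow(nt) > 0) {
      m <- pair_matrix(nt, stratum = "all")
      top_partners <- tidy_pair_matrix(m) |>
        dplyr::arrange(dplyr::desc(.data$nights)) |>
        head(5)
      social <- list(
        top_partners = top_partners,
        nights_alone = no_neighbor_counts(nt),
        location = location_tally(nt)
      )
    }
  }

  # PRT + shifting
  prt <- NULL
  if (!is.null(stores$prt) && nrow(stores$prt) > 0) {
    p <- stores$prt[stores$prt$chimp_id %in% chimps &
      in_period(stores$prt$date), , drop = FALSE]
    if (nrow(p) > 0) {
      prt <- list(
        engagement = engagement_summary(
          p, roster[roster$chimp_id %in% chimps, ], period
        ),
        compliance = if (!is.null(stores$shifts) && nrow(stores$shifts) > 0) {
          shifting_compliance(stores$shifts, chimp = chimps, period = period)
        } else {
          NULL
        }
      )
    }
  }

  out <- list(
    subject = subject,
    period = as.character(period),
    sections = list(
      wellness = section_or_empty(wellness),
      wounds = section_or_empty(wounds_section),
      hairloss = section_or_empty(hairloss),
      budget = section_or_empty(budget),
      tia_triggers = section_or_empty(triggers),
      social = section_or_empty(social),
      prt = section_or_empty(prt)
    ),
    log = if (length(audit) > 0) dplyr::bind_rows(audit) else "no flags or triggers"
  )
  class(out) <- "welfare_report"
  out
}

#' Serialize a welfare report to JSON
#'
#' @param report A [build_report()] result.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report),
    dataframe = "rows", Date = "ISO8601",
    POSIXt = "ISO8601", na = "null", auto_unbox = TRUE, pretty = TRUE,
    digits = NA
  )
  if (is.null(path)) {
    return(json)
  }
  writeLines(json, path)
  invisible(path)
}

#' @export
format.welfare_report <- function(x, ...) {
  fmt_section <- function(name, s) {
    head <- paste0("## ", name, "\n")
    body <- if (is.character(s) && length(s) == 1) {
      paste0("_", s, "_\n")
    } else if (is.data.frame(s)) {
      paste(utils::capture.output(print(as.data.frame(s))), collapse = "\n")
    } else {
      paste(
        vapply(names(s), function(nm) {
          paste0(
            "### ", nm, "\n",
            if (is.data.frame(s[[nm]])) {
              paste(utils::capture.output(print(as.data.frame(s[[nm]]))),
                collapse = "\n"
              )
            } else {
              paste(utils::capture.output(print(s[[nm]])), collapse = "\n")
            }
          )
        }, character(1)),
        collapse = "\n"
      )
    }
    paste0(head, body, "\n")
  }
  paste0(
    "# Integrated Welfare Report: ", x$subject, "\n",
    "Period: ", x$period[1], " to ", x$period[2], "\n\n",
    paste(
      mapply(fmt_section, names(x$sections), x$sections),
      collapse = "\n"
    )
  )
}

#' @export
print.welfare_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

tidy_pair_matrix <- function(m) {
  subjects <- rownames(m)
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  tibble::tibble(
    a = subjects[idx[, 1]],
    b = subjects[idx[, 2]],
    nights = as.numeric(m[idx])
  )
}
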