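# Canonical tabular schemas for every record stream. Each entry maps a
# column name to a parser tag; "enum:..." lists the admissible values.
record_schemas <- function() {
  list(
    observation = list(
      cols = c(
        timestamp = "datetime", observer = "character",
        focal_id = "character", behavior_code = "character",
        sampling = "enum:instantaneous|all_occurrence|continuous",
        duration_s = "double", neighbors_within_1m = "character"
      ),
      required = c("timestamp", "observer", "focal_id", "behavior_code", "sampling")
    ),
    wound = list(
      cols = c(
        wound_id = "character", chimp_id = "character", date = "date",
        grade = "integer", event_kind = "enum:initial|escalation"
      ),
      required = c("wound_id", "chimp_id", "date", "grade", "event_kind")
    ),
    wellness = list(
      cols = c(
        chimp_id = "character", observer = "character",
        department = "enum:husbandry|behavior|veterinary", date = "date",
        ABN = "integer", LOC = "integer", ACS = "integer", HAI = "integer",
        COT = "integer", SAG = "integer", SIA = "integer", SCO = "integer",
        ENR = "integer", WOU = "integer"
      ),
      required = c(
        "chimp_id", "observer", "department", "date",
        "ABN", "LOC", "ACS", "HAI", "COT", "SAG", "SIA", "SCO", "ENR", "WOU"
      )
    ),
    hairloss = list(
      cols = c(
        chimp_id = "character", date = "date", observer = "character",
        A = "double", B = "double", C = "double", D = "double",
        E = "double", F = "double", G = "double"
      ),
      required = c("chimp_id", "date", "observer")
    ),
    night = list(
      cols = c(
        chimp_id = "character", date = "date",
        location = "enum:indoor|outdoor",
        proximity = "enum:contact|arms_reach|within_3m|outside_3m|no_neighbor",
        neighbor_id = "character"
      ),
      required = c("chimp_id", "date", "location", "proximity")
    ),
    prt = list(
      cols = c(
        date = "date", time_of_day = "character", trainer = "character",
        chimp_id = "character", cue = "character", response = "integer",
        reinforcers = "character", co_trainers = "character",
        notes = "character"
      ),
      required = c("date", "time_of_day", "trainer", "chimp_id", "cue", "response")
    ),
    shift = list(
      cols = c(
        date = "date", group_id = "character", shifter = "character",
        goal = "character", weather_excluded = "logical",
        alternate_goal = "logical", chimp_id = "character",
        complied = "logical", notes = "character"
      ),
      required = c(
        "date", "group_id", "shifter", "weather_excluded",
        "alternate_goal", "chimp_id", "complied"
      )
    )
  )
}

parse_field <- function(x, type) {
  if (startsWith(type, "enum:")) {
    levels <- strsplit(sub("^enum:", "", type), "|", fixed = TRUE)[[1]]
    out <- ifelse(x %in% levels, x, NA_character_)
    return(list(value = out, ok = is.na(x) | x %in% levels))
  }
  switch(type,
    character = list(value = x, ok = rep(TRUE, length(x))),
    date = {
      v <- as.Date(x, format = "%Y-%m-%d")
      list(value = v, ok = is.na(x) | !is.na(v))
    },
    datetime = {
      v <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
      v2 <- as.POSIXct(x, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
      v[is.na(v)] <- v2[is.na(v)]
      list(value = v, ok = is.na(x) | !is.na(v))
    },
    integer = {
      suppressWarnings(v <- as.integer(x))
      list(value = v, ok = is.na(x) | !is.na(v))
    },
    double = {
      suppressWarnings(v <- as.numeric(x))
      list(value = v, ok = is.na(x) | !is.na(v))
    },
    logical = {
      v <- rep(NA, length(x))
      v[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
      v[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
      list(value = v, ok = is.na(x) | !is.na(v))
    },
    abort(paste0("unknown field type: ", type))
  )
}

#' Read a validated record table
#'
#' Reads one of the canonical record streams from CSV (header required) or
#' JSON, parses dates and enumerated fields, and validates row by row.
#' Malformed rows are either a hard error (default) or skipped and reported
#' with their source line numbers via the `"rejections"` attribute and a
#' warning. Row order is preserved.
#'
#' @param path CSV or JSON file path.
#' @param schema Record kind: one of `"observation"`, `"wound"`,
#'   `"wellness"`, `"hairloss"`, `"night"`, `"prt"`, `"shift"`.
#' @param on_error `"error"` or `"skip"`.
#' @return A tibble; under `"skip"` the `"rejections"` attribute holds a
#'   tibble of `line`, `problem` for each dropped row.
#' @export
read_records <- function(path, schema, on_error = c("error", "skip")) {
  on_error <- match.arg(on_error)
  spec <- record_schemas()[[schema]]
  if (is.null(spec)) {
    abort(paste0(
      "unknown record schema '", schema, "'; valid kinds: ",
      paste(names(record_schemas()), collapse = ", ")
    ))
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(df) == 0) df <- data.frame()
    tibble::as_tibble(as.data.frame(lapply(df, as.character),
      stringsAsFactors = FALSE
    ))
  } else {
    readr::read_csv(path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    )
  }
  miss <- setdiff(spec$required, names(raw))
  if (length(miss) > 0) {
    abort(paste0(
      "schema '", schema, "': missing required column(s): ",
      paste(miss, collapse = ", ")
    ))
  }
  keep <- intersect(names(spec$cols), names(raw))
  if (nrow(raw) == 0) {
    out <- tibble::as_tibble(lapply(spec$cols[keep], function(type) {
      parse_field(character(), type)$value
    }))
    attr(out, "rejections") <- tibble::tibble(line = integer(), problem = character())
    return(out)
  }
  parsed <- lapply(keep, function(col) parse_field(raw[[col]], spec$cols[[col]]))
  names(parsed) <- keep
  ok_mat <- vapply(parsed, function(p) p$ok, logical(nrow(raw)))
  ok_mat <- matrix(ok_mat, nrow = nrow(raw), dimnames = list(NULL, keep))
  req_missing <- vapply(
    intersect(spec$required, keep),
    function(col) is.na(raw[[col]]) | raw[[col]] == "",
    logical(nrow(raw))
  )
  req_missing <- matrix(req_missing, nrow = nrow(raw))
  bad_row <- rowSums(!ok_mat) > 0 | rowSums(req_missing) > 0
  out <- tibble::as_tibble(lapply(parsed, function(p) p$value))
  if (any(bad_row)) {
    problems <- vapply(which(bad_row), function(i) {
      bad_cols <- unique(c(
        keep[!ok_mat[i, ]],
        intersect(spec$required, keep)[req_missing[i, ]]
      ))
      paste0("unparseable or missing: ", paste(bad_cols, collapse = ", "))
    }, character(1))
    # +1 for the header row so numbers match the file as seen in an editor
    rej <- tibble::tibble(line = which(bad_row) + 1L, problem = problems)
    if (on_error == "error") {
      abort(paste0(
        "malformed rows in ", path, " (schema '", schema, "'): line ",
        paste(rej$line, collapse = ", line ")
      ))
    }
    warn(paste0(nrow(rej), " malformed row(s) skipped in ", path))
    out <- out[!bad_row, , drop = FALSE]
    attr(out, "rejections") <- rej
  } else {
    attr(out, "rejections") <- tibble::tibble(line = integer(), problem = character())
  }
  out
}

#' Write a record table to CSV or JSON
#'
#' Inverse of [read_records()]: a written file reloads to an identical
#' collection. Dates serialize as ISO-8601; the format is chosen from the
#' file extension.
#'
#' @param records Tibble as returned by [read_records()] or built in code.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  df <- as.data.frame(records)
  for (col in names(df)) {
    if (inherits(df[[col]], "POSIXct")) {
      df[[col]] <- format(df[[col]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    } else if (inherits(df[[col]], "Date")) {
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null", pretty = TRUE)
  } else {
    readr::write_csv(df, path, na = "")
  }
  invisible(path)
}

#' Validate a wound event log
#'
#' Enforces the event-log contract of the wound-reporting protocol: only a
#' wound's initial occurrence and severity escalations are recorded, so the
#' first event for each `wound_id` must be `initial`, grades lie in 1-5, and
#' each escalation's grade strictly exceeds the wound's previous maximum.
#'
#' @param log Wound event tibble (`wound_id`, `chimp_id`, `date`, `grade`,
#'   `event_kind`).
#' @return The validated log, invisibly classed `wound_log`.
#' @export
validate_wounds <- function(log) {
  log <- tibble::as_tibble(log)
  log$date <- as.Date(log$date)
  log$grade <- as.integer(log$grade)
  if (nrow(log) > 0 && !all(log$grade %in% 1:5)) {
    abort("wound grades must be integers 1-5")
  }
  check <- log |>
    dplyr::arrange(.data$date) |>
    dplyr::group_by(.data$wound_id) |>
    dplyr::summarise(
      first_initial = dplyr::first(.data$event_kind) == "initial",
      escalates = dplyr::n() == 1 ||
        (all(.data$event_kind[-1] == "escalation") &&
          all(diff(cummax(.data$grade)) > 0)),
      .groups = "drop"
    )
  if (nrow(check) > 0 && !all(check$first_initial)) {
    abort(paste0(
      "first event must be 'initial' for wound(s): ",
      paste(check$wound_id[!check$first_initial], collapse = ", ")
    ))
  }
  if (nrow(check) > 0 && !all(check$escalates)) {
    abort(paste0(
      "escalations must strictly increase grade for wound(s): ",
      paste(check$wound_id[!check$escalates], collapse = ", ")
    ))
  }
  if (!inherits(log, "wound_log")) class(log) <- c("wound_log", class(log))
  invisible(log)
}
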