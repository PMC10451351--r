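#' Construct and validate a colony roster
#'
#' The roster is the authoritative list of animals; every record stream is
#' validated against it. `chimp_id` is the opaque join key used throughout;
#' `name` is the display name observers type (and misspell).
#'
#' @param df Data frame with columns `chimp_id`, `name`, `sex` (`"M"`/`"F"`),
#'   `birth_date` (`Date` or ISO-8601 string), `group_id`.
#' @return A tibble of class `chimp_roster`.
#' @export
#' @examples
#' chimp_roster(data.frame(
#'   chimp_id = "c1", name = "Kasey", sex = "M",
#'   birth_date = "1988-03-01", group_id = "g1"
#' ))
chimp_roster <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("chimp_id", "name", "sex", "birth_date", "group_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("roster is missing columns: ", paste(miss, collapse = ", ")))
  }
  df$chimp_id <- as.character(df$chimp_id)
  df$name <- as.character(df$name)
  df$group_id <- as.character(df$group_id)
  df$birth_date <- as.Date(df$birth_date)
  if (anyDuplicated(df$chimp_id)) {
    abort("roster chimp_id values must be unique")
  }
  if (!all(df$sex %in% c("M", "F"))) {
    abort("roster sex must be 'M' or 'F'")
  }
  class(df) <- c("chimp_roster", class(df))
  df
}

#' Cross-check record names against the roster
#'
#' Observer-entered names drift (misspellings, case differences) and corrupt
#' per-animal counts downstream. This scans every identifier column of a
#' record table against the roster and reports unknown values together with
#' the nearest roster entry by Levenshtein edit distance as a correction
#' suggestion (ties broken alphabetically). Matching is case-insensitive by
#' default; unknown names are report content, never an error.
#'
#' @param records Data frame of any record kind.
#' @param roster A [chimp_roster()].
#' @param id_cols Identifier columns to check; defaults to any of
#'   `chimp_id`, `focal_id`, `neighbor_id` present in `records`.
#' @param ignore_case Accept names differing from the roster only by case?
#' @return Tibble with one row per offending cell: `row`, `column`, `value`,
#'   `suggestion`, `distance`. Zero rows when every name resolves.
#' @export
#' @examples
#' roster <- chimp_roster(data.frame(
#'   chimp_id = c("Kasey", "Latoya"), name = c("Kasey", "Latoya"),
#'   sex = c("M", "F"), birth_date = "1990-01-01", group_id = "g1"
#' ))
#' validate_names(data.frame(chimp_id = "Kassey"), roster)
validate_names <- function(records, roster,
                           id_cols = c("chimp_id", "focal_id", "neighbor_id"),
                           ignore_case = TRUE) {
  stopifnot(nrow(roster) > 0)
  records <- tibble::as_tibble(records)
  id_cols <- intersect(id_cols, names(records))
  known <- unique(c(roster$chimp_id, roster$name))
  key <- if (ignore_case) tolower(known) else known
  out <- purrr::map_dfr(id_cols, function(col) {
    vals <- as.character(records[[col]])
    probe <- if (ignore_case) tolower(vals) else vals
    bad <- which(!is.na(vals) & vals != "" & !(probe %in% key))
    if (length(bad) == 0) {
      return(tibble::tibble(
        row = integer(), column = character(), value = character(),
        suggestion = character(), distance = integer()
      ))
    }
    sug <- purrr::map_dfr(vals[bad], function(v) {
      d <- drop(adist(v, known, ignore.case = ignore_case))
      best <- min(d)
      cand <- sort(known[d == best])
      tibble::tibble(suggestion = cand[1], distance = as.integer(best))
    })
    tibble::tibble(
      row = bad, column = col, value = vals[bad],
      suggestion = sug$suggestion, distance = sug$distance
    )
  })
  dplyr::arrange(out, .data$row, .data$column)
}
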