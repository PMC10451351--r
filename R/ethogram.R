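#' Behavior categories used by all activity-budget computations
#'
#' The closed set of nine behavior categories every ethogram code must map
#' into. Budgets, triggers and the synthetic colony all share this set.
#'
#' @return Character vector of the nine category names.
#' @export
#' @examples
#' behavior_categories()
behavior_categories <- function() {
  c(
    "inactive", "food_drink", "self_directed", "locomotion",
    "affiliative", "abnormal", "aggressive", "sexual", "other"
  )
}

#' Construct an ethogram
#'
#' An ethogram is the catalogue of behavior codes recorded during
#' observation. Instantaneous codes are sampled at scan instants and feed
#' activity budgets; all-occurrence codes are rare events tallied whenever
#' they happen and feed per-hour rates.
#'
#' @param instantaneous Data frame with columns `code` and `category`
#'   (one of [behavior_categories()]).
#' @param all_occurrence Character vector of all-occurrence behavior codes.
#' @return A tibble of class `ethogram` with columns `code`, `category`,
#'   `sampling`.
#' @export
ethogram <- function(instantaneous, all_occurrence = character()) {
  instantaneous <- tibble::as_tibble(instantaneous)
  stopifnot(all(c("code", "category") %in% names(instantaneous)))
  bad <- setdiff(unique(instantaneous$category), behavior_categories())
  if (length(bad) > 0) {
    abort(paste0("unknown behavior categories: ", paste(bad, collapse = ", ")))
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(instantaneous[, c("code", "category")],
      sampling = "instantaneous"
    ),
    tibble::tibble(
      code = as.character(all_occurrence),
      category = "other",
      sampling = "all_occurrence"
    )
  )
  if (anyDuplicated(out$code)) {
    abort(paste0(
      "duplicated behavior codes: ",
      paste(unique(out$code[duplicated(out$code)]), collapse = ", ")
    ))
  }
  class(out) <- c("ethogram", class(out))
  out
}

#' Packaged default ethogram
#'
#' Thirty-four instantaneous codes distributed over the nine behavior
#' categories plus six all-occurrence codes. The code names are this
#' package's own working set; both lists are fully configurable through
#' [ethogram()] or [read_ethogram()].
#'
#' @return An `ethogram` tibble (40 rows).
#' @export
#' @examples
#' eth <- default_ethogram()
#' table(eth$sampling)
default_ethogram <- function() {
  inst <- tibble::tribble(
    ~code, ~category,
    "rest", "inactive",
    "sleep", "inactive",
    "sit_idle", "inactive",
    "lie", "inactive",
    "feed", "food_drink",
    "drink", "food_drink",
    "forage", "food_drink",
    "process_food", "food_drink",
    "self_groom", "self_directed",
    "scratch", "self_directed",
    "self_touch", "self_directed",
    "object_play_solo", "self_directed",
    "walk", "locomotion",
    "run", "locomotion",
    "climb", "locomotion",
    "brachiate", "locomotion",
    "swing", "locomotion",
    "groom_other", "affiliative",
    "social_play", "affiliative",
    "embrace", "affiliative",
    "touch_other", "affiliative",
    "food_share", "affiliative",
    "rock", "abnormal",
    "pace", "abnormal",
    "hair_pluck", "abnormal",
    "regurgitate", "abnormal",
    "self_clasp", "abnormal",
    "feces_manipulate", "abnormal",
    "threat", "aggressive",
    "chase", "aggressive",
    "hit", "aggressive",
    "mount", "sexual",
    "genital_inspect", "sexual",
    "out_of_view", "other"
  )
  ethogram(
    inst,
    all_occurrence = c(
      "display", "attack", "copulate", "scream_bout",
      "wound_pick", "self_injure"
    )
  )
}

#' Read an ethogram from a YAML or JSON config file
#'
#' Expected layout: a mapping `instantaneous:` of code -> category plus a
#' list `all_occurrence:` of codes.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `ethogram` tibble.
#' @export
read_ethogram <- function(path) {
  cfg <- read_config(path)
  if (is.null(cfg$instantaneous)) {
    abort("ethogram config must have an 'instantaneous' mapping")
  }
  inst <- tibble::tibble(
    code = names(cfg$instantaneous),
    category = unlist(cfg$instantaneous, use.names = FALSE)
  )
  ethogram(inst, all_occurrence = unlist(cfg$all_occurrence %||% character()))
}

#' @export
print.ethogram <- function(x, ...) {
  n_inst <- sum(x$sampling == "instantaneous")
  n_ao <- sum(x$sampling == "all_occurrence")
  cat(
    "<ethogram> ", n_inst, " instantaneous + ", n_ao,
    " all-occurrence codes\n",
    sep = ""
  )
  NextMethod()
}

read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x
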