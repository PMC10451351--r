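#' Tidy a time budget
#'
#' @param x A `time_budget`.
#' @param ... Unused.
#' @return Tibble: `category`, `pct`.
#' @method tidy time_budget
#' @export
tidy.time_budget <- function(x, ...) {
  tibble::tibble(category = x$category, pct = x$pct)
}

#' One-row summary of a time budget
#'
#' @param x A `time_budget`.
#' @param ... Unused.
#' @return Tibble: `subject`, `basis`, `n_samples`, `top_category`,
#'   `top_pct`, `abnormal_pct`.
#' @method glance time_budget
#' @export
glance.time_budget <- function(x, ...) {
  top <- which.max(x$pct)
  tibble::tibble(
    subject = paste(attr(x, "subject"), collapse = "+"),
    basis = attr(x, "basis"),
    n_samples = attr(x, "n_samples"),
    top_category = x$category[top],
    top_pct = x$pct[top],
    abnormal_pct = x$pct[x$category == "abnormal"]
  )
}

#' Tidy wellness scores into long parameter form
#'
#' @param x A `wellness_score`.
#' @param ... Unused.
#' @return Tibble: `chimp_id`, `date`, `parameter`, `value`.
#' @method tidy wellness_score
#' @export
tidy.wellness_score <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("chimp_id", "date", wellness_parameters())],
    dplyr::all_of(wellness_parameters()),
    names_to = "parameter", values_to = "value"
  )
}

#' One-row-per-survey wellness summary
#'
#' @param x A `wellness_score`.
#' @param ... Unused.
#' @return Tibble: `chimp_id`, `date`, `n_assessors`, `total`, `band`.
#' @method glance wellness_score
#' @export
glance.wellness_score <- function(x, ...) {
  tibble::as_tibble(x)[, c("chimp_id", "date", "n_assessors", "total", "band")]
}

#' Tidy a pair matrix into an edge list
#'
#' @param x A `pair_matrix`.
#' @param ... Unused.
#' @return Tibble: `a`, `b`, `nights` (nonzero unordered pairs).
#' @method tidy pair_matrix
#' @export
tidy.pair_matrix <- function(x, ...) {
  tidy_pair_matrix(x)
}

#' One-row summary of a pair matrix
#'
#' @param x A `pair_matrix`.
#' @param ... Unused.
#' @return Tibble: `stratum`, `n_subjects`, `n_nights`, `n_pairs`,
#'   `top_pair`, `top_nights`.
#' @method glance pair_matrix
#' @export
glance.pair_matrix <- function(x, ...) {
  edges <- tidy_pair_matrix(x)
  top <- if (nrow(edges) > 0) edges[which.max(edges$nights), ] else NULL
  tibble::tibble(
    stratum = attr(x, "stratum"),
    n_subjects = nrow(x),
    n_nights = attr(x, "n_nights"),
    n_pairs = nrow(edges),
    top_pair = if (is.null(top)) NA_character_ else paste(top$a, top$b, sep = "--"),
    top_nights = if (is.null(top)) NA_real_ else top$nights
  )
}
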