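#' Nearest-night-neighbor proximity classes
#'
#' Contact, within arm's reach, within 3 m, outside 3 m (a named neighbor
#' more than 3 m away, possibly in another room), and no neighbor in the
#' shared space. A record names a neighbor exactly when the proximity is
#' not `no_neighbor`.
#'
#' @return Character vector of the five classes, nearest first.
#' @export
proximity_classes <- function() {
  c("contact", "arms_reach", "within_3m", "outside_3m", "no_neighbor")
}

validate_nights <- function(observations, group = NULL) {
  obs <- tibble::as_tibble(observations)
  obs$date <- as.Date(obs$date)
  if (nrow(obs) == 0) {
    return(obs)
  }
  if (!all(obs$proximity %in% proximity_classes())) {
    abort("unknown proximity class in night observations")
  }
  no_nb <- obs$proximity == "no_neighbor"
  named <- !is.na(obs$neighbor_id) & obs$neighbor_id != ""
  if (any(no_nb & named) || any(!no_nb & !named)) {
    abort("neighbor_id must be present exactly when proximity != 'no_neighbor'")
  }
  if (any(named & obs$neighbor_id == obs$chimp_id)) {
    abort("a chimpanzee cannot be its own nearest neighbor")
  }
  if (anyDuplicated(obs[, c("chimp_id", "date")])) {
    abort("one night observation per chimp per night")
  }
  if (!is.null(group)) {
    bad <- setdiff(
      unique(c(obs$chimp_id, obs$neighbor_id[named])), group
    )
    if (length(bad) > 0) {
      abort(paste0(
        "chimp(s) outside the group roster: ", paste(bad, collapse = ", ")
      ))
    }
  }
  obs
}

stratum_classes <- function(stratum, cumulative) {
  named <- setdiff(proximity_classes(), "no_neighbor")
  switch(stratum,
    all = named,
    contact = "contact",
    arms_reach = if (cumulative) c("contact", "arms_reach") else "arms_reach",
    within_3m = if (cumulative) c("contact", "arms_reach", "within_3m") else "within_3m",
    abort(paste0(
      "unknown stratum '", stratum,
      "'; use all, contact, arms_reach or within_3m"
    ))
  )
}

#' Nearest-night-neighbor pair frequency matrix
#'
#' Counts, for each unordered pair of group members, the number of nights
#' on which at least one of the two named the other as its nearest
#' neighbor in the stratum's proximity class(es). Each pair counts at most
#' once per night even when both animals name each other, since edge
#' weights represent nights, not mentions. The `"all"` stratum accepts any
#' named-neighbor proximity including `outside_3m`; the three stratified
#' matrices are per-class by default, or nested (closer classes included)
#' with `cumulative = TRUE`.
#'
#' @param observations Night-observation tibble (`chimp_id`, `date`,
#'   `location`, `proximity`, `neighbor_id`).
#' @param group Character vector of group members; defaults to every chimp
#'   appearing as focal or neighbor.
#' @param stratum `"all"`, `"contact"`, `"arms_reach"` or `"within_3m"`.
#' @param cumulative Include closer classes in a stratified matrix?
#' @return A symmetric integer matrix of class `pair_matrix` with zero
#'   diagonal, subjects as dimnames, and attributes `stratum`, `n_nights`.
#' @export
pair_matrix <- function(observations, group = NULL,
                        stratum = c("all", "contact", "arms_reach", "within_3m"),
                        cumulative = FALSE) {
  stratum <- match.arg(stratum)
  obs <- validate_nights(observations, group)
  if (is.null(group)) {
    named <- obs$neighbor_id[!is.na(obs$neighbor_id) & obs$neighbor_id != ""]
    group <- sort(unique(c(obs$chimp_id, named)))
  }
  classes <- stratum_classes(stratum, cumulative)
  m <- matrix(0L, length(group), length(group), dimnames = list(group, group))
  hits <- obs[obs$proximity %in% classes, , drop = FALSE]
  if (nrow(hits) > 0) {
    a <- pmin(hits$chimp_id, hits$neighbor_id)
    b <- pmax(hits$chimp_id, hits$neighbor_id)
    pairs <- unique(tibble::tibble(date = hits$date, a = a, b = b))
    counts <- dplyr::count(pairs, .data$a, .data$b)
    for (i in seq_len(nrow(counts))) {
      m[counts$a[i], counts$b[i]] <- m[counts$a[i], counts$b[i]] + counts$n[i]
      m[counts$b[i], counts$a[i]] <- m[counts$a[i], counts$b[i]]
    }
  }
  attr(m, "stratum") <- stratum
  attr(m, "cumulative") <- cumulative
  attr(m, "n_nights") <- dplyr::n_distinct(obs$date)
  class(m) <- c("pair_matrix", class(m))
  m
}

#' Nights with no neighbor in shared space
#'
#' @param observations Night-observation tibble.
#' @param group Optional group roster for validation and ordering.
#' @return Tibble: `chimp_id`, `nights_alone`, `nights_observed`.
#' @export
no_neighbor_counts <- function(observations, group = NULL) {
  obs <- validate_nights(observations, group)
  out <- obs |>
    dplyr::group_by(.data$chimp_id) |>
    dplyr::summarise(
      nights_alone = sum(.data$proximity == "no_neighbor"),
      nights_observed = dplyr::n(),
      .groups = "drop"
    )
  if (!is.null(group)) {
    out <- tibble::tibble(chimp_id = group) |>
      dplyr::left_join(out, by = "chimp_id") |>
      dplyr::mutate(dplyr::across(
        c("nights_alone", "nights_observed"),
        ~ tidyr::replace_na(.x, 0L)
      ))
  }
  out
}

#' Indoor/outdoor night location tally
#'
#' @param observations Night-observation tibble.
#' @param group Optional group roster.
#' @param period Optional length-2 inclusive date range.
#' @return Tibble: `chimp_id`, `indoor`, `outdoor`, `nights_observed`
#'   (`indoor + outdoor = nights_observed`).
#' @export
location_tally <- function(observations, group = NULL, period = NULL) {
  obs <- validate_nights(observations, group)
  if (!is.null(period)) {
    period <- as.Date(period)
    obs <- dplyr::filter(obs, .data$date >= period[1], .data$date <= period[2])
  }
  obs |>
    dplyr::group_by(.data$chimp_id) |>
    dplyr::summarise(
      indoor = sum(.data$location == "indoor"),
      outdoor = sum(.data$location == "outdoor"),
      nights_observed = dplyr::n(),
      .groups = "drop"
    )
}

#' Seeded force-directed sociogram layout
#'
#' Node coordinates and edge weights for rendering a sociogram: a
#' weighted Fruchterman-Reingold layout in which heavily co-sleeping pairs
#' sit closer together. Deterministic given the seed; an all-zero matrix
#' still yields a layout of isolated nodes.
#'
#' @param matrix A [pair_matrix()].
#' @param seed Integer seed.
#' @param niter Iterations of the layout algorithm.
#' @return List of class `sociogram`: `nodes` (`chimp_id`, `x`, `y`) and
#'   `edges` (`a`, `b`, `weight`).
#' @export
sociogram_layout <- function(matrix, seed = 1L, niter = 500L) {
  subjects <- rownames(matrix)
  if (length(subjects) < 2) abort("a sociogram needs at least two subjects")
  m <- unclass(matrix)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  g <- igraph::graph_from_adjacency_matrix(m,
    mode = "undirected", weighted = TRUE, diag = FALSE
  )
  xy <- with_seed(seed, {
    if (igraph::ecount(g) > 0) {
      igraph::layout_with_fr(g,
        niter = niter,
        weights = igraph::E(g)$weight
      )
    } else {
      igraph::layout_in_circle(g)
    }
  })
  edges <- if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    tibble::tibble(a = el[, 1], b = el[, 2], weight = igraph::E(g)$weight)
  } else {
    tibble::tibble(a = character(), b = character(), weight = numeric())
  }
  out <- list(
    nodes = tibble::tibble(
      chimp_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]
    ),
    edges = edges
  )
  class(out) <- "sociogram"
  out
}

#' @export
print.sociogram <- function(x, ...) {
  cat(
    "<sociogram> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
    sep = ""
  )
  invisible(x)
}
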