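#' Convert a baboon age to its human-equivalent age
#'
#' Multiplies by the species conversion factor (default 4, the ratio implied
#' by the published equivalence pairs 7.5 -> 30, 13.0 -> 52, 22.1 -> 88) and
#' rounds half away from zero to an integer year.
#'
#' @param baboon_age Age in years (> 0); vectorized.
#' @param factor Conversion ratio (default 4.0).
#' @return Integer human-equivalent years.
#' @export
#' @examples
#' human_equivalent_age(c(7.5, 13.0, 22.1))
human_equivalent_age <- function(baboon_age, factor = 4.0) {
  if (any(!is.finite(baboon_age)) || any(baboon_age <= 0))
    stop_invalid("age must be positive")
  as.integer(round_half_away(factor * baboon_age))
}

#' Build one timeline event
#'
#' @param label Event label.
#' @param age_start Point age, or window start, in years.
#' @param age_end Window end in years (`NA` for point events).
#' @param sd Standard deviation in years, when available.
#' @param source One of `"pathway_tipping"`, `"staining_window"`,
#'   `"morphometry"`.
#' @return One-row event data frame.
#' @export
timeline_event <- function(label, age_start, age_end = NA_real_, sd = NA_real_,
                           source = c("pathway_tipping", "staining_window",
                                      "morphometry")) {
  source <- match.arg(source)
  if (!is.na(age_end) && age_end <= age_start)
    stop_invalid("window events need age_start < age_end")
  data.frame(label = label, age_start = age_start, age_end = age_end,
             sd = sd, source = source, stringsAsFactors = FALSE)
}

#' Order events into a timeline with human-equivalent ages
#'
#' Sorts events ascending by point age (windows by their start), breaking
#' ties alphabetically by label, and annotates each with human-equivalent
#' ages.
#'
#' @param events Data frame of stacked [timeline_event()] rows (>= 1).
#' @param factor Human-equivalence conversion factor.
#' @return Ordered data frame with `human_start` / `human_end` columns.
#' @export
order_events <- function(events, factor = 4.0) {
  if (is.null(events) || nrow(events) == 0) stop_invalid("need >= 1 event")
  events <- events[order(events$age_start, events$label), , drop = FALSE]
  events$human_start <- human_equivalent_age(events$age_start, factor)
  events$human_end <- NA_integer_
  has_end <- !is.na(events$age_end)
  if (any(has_end))
    events$human_end[has_end] <- human_equivalent_age(events$age_end[has_end],
                                                      factor)
  rownames(events) <- NULL
  events
}

#' Assemble the ordered event timeline
#'
#' Combines pathway tipping points (mean vertex +/- SD), the staining
#' accumulation and fast-accumulation windows, and optionally a morphometric
#' vertex (e.g. cardiomyocyte-width increase) into one ordered timeline.
#'
#' @param tipping_points Named list of [pathway_tipping_point()] results;
#'   entries without eligible members are skipped.
#' @param staining Optional `sigmoid_fit` from [estimate_onset()] (must carry
#'   the derived ages).
#' @param morphometry_vertex Optional point age (years) for a morphometric
#'   event.
#' @param factor Human-equivalence conversion factor.
#' @return Ordered timeline data frame (see [order_events()]).
#' @export
build_timeline <- function(tipping_points = list(), staining = NULL,
                           morphometry_vertex = NULL, factor = 4.0) {
  rows <- list()
  for (nm in names(tipping_points)) {
    tp <- tipping_points[[nm]]
    if (is.null(tp$n_members) || tp$n_members == 0) next
    rows[[length(rows) + 1L]] <-
      timeline_event(nm, tp$mean_vertex, sd = tp$sd_vertex,
                     source = "pathway_tipping")
  }
  if (!is.null(staining)) {
    if (is.null(staining$onset_age))
      stop_invalid("staining fit lacks derived ages; use estimate_onset()")
    rows[[length(rows) + 1L]] <-
      timeline_event("GAG accumulation", staining$onset_age,
                     staining$end_age, source = "staining_window")
    rows[[length(rows) + 1L]] <-
      timeline_event("GAG fast accumulation", staining$fast_start,
                     staining$fast_end, source = "staining_window")
  }
  if (!is.null(morphometry_vertex))
    rows[[length(rows) + 1L]] <-
      timeline_event("cardiomyocyte width increase", morphometry_vertex,
                     source = "morphometry")
  order_events(do.call(rbind, rows), factor = factor)
}
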