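#' Convert germination counts to censoring intervals
#'
#' Each seed's germination time is only known to lie between two consecutive
#' inspections: seeds newly germinated at inspection day `D_t` carry the
#' interval `(D_{t-1}, D_t]`, with `D_0 = 0` (sowing). Seeds that never
#' germinate within the trial are right censored on `(final_day, Inf)`.
#' Intervals are returned in aggregated form, one row per dish and interval
#' with a seed count `n`.
#'
#' @inheritParams validate_germination_counts
#' @return A tibble with columns `accession`, `treatment_mM`, `replicate`,
#'   `left`, `right`, `n` (only rows with `n > 0` are kept).
#' @examples
#' counts <- tibble::tibble(
#'   accession = "A", treatment_mM = 0, replicate = "r1",
#'   day = c(1, 2, 3, 6), new_germinated = c(10L, 20L, 5L, 0L),
#'   n_sown = 50L, abnormal_final = c(NA, NA, NA, 3L)
#' )
#' counts_to_intervals(counts)
#' @export
counts_to_intervals <- function(counts, schedule = inspection_schedule()) {
  sched <- as.numeric(schedule)
  lower <- setNames(c(0, head(sched, -1)), as.character(sched))
  germ <- counts %>%
    filter(.data$new_germinated > 0) %>%
    mutate(
      left = unname(lower[as.character(.data$day)]),
      right = .data$day,
      n = as.integer(.data$new_germinated)
    )
  cens <- counts %>%
    group_by(.data$accession, .data$treatment_mM, .data$replicate) %>%
    summarise(n = .data$n_sown[1] - sum(.data$new_germinated), .groups = "drop") %>%
    filter(.data$n > 0) %>%
    mutate(left = max(sched), right = Inf, n = as.integer(.data$n))
  bind_rows(
    germ %>% select("accession", "treatment_mM", "replicate", "left", "right", "n"),
    cens %>% select("accession", "treatment_mM", "replicate", "left", "right", "n")
  ) %>%
    arrange(.data$accession, .data$treatment_mM, .data$replicate, .data$left)
}

#' Turnbull (maximal-intersection) intervals
#'
#' The nonparametric MLE for interval-censored data places all its mass on
#' the "innermost" intervals `(q, p]`: `q` is one of the observed left
#' endpoints, `p` one of the observed right endpoints, `q < p`, and no other
#' observed endpoint lies strictly between them.
#'
#' @param left,right Numeric vectors of interval endpoints, one entry per
#'   observation (or per aggregated row); intervals are `(left, right]`,
#'   `right` may be `Inf`.
#' @return A tibble with columns `left`, `right`, the ordered disjoint
#'   support intervals.
#' @examples
#' turnbull_intervals(c(0, 0, 1, 1), c(2, 2, 3, 3))
#' @export
turnbull_intervals <- function(left, right) {
  if (length(left) == 0) abort("Need at least one interval.")
  if (length(left) != length(right)) abort("`left` and `right` lengths differ.")
  if (any(right <= left)) abort("All intervals must satisfy right > left.")
  L <- sort(unique(left))
  R <- sort(unique(right))
  ends <- sort(unique(c(L, R)))
  keep <- purrr::map(L, function(q) {
    p_cand <- R[R > q]
    if (!length(p_cand)) return(NULL)
    p <- p_cand[1]
    inner <- ends[ends > q & ends < p]
    if (length(inner)) NULL else c(q, p)
  })
  keep <- purrr::compact(keep)
  out <- tibble(
    left = purrr::map_dbl(keep, 1),
    right = purrr::map_dbl(keep, 2)
  )
  arrange(out, .data$left)
}
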