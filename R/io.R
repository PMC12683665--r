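#' Define an inspection schedule
#'
#' Germination trials are inspected on a fixed set of days after sowing
#' (DAS); counts between consecutive inspections are interval censored.
#' The default schedule (1, 2, 3 and 6 DAS) is the one used throughout the
#' screening experiments this package supports.
#'
#' @param times Numeric vector of inspection days, strictly increasing and
#'   all positive.
#'
#' @return A numeric vector of class `inspection_schedule`.
#' @examples
#' inspection_schedule()
#' inspection_schedule(c(2, 4, 7))
#' @export
inspection_schedule <- function(times = c(1, 2, 3, 6)) {
  times <- as.numeric(times)
  if (length(times) < 1 || anyNA(times)) {
    abort("`times` must be a non-empty numeric vector without NA.")
  }
  if (any(times <= 0)) abort("All inspection days must be > 0.")
  if (any(diff(times) <= 0)) abort("Inspection days must be strictly increasing.")
  structure(times, class = c("inspection_schedule", "numeric"))
}

count_cols <- c(
  "accession", "treatment_mM", "replicate", "day",
  "new_germinated", "n_sown", "abnormal_final"
)

seedling_cols <- c(
  "accession", "treatment_mM", "box", "seedling",
  "shoot_mm", "main_root_mm", "lateral_root_mm"
)

empty_counts <- function() {
  tibble(
    accession = character(), treatment_mM = double(), replicate = character(),
    day = double(), new_germinated = integer(), n_sown = integer(),
    abnormal_final = integer()
  )
}

#' Read a long-format germination count table
#'
#' The canonical interchange format is tidy CSV with one row per petri dish
#' and inspection day: columns `accession`, `treatment_mM`, `replicate`,
#' `day`, `new_germinated`, `n_sown` and `abnormal_final` (the count of
#' abnormal seedlings, populated only on final-day rows). Counts are *newly*
#' germinated seeds per interval; set `cumulative = TRUE` if the file holds
#' running totals instead, in which case they are differenced (a decrease
#' between consecutive days is an error).
#'
#' @param path Path to a CSV file.
#' @param schedule An [inspection_schedule()]. Days outside the schedule are
#'   rejected.
#' @param cumulative Logical; are the counts cumulative totals?
#'
#' @return A tibble with the columns above, one row per dish and day,
#'   sorted by accession, treatment, replicate and day.
#' @seealso [validate_germination_counts()], [dish_summaries()]
#' @export
read_germination_counts <- function(path, schedule = inspection_schedule(),
                                    cumulative = FALSE) {
  counts <- readr::read_csv(path, show_col_types = FALSE,
                            progress = FALSE, col_types = readr::cols())
  if (nrow(counts) == 0) {
    warn(paste0("No data rows in ", path, "; returning an empty table."))
    return(empty_counts())
  }
  missing <- setdiff(count_cols, names(counts))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ", toString(missing)))
  }
  counts <- counts %>%
    select(all_of(count_cols)) %>%
    mutate(
      accession = as.character(.data$accession),
      replicate = as.character(.data$replicate),
      treatment_mM = as.numeric(.data$treatment_mM),
      day = as.numeric(.data$day),
      new_germinated = as.integer(.data$new_germinated),
      n_sown = as.integer(.data$n_sown),
      abnormal_final = as.integer(.data$abnormal_final)
    ) %>%
    arrange(.data$accession, .data$treatment_mM, .data$replicate, .data$day)
  bad_day <- setdiff(unique(counts$day), as.numeric(schedule))
  if (length(bad_day)) {
    abort(paste0("Days outside the inspection schedule: ", toString(bad_day)))
  }
  if (cumulative) {
    counts <- counts %>%
      group_by(.data$accession, .data$treatment_mM, .data$replicate) %>%
      mutate(new_germinated = {
        inc <- diff(c(0L, .data$new_germinated))
        if (any(inc < 0)) {
          abort(paste0(
            "Cumulative counts decrease for dish ",
            .data$accession[1], " / ", .data$treatment_mM[1], " mM / ",
            .data$replicate[1]
          ))
        }
        as.integer(inc)
      }) %>%
      ungroup()
  }
  assert_counts_valid(counts, schedule)
  counts
}

#' Write a germination count table
#'
#' @param counts A germination count tibble as returned by
#'   [read_germination_counts()] or [simulate_panel()].
#' @param path Output CSV path.
#' @return `counts`, invisibly.
#' @export
write_germination_counts <- function(counts, path) {
  readr::write_csv(counts, path, progress = FALSE)
  invisible(counts)
}

# throws on hard invariant violations, naming the offending dish
assert_counts_valid <- function(counts, schedule) {
  diag <- validate_germination_counts(counts, schedule)
  hard <- diag %>% filter(.data$severity == "error")
  if (nrow(hard)) {
    abort(paste0(
      "Invalid germination counts:\n",
      paste0("- ", hard$issue, " [", hard$dish, "]", collapse = "\n")
    ))
  }
  invisible(counts)
}

dish_key <- function(df) {
  paste(df$accession, paste0(df$treatment_mM, "mM"), df$replicate, sep = "/")
}

#' Validate a germination count table
#'
#' Checks every dish against the data-model invariants: non-negative integer
#' counts, total germinated not exceeding sown, abnormal seedlings not
#' exceeding germinated, a complete inspection schedule per dish, and no
#' duplicated (accession, treatment, replicate, day) rows. Diagnostics are
#' returned, never thrown, so the function is usable as a pre-flight check.
#'
#' @inheritParams read_germination_counts
#' @param counts A long germination count tibble.
#'
#' @return A tibble with columns `dish`, `issue`, `severity` (zero rows if
#'   the table is clean).
#' @export
validate_germination_counts <- function(counts, schedule = inspection_schedule()) {
  out <- list()
  note <- function(dish, issue, severity = "error") {
    tibble(dish = dish, issue = issue, severity = severity)
  }
  if (nrow(counts) == 0) {
    return(note(character(), character(), character())[0, ])
  }
  dup <- counts %>%
    count(.data$accession, .data$treatment_mM, .data$replicate, .data$day) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    out <- c(out, list(note(dish_key(dup), "duplicate dish/day row")))
  }
  neg <- counts %>% filter(.data$new_germinated < 0 | .data$n_sown < 0)
  if (nrow(neg)) {
    out <- c(out, list(note(dish_key(neg), "negative count")))
  }
  per_dish <- counts %>%
    group_by(.data$accession, .data$treatment_mM, .data$replicate) %>%
    summarise(
      g6 = sum(.data$new_germinated),
      n_sown = .data$n_sown[1],
      sown_constant = length(unique(.data$n_sown)) == 1,
      n_abnormal = final_abnormal(.data$day, .data$abnormal_final, max(schedule)),
      days_ok = setequal(.data$day, as.numeric(schedule)),
      .groups = "drop"
    )
  over <- per_dish %>% filter(.data$g6 > .data$n_sown)
  if (nrow(over)) {
    out <- c(out, list(note(
      dish_key(over),
      paste0("germinated (", over$g6, ") exceeds sown (", over$n_sown, ")")
    )))
  }
  inc <- per_dish %>% filter(!.data$days_ok)
  if (nrow(inc)) {
    out <- c(out, list(note(dish_key(inc), "incomplete schedule")))
  }
  ab <- per_dish %>%
    filter(!is.na(.data$n_abnormal) & .data$n_abnormal > .data$g6)
  if (nrow(ab)) {
    out <- c(out, list(note(dish_key(ab), "abnormal count exceeds germinated")))
  }
  sc <- per_dish %>% filter(!.data$sown_constant)
  if (nrow(sc)) {
    out <- c(out, list(note(dish_key(sc), "n_sown varies within dish")))
  }
  if (length(out)) bind_rows(out) else note(character(), character(), character())[0, ]
}

final_abnormal <- function(day, abnormal_final, final_time) {
  x <- abnormal_final[day == final_time]
  if (length(x) == 0 || all(is.na(x))) NA_integer_ else as.integer(x[[1]])
}

#' Summarise germination counts per dish
#'
#' Collapses a long count table to one row per dish with the bookkeeping
#' totals used by the index formulas: `g6` (total germinated at the final
#' count), `n_abnormal`, and `n_normal = g6 - n_abnormal`.
#'
#' @inheritParams validate_germination_counts
#' @return A tibble with one row per (accession, treatment, replicate).
#' @export
dish_summaries <- function(counts, schedule = inspection_schedule()) {
  counts %>%
    group_by(.data$accession, .data$treatment_mM, .data$replicate) %>%
    summarise(
      n_sown = .data$n_sown[1],
      g6 = sum(.data$new_germinated),
      n_abnormal = final_abnormal(.data$day, .data$abnormal_final, max(schedule)),
      .groups = "drop"
    ) %>%
    mutate(n_normal = .data$g6 - .data$n_abnormal)
}

#' Read a per-seedling morphometry table
#'
#' Expects tidy CSV with one row per measured seedling: `accession`,
#' `treatment_mM`, `box`, `seedling`, `shoot_mm`, `main_root_mm`,
#' `lateral_root_mm`. Boxes with fewer measured seedlings than sown are
#' accepted; negative lengths are not.
#'
#' @param path Path to a CSV file.
#' @return A tibble with the columns above.
#' @export
read_seedling_lengths <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       progress = FALSE, col_types = readr::cols())
  missing <- setdiff(seedling_cols, names(x))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ", toString(missing)))
  }
  x <- x %>%
    select(all_of(seedling_cols)) %>%
    mutate(
      accession = as.character(.data$accession),
      box = as.character(.data$box),
      treatment_mM = as.numeric(.data$treatment_mM)
    )
  lens <- c(x$shoot_mm, x$main_root_mm, x$lateral_root_mm)
  if (any(lens < 0, na.rm = TRUE)) {
    abort("Negative seedling lengths found; lengths must be >= 0 mm.")
  }
  x
}

#' Validate a per-seedling morphometry table
#'
#' Diagnostic counterpart of [validate_germination_counts()] for seedling
#' tables: flags negative lengths and duplicated seedling keys. Returns
#' diagnostics, never throws.
#'
#' @param seedlings A per-seedling tibble, see [read_seedling_lengths()].
#' @return A tibble with columns `box`, `issue`, `severity`.
#' @export
validate_seedling_lengths <- function(seedlings) {
  out <- list()
  note <- function(box, issue) {
    tibble(box = box, issue = issue, severity = "error")
  }
  key <- function(df) {
    paste(df$accession, paste0(df$treatment_mM, "mM"), df$box, sep = "/")
  }
  if (nrow(seedlings)) {
    neg <- seedlings %>%
      filter(.data$shoot_mm < 0 | .data$main_root_mm < 0 |
               .data$lateral_root_mm < 0)
    if (nrow(neg)) out <- c(out, list(note(key(neg), "negative length")))
    dup <- seedlings %>%
      count(.data$accession, .data$treatment_mM, .data$box, .data$seedling) %>%
      filter(.data$n > 1)
    if (nrow(dup)) out <- c(out, list(note(key(dup), "duplicate seedling")))
  }
  if (length(out)) bind_rows(out) else note(character(), character())[0, ]
}

#' Write a per-seedling morphometry table
#'
#' @param seedlings A seedling tibble as returned by
#'   [read_seedling_lengths()] or [simulate_seedlings()].
#' @param path Output CSV path.
#' @return `seedlings`, invisibly.
#' @export
write_seedling_lengths <- function(seedlings, path) {
  readr::write_csv(seedlings, path, progress = FALSE)
  invisible(seedlings)
}
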