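#' Per-dish germination indices
#'
#' Computes, for every dish, the six classical germination indices from the
#' newly-germinated counts `N_t` at inspection days `D_t`, the number of
#' sown seeds `Ntot`, the final total germinated `G6` and the number of
#' morphologically normal seedlings `Nnorm`:
#'
#' * `tg` — total germination, `G6 / Ntot x 100` (%);
#' * `vc` — velocity coefficient, `G6 / sum(N_t D_t)` (per DAS);
#' * `gi` — germination index, `sum(N_t / D_t)` (seeds per DAS);
#' * `mgt` — mean germination time, `sum(N_t D_t) / Ntot` (DAS);
#' * `gsi` — germination synchrony index,
#'   `sum(N_t (N_t - 1)) / (G6 (G6 - 1))`, undefined for `G6 <= 1`;
#' * `nr` — normality rate, `Nnorm / G6 x 100` (%), undefined for `G6 = 0`.
#'
#' The `mgt` denominator follows the screening formula (`Ntot`); the
#' conventional variant dividing by germinated seeds is available via
#' `mgt_denominator = "germinated"`. With the default denominator the
#' algebraic identity `mgt * vc = G6 / Ntot` holds on every dish where both
#' are defined. Undefined values propagate as `NA`; on a dish with `G6 = 0`
#' the formulas give `tg = vc = gi = mgt = 0`.
#'
#' @inheritParams validate_germination_counts
#' @param mgt_denominator `"ntot"` (screening formula) or `"germinated"`.
#' @return A tibble with one row per dish: identifiers, bookkeeping totals
#'   and the six indices plus `abnormality_pct = 100 - nr`.
#' @export
germination_indices <- function(counts, schedule = inspection_schedule(),
                                mgt_denominator = c("ntot", "germinated")) {
  mgt_denominator <- match.arg(mgt_denominator)
  counts %>%
    group_by(.data$accession, .data$treatment_mM, .data$replicate) %>%
    summarise(
      n_sown = .data$n_sown[1],
      g6 = sum(.data$new_germinated),
      n_abnormal = final_abnormal(.data$day, .data$abnormal_final, max(schedule)),
      sum_ntdt = sum(.data$new_germinated * .data$day),
      gi = sum(.data$new_germinated / .data$day),
      sum_ntnt1 = sum(.data$new_germinated * (.data$new_germinated - 1)),
      .groups = "drop"
    ) %>%
    mutate(
      n_normal = .data$g6 - .data$n_abnormal,
      tg = 100 * .data$g6 / .data$n_sown,
      vc = if_else(.data$sum_ntdt > 0, .data$g6 / .data$sum_ntdt, 0),
      mgt = if (mgt_denominator == "ntot") {
        .data$sum_ntdt / .data$n_sown
      } else {
        if_else(.data$g6 > 0, .data$sum_ntdt / .data$g6, NA_real_)
      },
      gsi = if_else(.data$g6 > 1,
                    .data$sum_ntnt1 / (.data$g6 * (.data$g6 - 1)), NA_real_),
      nr = if_else(.data$g6 > 0, 100 * .data$n_normal / .data$g6, NA_real_),
      abnormality_pct = 100 - .data$nr
    ) %>%
    select("accession", "treatment_mM", "replicate", "n_sown", "g6",
           "n_abnormal", "n_normal", "tg", "vc", "gi", "mgt", "gsi", "nr",
           "abnormality_pct")
}

#' Stress tolerance index
#'
#' The ratio of a trait's value under stress to its value under control
#' conditions, `STI_x = X_stress / X_control`; 1 means the trait is
#' unaffected by the stress. Undefined (`NA`) when the control value is
#' zero or missing.
#'
#' @param x_control,x_stress Numeric vectors of trait values.
#' @return `x_stress / x_control`, with `NA` where undefined.
#' @examples
#' stress_tolerance_index(2, 1)
#' stress_tolerance_index(0, 1)
#' @export
stress_tolerance_index <- function(x_control, x_stress) {
  if_else(!is.na(x_control) & x_control != 0,
          x_stress / x_control, NA_real_)
}

sti_index_cols <- c("tg", "nr", "gi", "vc", "gsi", "mgt")

#' Accession-level stress tolerance index profiles
#'
#' Computes the six germination indices per dish, averages them over
#' replicates within accession x treatment, and forms the stress tolerance
#' index of each as the ratio of the stress-treatment mean to the control
#' mean (ratio of means; the more stable choice when control values can be
#' near zero). `aggregate = "mean_of_ratios"` instead pairs dishes by
#' replicate label, ratios each pair and averages. Accessions missing
#' either treatment are excluded with a message.
#'
#' @inheritParams germination_indices
#' @param control_mM,stress_mM Treatment levels (mM NaCl) used as
#'   denominator and numerator.
#' @param aggregate Aggregation scheme, see Details.
#' @return A tibble with one row per accession and columns `sti_tg`,
#'   `sti_nr`, `sti_gi`, `sti_vc`, `sti_gsi`, `sti_mgt`.
#' @export
sti_profiles <- function(counts, schedule = inspection_schedule(),
                         control_mM = 0, stress_mM = 200,
                         aggregate = c("ratio_of_means", "mean_of_ratios"),
                         mgt_denominator = c("ntot", "germinated")) {
  aggregate <- match.arg(aggregate)
  idx <- germination_indices(counts, schedule, mgt_denominator) %>%
    filter(.data$treatment_mM %in% c(control_mM, stress_mM))
  have_both <- idx %>%
    distinct(.data$accession, .data$treatment_mM) %>%
    count(.data$accession) %>%
    filter(.data$n == 2) %>%
    pull(.data$accession)
  dropped <- setdiff(unique(idx$accession), have_both)
  if (length(dropped)) {
    inform(paste0("Excluding accession(s) missing a treatment: ",
                  toString(dropped)))
  }
  idx <- idx %>% filter(.data$accession %in% have_both)
  if (aggregate == "ratio_of_means") {
    means <- idx %>%
      group_by(.data$accession, .data$treatment_mM) %>%
      summarise(across(all_of(sti_index_cols), ~ mean(.x, na.rm = TRUE)),
                .groups = "drop")
    ctrl <- means %>% filter(.data$treatment_mM == control_mM)
    strs <- means %>% filter(.data$treatment_mM == stress_mM)
    joined <- left_join(ctrl, strs, by = "accession",
                        suffix = c("_0", "_s"))
    out <- tibble(accession = joined$accession)
    for (v in sti_index_cols) {
      out[[paste0("sti_", v)]] <- stress_tolerance_index(
        joined[[paste0(v, "_0")]], joined[[paste0(v, "_s")]]
      )
    }
    out
  } else {
    ctrl <- idx %>% filter(.data$treatment_mM == control_mM)
    strs <- idx %>% filter(.data$treatment_mM == stress_mM)
    joined <- dplyr::inner_join(ctrl, strs, by = c("accession", "replicate"),
                                suffix = c("_0", "_s"))
    per_rep <- tibble(accession = joined$accession)
    for (v in sti_index_cols) {
      per_rep[[paste0("sti_", v)]] <- stress_tolerance_index(
        joined[[paste0(v, "_0")]], joined[[paste0(v, "_s")]]
      )
    }
    per_rep %>%
      group_by(.data$accession) %>%
      summarise(across(dplyr::starts_with("sti_"),
                       ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  }
}

#' Per-box seedling vigor index
#'
#' For every germination box, averages the measured seedling lengths and
#' combines them with the germinability carried over from the germination
#' experiment:
#' `SVI = germinability_pct x (mean shoot + mean main root + mean lateral
#' root)`, in units of %·mm (the scale cancels in the stress tolerance
#' ratio).
#'
#' @param seedlings Per-seedling morphometry tibble, see
#'   [read_seedling_lengths()].
#' @param germinability A tibble with columns `accession`, `treatment_mM`,
#'   `germinability_pct` (0–100).
#' @return A tibble with one row per box: trait means, `n_seedlings`,
#'   `germinability_pct` and `svi`.
#' @export
seedling_vigor <- function(seedlings, germinability) {
  need <- c("accession", "treatment_mM", "germinability_pct")
  miss <- setdiff(need, names(germinability))
  if (length(miss)) {
    abort(paste0("`germinability` missing column(s): ", toString(miss)))
  }
  if (nrow(seedlings) == 0) abort("No seedlings measured.")
  boxes <- seedlings %>%
    group_by(.data$accession, .data$treatment_mM, .data$box) %>%
    summarise(
      n_seedlings = dplyr::n(),
      shoot_mm = mean(.data$shoot_mm),
      main_root_mm = mean(.data$main_root_mm),
      lateral_root_mm = mean(.data$lateral_root_mm),
      .groups = "drop"
    ) %>%
    left_join(germinability, by = c("accession", "treatment_mM"))
  if (anyNA(boxes$germinability_pct)) {
    bad <- boxes %>% filter(is.na(.data$germinability_pct))
    abort(paste0("No germinability for: ",
                 toString(unique(paste(bad$accession, bad$treatment_mM)))))
  }
  boxes %>%
    mutate(svi = .data$germinability_pct *
             (.data$shoot_mm + .data$main_root_mm + .data$lateral_root_mm))
}

#' Accession-level seedling stress tolerance indices
#'
#' Averages per-box trait means and vigor indices over boxes within
#' accession x treatment, then ratios stress to control for shoot length,
#' main root length, lateral root length and the seedling vigor index.
#'
#' @param vigor Per-box table from [seedling_vigor()].
#' @inheritParams sti_profiles
#' @return A tibble with one row per accession and columns `sti_shoot`,
#'   `sti_main_root`, `sti_lateral_root`, `sti_svi`.
#' @export
seedling_sti <- function(vigor, control_mM = 0, stress_mM = 200) {
  traits <- c(shoot = "shoot_mm", main_root = "main_root_mm",
              lateral_root = "lateral_root_mm", svi = "svi")
  means <- vigor %>%
    filter(.data$treatment_mM %in% c(control_mM, stress_mM)) %>%
    group_by(.data$accession, .data$treatment_mM) %>%
    summarise(across(all_of(unname(traits)), ~ mean(.x, na.rm = TRUE)),
              .groups = "drop")
  ctrl <- means %>% filter(.data$treatment_mM == control_mM)
  strs <- means %>% filter(.data$treatment_mM == stress_mM)
  joined <- dplyr::inner_join(ctrl, strs, by = "accession",
                              suffix = c("_0", "_s"))
  out <- tibble(accession = joined$accession)
  for (nm in names(traits)) {
    out[[paste0("sti_", nm)]] <- stress_tolerance_index(
      joined[[paste0(traits[[nm]], "_0")]], joined[[paste0(traits[[nm]], "_s")]]
    )
  }
  out
}
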