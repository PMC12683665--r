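#' Experiment-1 style analysis: germination dynamics along a salinity gradient
#'
#' Runs the full interval-censored time-to-event analysis for a panel of
#' varieties x treatments: a pooled-fit permutation test of curve equality,
#' per-group generalized Wilcoxon scores, T50 with bootstrap standard
#' errors, and per-variety comparisons of total germination and abnormality
#' percentages across treatments (one-way ANOVA, all-pairs contrasts with
#' Sidak adjustment, compact letters).
#'
#' All randomness (permutations, bootstrap) flows from the single `seed`;
#' stream order is: permutation test first, then bootstrap per group in
#' the row order of the output table.
#'
#' @inheritParams counts_to_intervals
#' @param group Columns defining the comparison groups.
#' @param n_perm Permutations for the curve-equality test.
#' @param n_boot Bootstrap replicates for the T50 standard error.
#' @param seed Integer seed.
#' @param t50_reference Denominator convention for T50, see
#'   [quantile_time()]; `"germinated"` matches "time to 50% of the total
#'   germinated seeds".
#' @param unit Permutation unit, see [permutation_test()].
#' @return A list of class `germscreen_exp1`: `tte` (per-group Wilcoxon
#'   score, T50, SE50), `permutation` (test summary), `germination`
#'   (per-dish indices), `contrasts` (per-accession `germ_grouptest`s for
#'   `tg` and `abnormality_pct`).
#' @export
run_experiment1 <- function(counts, schedule = inspection_schedule(),
                            group = c("accession", "treatment_mM"),
                            n_perm = 1000, n_boot = 200, seed = 1,
                            t50_reference = c("germinated", "sown"),
                            unit = c("dish", "seed")) {
  t50_reference <- match.arg(t50_reference)
  unit <- match.arg(unit)
  set.seed(seed)
  iv <- counts_to_intervals(counts, schedule)
  g <- group_label(iv, group)
  if (nlevels(g) < 2) abort("Need >= 2 groups (variety x treatment).")
  perm <- permutation_test(iv, group = group, n_perm = n_perm, unit = unit)
  groups <- iv %>% distinct(across(all_of(group))) %>%
    arrange(across(all_of(group)))
  tte <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    sub <- dplyr::semi_join(iv, groups[i, ], by = group)
    q <- bootstrap_quantile_se(sub, p = 0.5, n_boot = n_boot,
                               reference = t50_reference)
    dplyr::bind_cols(groups[i, ], tibble(t50 = q$time, se50 = q$se))
  }) %>%
    left_join(perm$group_scores, by = group) %>%
    rename(wilcoxon_score = "score") %>%
    select(all_of(group), "wilcoxon_score", "n_seeds", "t50", "se50") %>%
    arrange(across(all_of(group)))
  idx <- germination_indices(counts, schedule)
  contrasts <- list(tg = list(), abnormality_pct = list())
  for (acc in unique(idx$accession)) {
    sub <- idx %>% filter(.data$accession == acc)
    if (length(unique(sub$treatment_mM)) >= 2 &&
        all(table(sub$treatment_mM) >= 2)) {
      sub$trt <- as.character(sub$treatment_mM)
      contrasts$tg[[acc]] <- anova_pairwise(sub, "tg", "trt")
      sub_ab <- sub %>% filter(!is.na(.data$abnormality_pct))
      if (length(unique(sub_ab$trt)) >= 2 && all(table(sub_ab$trt) >= 2)) {
        contrasts$abnormality_pct[[acc]] <-
          anova_pairwise(sub_ab, "abnormality_pct", "trt")
      }
    }
  }
  out <- list(tte = tte, permutation = glance(perm), germination = idx,
              contrasts = contrasts, seed = seed)
  class(out) <- "germscreen_exp1"
  out
}

#' @export
print.germscreen_exp1 <- function(x, ...) {
  cat("Gradient time-to-event analysis\n")
  print(x$tte, n = Inf)
  cat("permutation p-value:", format(x$permutation$p_value), "\n")
  invisible(x)
}

#' Experiment-2 style analysis: STI screening and clustering of a panel
#'
#' Computes accession-level stress tolerance index profiles, a PCA of the
#' STI matrix, a hierarchical k-means clustering, within-cluster PCAs, and
#' Kruskal–Wallis/Dunn comparisons of every STI across clusters. If the
#' panel carries no between-treatment contrast (all STIs essentially
#' constant), clustering is flagged degenerate instead of fitted.
#'
#' @inheritParams sti_profiles
#' @param k Number of clusters.
#' @param seed Integer seed (recorded; the clustering itself is
#'   deterministic).
#' @return A list of class `germscreen_exp2`: `sti`, `pca`, `clusters`
#'   (a [hkmeans()] object or `NULL`), `within_pca` (per-cluster
#'   [pca_sti()] fits), `sti_tests` (per-index `germ_grouptest`),
#'   `degenerate`.
#' @export
run_experiment2 <- function(counts, schedule = inspection_schedule(),
                            k = 3, seed = 1, control_mM = 0, stress_mM = 200,
                            aggregate = "ratio_of_means") {
  sti <- sti_profiles(counts, schedule, control_mM, stress_mM,
                      aggregate = aggregate)
  num <- sti %>% select(dplyr::where(is.numeric))
  sds <- purrr::map_dbl(num, ~ sd(.x, na.rm = TRUE))
  degenerate <- all(is.na(sds) | sds < 1e-8)
  pca <- NULL
  clusters <- NULL
  within_pca <- list()
  sti_tests <- list()
  if (degenerate) {
    inform("All STIs are (numerically) constant; PCA and clustering skipped.")
  } else {
    pca <- pca_sti(sti)
    clusters <- hkmeans(sti, k = k, seed = seed)
    labelled <- left_join(sti, clusters$clusters, by = "accession")
    for (cl in sort(unique(labelled$cluster))) {
      sub <- labelled %>% filter(.data$cluster == cl) %>%
        select(-"cluster")
      within_pca[[as.character(cl)]] <- tryCatch(
        pca_sti(sub), error = function(e) NULL
      )
    }
    labelled$cluster <- as.character(labelled$cluster)
    for (v in grep("^sti_", names(labelled), value = TRUE)) {
      sti_tests[[v]] <- dunn_test(labelled, v, "cluster")
    }
  }
  out <- list(sti = sti, pca = pca, clusters = clusters,
              within_pca = within_pca, sti_tests = sti_tests,
              degenerate = degenerate, seed = seed)
  class(out) <- "germscreen_exp2"
  out
}

#' @export
print.germscreen_exp2 <- function(x, ...) {
  cat("STI screening of", nrow(x$sti), "accessions\n")
  if (!is.null(x$pca)) {
    ve <- round(100 * x$pca$var_explained[1:2], 1)
    cat("PC1/PC2 variance (%):", paste(ve, collapse = "/"), "\n")
  }
  if (x$degenerate) {
    cat("clustering: degenerate (no treatment contrast)\n")
  } else {
    cat("cluster sizes:", paste(table(x$clusters$clusters$cluster),
                                collapse = "/"), "\n")
  }
  invisible(x)
}

#' Experiment-3 style analysis: seedling stress tolerance by cluster
#'
#' Computes per-box seedling vigor, accession-level trait STIs (shoot,
#' main root, lateral root, vigor index), joins the germination-stage
#' cluster labels, and compares each trait STI across clusters with
#' Kruskal–Wallis/Dunn. Per-box STIs (each stress box ratioed to its
#' accession's control mean) provide the replication for the tests.
#'
#' @inheritParams seedling_vigor
#' @inheritParams seedling_sti
#' @param clusters A tibble with columns `accession`, `cluster` (e.g.
#'   `tidy()` of the [hkmeans()] fit from [run_experiment2()]).
#' @return A list of class `germscreen_exp3`: `vigor` (per box), `sti`
#'   (per accession, with cluster), `box_sti` (per stress box),
#'   `cluster_means`, `tests` (per-trait `germ_grouptest`).
#' @export
run_experiment3 <- function(seedlings, germinability, clusters,
                            control_mM = 0, stress_mM = 200) {
  vigor <- seedling_vigor(seedlings, germinability)
  sti <- seedling_sti(vigor, control_mM, stress_mM)
  miss <- setdiff(sti$accession, clusters$accession)
  if (length(miss)) {
    abort(paste0("No cluster label for accession(s): ", toString(miss)))
  }
  sti <- left_join(sti, clusters %>% select("accession", "cluster"),
                   by = "accession")
  traits <- c(shoot = "shoot_mm", main_root = "main_root_mm",
              lateral_root = "lateral_root_mm", svi = "svi")
  ctrl_means <- vigor %>%
    filter(.data$treatment_mM == control_mM) %>%
    group_by(.data$accession) %>%
    summarise(across(all_of(unname(traits)), mean), .groups = "drop")
  box_sti <- vigor %>%
    filter(.data$treatment_mM == stress_mM) %>%
    left_join(ctrl_means, by = "accession", suffix = c("", "_ctrl")) %>%
    mutate(
      sti_shoot = stress_tolerance_index(.data$shoot_mm_ctrl, .data$shoot_mm),
      sti_main_root = stress_tolerance_index(.data$main_root_mm_ctrl,
                                             .data$main_root_mm),
      sti_lateral_root = stress_tolerance_index(.data$lateral_root_mm_ctrl,
                                                .data$lateral_root_mm),
      sti_svi = stress_tolerance_index(.data$svi_ctrl, .data$svi)
    ) %>%
    select("accession", "box", dplyr::starts_with("sti_")) %>%
    left_join(clusters %>% select("accession", "cluster"), by = "accession")
  cluster_means <- sti %>%
    group_by(.data$cluster) %>%
    summarise(across(dplyr::starts_with("sti_"), ~ mean(.x, na.rm = TRUE)),
              n_accessions = dplyr::n(), .groups = "drop")
  tests <- list()
  bs <- box_sti %>% mutate(cluster = as.character(.data$cluster))
  for (v in grep("^sti_", names(bs), value = TRUE)) {
    tests[[v]] <- dunn_test(bs, v, "cluster")
  }
  out <- list(vigor = vigor, sti = sti, box_sti = box_sti,
              cluster_means = cluster_means, tests = tests)
  class(out) <- "germscreen_exp3"
  out
}

#' @export
print.germscreen_exp3 <- function(x, ...) {
  cat("Seedling STI analysis,", nrow(x$sti), "accessions\n")
  print(x$cluster_means)
  invisible(x)
}
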