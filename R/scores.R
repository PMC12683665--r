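# survival evaluated at observation endpoints against a pooled fit;
# S(Inf) = 0 by convention
pooled_survival_at <- function(fit, t) {
  out <- numeric(length(t))
  finite <- is.finite(t)
  if (any(finite)) {
    out[finite] <- 1 - npmle_cdf(fit, t[finite], interpolate = "linear")$cdf
  }
  out[!finite] <- 0
  out
}

group_label <- function(intervals, group) {
  miss <- setdiff(group, names(intervals))
  if (length(miss)) {
    abort(paste0("Grouping column(s) not found: ", toString(miss)))
  }
  interaction(intervals[group], drop = TRUE, sep = " / ", lex.order = TRUE)
}

#' Generalized Wilcoxon scores for interval-censored groups
#'
#' Fits one pooled NPMLE across all groups and assigns every seed the
#' generalized (Peto-Prentice type) Wilcoxon score
#' \eqn{u = \hat S(L) + \hat S(R) - 1} computed from the pooled survival
#' curve, with \eqn{\hat S(\infty) = 0}. Group scores are the sums of their
#' seeds' scores: positive values flag earlier-than-pooled germination,
#' negative values later. Scores over all groups sum to (numerically) zero.
#'
#' @param intervals Aggregated censoring intervals (columns `left`, `right`,
#'   `n`, plus grouping columns), e.g. from [counts_to_intervals()].
#' @param group Character vector of column names whose combination defines
#'   the comparison groups.
#' @param tol,max_iter Passed on to [fit_npmle()].
#' @return A tibble with the grouping columns, `score` and `n_seeds`, in
#'   decreasing score order.
#' @examples
#' iv <- tibble::tibble(
#'   grp = rep(c("A", "B"), each = 1),
#'   left = c(0, 1), right = c(1, 2), n = c(10, 10)
#' )
#' wilcoxon_scores(iv, group = "grp")
#' @export
wilcoxon_scores <- function(intervals, group = c("accession", "treatment_mM"),
                            tol = 1e-8, max_iter = 10000) {
  g <- group_label(intervals, group)
  if (nlevels(g) < 2) abort("Need at least two groups.")
  n_col <- if ("n" %in% names(intervals)) as.numeric(intervals$n) else
    rep(1, nrow(intervals))
  if (any(tapply(n_col, g, sum) == 0)) abort("Every group needs >= 1 seed.")
  fit <- fit_npmle(intervals, tol = tol, max_iter = max_iter)
  u <- pooled_survival_at(fit, intervals$left) +
    pooled_survival_at(fit, intervals$right) - 1
  intervals %>%
    mutate(.score = u * n_col, .n = n_col) %>%
    group_by(across(all_of(group))) %>%
    summarise(score = sum(.data$.score), n_seeds = sum(.data$.n),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$score))
}

#' Permutation test for equality of germination curves
#'
#' Tests the null hypothesis that all groups share one germination-time
#' distribution. The statistic is \eqn{\sum_g S_g^2 / n_g}, where `S_g` is
#' the group's generalized Wilcoxon score against the pooled NPMLE and
#' `n_g` its seed count; its null distribution is obtained by shuffling
#' group labels. By default labels are permuted at the dish level, which
#' respects the experimental unit; `unit = "seed"` permutes individual
#' seeds (exchangeable only when dish effects are negligible, but the only
#' option with very few dishes per group). The p-value uses the add-one
#' estimator \eqn{(1 + \#\{T^* \ge T\}) / (1 + n_{perm})}, so it can never
#' be exactly zero.
#'
#' @inheritParams wilcoxon_scores
#' @param n_perm Number of label permutations (a warning is issued below 99).
#' @param seed Optional integer seed.
#' @param unit Permutation unit, `"dish"` or `"seed"`.
#' @param dish_cols Columns identifying a dish (used for `unit = "dish"`).
#' @return An object of class `germ_permtest` with elements `statistic`,
#'   `p_value`, `n_perm`, `unit` and `group_scores`; `tidy()` returns the
#'   group scores, `glance()` the test summary.
#' @export
permutation_test <- function(intervals, group = c("accession", "treatment_mM"),
                             n_perm = 1000, seed = NULL,
                             unit = c("dish", "seed"),
                             dish_cols = c("accession", "treatment_mM",
                                           "replicate"),
                             tol = 1e-8, max_iter = 10000) {
  unit <- match.arg(unit)
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 99) warn("Fewer than 99 permutations gives a very coarse p-value.")
  g <- group_label(intervals, group)
  if (nlevels(g) < 2) abort("Need at least two groups.")
  n_col <- if ("n" %in% names(intervals)) as.numeric(intervals$n) else
    rep(1, nrow(intervals))
  fit <- fit_npmle(intervals, tol = tol, max_iter = max_iter)
  u <- pooled_survival_at(fit, intervals$left) +
    pooled_survival_at(fit, intervals$right) - 1

  stat_of <- function(scores, sizes) sum(scores^2 / sizes)

  if (unit == "seed") {
    us <- rep(u, times = n_col)
    gs <- rep(as.integer(g), times = n_col)
    obs_scores <- rowsum(us, gs)[, 1]
    obs_sizes <- tabulate(gs, nlevels(g))
    perm <- purrr::map_dbl(seq_len(n_perm), function(i) {
      gp <- gs[sample.int(length(gs))]
      stat_of(rowsum(us, gp)[, 1], tabulate(gp, nlevels(g)))
    })
  } else {
    dish_cols <- intersect(dish_cols, names(intervals))
    d <- if (length(dish_cols)) interaction(intervals[dish_cols], drop = TRUE)
         else abort("`unit = \"dish\"` requires dish identifier columns.")
    gd_tab <- table(d, g)
    if (any(rowSums(gd_tab > 0) > 1)) {
      abort("A dish maps to more than one group; dishes must nest in groups.")
    }
    gd <- as.integer(g)[match(levels(d), as.character(d))]
    ud <- rowsum(u * n_col, d)[, 1]
    nd <- rowsum(n_col, d)[, 1]
    if (any(tabulate(gd, nlevels(g)) < 2)) {
      abort("Need >= 2 dishes per group for dish-level permutation.")
    }
    obs_scores <- rowsum(ud, gd)[, 1]
    obs_sizes <- rowsum(nd, gd)[, 1]
    perm <- purrr::map_dbl(seq_len(n_perm), function(i) {
      gp <- gd[sample.int(length(gd))]
      stat_of(rowsum(ud, gp)[, 1], rowsum(nd, gp)[, 1])
    })
  }
  obs <- stat_of(obs_scores, obs_sizes)
  p <- (1 + sum(perm >= obs - 1e-9 * max(1, abs(obs)))) / (1 + n_perm)
  scores <- intervals %>%
    mutate(.score = u * n_col, .n = n_col) %>%
    group_by(across(all_of(group))) %>%
    summarise(score = sum(.data$.score), n_seeds = sum(.data$.n),
              .groups = "drop")
  out <- list(
    statistic = obs, p_value = p, n_perm = n_perm, unit = unit,
    group_scores = scores
  )
  class(out) <- "germ_permtest"
  out
}

#' @export
print.germ_permtest <- function(x, ...) {
  cat("Permutation test for equality of germination curves\n")
  cat("statistic:", format(x$statistic), " p-value:", format(x$p_value),
      " (", x$n_perm, " permutations, unit =", x$unit, ")\n")
  print(x$group_scores, ...)
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `germ_permtest` object.
#' @param ... Unused.
#' @method tidy germ_permtest
#' @export
tidy.germ_permtest <- function(x, ...) x$group_scores

#' @rdname permutation_test
#' @method glance germ_permtest
#' @export
glance.germ_permtest <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_perm = x$n_perm, unit = x$unit)
}
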