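# compact letter display from a set of significantly different pairs:
# insert-and-absorb algorithm on the "not significantly different" graph
compact_letters <- function(groups, sig_pairs) {
  sets <- list(groups)
  if (nrow(sig_pairs)) {
    for (i in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs$group_a[i]
      b <- sig_pairs$group_b[i]
      hit <- which(purrr::map_lgl(sets, ~ a %in% .x && b %in% .x))
      for (h in hit) {
        s <- sets[[h]]
        sets[[h]] <- setdiff(s, a)
        sets <- c(sets, list(setdiff(s, b)))
      }
      # absorb sets contained in another
      keep <- rep(TRUE, length(sets))
      for (u in seq_along(sets)) {
        for (v in seq_along(sets)) {
          if (u != v && keep[u] &&
              all(sets[[u]] %in% sets[[v]]) &&
              (length(sets[[u]]) < length(sets[[v]]) || u > v)) {
            keep[u] <- FALSE
            break
          }
        }
      }
      sets <- sets[keep]
    }
  }
  sets <- sets[order(purrr::map_dbl(sets, ~ min(match(.x, groups))))]
  lab <- purrr::map_chr(groups, function(g) {
    paste0(letters[which(purrr::map_lgl(sets, ~ g %in% .x))], collapse = "")
  })
  tibble(group = groups, letters = lab)
}

posthoc_result <- function(method, omnibus, pairwise, letters) {
  out <- list(method = method, omnibus = omnibus, pairwise = pairwise,
              letters = letters)
  class(out) <- "germ_grouptest"
  out
}

#' @export
print.germ_grouptest <- function(x, ...) {
  cat(x$method, "\n")
  print(x$omnibus)
  print(x$pairwise, ...)
  print(x$letters)
  invisible(x)
}

#' @rdname kruskal_wallis_test
#' @param x A `germ_grouptest` object.
#' @param ... Unused.
#' @method tidy germ_grouptest
#' @export
tidy.germ_grouptest <- function(x, ...) x$pairwise

#' @rdname kruskal_wallis_test
#' @method glance germ_grouptest
#' @export
glance.germ_grouptest <- function(x, ...) x$omnibus

split_groups <- function(data, value, group) {
  v <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  split(v[keep], g[keep])
}

#' Kruskal–Wallis rank test across groups
#'
#' Omnibus rank test for a location difference among two or more groups,
#' with the standard tie correction (via [stats::kruskal.test()]). When all
#' values are identical the statistic is reported as 0 with p = 1.
#'
#' @param data A data frame.
#' @param value,group Names (strings) of the value and grouping columns.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `method`.
#' @examples
#' df <- data.frame(y = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                  g = rep(c("a", "b", "c"), each = 3))
#' kruskal_wallis_test(df, "y", "g")
#' @export
kruskal_wallis_test <- function(data, value, group) {
  gs <- split_groups(data, value, group)
  if (length(gs) < 2) abort("Need at least two groups.")
  vals <- unlist(gs)
  if (length(unique(vals)) < 2) {
    return(tibble(statistic = 0, df = length(gs) - 1L, p_value = 1,
                  method = "Kruskal-Wallis"))
  }
  kw <- kruskal.test(gs)
  tibble(statistic = unname(kw$statistic), df = unname(kw$parameter),
         p_value = kw$p.value, method = "Kruskal-Wallis")
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' All pairwise mean-rank contrasts following a Kruskal–Wallis test. For
#' groups a and b, \deqn{z = (\bar R_a - \bar R_b) / \sqrt{\Big(
#' \frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12 (N-1)}\Big)
#' (1/n_a + 1/n_b)}} with the tie term summed over tied value groups.
#' Two-sided normal p-values are Bonferroni-multiplied by the number of
#' pairs; a compact letter display is derived from the significant pairs.
#'
#' @inheritParams kruskal_wallis_test
#' @param alpha Significance level used for the letter display.
#' @return A `germ_grouptest` object: `omnibus` (the Kruskal–Wallis
#'   summary), `pairwise` (one row per pair: `group_a`, `group_b`, `z`,
#'   `p_value`, `adjusted_p`, `significant`), `letters`.
#' @export
dunn_test <- function(data, value, group, alpha = 0.05) {
  gs <- split_groups(data, value, group)
  if (length(gs) < 2) abort("Need at least two groups.")
  omnibus <- kruskal_wallis_test(data, value, group)
  vals <- unlist(gs)
  g <- rep(names(gs), lengths(gs))
  N <- length(vals)
  r <- rank(vals)
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  ties <- table(vals)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  nm <- names(gs)
  pairs <- utils::combn(nm, 2)
  m <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(v0 * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z <- if (se > 0) (mean_rank[[a]] - mean_rank[[b]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    tibble(group_a = a, group_b = b, z = z, p_value = p,
           adjusted_p = min(1, p * m))
  }) %>%
    mutate(significant = .data$adjusted_p <= alpha)
  letters <- compact_letters(nm, pw %>% filter(.data$significant))
  posthoc_result("Dunn's test (Bonferroni-adjusted)", omnibus, pw, letters)
}

#' One-way ANOVA with adjusted pairwise contrasts
#'
#' Fits a one-way ANOVA and compares all group-mean pairs with
#' pooled-variance t statistics; p-values are adjusted by the Sidak formula
#' `1 - (1 - p)^m` over the `m` pairs by default (Bonferroni and unadjusted
#' also available). A compact letter display is derived from the
#' significant pairs. When every group has zero within-group variance the F
#' statistic is undefined and flagged (`statistic = NA`).
#'
#' @inheritParams dunn_test
#' @param adjust Multiplicity adjustment for the pairwise p-values.
#' @return A `germ_grouptest` object (see [dunn_test()]) whose `omnibus`
#'   row holds the F statistic, numerator/denominator df and p-value.
#' @export
anova_pairwise <- function(data, value, group,
                           adjust = c("sidak", "bonferroni", "none"),
                           alpha = 0.05) {
  adjust <- match.arg(adjust)
  gs <- split_groups(data, value, group)
  if (length(gs) < 2) abort("Need at least two groups.")
  if (any(lengths(gs) < 2)) abort("Every group needs >= 2 observations.")
  vals <- unlist(gs)
  g <- factor(rep(names(gs), lengths(gs)))
  fit <- aov(vals ~ g)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  df2 <- an["Residuals", "Df"]
  degenerate <- mse <= .Machine$double.eps * mean(vals^2 + 1)
  omnibus <- if (degenerate) {
    tibble(statistic = NA_real_, df1 = length(gs) - 1L, df2 = df2,
           p_value = NA_real_, method = "one-way ANOVA (zero residual variance)")
  } else {
    tibble(statistic = an["g", "F value"], df1 = an["g", "Df"], df2 = df2,
           p_value = an["g", "Pr(>F)"], method = "one-way ANOVA")
  }
  nm <- names(gs)
  means <- purrr::map_dbl(gs, mean)
  n_g <- lengths(gs)
  pairs <- utils::combn(nm, 2)
  m <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(mse * (1 / n_g[[a]] + 1 / n_g[[b]]))
    tstat <- if (se > 0) (means[[a]] - means[[b]]) / se else
      if (means[[a]] == means[[b]]) 0 else Inf * sign(means[[a]] - means[[b]])
    p <- 2 * pt(-abs(tstat), df2)
    adj <- switch(adjust,
      sidak = 1 - (1 - p)^m,
      bonferroni = min(1, p * m),
      none = p
    )
    tibble(group_a = a, group_b = b, estimate = means[[a]] - means[[b]],
           statistic = tstat, p_value = p, adjusted_p = adj)
  }) %>%
    mutate(significant = !is.na(.data$adjusted_p) & .data$adjusted_p <= alpha)
  letters <- compact_letters(nm, pw %>% filter(.data$significant))
  posthoc_result(paste0("one-way ANOVA, all-pairs contrasts (", adjust, ")"),
                 omnibus, pw, letters)
}
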