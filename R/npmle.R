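#' Fit the Turnbull nonparametric MLE for interval-censored germination times
#'
#' Maximises the interval-censored likelihood
#' \deqn{\prod_i \Big(\sum_{j:\ (q_j,p_j] \subseteq (L_i,R_i]} w_j\Big)^{n_i}}
#' over probability masses \eqn{w_j} on the Turnbull support intervals, by
#' the classical self-consistency EM iteration started from the uniform
#' allocation. The objective is concave on the simplex, so the EM fixed
#' point attains the global optimum; convergence is declared when the
#' largest mass change in one sweep falls below `tol`.
#'
#' @param intervals A tibble with columns `left`, `right` and optionally a
#'   count column `n` (defaults to 1 per row), e.g. from
#'   [counts_to_intervals()]. Right endpoints may be `Inf`.
#' @param tol Convergence tolerance on the maximum absolute mass change.
#' @param max_iter Iteration cap; non-convergence is flagged, never silent.
#' @param trace Record the log-likelihood at every EM iteration (element
#'   `loglik_trace`); useful for diagnosing convergence.
#'
#' @return An object of class `npmle_fit`: a list with `intervals` (tibble
#'   of `left`, `right`, `mass`, `cdf` at the right endpoint), `loglik`,
#'   `n_iter`, `converged`, `n` (number of seeds) and `tol`.
#'   `tidy()` returns the support intervals, `glance()` the fit summary,
#'   and `autoplot()` draws the cumulative curve with its indeterminate
#'   regions shaded.
#' @examples
#' iv <- tibble::tibble(
#'   left = c(0, 1, 2, 6), right = c(1, 2, 3, Inf), n = c(10, 20, 5, 15)
#' )
#' fit <- fit_npmle(iv)
#' tidy(fit)
#' @export
fit_npmle <- function(intervals, tol = 1e-8, max_iter = 10000, trace = FALSE) {
  if (!all(c("left", "right") %in% names(intervals))) {
    abort("`intervals` needs columns `left` and `right`.")
  }
  n_i <- if ("n" %in% names(intervals)) as.numeric(intervals$n) else
    rep(1, nrow(intervals))
  keep <- n_i > 0
  L <- intervals$left[keep]
  R <- intervals$right[keep]
  n_i <- n_i[keep]
  if (!length(L)) abort("Need at least one interval with positive count.")
  tb <- turnbull_intervals(L, R)
  k <- nrow(tb)
  # clique membership: Turnbull interval j is contained in observation i
  A <- outer(L, tb$left, `<=`) & outer(R, tb$right, `>=`)
  storage.mode(A) <- "double"
  N <- sum(n_i)
  w <- rep(1 / k, k)
  converged <- FALSE
  iter <- 0L
  ll_trace <- if (trace) numeric(0) else NULL
  repeat {
    iter <- iter + 1L
    denom <- drop(A %*% w)
    if (trace) ll_trace <- c(ll_trace, sum(n_i * log(denom)))
    w_new <- drop(crossprod(A, n_i / denom)) * w / N
    delta <- max(abs(w_new - w))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warn(paste0("NPMLE EM did not converge in ", max_iter, " iterations."))
  }
  loglik <- sum(n_i * log(drop(A %*% w)))
  out <- list(
    intervals = tb %>% mutate(mass = w, cdf = cumsum(w)),
    loglik = loglik,
    n_iter = iter,
    converged = converged,
    n = N,
    tol = tol,
    loglik_trace = ll_trace
  )
  class(out) <- "npmle_fit"
  out
}

#' @export
print.npmle_fit <- function(x, ...) {
  cat("Turnbull NPMLE fit:", x$n, "seeds,", nrow(x$intervals),
      "support interval(s)\n")
  cat("log-likelihood:", format(x$loglik), "| EM iterations:", x$n_iter,
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(x$intervals, ...)
  invisible(x)
}

#' @rdname fit_npmle
#' @param x An `npmle_fit` object.
#' @param ... Unused.
#' @method tidy npmle_fit
#' @export
tidy.npmle_fit <- function(x, ...) x$intervals

#' @rdname fit_npmle
#' @method glance npmle_fit
#' @export
glance.npmle_fit <- function(x, ...) {
  tibble(
    loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    n = x$n, n_support = nrow(x$intervals)
  )
}

#' Evaluate the fitted cumulative germination curve
#'
#' The NPMLE determines the cumulative probability `F(t)` exactly at the
#' right endpoints of its support intervals and on the gaps between them;
#' *inside* a support interval only the total jump is identified. There the
#' declared interpolation policy is applied (linear by default) and the
#' point is flagged `indeterminate`, mirroring the shaded uncertainty bands
#' customarily drawn on interval-censored germination curves.
#'
#' @param fit An [fit_npmle()] object.
#' @param t Numeric vector of times (DAS), all `>= 0`.
#' @param interpolate `"linear"` interpolates the jump across the interval;
#'   `"left"` carries the lower bound forward.
#' @return A tibble with columns `t`, `cdf`, `indeterminate`.
#' @examples
#' fit <- fit_npmle(tibble::tibble(left = c(0, 1), right = c(1, 2), n = c(1, 1)))
#' npmle_cdf(fit, c(0, 1, 1.5, 2))
#' @export
npmle_cdf <- function(fit, t, interpolate = c("linear", "left")) {
  interpolate <- match.arg(interpolate)
  if (any(t < 0)) abort("Times must be >= 0.")
  tb <- fit$intervals
  cum <- c(0, tb$cdf)
  res <- purrr::map_dfr(t, function(ti) {
    # index of the support interval ti falls strictly inside, if any
    inside <- which(tb$left < ti & ti < tb$right)
    if (length(inside)) {
      j <- inside[1]
      base <- cum[j]
      val <- if (interpolate == "linear" && is.finite(tb$right[j])) {
        base + tb$mass[j] * (ti - tb$left[j]) / (tb$right[j] - tb$left[j])
      } else {
        base
      }
      tibble(t = ti, cdf = val, indeterminate = TRUE)
    } else {
      tibble(t = ti, cdf = sum(tb$mass[tb$right <= ti]), indeterminate = FALSE)
    }
  })
  res
}

#' Germination-time quantiles (T50) from an NPMLE fit
#'
#' Returns the smallest time at which the cumulative curve reaches the
#' target fraction, interpolating linearly across the support interval in
#' which the crossing occurs. With `reference = "sown"` the fraction is of
#' all sown seeds; with `reference = "germinated"` it is of the seeds that
#' germinated within the trial (the convention behind "time to reach 50% of
#' the total germinated seeds", appropriate when viability differs between
#' treatments). The quantile is undefined — `defined = FALSE`, `time = NA`
#' — when the curve never attains the target within the observation window.
#'
#' @param fit An [fit_npmle()] object.
#' @param p Target fraction(s) in (0, 1); 0.5 gives T50.
#' @param reference Denominator convention, see Details.
#' @return A tibble with columns `p`, `time`, `defined`.
#' @examples
#' iv <- tibble::tibble(left = c(0, 1, 2, 6), right = c(1, 2, 3, Inf),
#'                      n = c(10, 20, 5, 15))
#' quantile_time(fit_npmle(iv), 0.5)
#' @export
quantile_time <- function(fit, p = 0.5, reference = c("sown", "germinated")) {
  reference <- match.arg(reference)
  if (any(p <= 0 | p >= 1)) abort("`p` must lie strictly in (0, 1).")
  tb <- fit$intervals
  fin <- is.finite(tb$right)
  f_max <- sum(tb$mass[fin])
  purrr::map_dfr(p, function(pp) {
    level <- if (reference == "sown") pp else pp * f_max
    if (level > f_max + 1e-12 || f_max <= 0) {
      return(tibble(p = pp, time = NA_real_, defined = FALSE))
    }
    cum <- cumsum(tb$mass)
    j <- which(fin & cum >= level - 1e-12)[1]
    if (is.na(j)) return(tibble(p = pp, time = NA_real_, defined = FALSE))
    base <- if (j == 1) 0 else cum[j - 1]
    tt <- if (tb$mass[j] <= 0) {
      tb$right[j]
    } else {
      tb$left[j] + (level - base) / tb$mass[j] * (tb$right[j] - tb$left[j])
    }
    tibble(p = pp, time = max(tt, 0), defined = TRUE)
  })
}

#' Bootstrap standard error for a germination-time quantile
#'
#' Resamples seeds with replacement *within* each dish (the experimental
#' unit), refits the NPMLE on the pooled resample, and reports the standard
#' deviation of the quantile across replicates. Resamples in which the
#' quantile is undefined are dropped and counted; if more than half are
#' undefined the standard error itself is reported as undefined.
#'
#' @inheritParams quantile_time
#' @param intervals Aggregated censoring intervals, e.g. from
#'   [counts_to_intervals()]; rows are grouped into dishes by the columns
#'   named in `dish_cols` when present.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed for reproducibility.
#' @param dish_cols Columns identifying the resampling unit.
#' @param tol,max_iter Passed on to [fit_npmle()].
#' @return A tibble with columns `p`, `time` (point estimate from the full
#'   fit), `se`, `n_defined`, `n_boot`.
#' @export
bootstrap_quantile_se <- function(intervals, p = 0.5, n_boot = 500,
                                  seed = NULL,
                                  reference = c("sown", "germinated"),
                                  dish_cols = c("accession", "treatment_mM",
                                                "replicate"),
                                  tol = 1e-8, max_iter = 10000) {
  reference <- match.arg(reference)
  if (!is.null(seed)) set.seed(seed)
  if (length(p) != 1) abort("`p` must be a single fraction.")
  n_col <- if ("n" %in% names(intervals)) intervals$n else rep(1L, nrow(intervals))
  dish_cols <- intersect(dish_cols, names(intervals))
  dish_id <- if (length(dish_cols)) {
    interaction(intervals[dish_cols], drop = TRUE)
  } else {
    factor(rep(1, nrow(intervals)))
  }
  fit0 <- fit_npmle(intervals, tol = tol, max_iter = max_iter)
  q0 <- quantile_time(fit0, p, reference = reference)
  if (!q0$defined) {
    return(tibble(p = p, time = NA_real_, se = NA_real_,
                  n_defined = 0L, n_boot = n_boot))
  }
  by_dish <- split(seq_len(nrow(intervals)), dish_id)
  qs <- purrr::map_dbl(seq_len(n_boot), function(b) {
    n_new <- unlist(purrr::map(by_dish, function(idx) {
      stats::rmultinom(1, size = sum(n_col[idx]),
                       prob = n_col[idx] / sum(n_col[idx]))[, 1]
    }))
    iv <- tibble(
      left = intervals$left[unlist(by_dish)],
      right = intervals$right[unlist(by_dish)],
      n = as.integer(n_new)
    ) %>% filter(.data$n > 0)
    fb <- fit_npmle(iv, tol = tol, max_iter = max_iter)
    qb <- quantile_time(fb, p, reference = reference)
    if (qb$defined) qb$time else NA_real_
  })
  n_def <- sum(!is.na(qs))
  se <- if (n_def < n_boot / 2 || n_def < 2) NA_real_ else sd(qs, na.rm = TRUE)
  tibble(p = p, time = q0$time, se = se, n_defined = n_def, n_boot = n_boot)
}
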