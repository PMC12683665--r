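# small in-code fixtures and independent oracles shared across tests

# one dish in long format; defaults reproduce the worked bookkeeping example
make_dish <- function(new_germ = c(10L, 20L, 5L, 0L), n_sown = 50L,
                      abnormal = 3L, days = c(1, 2, 3, 6),
                      accession = "A", treatment_mM = 0, replicate = "r1") {
  tibble::tibble(
    accession = accession, treatment_mM = treatment_mM,
    replicate = replicate, day = days,
    new_germinated = as.integer(new_germ), n_sown = as.integer(n_sown),
    abnormal_final = c(rep(NA_integer_, length(days) - 1L),
                       as.integer(abnormal))
  )
}

# all weak compositions of `total` into k parts (rows)
compositions <- function(total, k) {
  if (k == 1) return(matrix(total, 1, 1))
  do.call(rbind, lapply(0:total, function(i) {
    cbind(i, compositions(total - i, k - 1))
  }))
}

# independent oracle: maximise the interval-censored log-likelihood by
# exhaustive search over a probability-simplex grid on the Turnbull intervals
grid_max_loglik <- function(left, right, n, step = 0.01) {
  tb <- turnbull_intervals(left, right)
  A <- outer(left, tb$left, `<=`) & outer(right, tb$right, `>=`)
  storage.mode(A) <- "double"
  W <- t(compositions(round(1 / step), nrow(tb)) * step)
  ll <- colSums(n * log(A %*% W))
  max(ll[is.finite(ll)])
}

# random small censoring instance with endpoints on the standard schedule;
# resamples until the Turnbull support has at most `max_support` intervals
random_small_instance <- function(max_support = 4) {
  ends <- c(0, 1, 2, 3, 6)
  repeat {
    m <- sample(3:12, 1)
    left <- sample(ends, m, replace = TRUE)
    right <- vapply(left, function(l) {
      cand <- ends[ends > l]
      if (length(cand) == 0 || runif(1) < 0.15) Inf
      else sample(rep(cand, 2), 1)
    }, numeric(1))
    if (nrow(turnbull_intervals(left, right)) <= max_support) {
      return(tibble::tibble(left = left, right = right,
                            n = sample(1:5, m, replace = TRUE)))
    }
  }
}

# a small three-archetype panel configuration for fast end-to-end runs
small_config <- function(n_acc = c(C1 = 4, C2 = 3, C3 = 3)) {
  simulation_config(
    n_accessions = n_acc,
    n_morpho_accessions = pmin(n_acc, c(C1 = 2, C2 = 2, C3 = 2)[names(n_acc)])
  )
}
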