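#' Archetype parameters for the germination simulator
#'
#' The simulator draws each seed's latent germination time from a
#' log-normal distribution and applies salt stress through four
#' multipliers: a delay on the median time (`delta`), a viability reduction
#' (`rho`), a synchronization factor on the log-scale spread (`kappa`,
#' below 1 because germination typically becomes *more* synchronous under
#' salt), and a higher abnormality probability. Dishes share a small
#' log-scale random effect (`tau`) that produces realistic replicate
#' overdispersion. Seedling morphometry is Gamma-distributed around
#' archetype-specific control means, shrunk under salt by per-trait
#' multipliers.
#'
#' @param mu0 Log median germination time under control (log-DAS).
#' @param sigma Log-scale spread of germination times under control.
#' @param delta Salt delay multiplier on the median time (>= 1).
#' @param kappa Salt multiplier on `sigma` (0 < kappa <= 1 synchronizes).
#' @param pi0 Control viability (probability a seed can germinate).
#' @param rho Salt viability multiplier (<= 1).
#' @param alpha0,alpha_salt Abnormality probability among germinated seeds
#'   under control / salt.
#' @param tau Dish-level random-effect SD on `mu0` (log-DAS).
#' @param length_means Named control means (mm) for `shoot`, `main_root`,
#'   `lateral_root`.
#' @param length_sti Named salt multipliers for the same three traits.
#' @param length_cv Coefficient of variation of individual seedling lengths.
#' @return A list of class `archetype_params`.
#' @seealso [default_archetypes()], [simulate_dish()]
#' @export
archetype_params <- function(mu0 = log(0.9), sigma = 0.3, delta = 2,
                             kappa = 0.3, pi0 = 0.97, rho = 0.9,
                             alpha0 = 0.08, alpha_salt = 0.17, tau = 0.05,
                             length_means = c(shoot = 30, main_root = 60,
                                              lateral_root = 20),
                             length_sti = c(shoot = 0.5, main_root = 0.25,
                                            lateral_root = 0.1),
                             length_cv = 0.25) {
  stopifnot(
    delta >= 1, kappa > 0, tau >= 0, sigma > 0,
    pi0 >= 0, pi0 <= 1, rho >= 0, rho * pi0 <= 1,
    alpha0 >= 0, alpha0 <= 1, alpha_salt >= 0, alpha_salt <= 1,
    all(length_means > 0), all(length_sti > 0), length_cv > 0
  )
  structure(
    list(mu0 = mu0, sigma = sigma, delta = delta, kappa = kappa,
         pi0 = pi0, rho = rho, alpha0 = alpha0, alpha_salt = alpha_salt,
         tau = tau, length_means = length_means, length_sti = length_sti,
         length_cv = length_cv),
    class = "archetype_params"
  )
}

#' Default cluster archetypes
#'
#' Three archetypes whose defaults are calibrated so that a default
#' simulated panel reproduces the qualitative phenotype contrasts observed
#' in published salinity screens of camelina germination:
#'
#' * `C1` — slow but complete: strong salt delay, high retained
#'   germination (stress/control total-germination ratio about 0.90);
#' * `C2` — salt-sensitive: germination drops to about 0.62 of control,
#'   with a twofold median-time delay;
#' * `C3` — fast but frail: quick, highly synchronized germination under
#'   salt (smallest delay, strongest synchronization) paired with the
#'   weakest seedling growth.
#'
#' Seedling salt multipliers are the published cluster-level stress
#' tolerance ratios (shoot 0.53/0.47/0.24, main root 0.29/0.23/0.15,
#' lateral root 0.17/0.07/0.04 for C1/C2/C3).
#'
#' @return A named list of three [archetype_params()] objects.
#' @export
default_archetypes <- function() {
  list(
    C1 = archetype_params(
      mu0 = log(0.97), sigma = 0.30, delta = 2.15, kappa = 0.15,
      pi0 = 0.97, rho = 0.90, alpha0 = 0.08, alpha_salt = 0.17, tau = 0.05,
      length_sti = c(shoot = 0.53, main_root = 0.29, lateral_root = 0.17)
    ),
    C2 = archetype_params(
      mu0 = log(1.08), sigma = 0.30, delta = 2.00, kappa = 0.34,
      pi0 = 0.97, rho = 0.62, alpha0 = 0.08, alpha_salt = 0.17, tau = 0.05,
      length_sti = c(shoot = 0.47, main_root = 0.23, lateral_root = 0.07)
    ),
    C3 = archetype_params(
      mu0 = log(0.85), sigma = 0.33, delta = 1.79, kappa = 0.10,
      pi0 = 0.97, rho = 0.90, alpha0 = 0.08, alpha_salt = 0.17, tau = 0.05,
      length_sti = c(shoot = 0.24, main_root = 0.15, lateral_root = 0.04)
    )
  )
}

#' Simulation design configuration
#'
#' Bundles the experimental design of a simulated screening panel. The
#' defaults mirror the screening design this package targets: 57
#' accessions split 32/9/14 over the three archetypes, two treatments
#' (0 and 200 mM NaCl), three dishes of 50 seeds inspected at 1, 2, 3 and
#' 6 DAS, and a morphometry follow-up of 5 boxes x 11 seedlings for a
#' 7/3/4 subset of accessions.
#'
#' @param archetypes Named list of [archetype_params()].
#' @param n_accessions Named integer vector, accessions per archetype.
#' @param schedule An [inspection_schedule()].
#' @param treatments Treatment levels in mM NaCl (must include the control).
#' @param n_dishes,n_seeds_per_dish Germination design sizes.
#' @param n_morpho_accessions Named integer vector, accessions per
#'   archetype carried into the seedling experiment; defaults to the 7/3/4
#'   split, capped at the archetype's accession count.
#' @param n_boxes,n_seedlings_per_box Morphometry design sizes.
#' @param control_mM The control level.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(archetypes = default_archetypes(),
                              n_accessions = c(C1 = 32, C2 = 9, C3 = 14),
                              schedule = inspection_schedule(),
                              treatments = c(0, 200),
                              n_dishes = 3, n_seeds_per_dish = 50,
                              n_morpho_accessions = NULL,
                              n_boxes = 5, n_seedlings_per_box = 11,
                              control_mM = 0) {
  if (is.null(n_morpho_accessions)) {
    pattern <- c(C1 = 7, C2 = 3, C3 = 4)[names(n_accessions)]
    pattern[is.na(pattern)] <- Inf
    n_morpho_accessions <- pmin(n_accessions, pattern)
    names(n_morpho_accessions) <- names(n_accessions)
  }
  stopifnot(
    length(archetypes) >= 1,
    setequal(names(n_accessions), names(archetypes)),
    all(n_accessions >= 1), n_dishes >= 1, n_seeds_per_dish >= 1,
    n_boxes >= 1, n_seedlings_per_box >= 1,
    control_mM %in% treatments,
    all(n_morpho_accessions <= n_accessions[names(n_morpho_accessions)])
  )
  structure(
    list(archetypes = archetypes, n_accessions = n_accessions,
         schedule = schedule, treatments = treatments,
         n_dishes = n_dishes, n_seeds_per_dish = n_seeds_per_dish,
         n_morpho_accessions = n_morpho_accessions, n_boxes = n_boxes,
         n_seedlings_per_box = n_seedlings_per_box, control_mM = control_mM),
    class = "simulation_config"
  )
}

#' Simulate one dish of germination counts
#'
#' Each seed is viable with probability `pi0` (control) or `pi0 * rho`
#' (salt); viable seeds draw a latent log-normal germination time whose
#' median is multiplied by `delta` and whose log-spread by `kappa` under
#' salt, on top of a dish-level random shift of SD `tau`. Times are binned
#' by the inspection schedule; non-viable seeds and times past the final
#' inspection are right censored. Abnormal seedlings among the germinated
#' are Binomial with the treatment's abnormality probability.
#'
#' Uses the current RNG state; seed the session (or use [simulate_panel()])
#' for reproducibility.
#'
#' @param params An [archetype_params()] object.
#' @param treatment_mM Treatment level; anything different from
#'   `control_mM` applies the salt multipliers.
#' @param schedule An [inspection_schedule()].
#' @param n_seeds Seeds sown in the dish.
#' @param accession,replicate Labels stamped on the output.
#' @param control_mM The control level.
#' @return A long-format count tibble (one row per inspection day) in the
#'   layout of [read_germination_counts()].
#' @export
simulate_dish <- function(params, treatment_mM, schedule = inspection_schedule(),
                          n_seeds = 50, accession = "ACC", replicate = "r1",
                          control_mM = 0) {
  salt <- treatment_mM != control_mM
  sched <- as.numeric(schedule)
  pi_v <- params$pi0 * if (salt) params$rho else 1
  mu_dish <- rnorm(1, params$mu0, params$tau)
  mu <- mu_dish + if (salt) log(params$delta) else 0
  sig <- params$sigma * if (salt) params$kappa else 1
  viable <- rbinom(1, n_seeds, pi_v)
  times <- if (viable > 0) rlnorm(viable, mu, sig) else numeric(0)
  new_germ <- as.integer(table(cut(times, breaks = c(0, sched))))
  g6 <- sum(new_germ)
  alpha <- if (salt) params$alpha_salt else params$alpha0
  n_abn <- rbinom(1, g6, alpha)
  tibble(
    accession = accession, treatment_mM = as.numeric(treatment_mM),
    replicate = replicate, day = sched,
    new_germinated = new_germ, n_sown = as.integer(n_seeds),
    abnormal_final = c(rep(NA_integer_, length(sched) - 1L), as.integer(n_abn))
  )
}

#' Simulate a full germination screening panel
#'
#' Generates the germination-count table for every accession, treatment
#' and dish in the design, together with a ground-truth table recording
#' each accession's archetype and generative parameters. Fully
#' reproducible given `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list with `counts` (long count tibble), `truth` (tibble of
#'   `accession`, `archetype`, `delta`, `rho`) and `config`.
#' @examples
#' sim <- simulate_panel(simulation_config(
#'   n_accessions = c(C1 = 2, C2 = 2, C3 = 2)), seed = 1)
#' dplyr::count(sim$truth, archetype)
#' @export
simulate_panel <- function(config = simulation_config(), seed = 1) {
  set.seed(seed)
  arch_of <- rep(names(config$n_accessions), config$n_accessions)
  acc <- sprintf("ACC%03d", seq_along(arch_of))
  truth <- tibble(
    accession = acc, archetype = arch_of,
    delta = purrr::map_dbl(arch_of, ~ config$archetypes[[.x]]$delta),
    rho = purrr::map_dbl(arch_of, ~ config$archetypes[[.x]]$rho)
  )
  counts <- purrr::map_dfr(seq_along(acc), function(i) {
    params <- config$archetypes[[arch_of[i]]]
    purrr::map_dfr(config$treatments, function(tr) {
      purrr::map_dfr(seq_len(config$n_dishes), function(d) {
        simulate_dish(params, tr, config$schedule,
                      n_seeds = config$n_seeds_per_dish,
                      accession = acc[i], replicate = paste0("r", d),
                      control_mM = config$control_mM)
      })
    })
  })
  list(counts = counts, truth = truth, config = config)
}

#' Simulate seedling morphometry for a panel subset
#'
#' Draws per-seedling shoot, main-root and lateral-root lengths from Gamma
#' distributions with archetype-specific control means, shrunk under salt
#' by the archetype's per-trait multipliers. Germinability is attached
#' from the archetype's expected germination fraction at the final
#' inspection, the quantity carried over from the germination experiment.
#'
#' @param config A [simulation_config()].
#' @param truth Truth table from [simulate_panel()]; the first
#'   `n_morpho_accessions` of each archetype are carried forward.
#' @param seed Integer seed.
#' @return A list with `seedlings` (per-seedling tibble), `germinability`
#'   (per accession x treatment) and `truth` (selected accessions).
#' @export
simulate_seedlings <- function(config = simulation_config(), truth, seed = 1) {
  set.seed(seed)
  sel <- purrr::map_dfr(names(config$n_morpho_accessions), function(a) {
    truth %>% filter(.data$archetype == a) %>%
      head(config$n_morpho_accessions[[a]])
  })
  sched_final <- max(as.numeric(config$schedule))
  germ <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    p <- config$archetypes[[sel$archetype[i]]]
    purrr::map_dfr(config$treatments, function(tr) {
      salt <- tr != config$control_mM
      mu <- p$mu0 + if (salt) log(p$delta) else 0
      sig <- p$sigma * if (salt) p$kappa else 1
      pi_v <- p$pi0 * if (salt) p$rho else 1
      tibble(accession = sel$accession[i], treatment_mM = as.numeric(tr),
             germinability_pct = 100 * pi_v * plnorm(sched_final, mu, sig))
    })
  })
  seedlings <- purrr::map_dfr(seq_len(nrow(sel)), function(i) {
    p <- config$archetypes[[sel$archetype[i]]]
    shape <- 1 / p$length_cv^2
    purrr::map_dfr(config$treatments, function(tr) {
      salt <- tr != config$control_mM
      mult <- if (salt) p$length_sti else c(shoot = 1, main_root = 1,
                                            lateral_root = 1)
      means <- p$length_means * mult[names(p$length_means)]
      purrr::map_dfr(seq_len(config$n_boxes), function(b) {
        n <- config$n_seedlings_per_box
        tibble(
          accession = sel$accession[i], treatment_mM = as.numeric(tr),
          box = paste0("b", b), seedling = seq_len(n),
          shoot_mm = rgamma(n, shape, rate = shape / means[["shoot"]]),
          main_root_mm = rgamma(n, shape, rate = shape / means[["main_root"]]),
          lateral_root_mm = rgamma(n, shape,
                                   rate = shape / means[["lateral_root"]])
        )
      })
    })
  })
  list(seedlings = seedlings, germinability = germ, truth = sel)
}
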