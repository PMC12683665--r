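test_that("simulated panels are reproducible and honour the design", {
  cfg <- small_config()
  a <- simulate_panel(cfg, seed = 5)
  b <- simulate_panel(cfg, seed = 5)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), sum(cfg$n_accessions))
  expect_equal(
    nrow(a$counts),
    sum(cfg$n_accessions) * length(cfg$treatments) * cfg$n_dishes *
      length(cfg$schedule)
  )
  c_other <- simulate_panel(cfg, seed = 6)
  expect_false(identical(a$counts, c_other$counts))
})

test_that("deterministic limits of the dish generator are exact", {
  # no viability: nothing germinates
  p0 <- archetype_params(pi0 = 0)
  d0 <- simulate_dish(p0, 0)
  expect_equal(sum(d0$new_germinated), 0)
  # near-degenerate timing: all seeds fall in (1, 2]
  p1 <- archetype_params(mu0 = log(1.5), sigma = 1e-6, tau = 0, pi0 = 1)
  d1 <- simulate_dish(p1, 0)
  expect_equal(d1$new_germinated[d1$day == 2], 50L)
  expect_equal(sum(d1$new_germinated), 50L)
})

test_that("the salt delay multiplier is recovered from simulated dishes", {
  pars <- archetype_params(delta = 2, rho = 0.6, tau = 0)
  set.seed(23)
  ratios <- replicate(30, {
    ctrl <- simulate_dish(pars, 0, n_seeds = 200)
    salt <- simulate_dish(pars, 200, n_seeds = 200)
    t0 <- quantile_time(fit_npmle(counts_to_intervals(ctrl)), 0.5,
                        reference = "germinated")$time
    ts <- quantile_time(fit_npmle(counts_to_intervals(salt)), 0.5,
                        reference = "germinated")$time
    ts / t0
  })
  expect_equal(mean(ratios), 2, tolerance = 0.1)
})

test_that("a larger delay increases mean germination time", {
  set.seed(29)
  mgt_at <- function(delta) {
    pars <- archetype_params(delta = delta, kappa = 1, tau = 0)
    mean(replicate(40, {
      germination_indices(simulate_dish(pars, 200))$mgt
    }))
  }
  expect_gt(mgt_at(2.5), mgt_at(1.2))
})

test_that("seedling simulation respects multipliers and trait ordering", {
  cfg <- small_config()
  pan <- simulate_panel(cfg, seed = 2)
  sl <- simulate_seedlings(cfg, pan$truth, seed = 3)
  expect_equal(nrow(sl$truth), sum(cfg$n_morpho_accessions))
  # zero-variance lengths make the box STI exactly the configured multiplier
  arch_one <- list(A = archetype_params(length_cv = 1e-9, tau = 0,
                                        length_sti = c(shoot = 0.5,
                                                       main_root = 0.25,
                                                       lateral_root = 0.1)))
  cfg0 <- simulation_config(archetypes = arch_one,
                            n_accessions = c(A = 2),
                            n_morpho_accessions = c(A = 2))
  sl0 <- simulate_seedlings(cfg0, tibble::tibble(
    accession = c("ACC001", "ACC002"), archetype = "A",
    delta = 2, rho = 0.9
  ), seed = 4)
  sti0 <- seedling_sti(seedling_vigor(sl0$seedlings, sl0$germinability))
  expect_equal(sti0$sti_shoot, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sti0$sti_main_root, c(0.25, 0.25), tolerance = 1e-6)
  expect_equal(sti0$sti_lateral_root, c(0.1, 0.1), tolerance = 1e-6)
  # default archetypes: shoot least affected, lateral root most
  sti <- seedling_sti(seedling_vigor(sl$seedlings, sl$germinability))
  expect_gt(mean(sti$sti_shoot), mean(sti$sti_main_root))
  expect_gt(mean(sti$sti_main_root), mean(sti$sti_lateral_root))
})

test_that("salt multipliers of one produce trait STIs near one", {
  arch <- list(A = archetype_params(length_sti = c(shoot = 1, main_root = 1,
                                                   lateral_root = 1)))
  cfg <- simulation_config(archetypes = arch, n_accessions = c(A = 3),
                           n_morpho_accessions = c(A = 3))
  pan <- simulate_panel(cfg, seed = 7)
  sl <- simulate_seedlings(cfg, pan$truth, seed = 8)
  sti <- seedling_sti(seedling_vigor(sl$seedlings, sl$germinability))
  expect_equal(mean(sti$sti_shoot), 1, tolerance = 0.15)
  expect_equal(mean(sti$sti_main_root), 1, tolerance = 0.15)
})

test_that("archetypes with identical parameters carry no cluster signal", {
  arch <- default_archetypes()
  arch$C2 <- arch$C1
  arch$C3 <- arch$C1
  cfg <- simulation_config(archetypes = arch,
                           n_accessions = c(C1 = 10, C2 = 10, C3 = 10),
                           n_morpho_accessions = c(C1 = 2, C2 = 2, C3 = 2))
  sim <- simulate_panel(cfg, seed = 19)
  sti <- sti_profiles(sim$counts)
  hk <- hkmeans(sti, k = 3, seed = 1)
  joined <- dplyr::left_join(tidy(hk), sim$truth, by = "accession")
  ri <- rand_index(joined$cluster, joined$archetype)
  # chance level for balanced 3-cluster labels is around 0.55; well below 0.9
  expect_lt(ri, 0.75)
})

test_that("invalid archetype parameters are rejected", {
  expect_error(archetype_params(delta = 0.5))
  expect_error(archetype_params(pi0 = 1.2))
  expect_error(archetype_params(length_cv = -1))
  expect_error(simulation_config(n_accessions = c(C1 = 2)), "setequal")
})
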