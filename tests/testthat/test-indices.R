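test_that("the worked dish reproduces all six printed index values", {
  dish <- make_dish(new_germ = c(20L, 20L, 10L), days = c(1, 2, 3),
                    abnormal = 5L)
  idx <- germination_indices(dish, inspection_schedule(c(1, 2, 3)))
  expect_equal(idx$tg, 100)
  expect_equal(idx$vc, 50 / 90, tolerance = 1e-9)     # 0.556
  expect_equal(idx$gi, 20 / 1 + 20 / 2 + 10 / 3, tolerance = 1e-9) # 33.33
  expect_equal(idx$mgt, 1.8)
  expect_equal(idx$gsi, 850 / 2450, tolerance = 1e-9) # 0.3469
  expect_equal(idx$nr, 90)
  expect_equal(idx$abnormality_pct, 10)
})

test_that("single-flush germination hits the limiting values", {
  dish <- make_dish(new_germ = c(50L, 0L, 0L, 0L), abnormal = 0L)
  idx <- germination_indices(dish)
  expect_equal(idx$tg, 100)
  expect_equal(idx$vc, 1)
  expect_equal(idx$gi, 50)
  expect_equal(idx$mgt, 1)
  expect_equal(idx$gsi, 1)
  expect_equal(idx$nr, 100)
})

test_that("a dish with no germination degrades gracefully", {
  dish <- make_dish(new_germ = c(0L, 0L, 0L, 0L), abnormal = 0L)
  idx <- germination_indices(dish)
  expect_equal(idx$tg, 0)
  expect_equal(idx$vc, 0)
  expect_equal(idx$gi, 0)
  expect_equal(idx$mgt, 0)
  expect_true(is.na(idx$gsi))
  expect_true(is.na(idx$nr))
})

test_that("mgt x vc equals the germinated fraction on random dishes", {
  set.seed(31)
  pars <- archetype_params()
  for (i in 1:200) {
    trt <- sample(c(0, 200), 1)
    dish <- simulate_dish(pars, trt)
    idx <- germination_indices(dish)
    if (!is.na(idx$vc) && idx$vc > 0) {
      expect_equal(idx$mgt * idx$vc, idx$g6 / idx$n_sown, tolerance = 1e-12)
    }
  }
})

test_that("the conventional MGT denominator divides by germinated seeds", {
  dish <- make_dish()
  a <- germination_indices(dish)
  b <- germination_indices(dish, mgt_denominator = "germinated")
  expect_equal(a$mgt, b$mgt * a$g6 / a$n_sown, tolerance = 1e-12)
})

test_that("synchrony is maximal in one flush and drops when spread out", {
  one_flush <- germination_indices(make_dish(new_germ = c(0L, 30L, 0L, 0L)))
  expect_equal(one_flush$gsi, 1)
  moved <- germination_indices(make_dish(new_germ = c(1L, 29L, 0L, 0L)))
  expect_lt(moved$gsi, 1)
})

test_that("timing indices respond to the day axis as dimensional analysis demands", {
  dish <- make_dish()
  sched2 <- inspection_schedule(c(2, 4, 6, 12))
  dish2 <- dplyr::mutate(dish, day = day * 2)
  a <- germination_indices(dish)
  b <- germination_indices(dish2, sched2)
  expect_equal(b$mgt, 2 * a$mgt)           # equivariant
  expect_equal(b$vc, a$vc / 2)
  expect_equal(b$tg, a$tg)                 # invariant
  expect_equal(b$gsi, a$gsi)
})

test_that("stress tolerance index handles zeros, identity and scaling", {
  expect_equal(stress_tolerance_index(2, 1), 0.5)
  expect_equal(stress_tolerance_index(3, 3), 1)
  expect_true(is.na(stress_tolerance_index(0, 1)))
  expect_true(is.na(stress_tolerance_index(NA, 1)))
  # scale invariance
  expect_equal(stress_tolerance_index(2 * 7, 1 * 7),
               stress_tolerance_index(2, 1))
})

test_that("identical treatments give STI profiles of exactly one", {
  sim <- simulate_panel(small_config(), seed = 6)
  ctrl <- dplyr::filter(sim$counts, treatment_mM == 0)
  mirrored <- dplyr::bind_rows(ctrl, dplyr::mutate(ctrl, treatment_mM = 200))
  sti <- sti_profiles(mirrored)
  vals <- as.matrix(dplyr::select(sti, dplyr::starts_with("sti_")))
  expect_equal(unname(vals[!is.na(vals)]),
               rep(1, sum(!is.na(vals))), tolerance = 1e-12)
})

test_that("accessions missing a treatment are excluded with a message", {
  sim <- simulate_panel(small_config(), seed = 9)
  drop_one <- dplyr::filter(
    sim$counts, !(accession == "ACC001" & treatment_mM == 200)
  )
  expect_message(sti <- sti_profiles(drop_one), "ACC001")
  expect_false("ACC001" %in% sti$accession)
})

test_that("STI_TG recovers the viability multiplier on a large panel", {
  pars <- archetype_params(delta = 2, rho = 0.6, tau = 0)
  set.seed(14)
  counts <- purrr::map_dfr(1:20, function(d) {
    dplyr::bind_rows(
      simulate_dish(pars, 0, n_seeds = 150, replicate = paste0("r", d)),
      simulate_dish(pars, 200, n_seeds = 150, replicate = paste0("r", d))
    )
  })
  sti <- sti_profiles(counts)
  expect_equal(sti$sti_tg, 0.6, tolerance = 0.05)
})

test_that("seedling vigor follows the printed formula", {
  sl <- tibble::tibble(
    accession = "A", treatment_mM = 0, box = "b1", seedling = 1:2,
    shoot_mm = c(20, 40), main_root_mm = c(30, 50), lateral_root_mm = c(5, 15)
  )
  germ <- tibble::tibble(accession = "A", treatment_mM = 0,
                         germinability_pct = 90)
  v <- seedling_vigor(sl, germ)
  expect_equal(v$svi, 90 * (30 + 40 + 10))
  expect_equal(v$n_seedlings, 2L)

  germ0 <- dplyr::mutate(germ, germinability_pct = 0)
  expect_equal(seedling_vigor(sl, germ0)$svi, 0)

  expect_error(seedling_vigor(sl[0, ], germ), "No seedlings")
  expect_error(seedling_vigor(sl, germ[0, ]), "germinability")
})

test_that("identical control and salt boxes give STI_SVI of one", {
  sl <- tibble::tibble(
    accession = "A", treatment_mM = rep(c(0, 200), each = 3),
    box = rep(c("b1", "b2"), each = 3)[1:6], seedling = rep(1:3, 2),
    shoot_mm = 30, main_root_mm = 60, lateral_root_mm = 20
  )
  germ <- tibble::tibble(accession = "A", treatment_mM = c(0, 200),
                         germinability_pct = 95)
  sti <- seedling_sti(seedling_vigor(sl, germ))
  expect_equal(sti$sti_svi, 1)
  expect_equal(sti$sti_shoot, 1)
})
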