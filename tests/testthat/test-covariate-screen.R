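test_that("exposure classification follows the before/during/after/never rule", {
  ev1 <- tibble::tibble(start_day = 110, stop_day = 117)
  expect_equal(classify_exposure(100, ev1), "before")
  expect_equal(classify_exposure(113, ev1), "during")
  expect_equal(classify_exposure(120, ev1), "after")
  ev2 <- tibble::tibble(start_day = c(110, 150), stop_day = c(117, 157))
  expect_equal(classify_exposure(140, ev2), "after")
  expect_equal(classify_exposure(152, ev2), "during")
  expect_equal(classify_exposure(5, NULL), "never")
  expect_equal(classify_exposure(100,
    tibble::tibble(start_day = 90, stop_day = NA)), "during")  # open window
  expect_error(classify_exposure(1,
    tibble::tibble(start_day = c(10, 15), stop_day = c(20, 25))), "overlapping")
})

test_that("exposure_states covers every sample and covariate", {
  smp <- tibble::tibble(sample_id = c("a", "b"), subject_id = c("S1", "S2"),
                        age_days = c(100L, 200L))
  ev <- tibble::tibble(subject_id = "S1", covariate = "abx",
                       start_day = 150, stop_day = 160)
  es <- exposure_states(smp, ev)
  expect_equal(nrow(es), 2)
  expect_equal(es$exposure[es$sample_id == "a"], "before")
  expect_equal(es$exposure[es$sample_id == "b"], "never")  # S2 has no events
})

test_that("month windows partition 3-40 and keep first samples only", {
  w <- default_windows()
  covered <- unlist(purrr::map2(w$month_min, w$month_max, seq))
  expect_equal(sort(covered), 3:40)          # every month in exactly one window
  expect_equal(anyDuplicated(covered), 0)

  smp <- tibble::tibble(
    sample_id = paste0("s", 1:5), subject_id = "A",
    age_months = c(3L, 4L, 5L, 6L, 7L),
    age_days = as.integer(round(c(3.5, 4.5, 5.5, 6.5, 7.5) * 30.44)))
  first <- window_first_samples(smp)
  expect_equal(nrow(first), 2)               # month 3 (window 3-6), month 7 (7-10)
  expect_setequal(first$age_months, c(3L, 7L))
  out <- suppressMessages(window_first_samples(
    dplyr::mutate(smp, age_months = c(1L, 2L, 41L, 50L, 7L))))
  expect_equal(nrow(out), 1)
})

test_that("envfit r2 matches the direct sums-of-squares computation", {
  co <- rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0))
  res <- envfit_factor(co, c("A", "A", "B", "B"), n_permutations = 200, seed = 1)
  expect_equal(res$r2, 1 - 1 / 101, tolerance = 1e-12)
  expect_gte(res$p_value, 1 / 201)
})

test_that("envfit agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(8, {
    co <- matrix(rnorm(60), 30, 2)
    lab <- sample(c("x", "y", "z"), 30, replace = TRUE)
  })
  ours <- envfit_factor(co, lab, n_permutations = 499, seed = 1)
  ref <- vegan::envfit(co, data.frame(f = factor(lab)), permutations = 499)
  expect_equal(ours$r2, unname(ref$factors$r), tolerance = 1e-10)
})

test_that("envfit r2 is invariant to rotation and translation", {
  withr::with_seed(4, {
    co <- matrix(rnorm(40), 20, 2)
    lab <- rep(c("a", "b"), 10)
  })
  th <- 0.7
  rot <- co %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shifted <- sweep(rot, 2, c(5, -3), "+")
  expect_equal(envfit_factor(co, lab, 49, seed = 1)$r2,
               envfit_factor(shifted, lab, 49, seed = 1)$r2, tolerance = 1e-12)
})

test_that("envfit input contracts hold", {
  co <- matrix(rnorm(20), 10, 2)
  expect_error(envfit_factor(co, rep("a", 10)), "two factor levels")
  expect_warning(envfit_factor(co, c(rep("a", 5), rep("b", 4), "c"),
                               n_permutations = 9, seed = 1), "fewer than 2")
})

test_that("permutation p-values are uniform on the null", {
  # KS check over independent null replicates
  ps <- withr::with_seed(31, {
    vapply(1:200, function(r) {
      co <- matrix(rnorm(40), 20, 2)
      envfit_factor(co, rep(c("a", "b"), 10), n_permutations = 199,
                    seed = r)$p_value
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("BH adjustment matches the closed-form step-up", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("screening recovers the planted breastfeeding effect in early windows", {
  # ordination variance is cluster-dominated, so this screen needs
  # study-scale windows (several hundred children each)
  coh <- generate_cohort(cohort_config(n_subjects = 700, months = 3:11, seed = 12))
  scr <- suppressWarnings(suppressMessages(screen_covariates(
    coh$counts, coh$samples, coh$subjects, coh$events,
    covariates = c("breastfeeding", "delivery_mode", "sex", "siblings",
                   "furry_pets", "season_of_birth", "household_smoking"),
    windows = tibble::tibble(window = c("3-6", "7-10"),
                             month_min = c(3, 7), month_max = c(6, 10)),
    n_permutations = 499, seed = 5)))
  bf <- scr |> dplyr::filter(covariate == "breastfeeding",
                             window %in% c("3-6", "7-10"))
  expect_true(all(bf$significant))
  expect_true(all(scr$q_value >= scr$p_value - 1e-12))
})
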