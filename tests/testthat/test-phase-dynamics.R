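mk_samples <- function(subject, months) {
  tibble::tibble(
    sample_id = sprintf("%s_m%02d", subject, months),
    subject_id = subject,
    age_days = as.integer(round((months + 0.5) * 30.44)),
    age_months = as.integer(months)
  )
}

test_that("transition graph counts consecutive-sample edges", {
  smp <- mk_samples("A", c(3, 4, 5))
  asg <- tibble::tibble(sample_id = smp$sample_id, cluster = c(1L, 1L, 3L))
  g <- build_transition_graph(asg, smp)
  expect_equal(nrow(g$edges), 2)
  e <- dplyr::arrange(g$edges, from_month)
  expect_equal(e$from_cluster, c(1L, 1L))
  expect_equal(e$to_cluster, c(1L, 3L))
  expect_equal(e$n, c(1L, 1L))
  expect_equal(formals(build_transition_graph)$min_frequency, 0.04)
})

test_that("edges span sampling gaps and frequencies stay conserved", {
  smp <- dplyr::bind_rows(mk_samples("A", c(3, 4, 7)), mk_samples("B", c(3, 4)))
  asg <- tibble::tibble(sample_id = smp$sample_id,
                        cluster = c(1L, 2L, 2L, 1L, 1L))
  g <- build_transition_graph(asg, smp)
  # outgoing frequency from each node sums to <= 1
  out <- g$edges |>
    dplyr::group_by(from_month, from_cluster) |>
    dplyr::summarise(f = sum(frequency), .groups = "drop")
  expect_true(all(out$f <= 1 + 1e-12))
  # node counts per month equal samples per month
  expect_equal(sum(g$nodes$n[g$nodes$month == 3]), 2L)
  # A's gap 4 -> 7 still yields one edge
  expect_true(any(g$edges$from_month == 4 & g$edges$to_month == 7))
})

test_that("low-frequency edges are flagged hidden, not dropped", {
  smp <- dplyr::bind_rows(purrr::map(1:30, ~ mk_samples(paste0("S", .x), c(3, 4))))
  cl <- rep(1L, nrow(smp))
  cl[smp$age_months == 4] <- c(2L, rep(1L, 29))  # one rare transition, 1/30
  g <- build_transition_graph(tibble::tibble(sample_id = smp$sample_id, cluster = cl), smp)
  rare <- g$edges |> dplyr::filter(to_cluster == 2L)
  expect_true(rare$hidden)
  expect_equal(rare$frequency, 1 / 30)
  expect_error(
    build_transition_graph(
      tibble::tibble(sample_id = c("A_m03", "x"), cluster = c(1L, 1L)),
      dplyr::bind_rows(mk_samples("A", 3),
                       tibble::tibble(sample_id = "x", subject_id = "A",
                                      age_days = mk_samples("A", 3)$age_days,
                                      age_months = 3L))),
    "duplicate")
})

test_that("stability metrics count unique states and transitions", {
  run <- function(cl) {
    smp <- mk_samples("A", seq(3, length.out = length(cl)))
    stability_metrics(tibble::tibble(sample_id = smp$sample_id, cluster = cl), smp)
  }
  expect_equal(unlist(run(c(1L, 1L, 3L, 3L, 8L))[1, c("n_unique_states", "n_transitions")]),
               c(n_unique_states = 3L, n_transitions = 2L))
  expect_equal(unlist(run(2L)[1, c("n_unique_states", "n_transitions")]),
               c(n_unique_states = 1L, n_transitions = 0L))
  expect_equal(unlist(run(c(1L, 2L, 1L, 2L))[1, c("n_unique_states", "n_transitions")]),
               c(n_unique_states = 2L, n_transitions = 3L))
})

test_that("stability metric bounds hold on random trajectories", {
  withr::with_seed(3, {
    for (i in 1:20) {
      n <- sample(1:12, 1)
      cl <- sample.int(5, n, replace = TRUE)
      smp <- mk_samples("A", seq(3, length.out = n))
      res <- stability_metrics(tibble::tibble(sample_id = smp$sample_id,
                                              cluster = cl), smp)
      expect_lte(res$n_transitions, n - 1 + (n == 1))
      expect_lte(res$n_unique_states, n)
    }
  })
  expect_error(stability_metrics(
    tibble::tibble(sample_id = "A_m03", cluster = 1L),
    mk_samples("A", 3), window = c(1000, 2000)), "window")
})

test_that("a constant response has zero slope and is not significant", {
  dat <- tidyr::expand_grid(subject_id = paste0("S", 1:6), age_months = 3:14) |>
    dplyr::mutate(sample_id = paste(subject_id, age_months), flat = 1.0)
  rep <- phase_slope_test(dat, "flat",
                          phases = tibble::tibble(phase = "developmental",
                                                  month_min = 3, month_max = 14))
  expect_equal(rep$slope, 0)
  expect_false(rep$significant)
})

test_that("planted slopes are detected and null slopes calibrate", {
  # power: slope 0.02/month, residual sd 0.02, 40 subjects x 12 months
  detect <- withr::with_seed(17, {
    vapply(1:30, function(r) {
      dat <- tidyr::expand_grid(subject_id = paste0("S", 1:40), age_months = 3:14) |>
        dplyr::mutate(y = 0.02 * age_months + rnorm(dplyr::n(), 0, 0.02) +
                        rep(rnorm(40, 0, 0.01), each = 12))
      rep <- phase_slope_test(dat, "y",
                              phases = tibble::tibble(phase = "p", month_min = 3,
                                                      month_max = 14))
      rep$significant
    }, logical(1))
  })
  expect_gte(mean(detect), 0.95)

  # type-I: null slope, same design, 200 replicates
  rej <- withr::with_seed(23, {
    vapply(1:200, function(r) {
      dat <- tidyr::expand_grid(subject_id = paste0("S", 1:40), age_months = 3:14) |>
        dplyr::mutate(y = rnorm(dplyr::n(), 0, 0.02) +
                        rep(rnorm(40, 0, 0.01), each = 12))
      phase_slope_test(dat, "y",
                       phases = tibble::tibble(phase = "p", month_min = 3,
                                               month_max = 14))$significant
    }, logical(1))
  })
  expect_lt(abs(mean(rej) - 0.05), 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("phase labels follow the all/none/some significance rule", {
  mk <- function(sig) {
    tibble::tibble(phase = "w", response = paste0("r", seq_along(sig)),
                   slope = 0, se = 1, p_value = ifelse(sig, 0.001, 0.5),
                   significant = sig, n = 10, n_subjects = 5)
  }
  expect_equal(classify_phases(mk(rep(TRUE, 6)))$label, "developmental-like")
  expect_equal(classify_phases(mk(rep(FALSE, 6)))$label, "stable-like")
  expect_equal(classify_phases(mk(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))$label,
               "transitional-like")
})

test_that("degenerate phases are rejected", {
  dat <- tibble::tibble(subject_id = c("A", "B"), age_months = c(5, 5), y = c(1, 2))
  expect_error(phase_slope_test(dat, "y",
                                phases = tibble::tibble(phase = "p", month_min = 3,
                                                        month_max = 14)),
               "distinct ages")
})
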