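# Community-state transition structure over age, per-subject stability
# summaries, and developmental-phase slope tests.

#' Build the cluster-transition graph over month bins
#'
#' Nodes are (month, cluster) pairs with sample counts; edges connect the
#' consecutive samples of each subject (monthly sampling has gaps, so edges
#' may span more than one month bin). Edge frequency is the transition count
#' divided by the count of the origin node, computed before any filtering;
#' edges below `min_frequency` are retained but flagged `hidden` (the
#' conventional display rule hides transitions under 4% frequency).
#'
#' @param assignments Tibble `sample_id`, `cluster` (from
#'   [assign_clusters()]).
#' @param samples Sample records (`sample_id`, `subject_id`, `age_months`,
#'   `age_days`).
#' @param min_frequency Display threshold on edge frequency (default 0.04).
#' @return A list of class `gd_transitions`: `nodes` (`month`, `cluster`,
#'   `n`), `edges` (`from_month`, `from_cluster`, `to_month`, `to_cluster`,
#'   `n`, `frequency`, `hidden`), `min_frequency`.
#' @export
build_transition_graph <- function(assignments, samples, min_frequency = 0.04) {
  dat <- samples |>
    inner_join(assignments, by = "sample_id") |>
    arrange(.data$subject_id, .data$age_days)
  dup <- dat |>
    dplyr::count(.data$subject_id, .data$age_days) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("subject with duplicate sample ages: ", dup$subject_id[1]))
  }
  nodes <- dat |>
    dplyr::count(month = .data$age_months, cluster = .data$cluster, name = "n")
  edges <- dat |>
    group_by(.data$subject_id) |>
    mutate(to_month = dplyr::lead(.data$age_months),
           to_cluster = dplyr::lead(.data$cluster)) |>
    ungroup() |>
    filter(!is.na(.data$to_month)) |>
    dplyr::count(from_month = .data$age_months, from_cluster = .data$cluster,
                 to_month = .data$to_month, to_cluster = .data$to_cluster,
                 name = "n") |>
    left_join(nodes |> rename(from_n = "n"),
              by = c(from_month = "month", from_cluster = "cluster")) |>
    mutate(frequency = .data$n / .data$from_n,
           hidden = .data$frequency < min_frequency) |>
    select(-"from_n")
  structure(list(nodes = nodes, edges = edges, min_frequency = min_frequency),
            class = "gd_transitions")
}

#' @export
print.gd_transitions <- function(x, ...) {
  cat(sprintf("community-state transition graph: %d nodes, %d edges (%d shown at >= %.0f%% frequency)\n",
              nrow(x$nodes), nrow(x$edges), sum(!x$edges$hidden),
              100 * x$min_frequency))
  invisible(x)
}

#' Per-subject community stability metrics
#'
#' For each subject (optionally restricted to a day-of-life window): the
#' number of unique community states exhibited and the number of temporal
#' transitions between different states across consecutive samples.
#'
#' @param assignments Tibble `sample_id`, `cluster`.
#' @param samples Sample records (`sample_id`, `subject_id`, `age_days`).
#' @param window Optional numeric `c(min_day, max_day)`; samples with
#'   `min_day <= age_days < max_day` are kept.
#' @return Tibble: `subject_id`, `n_samples`, `n_unique_states`,
#'   `n_transitions`.
#' @export
stability_metrics <- function(assignments, samples, window = NULL) {
  dat <- samples |>
    inner_join(assignments, by = "sample_id") |>
    arrange(.data$subject_id, .data$age_days)
  if (!is.null(window)) {
    dat <- dat |> filter(.data$age_days >= window[1], .data$age_days < window[2])
  }
  if (nrow(dat) == 0) abort("no samples in window")
  dat |>
    group_by(.data$subject_id) |>
    summarise(
      n_samples = n(),
      n_unique_states = dplyr::n_distinct(.data$cluster),
      n_transitions = sum(diff(.data$cluster) != 0),
      .groups = "drop"
    )
}

#' Default developmental-phase windows (months)
#' @return Tibble `phase`, `month_min`, `month_max`.
#' @export
default_phases <- function() {
  tibble(phase = c("developmental", "transitional", "stable"),
         month_min = c(3, 15, 31), month_max = c(14, 30, 46))
}

#' Per-phase slope tests on phylum abundances and diversity
#'
#' Within each phase window, each response is regressed on age in months by
#' ordinary least squares with subject-clustered (CR) standard errors, the
#' longitudinal-data analogue of a random-intercept model for testing a
#' population-average slope. Two-sided p-values use a t reference with
#' degrees of freedom `n_subjects - 1`. The canonical responses are the
#' relative abundances of the top five phyla plus Shannon's diversity, built
#' with [phase_responses()].
#'
#' @param data Tibble with `subject_id`, `age_months`, and the response
#'   columns.
#' @param responses Character vector of response column names.
#' @param phases Phase window tibble (default [default_phases()]).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Multiplicity correction across responses within a phase
#'   (default `"none"`, reporting per-response significance; `"BH"`
#'   available).
#' @return A `gd_phase_report`: tibble with `phase`, `response`, `slope`,
#'   `se`, `p_value`, `significant`, `n`, `n_subjects`.
#' @export
phase_slope_test <- function(data, responses, phases = default_phases(),
                             alpha = 0.05, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  out <- purrr::map_dfr(seq_len(nrow(phases)), function(i) {
    ph <- phases[i, ]
    dat <- data |>
      filter(.data$age_months >= ph$month_min, .data$age_months <= ph$month_max)
    if (dplyr::n_distinct(dat$subject_id) < 2 ||
        dplyr::n_distinct(dat$age_months) < 3) {
      abort(paste0("phase ", ph$phase,
                   " needs >= 2 subjects and >= 3 distinct ages"))
    }
    purrr::map_dfr(responses, function(rv) {
      y <- dat[[rv]]
      if (var(y) == 0) {
        return(tibble(phase = ph$phase, response = rv, slope = 0, se = NA_real_,
                      p_value = 1, n = nrow(dat),
                      n_subjects = dplyr::n_distinct(dat$subject_id)))
      }
      fit <- lm(y ~ age_months, data = dat)
      vc <- sandwich::vcovCL(fit, cluster = dat$subject_id)
      b <- coef(fit)[["age_months"]]
      se <- sqrt(vc["age_months", "age_months"])
      df <- dplyr::n_distinct(dat$subject_id) - 1
      tibble(phase = ph$phase, response = rv, slope = b, se = se,
             p_value = 2 * pt(abs(b / se), df, lower.tail = FALSE),
             n = nrow(dat), n_subjects = df + 1)
    })
  })
  if (p_adjust == "BH") {
    out <- out |>
      group_by(.data$phase) |>
      mutate(p_value = p.adjust(.data$p_value, "BH")) |>
      ungroup()
  }
  out <- out |> mutate(significant = .data$p_value < alpha)
  class(out) <- c("gd_phase_report", class(out))
  out
}

#' Build the canonical phase-test responses
#'
#' Joins per-sample relative abundances of the `n_phyla` most abundant phyla
#' with Shannon's diversity and sample metadata, ready for
#' [phase_slope_test()].
#'
#' @param counts Wide (genus-level) count tibble.
#' @param samples Sample records.
#' @param taxonomy Taxonomy tibble mapping features to phyla.
#' @param n_phyla Number of top phyla (default 5).
#' @return Tibble: `sample_id`, `subject_id`, `age_months`, one column per
#'   phylum (relative abundance), `shannon`.
#' @export
phase_responses <- function(counts, samples, taxonomy, n_phyla = 5) {
  phyl <- collapse_taxonomy(counts, taxonomy, rank = "phylum")
  rel <- relative_abundance(phyl)
  top <- names(sort(colSums(count_matrix(phyl)), decreasing = TRUE))[seq_len(n_phyla)]
  div <- alpha_diversity(counts)
  rel |>
    select(dplyr::all_of(c("sample_id", top))) |>
    left_join(div |> select("sample_id", "shannon"), by = "sample_id") |>
    inner_join(samples |> select("sample_id", "subject_id", "age_months"),
               by = "sample_id")
}

#' Label phases from a slope report
#'
#' A phase is `"developmental-like"` when every response changes
#' significantly with age, `"stable-like"` when none does, and
#' `"transitional-like"` otherwise.
#'
#' @param report A `gd_phase_report` from [phase_slope_test()].
#' @return Tibble: `phase`, `n_significant`, `n_responses`, `label`.
#' @export
classify_phases <- function(report) {
  report |>
    as_tibble() |>
    group_by(.data$phase) |>
    summarise(n_significant = sum(.data$significant),
              n_responses = n(), .groups = "drop") |>
    mutate(label = dplyr::case_when(
      .data$n_significant == .data$n_responses ~ "developmental-like",
      .data$n_significant == 0 ~ "stable-like",
      TRUE ~ "transitional-like"
    ))
}
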