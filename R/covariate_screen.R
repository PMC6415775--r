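# Dynamic-covariate exposure classification, time-window sample selection,
# and permutation screening of covariates on ordinations.

#' Classify a sample's exposure state for one dynamic covariate
#'
#' Relative to a subject's event windows for a covariate, a sample collected
#' on `sample_day` is `"never"` when the subject has no events, `"before"`
#' when it precedes the first event, `"during"` when it falls inside an
#' event window (open-ended windows stay `"during"` from their start on),
#' and `"after"` otherwise.
#'
#' @param sample_day Integer day of life of the sample.
#' @param events Tibble (or data frame) with `start_day` and `stop_day`
#'   columns (`stop_day` `NA` = open); rows must be ordered and
#'   non-overlapping.
#' @return One of `"before"`, `"during"`, `"after"`, `"never"`.
#' @export
classify_exposure <- function(sample_day, events) {
  if (is.null(events) || nrow(events) == 0) return("never")
  ev <- events |> arrange(.data$start_day)
  stops <- ifelse(is.na(ev$stop_day), Inf, ev$stop_day)
  if (any(ev$start_day > stops)) abort("event with start after stop")
  if (nrow(ev) > 1 && any(ev$start_day[-1] <= stops[-nrow(ev)])) {
    abort("overlapping event windows")
  }
  if (sample_day < ev$start_day[1]) return("before")
  if (any(sample_day >= ev$start_day & sample_day <= stops)) return("during")
  "after"
}

#' Exposure states of every sample for every dynamic covariate
#'
#' @param samples Sample-record tibble (`sample_id`, `subject_id`,
#'   `age_days`).
#' @param events Long event tibble (`subject_id`, `covariate`, `start_day`,
#'   `stop_day`).
#' @param covariates Covariates to classify (default: all in `events`).
#' @return Long tibble: `sample_id`, `covariate`, `exposure`.
#' @export
exposure_states <- function(samples, events, covariates = unique(events$covariate)) {
  ev_by <- events |>
    filter(.data$covariate %in% covariates) |>
    select("subject_id", "covariate", "start_day", "stop_day") |>
    tidyr::nest(ev = c("start_day", "stop_day"))
  grid <- tidyr::expand_grid(
    samples |> select("sample_id", "subject_id", "age_days"),
    covariate = covariates
  ) |>
    left_join(ev_by, by = c("subject_id", "covariate"))
  grid$exposure <- purrr::map2_chr(grid$age_days, grid$ev, function(day, ev) {
    if (is.null(ev)) "never" else classify_exposure(day, ev)
  })
  grid |> select("sample_id", "covariate", "exposure")
}

#' Default screening windows in months
#'
#' Closed integer-month windows partitioning months 3-40; within each
#' window only a child's first sample is analysed, removing repeated
#' measures.
#'
#' @return Tibble with `window`, `month_min`, `month_max`.
#' @export
default_windows <- function() {
  lo <- c(3, 7, 11, 15, 19, 23, 27, 31)
  hi <- c(6, 10, 14, 18, 22, 26, 30, 40)
  tibble(window = sprintf("%d-%d", lo, hi), month_min = lo, month_max = hi)
}

#' First sample per subject within each month window
#'
#' @param samples Sample-record tibble with `subject_id`, `age_months`,
#'   `age_days`.
#' @param windows Window tibble as [default_windows()].
#' @return `samples` with a `window` column, one (earliest) row per subject
#'   per window; samples outside all windows are dropped (their count is
#'   reported via a message).
#' @export
window_first_samples <- function(samples, windows = default_windows()) {
  lab <- rep(NA_character_, nrow(samples))
  for (i in seq_len(nrow(windows))) {
    inw <- samples$age_months >= windows$month_min[i] &
      samples$age_months <= windows$month_max[i]
    lab[inw] <- windows$window[i]
  }
  dropped <- sum(is.na(lab))
  if (dropped > 0) inform(sprintf("%d sample(s) outside all windows; excluded", dropped))
  samples |>
    mutate(window = lab) |>
    filter(!is.na(.data$window)) |>
    group_by(.data$window, .data$subject_id) |>
    arrange(.data$age_days, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Fit a factor onto an ordination with permutation significance
#'
#' The fraction of coordinate variance explained by group centroids,
#' `r2 = 1 - SS_within / SS_total` (sums of squares about group centroids
#' versus the grand centroid), with a permutation p-value
#' `(#{permuted r2 >= observed} + 1) / (n_permutations + 1)` from seeded
#' label shuffles. Levels with fewer than 2 samples are dropped with a
#' warning.
#'
#' @param coords Numeric matrix or tibble of ordination coordinates
#'   (samples x axes; a `gd_ordination` is also accepted).
#' @param labels Factor (or character) of group labels, one per sample.
#' @param n_permutations Number of label permutations (default 999;
#'   10,000 is typical for final screens).
#' @param seed Integer seed for the shuffles.
#' @return Tibble: `r2`, `p_value`, `n`, `n_levels`, `n_permutations`.
#' @export
envfit_factor <- function(coords, labels, n_permutations = 999, seed = 1) {
  if (inherits(coords, "gd_ordination")) {
    coords <- coords$coordinates[, -1, drop = FALSE]
  }
  Y <- as.matrix(coords)
  storage.mode(Y) <- "double"
  labels <- as.character(labels)
  if (length(labels) != nrow(Y)) abort("one label per sample required")
  keep_lv <- names(which(table(labels) >= 2))
  if (length(unique(labels)) < 2) abort("need at least two factor levels")
  if (length(keep_lv) < length(unique(labels))) {
    warn("dropping factor level(s) with fewer than 2 samples")
  }
  keep <- labels %in% keep_lv
  Y <- Y[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(keep_lv) < 2) abort("need at least two factor levels with >= 2 samples")

  Yc <- scale(Y, scale = FALSE)
  ss_total <- sum(Yc^2)
  r2_of <- function(lab) {
    G <- rowsum(Yc, lab)
    cnt <- as.vector(table(lab)[rownames(G)])
    1 - (ss_total - sum(G^2 / cnt)) / ss_total
  }
  obs <- r2_of(labels)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) r2_of(sample(labels)), numeric(1))
  })
  p <- (sum(perm >= obs) + 1) / (n_permutations + 1)
  tibble(r2 = obs, p_value = p, n = length(labels),
         n_levels = length(keep_lv), n_permutations = n_permutations)
}

#' Screen covariates on per-window ordinations
#'
#' For each time window: keep each child's first sample, compute Bray-Curtis
#' dissimilarities and an NMDS ordination, classify exposure states of
#' dynamic covariates at the sample's day of life, and fit every covariate
#' onto the ordination with [envfit_factor()]. P-values are
#' Benjamini-Hochberg adjusted across the covariate set within each window;
#' `significant` flags `q_value < 0.05`.
#'
#' @param counts Wide count tibble (rarefied).
#' @param samples Sample records (`sample_id`, `subject_id`, `age_days`,
#'   `age_months`).
#' @param subjects Subject records with static covariate columns.
#' @param events Dynamic covariate event windows (long tibble).
#' @param covariates Character vector of covariates to screen; names
#'   matching `events$covariate` are classified into exposure states, the
#'   rest must be `subjects` columns.
#' @param windows Window tibble (default [default_windows()]).
#' @param n_permutations Permutations per envfit (default 999).
#' @param seed Integer seed.
#' @param q_threshold FDR significance threshold (default 0.05).
#' @return Tibble: `window`, `covariate`, `r2`, `p_value`, `q_value`,
#'   `significant`, `n`, `n_levels`, plus a `skipped` attribute listing
#'   covariates constant within a window.
#' @export
screen_covariates <- function(counts, samples, subjects, events,
                              covariates = covariate_catalogue()$covariate,
                              windows = default_windows(),
                              n_permutations = 999, seed = 1,
                              q_threshold = 0.05) {
  firsts <- window_first_samples(samples, windows)
  dyn <- intersect(covariates, unique(events$covariate))
  stat <- setdiff(covariates, dyn)
  missing_static <- setdiff(stat, names(subjects))
  if (length(missing_static)) {
    abort(paste0("covariate(s) not in subjects: ",
                 paste(missing_static, collapse = ", ")))
  }
  skipped <- list()
  out <- purrr::map_dfr(unique(firsts$window), function(w) {
    smp <- firsts |> filter(.data$window == w)
    if (nrow(smp) < 5) return(NULL)
    sub_counts <- counts |> filter(.data$sample_id %in% smp$sample_id)
    sub_counts <- sub_counts[match(smp$sample_id, sub_counts$sample_id), ]
    ord <- nmds_ordination(bray_curtis(sub_counts), seed = seed)
    expo <- if (length(dyn)) {
      exposure_states(smp, events, dyn) |>
        tidyr::pivot_wider(names_from = "covariate", values_from = "exposure")
    } else smp["sample_id"]
    meta <- smp |>
      left_join(expo, by = "sample_id") |>
      left_join(subjects |> select(dplyr::all_of(c("subject_id", stat))),
                by = "subject_id")
    purrr::map_dfr(covariates, function(cv) {
      lab <- as.character(meta[[cv]])
      if (length(unique(lab)) < 2) {
        skipped[[length(skipped) + 1]] <<- tibble(window = w, covariate = cv)
        return(NULL)
      }
      res <- tryCatch(
        suppressWarnings(envfit_factor(ord, lab, n_permutations,
                                       seed = seed + sum(utf8ToInt(cv)))),
        error = function(e) NULL
      )
      if (is.null(res)) {
        skipped[[length(skipped) + 1]] <<- tibble(window = w, covariate = cv)
        return(NULL)
      }
      res |> mutate(window = w, covariate = cv, .before = 1)
    })
  })
  out <- out |>
    group_by(.data$window) |>
    mutate(q_value = p.adjust(.data$p_value, "BH"),
           significant = .data$q_value < q_threshold) |>
    ungroup()
  attr(out, "skipped") <- bind_rows(skipped)
  out
}
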