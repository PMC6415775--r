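# Microbiota-age regression forest and microbiota-for-age Z (MAZ) scoring.
#
# A random-forest regression of chronological age on relative abundances is
# trained on a healthy reference subset (full-term, vaginally delivered,
# breastfed children with enough longitudinal samples). Cross-validated
# recursive feature halving picks a compact taxon panel; the model's
# prediction for a new sample is its "microbiota age", standardised per
# month bin against the reference cohort to give MAZ.

#' Select the healthy reference subjects
#'
#' Eligible children are full term (> 37 weeks gestation), vaginally
#' delivered, breastfed, and have at least `min_samples` samples; a seeded
#' random draw of at most `n` of them forms the reference.
#'
#' @param subjects Subject records with `gestational_weeks`,
#'   `delivery_mode`, `breastfed`.
#' @param samples Sample records (used for per-subject sample counts).
#' @param n Reference size cap (default 150).
#' @param min_samples Minimum samples per subject (default 10).
#' @param seed Integer seed for the draw.
#' @return Character vector of reference subject ids.
#' @export
select_reference <- function(subjects, samples, n = 150, min_samples = 10,
                             seed = 1) {
  counts <- samples |> dplyr::count(.data$subject_id, name = "n_samples")
  elig <- subjects |>
    left_join(counts, by = "subject_id") |>
    filter(.data$gestational_weeks > 37,
           .data$delivery_mode == "vaginal",
           .data$breastfed,
           !is.na(.data$n_samples), .data$n_samples >= min_samples)
  if (nrow(elig) == 0) abort("no eligible reference subjects")
  withr::with_seed(seed, sample(elig$subject_id, min(n, nrow(elig))))
}

# Subject-blocked fold assignment: every subject's samples share a fold.
subject_folds <- function(subject_ids, k, seed) {
  subj <- unique(subject_ids)
  if (k > length(subj)) abort("more folds than subjects")
  fold_of <- withr::with_seed(seed, {
    setNames(sample(rep_len(seq_len(k), length(subj))), subj)
  })
  unname(fold_of[subject_ids])
}

#' Train the microbiota-age model
#'
#' Fits a regression forest of age in months on relative abundances over
#' the reference samples, then performs recursive feature halving: features
#' are ranked by permutation importance, cross-validated mean squared error
#' is evaluated at feature counts n, n/2, n/4, ... with folds split by
#' subject (never within), and the count minimising CV MSE (ties toward
#' fewer features) defines the final panel. The forest is retrained on that
#' panel, and per-month-bin reference statistics (median and SD of predicted
#' microbiota age) are stored for MAZ scoring. The conventional full-scale
#' configuration is 10,000 trees with n/3 features per split; `n_trees`
#' defaults lower for desk-scale runs, with `cv_trees` lighter still during
#' the halving search.
#'
#' @param counts Wide count tibble (reference + any other samples).
#' @param samples Sample records with `age_months`.
#' @param reference_subjects Ids from [select_reference()].
#' @param n_trees Trees of the final forest (default 500).
#' @param cv_trees Trees per CV fit during feature selection (default 150).
#' @param cv_folds Cross-validation folds, split by subject (default 10).
#' @param seed Integer seed.
#' @return A `gd_maturity` model: `selected_features`, `forest`,
#'   `reference_stats` (per month bin median/SD of reference microbiota
#'   age), `cv_error_curve`, `config`.
#' @export
train_maturity <- function(counts, samples, reference_subjects,
                           n_trees = 500, cv_trees = 150, cv_folds = 10,
                           seed = 1) {
  smp <- samples |> filter(.data$subject_id %in% reference_subjects)
  if (nrow(smp) == 0) abort("no reference samples")
  rel <- relative_abundance(counts |> filter(.data$sample_id %in% smp$sample_id))
  rel <- rel[match(smp$sample_id, rel$sample_id), ]
  X <- count_matrix(rel)
  y <- smp$age_months
  if (ncol(X) < 2) abort("need at least two features")
  folds <- subject_folds(smp$subject_id, cv_folds, seed)

  full <- withr::with_seed(seed, randomForest::randomForest(
    x = X, y = y, ntree = n_trees, mtry = max(1, floor(ncol(X) / 3)),
    importance = TRUE))
  imp <- randomForest::importance(full, type = 1)[, 1]
  ranked <- names(sort(imp, decreasing = TRUE))

  sizes <- ncol(X)
  while (sizes[length(sizes)] > 2) {
    sizes <- c(sizes, max(2, floor(sizes[length(sizes)] / 2)))
  }
  cv_curve <- purrr::map_dfr(sizes, function(m) {
    feats <- ranked[seq_len(m)]
    err <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      fit <- withr::with_seed(seed + f, randomForest::randomForest(
        x = X[tr, feats, drop = FALSE], y = y[tr], ntree = cv_trees,
        mtry = max(1, floor(m / 3))))
      mean((predict(fit, X[!tr, feats, drop = FALSE]) - y[!tr])^2)
    }, numeric(1))
    tibble(n_features = m, cv_mse = mean(err))
  })
  best_m <- cv_curve |>
    filter(.data$cv_mse == min(.data$cv_mse)) |>
    pull("n_features") |>
    min()
  selected <- ranked[seq_len(best_m)]

  forest <- withr::with_seed(seed, randomForest::randomForest(
    x = X[, selected, drop = FALSE], y = y, ntree = n_trees,
    mtry = max(1, floor(best_m / 3))))
  pred_ref <- predict(forest, X[, selected, drop = FALSE])
  ref_stats <- tibble(month = smp$age_months, pred = pred_ref) |>
    group_by(.data$month) |>
    summarise(median_age = median(.data$pred), sd_age = sd(.data$pred),
              n = n(), .groups = "drop")

  structure(
    list(
      selected_features = selected,
      forest = forest,
      reference_stats = ref_stats,
      cv_error_curve = cv_curve,
      reference_subjects = reference_subjects,
      config = list(n_trees = n_trees, cv_trees = cv_trees,
                    cv_folds = cv_folds, mtry_rule = "n/3", seed = seed)
    ),
    class = "gd_maturity"
  )
}

#' @export
print.gd_maturity <- function(x, ...) {
  cat(sprintf("microbiota-age model: %d selected features, %d trees, %d reference subjects\n",
              length(x$selected_features), x$config$n_trees,
              length(x$reference_subjects)))
  invisible(x)
}

#' Predict microbiota age
#'
#' Forest prediction of age in months from a sample's relative abundances.
#' Model features missing from the input are imputed as zero (absence in a
#' rarefied profile) with a warning.
#'
#' @param model A `gd_maturity` model.
#' @param counts Wide count tibble.
#' @return Tibble: `sample_id`, `microbiota_age` (months).
#' @export
microbiota_age <- function(model, counts) {
  m <- count_matrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warn("all-zero sample(s); predicting from an all-zero profile")
    tot[tot == 0] <- 1
  }
  rel <- m / tot
  missing <- setdiff(model$selected_features, colnames(rel))
  if (length(missing)) {
    warn(sprintf("%d model feature(s) missing from input; imputed as 0",
                 length(missing)))
    rel <- cbind(rel, matrix(0, nrow(rel), length(missing),
                             dimnames = list(NULL, missing)))
  }
  tibble(sample_id = rownames(m),
         microbiota_age = unname(predict(model$forest,
                                         rel[, model$selected_features,
                                             drop = FALSE])))
}

#' Microbiota-for-age Z-score (MAZ)
#'
#' `MAZ = (microbiota age - median reference microbiota age at that month) /
#' SD of reference microbiota age at that month`. Months absent from the
#' reference statistics fall back to the nearest available bin with a
#' warning; a zero reference SD is an error for that bin.
#'
#' @param model A `gd_maturity` model.
#' @param counts Wide count tibble.
#' @param samples Sample records with `age_months` for the scored samples.
#' @return Tibble: `sample_id`, `age_months`, `microbiota_age`, `maz`.
#' @export
maz_score <- function(model, counts, samples) {
  ma <- microbiota_age(model, counts)
  dat <- ma |>
    inner_join(samples |> select("sample_id", "age_months"), by = "sample_id")
  rs <- model$reference_stats
  idx <- vapply(dat$age_months, function(mo) {
    which.min(abs(rs$month - mo))
  }, integer(1))
  if (any(rs$month[idx] != dat$age_months)) {
    warn("some months absent from reference stats; nearest bin used")
  }
  sd_ref <- rs$sd_age[idx]
  if (any(!is.na(sd_ref) & sd_ref == 0)) abort("zero reference SD in a month bin")
  dat |>
    mutate(maz = (.data$microbiota_age - rs$median_age[idx]) / sd_ref) |>
    select("sample_id", "age_months", "microbiota_age", "maz")
}
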