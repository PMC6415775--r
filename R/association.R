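# Per-feature covariate association on variance-stabilised relative
# abundances (multivariate linear modelling in the MaAsLin tradition,
# reduced to fixed effects for one-sample-per-child windowed designs).

#' Arcsine square-root transform
#'
#' The variance-stabilising transform for proportions,
#' `asin(sqrt(p))`, with range `[0, pi/2]`. Values outside `[0, 1]` by more
#' than 1e-12 are an error; smaller excursions are clamped.
#'
#' @param p Numeric vector of proportions.
#' @return Transformed values.
#' @export
arcsin_sqrt <- function(p) {
  if (any(p < -1e-12 | p > 1 + 1e-12)) abort("proportions must lie in [0, 1]")
  asin(sqrt(pmin(pmax(p, 0), 1)))
}

#' Per-feature linear models of a target covariate
#'
#' For every feature passing the abundance filter, fits an ordinary linear
#' model of the arcsine-square-root-transformed relative abundance on the
#' target covariate plus adjustment covariates, and reports the target's
#' coefficient(s) with BH-adjusted p-values across features. Defaults follow
#' the conventional multivariate microbiome screen: features below 0.01%
#' mean relative abundance are excluded, covariates with more than 10%
#' missing values are dropped from the adjustment set, and associations
#' with `q < 0.25` are flagged. The input is expected to hold one sample
#' per subject (e.g. from [window_first_samples()]), so fixed-effect models
#' apply.
#'
#' @param counts Wide count tibble (rarefied).
#' @param metadata Tibble with `sample_id`, the target column and adjuster
#'   columns.
#' @param target Name of the covariate of interest.
#' @param adjusters Character vector of adjustment covariate names
#'   (age and outcome status belong here in the windowed design).
#' @param min_mean_abundance Minimum mean relative abundance (default 1e-4,
#'   i.e. 0.01%).
#' @param max_meta_na Maximum fraction of missing metadata per covariate
#'   (default 0.10).
#' @param q_threshold Reporting threshold on the BH q-value (default 0.25).
#' @return Tibble: `feature_id`, `term`, `estimate`, `std_error`,
#'   `p_value`, `q_value`, `significant`, `n`, `direction`.
#' @export
fit_feature_models <- function(counts, metadata, target, adjusters = character(),
                               min_mean_abundance = 1e-4, max_meta_na = 0.10,
                               q_threshold = 0.25) {
  rel <- relative_abundance(counts)
  meta <- metadata[match(rel$sample_id, metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) abort("metadata missing for some samples")
  if (!target %in% names(meta)) abort(paste0("target '", target, "' not in metadata"))

  # drop adjusters with too much missingness
  keep_adj <- adjusters[vapply(adjusters, function(a) {
    mean(is.na(meta[[a]])) <= max_meta_na
  }, logical(1))]
  dropped <- setdiff(adjusters, keep_adj)
  if (length(dropped)) {
    inform(paste0("adjuster(s) exceeding the missingness limit dropped: ",
                  paste(dropped, collapse = ", ")))
  }
  if (mean(is.na(meta[[target]])) > max_meta_na) {
    abort("target covariate exceeds the metadata missingness limit")
  }

  m <- count_matrix(rel)
  keep_feat <- colMeans(m) >= min_mean_abundance
  if (!any(keep_feat)) abort("no feature passes the abundance filter")

  vars <- c(target, keep_adj)
  dat0 <- meta[, vars, drop = FALSE]
  cc <- complete.cases(dat0)
  form <- stats::as.formula(paste("y ~", paste(vars, collapse = " + ")))

  res <- purrr::map_dfr(colnames(m)[keep_feat], function(ft) {
    dat <- dat0[cc, , drop = FALSE]
    dat$y <- arcsin_sqrt(m[cc, ft])
    n_par <- length(vars) + 1
    if (nrow(dat) < n_par + 2) abort("too few samples for the model size")
    fit <- lm(form, data = dat)
    sm <- summary(fit)$coefficients
    alias <- setdiff(names(coef(fit))[is.na(coef(fit))], character())
    if (length(alias)) warn(paste0("aliased term(s) dropped: ",
                                   paste(alias, collapse = ", ")))
    terms_wanted <- rownames(sm)[startsWith(rownames(sm), target)]
    tibble(feature_id = ft, term = terms_wanted,
           estimate = sm[terms_wanted, "Estimate"],
           std_error = sm[terms_wanted, "Std. Error"],
           p_value = sm[terms_wanted, "Pr(>|t|)"],
           n = nrow(dat))
  })
  res |>
    group_by(.data$term) |>
    mutate(q_value = p.adjust(.data$p_value, "BH")) |>
    ungroup() |>
    mutate(significant = .data$q_value < q_threshold,
           direction = ifelse(.data$estimate >= 0, "positive", "negative")) |>
    arrange(.data$q_value)
}
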