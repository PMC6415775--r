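# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted Dirichlet-multinomial mixture
#'
#' One row per (cluster, feature): the Dirichlet parameter and the
#' component's expected relative abundance for that feature.
#'
#' @param x A `gd_dmm` model.
#' @param ... Unused.
#' @return Tibble: `cluster`, `feature_id`, `alpha`, `expected_abundance`,
#'   `weight`.
#' @export
tidy.gd_dmm <- function(x, ...) {
  purrr::map_dfr(seq_len(x$k), function(j) {
    tibble(cluster = j, feature_id = x$feature_ids,
           alpha = x$alpha[j, ],
           expected_abundance = x$alpha[j, ] / sum(x$alpha[j, ]),
           weight = x$pi[j])
  })
}

#' @rdname tidy.gd_dmm
#' @return For `glance`: one-row tibble with `k`, `nll`, `laplace`,
#'   `converged`, `n_iterations`, `n_samples`, `n_features`.
#' @export
glance.gd_dmm <- function(x, ...) {
  tibble(k = x$k, nll = x$nll, laplace = x$laplace, converged = x$converged,
         n_iterations = length(x$nll_trace),
         n_samples = length(x$sample_ids), n_features = length(x$feature_ids))
}

#' Tidy a conditional logistic regression fit
#'
#' @param x A `gd_clr` fit.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `std_error`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`).
#' @export
tidy.gd_clr <- function(x, ...) x$coefficients

#' @rdname tidy.gd_clr
#' @export
glance.gd_clr <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, loglik = x$loglik, converged = x$converged)
}

#' Tidy a maturity model
#'
#' @param x A `gd_maturity` model.
#' @param ... Unused.
#' @return Tibble of selected features in importance order.
#' @export
tidy.gd_maturity <- function(x, ...) {
  tibble(feature_id = x$selected_features,
         rank = seq_along(x$selected_features))
}

#' @rdname tidy.gd_maturity
#' @export
glance.gd_maturity <- function(x, ...) {
  tibble(n_selected = length(x$selected_features),
         n_trees = x$config$n_trees,
         cv_mse = min(x$cv_error_curve$cv_mse),
         n_reference_subjects = length(x$reference_subjects))
}
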