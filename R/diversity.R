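#' Per-sample alpha diversity
#'
#' Computes richness (number of features with count > 0) and Shannon's
#' diversity index H' = -sum p log p in natural-log units for every sample.
#' Samples should be rarefied to a common depth first so richness is
#' comparable.
#'
#' @param counts Wide count tibble.
#' @return Tibble with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(counts) {
  m <- count_matrix(counts)
  if (any(rowSums(m) == 0)) abort("zero-total sample: Shannon undefined")
  tibble(
    sample_id = rownames(m),
    richness  = as.integer(rowSums(m > 0)),
    shannon   = unname(apply(m, 1, shannon_index))
  )
}

#' Shannon index of one count vector
#'
#' @param x Non-negative count (or proportion) vector with positive total.
#' @return H' in nats.
#' @export
shannon_index <- function(x) {
  if (sum(x) <= 0) abort("zero-total sample: Shannon undefined")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Richness of one count vector
#'
#' @param x Non-negative count vector.
#' @return Number of features with count > 0.
#' @export
richness_index <- function(x) as.integer(sum(x > 0))

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 sum_j min(x_j, y_j) / (sum x + sum y), the standard
#' abundance-based beta-diversity measure; symmetric with zero diagonal and
#' values in [0, 1]. Computed with `vegan::vegdist`. A warning is issued if
#' sample depths are unequal (rarefy first).
#'
#' @param counts Wide count tibble with at least two samples.
#' @return A `dist` object labelled by sample id.
#' @export
bray_curtis <- function(counts) {
  m <- count_matrix(counts)
  if (nrow(m) < 2) abort("need at least two samples")
  tot <- rowSums(m)
  if (any(tot == 0)) abort("zero-total sample: Bray-Curtis undefined")
  if (diff(range(tot)) > 1e-8) warn("unequal sample depths; consider rarefying first")
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS via `vegan::metaMDS` on a precomputed
#' dissimilarity: monotone regression of fitted against observed
#' dissimilarities, best solution over random restarts, deterministic given
#' `seed`. Coordinates are centred at the origin.
#'
#' @param d A `dist` object (e.g. from [bray_curtis()]).
#' @param k Number of ordination dimensions (default 2).
#' @param n_restarts Random restarts (`try` passed to metaMDS).
#' @param seed Integer seed.
#' @param max_iter Maximum iterations per run.
#' @return A list of class `gd_ordination`: `coordinates` (tibble
#'   `sample_id`, `NMDS1`, `NMDS2`, ...), `stress` in [0, 1], `converged`,
#'   `n_restarts`.
#' @export
nmds_ordination <- function(d, k = 2, n_restarts = 10, seed = 1, max_iter = 200) {
  if (!inherits(d, "dist")) abort("d must be a 'dist' object")
  fit <- withr::with_seed(seed, suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                   maxit = max_iter, trace = 0, autotransform = FALSE,
                   wascores = FALSE)
  )))
  coords <- scale(vegan::scores(fit, display = "sites"), scale = FALSE)
  out <- as_tibble(coords)
  names(out) <- paste0("NMDS", seq_len(ncol(out)))
  structure(
    list(
      coordinates = dplyr::bind_cols(tibble(sample_id = labels(d)), out),
      stress = fit$stress,
      converged = isTRUE(fit$converged) || fit$stress < 1e-3,
      n_restarts = n_restarts
    ),
    class = "gd_ordination"
  )
}

#' @export
print.gd_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples, %d dimensions, stress %.4f (%s)\n",
              nrow(x$coordinates), ncol(x$coordinates) - 1L, x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Core microbiome of a sample group
#'
#' Features present (count > 0) in strictly more than `prevalence_threshold`
#' of the group's samples; the default reproduces the ">90% prevalence"
#' core-microbiome convention.
#'
#' @param counts Wide count tibble.
#' @param sample_ids Sample ids defining the group (default: all samples).
#' @param prevalence_threshold Strict lower bound on prevalence (default 0.9).
#' @return Tibble with `feature_id`, `prevalence`, filtered to the core.
#' @export
core_microbiome <- function(counts, sample_ids = counts$sample_id,
                            prevalence_threshold = 0.9) {
  if (length(sample_ids) == 0) abort("empty sample group")
  m <- count_matrix(counts)
  missing <- setdiff(sample_ids, rownames(m))
  if (length(missing)) abort(paste0("unknown sample ids: ", paste(missing, collapse = ", ")))
  prev <- colMeans(m[sample_ids, , drop = FALSE] > 0)
  tibble(feature_id = names(prev), prevalence = unname(prev)) |>
    filter(.data$prevalence > prevalence_threshold) |>
    arrange(desc(.data$prevalence))
}
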