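# Matched case-control sample pairing and 1:1 conditional logistic
# regression for taxa and community-stability metrics.

#' Match control samples to case samples by day of life
#'
#' Case samples are taken in chronological order; each greedily claims the
#' unused control sample nearest in day of life. A match is retained only if
#' `|day difference| / case day <= tolerance` (the +/-20% rule); other case
#' samples are omitted with a reason.
#'
#' @param case_samples,control_samples Sample records of the two pair
#'   members (`sample_id`, `age_days`).
#' @param tolerance Relative day-of-life tolerance (default 0.20).
#' @return A list: `matched` tibble (`case_sample`, `control_sample`,
#'   `case_day`, `control_day`, `day_diff`), and `omitted` tibble
#'   (`case_sample`, `reason`).
#' @export
match_pair_samples <- function(case_samples, control_samples, tolerance = 0.20) {
  if (nrow(case_samples) == 0 || nrow(control_samples) == 0) {
    abort("both pair members need at least one sample")
  }
  cs <- case_samples |> arrange(.data$age_days)
  ct <- control_samples |> arrange(.data$age_days)
  used <- logical(nrow(ct))
  matched <- list(); omitted <- list()
  for (i in seq_len(nrow(cs))) {
    avail <- which(!used)
    if (length(avail) == 0) {
      omitted[[length(omitted) + 1]] <-
        tibble(case_sample = cs$sample_id[i], reason = "no unused control sample")
      next
    }
    dd <- abs(ct$age_days[avail] - cs$age_days[i])
    j <- avail[which.min(dd)]
    reldiff <- abs(ct$age_days[j] - cs$age_days[i]) / cs$age_days[i]
    if (reldiff <= tolerance) {
      used[j] <- TRUE
      matched[[length(matched) + 1]] <- tibble(
        case_sample = cs$sample_id[i], control_sample = ct$sample_id[j],
        case_day = cs$age_days[i], control_day = ct$age_days[j],
        day_diff = ct$age_days[j] - cs$age_days[i])
    } else {
      omitted[[length(omitted) + 1]] <-
        tibble(case_sample = cs$sample_id[i],
               reason = sprintf("nearest control outside +/-%.0f%% (%.2f)",
                                100 * tolerance, reldiff))
    }
  }
  if (length(matched) == 0) warn("pair contributes zero matched samples")
  list(matched = bind_rows(matched), omitted = bind_rows(omitted))
}

#' Build the matched-sample dataset for a paired cohort
#'
#' Applies [match_pair_samples()] to every case-control pair.
#'
#' @param samples Sample records with `subject_id`.
#' @param subjects Subject records with `case_status` (`"case"` /
#'   `"control"`) and `matched_pair_id`.
#' @param tolerance Relative day tolerance (default 0.20).
#' @return A list: `matched` tibble with `pair_id`, `case_subject`,
#'   `control_subject` and the matched sample columns; `omitted` tibble.
#' @export
match_cohort_samples <- function(samples, subjects, tolerance = 0.20) {
  pairs <- subjects |>
    filter(!is.na(.data$matched_pair_id)) |>
    select("subject_id", "case_status", "matched_pair_id") |>
    tidyr::pivot_wider(names_from = "case_status", values_from = "subject_id")
  matched <- list(); omitted <- list()
  for (i in seq_len(nrow(pairs))) {
    cm <- match_pair_samples(
      samples |> filter(.data$subject_id == pairs$case[i]),
      samples |> filter(.data$subject_id == pairs$control[i]),
      tolerance)
    if (nrow(cm$matched)) {
      matched[[i]] <- cm$matched |>
        mutate(pair_id = pairs$matched_pair_id[i],
               case_subject = pairs$case[i],
               control_subject = pairs$control[i], .before = 1)
    }
    if (nrow(cm$omitted)) {
      omitted[[i]] <- cm$omitted |> mutate(pair_id = pairs$matched_pair_id[i])
    }
  }
  list(matched = bind_rows(matched), omitted = bind_rows(omitted))
}

#' 1:1 conditional logistic regression
#'
#' Maximises the pair-conditional likelihood
#' `prod_i exp(b'x_case) / (exp(b'x_case) + exp(b'x_control))`, equivalent
#' to logistic regression without intercept on within-pair differences, by
#' Newton-Raphson. Standard errors come from the inverse observed
#' information; odds ratios are `exp(b)` with Wald 95% intervals. Complete
#' separation triggers a divergence guard (coefficients capped at |b| = 15)
#' and a non-converged flag.
#'
#' @param case_x,control_x Numeric matrices (pairs x predictors) of the
#'   case and control member values.
#' @param max_iter,tol Newton-Raphson controls.
#' @return A `gd_clr` fit: tibble `term`, `estimate`, `std_error`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, plus `n_pairs`,
#'   `converged`, `loglik`.
#' @export
clr_fit <- function(case_x, control_x, max_iter = 50, tol = 1e-10) {
  case_x <- as.matrix(case_x); control_x <- as.matrix(control_x)
  if (!all(dim(case_x) == dim(control_x))) abort("case and control dimensions differ")
  d <- case_x - control_x
  keep <- colSums(abs(d)) > 0
  if (!any(keep)) abort("non-identifiable: all within-pair differences are zero")
  if (any(!keep)) {
    warn(paste0("dropping constant-within-pair predictor(s): ",
                paste(colnames(d)[!keep], collapse = ", ")))
  }
  d <- d[, keep, drop = FALSE]
  if (is.null(colnames(d))) colnames(d) <- paste0("x", seq_len(ncol(d)))
  beta <- numeric(ncol(d))
  converged <- FALSE
  cap <- 15
  for (it in seq_len(max_iter)) {
    eta <- drop(d %*% beta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(d, 1 - p))
    W <- p * (1 - p)
    H <- crossprod(d * sqrt(W))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta_new <- beta + step
    if (any(abs(beta_new) > cap)) {
      beta <- pmin(pmax(beta_new, -cap), cap)
      warn("divergence guard triggered (possible complete separation)")
      break
    }
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  eta <- drop(d %*% beta)
  p <- stats::plogis(eta)
  W <- p * (1 - p)
  H <- crossprod(d * sqrt(W))
  se <- sqrt(diag(tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, ncol(d), ncol(d))
  })))
  beta <- unname(beta)
  se <- unname(se)
  res <- tibble(
    term = colnames(d), estimate = beta, std_error = se,
    odds_ratio = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  )
  structure(list(coefficients = res, n_pairs = nrow(d), converged = converged,
                 loglik = sum(stats::plogis(eta, log.p = TRUE))),
            class = "gd_clr")
}

#' @export
print.gd_clr <- function(x, ...) {
  cat(sprintf("conditional logistic regression: %d pairs, %s\n", x$n_pairs,
              if (x$converged) "converged" else "NOT converged"))
  print(x$coefficients)
  invisible(x)
}

# Assemble per-pair predictor matrices for one genus + adjusters from the
# matched sample table.
pair_design <- function(matched, values_case, values_control) {
  list(case = values_case, control = values_control)
}

#' Conditional logistic screen of dominant genera
#'
#' For the `n_top` most abundant genera (overall mean relative abundance),
#' fits one conditional logistic regression per genus on the matched sample
#' pairs, entering the genus as `log2(count + pseudo)` together with the
#' adjusters; p-values are BH-corrected across genera and `significant`
#' flags corrected p < 0.05.
#'
#' @param counts Wide (genus-level, rarefied) count tibble.
#' @param matched Matched sample tibble from [match_cohort_samples()].
#' @param adjusters Optional tibble `sample_id` + numeric adjuster columns
#'   (per-sample values; within-pair differences enter the likelihood).
#' @param n_top Number of dominant genera (default 50).
#' @param pseudo Pseudo-count added before log2 (default 0.01).
#' @return Tibble: `genus`, `estimate`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `q_value`, `significant`, `n_pairs`, `converged`.
#' @export
genus_clr_screen <- function(counts, matched, adjusters = NULL, n_top = 50,
                             pseudo = 0.01) {
  m <- count_matrix(counts)
  rel_mean <- colMeans(m / rowSums(m))
  top <- names(sort(rel_mean, decreasing = TRUE))[seq_len(min(n_top, ncol(m)))]
  lg <- log2(m + pseudo)
  adj_case <- adj_ctrl <- NULL
  if (!is.null(adjusters)) {
    av <- as.matrix(adjusters[, setdiff(names(adjusters), "sample_id"), drop = FALSE])
    rownames(av) <- adjusters$sample_id
    adj_case <- av[matched$case_sample, , drop = FALSE]
    adj_ctrl <- av[matched$control_sample, , drop = FALSE]
  }
  res <- purrr::map_dfr(top, function(g) {
    xc <- cbind(genus = lg[matched$case_sample, g], adj_case)
    xk <- cbind(genus = lg[matched$control_sample, g], adj_ctrl)
    fit <- tryCatch(suppressWarnings(clr_fit(xc, xk)), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(genus = g, estimate = NA_real_, odds_ratio = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                    n_pairs = nrow(matched), converged = NA))
    }
    co <- fit$coefficients |> filter(.data$term == "genus")
    tibble(genus = g, estimate = co$estimate, odds_ratio = co$odds_ratio,
           ci_low = co$ci_low, ci_high = co$ci_high, p_value = co$p_value,
           n_pairs = fit$n_pairs, converged = fit$converged)
  })
  res |>
    mutate(q_value = p.adjust(.data$p_value, "BH"),
           significant = !is.na(.data$q_value) & .data$q_value < 0.05) |>
    arrange(.data$q_value)
}

#' Conditional logistic regression of community stability
#'
#' Computes each pair member's stability metrics (unique community states
#' and transitions) inside pre-diagnosis windows anchored at the case's
#' diagnosis day — identically for both members — then fits one conditional
#' logistic regression per metric per window. A pair contributes the
#' transition metric only when both members have >= 2 samples in the window
#' (>= 1 for the unique-state count).
#'
#' @param assignments Tibble `sample_id`, `cluster`.
#' @param samples Sample records.
#' @param subjects Subject records with `case_status`, `matched_pair_id`,
#'   `diagnosis_day`.
#' @param windows_before Numeric vector of window edges in days before
#'   diagnosis, e.g. `c(365, 0)` for "the year before diagnosis"; windows
#'   are `[diagnosis - a, diagnosis - b)` for consecutive edges `a > b`.
#' @param adjusters Optional tibble `subject_id` + numeric adjuster columns.
#' @return Tibble: `window`, `metric`, `estimate`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `n_pairs`, `converged`.
#' @export
stability_clr <- function(assignments, samples, subjects,
                          windows_before = c(365, 0), adjusters = NULL) {
  pairs <- subjects |>
    filter(!is.na(.data$matched_pair_id)) |>
    select("subject_id", "case_status", "matched_pair_id", "diagnosis_day") |>
    tidyr::pivot_wider(names_from = "case_status",
                       values_from = c("subject_id", "diagnosis_day")) |>
    rename(case = "subject_id_case", control = "subject_id_control",
           diagnosis = "diagnosis_day_case")
  edges <- sort(windows_before, decreasing = TRUE)
  win_tbl <- tibble(a = edges[-length(edges)], b = edges[-1])
  av <- NULL
  if (!is.null(adjusters)) {
    av <- as.matrix(adjusters[, setdiff(names(adjusters), "subject_id"), drop = FALSE])
    rownames(av) <- adjusters$subject_id
  }
  purrr::map_dfr(seq_len(nrow(win_tbl)), function(wi) {
    lab <- sprintf("%d-%d days before diagnosis", win_tbl$a[wi], win_tbl$b[wi])
    met <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      lo <- pairs$diagnosis[i] - win_tbl$a[wi]
      hi <- pairs$diagnosis[i] - win_tbl$b[wi]
      both <- purrr::map_dfr(c(pairs$case[i], pairs$control[i]), function(sj) {
        smp <- samples |> filter(.data$subject_id == sj)
        res <- tryCatch(stability_metrics(assignments, smp, c(lo, hi)),
                        error = function(e) NULL)
        if (is.null(res)) {
          tibble(subject_id = sj, n_samples = 0L, n_unique_states = NA_integer_,
                 n_transitions = NA_integer_)
        } else res
      })
      both |> mutate(pair = i, role = c("case", "control"))
    })
    purrr::map_dfr(c("n_unique_states", "n_transitions"), function(metric) {
      need <- if (metric == "n_transitions") 2L else 1L
      wide <- met |>
        select("pair", "role", "n_samples", value = dplyr::all_of(metric)) |>
        tidyr::pivot_wider(names_from = "role",
                           values_from = c("value", "n_samples")) |>
        filter(.data$n_samples_case >= need, .data$n_samples_control >= need,
               !is.na(.data$value_case), !is.na(.data$value_control))
      if (nrow(wide) < 2) return(NULL)
      xc <- cbind(metric = wide$value_case)
      xk <- cbind(metric = wide$value_control)
      if (!is.null(av)) {
        xc <- cbind(xc, av[pairs$case[wide$pair], , drop = FALSE])
        xk <- cbind(xk, av[pairs$control[wide$pair], , drop = FALSE])
      }
      fit <- tryCatch(suppressWarnings(clr_fit(xc, xk)), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      co <- fit$coefficients |> filter(.data$term == "metric")
      tibble(window = lab, metric = metric, estimate = co$estimate,
             odds_ratio = co$odds_ratio, ci_low = co$ci_low,
             ci_high = co$ci_high, p_value = co$p_value,
             n_pairs = fit$n_pairs, converged = fit$converged)
    })
  })
}
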