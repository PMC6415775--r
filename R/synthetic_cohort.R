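# Seeded synthetic-cohort generator.
#
# Emulates the data structure of a longitudinal infant-cohort microbiome
# study: monthly stool samples from month 3 onward, latent community types
# with age-dependent sticky transitions (planted developmental, transitional
# and stable phases), covariate-linked taxon shifts (breastfeeding boosts
# Bifidobacterium, vaginal birth boosts Bacteroides, weaning boosts
# Firmicutes genera), an age-correlated maturation tilt, per-species KEGG
# orthologue profiles, and optional 1:1 matched case-control structure.
# Every emitted sample carries a ground-truth record, so each downstream
# stage can be validated against the planted answer.

#' Configuration of the synthetic cohort generator
#'
#' Defaults define the reference study conditions: 10 well-separated
#' community types over a 60-genus panel, monthly samples over months 3-46
#' with 10% missed visits, sequencing depth 3,000 reads, planted phase
#' boundaries at months 14 and 30 (cluster-mix targets drift over months
#' 3-24 and are constant afterwards, so months >= 31 are stable by
#' construction), breastfeeding stopping at a lognormal median of ~9 months,
#' caesarean probability 0.25, and multiplicative covariate effects on the
#' Dirichlet parameters (breastfeeding boosts Bifidobacterium, vaginal birth
#' boosts Bacteroides-type genera for the first year, weaning boosts a
#' Firmicutes set). Effect multipliers are moderate by default so the
#' covariate shifts perturb compositions without splitting the planted
#' community types into additional effective mixture components.
#'
#' @param n_subjects Number of children.
#' @param months Integer month range of visits (default 3:46).
#' @param depth Reads per sample before any rarefaction.
#' @param missingness Probability a scheduled visit is missed.
#' @param k_true Number of planted community types (fixed at 10 for the
#'   default parameter set).
#' @param stickiness Probability the latent community type is carried over
#'   from the previous month rather than redrawn from the age target.
#' @param effects `"planted"` for the default covariate effects, `"none"`
#'   to zero every covariate-linked shift (null generator).
#' @param bf_mult,vaginal_mult,weaning_mult Multiplicative Dirichlet-mass
#'   shifts of the planted covariate effects.
#' @param maturation_strength Log-scale amplitude of the monotone
#'   maturation tilt applied up to `maturation_cap_month`.
#' @param maturation_cap_month Month at which the maturation tilt plateaus.
#' @param caesarean_prob Probability of caesarean delivery.
#' @param bf_median_months,bf_sdlog Lognormal breastfeeding-stop age.
#' @param ko_profiles Emit per-species KEGG orthologue profiles.
#' @param seed Integer seed; all output is a deterministic function of it.
#' @return A `gd_cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 60,
                          months = 3:46,
                          depth = 3000,
                          missingness = 0.10,
                          k_true = 10,
                          stickiness = 0.55,
                          effects = c("planted", "none"),
                          bf_mult = 1.7,
                          vaginal_mult = 1.7,
                          weaning_mult = 1.4,
                          maturation_strength = 0.8,
                          maturation_cap_month = 24,
                          caesarean_prob = 0.25,
                          bf_median_months = 9,
                          bf_sdlog = 0.4,
                          ko_profiles = TRUE,
                          seed = 1) {
  effects <- match.arg(effects)
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  if (depth < 1) abort("depth must be >= 1")
  if (k_true != 10) abort("the default parameter set plants k_true = 10")
  if (missingness < 0 || missingness >= 1) abort("missingness must be in [0, 1)")
  panel <- default_taxa_panel()
  structure(list(
    n_subjects = n_subjects, months = as.integer(months), depth = depth,
    missingness = missingness, k_true = k_true, stickiness = stickiness,
    effects = effects, bf_mult = bf_mult, vaginal_mult = vaginal_mult,
    weaning_mult = weaning_mult,
    maturation_strength = maturation_strength,
    maturation_cap_month = maturation_cap_month,
    caesarean_prob = caesarean_prob,
    bf_median_months = bf_median_months, bf_sdlog = bf_sdlog,
    ko_profiles = ko_profiles,
    taxa = panel, alpha = default_component_alpha(panel$feature_id),
    seed = seed
  ), class = "gd_cohort_config")
}

# The 22 covariates screened downstream; `dynamic` ones are event windows.
covariate_catalogue <- function() {
  tibble(
    covariate = c("breastfeeding", "formula_feeding", "solid_food",
                  "antibiotics", "probiotics", "respiratory_infection",
                  "gastrointestinal_infection", "daycare", "vitamin_d_drops",
                  "delivery_mode", "sex", "site", "hla_group", "premature",
                  "siblings", "furry_pets", "maternal_bmi_group",
                  "maternal_weight_gain_group", "maternal_antibiotics",
                  "maternal_probiotics", "season_of_birth",
                  "household_smoking"),
    dynamic = c(rep(TRUE, 9), rep(FALSE, 13))
  )
}

# Genera boosted after weaning (solid-food introduction).
weaning_taxa <- function() c("Blautia", "Ruminococcus", "Faecalibacterium",
                             "Roseburia", "Coprococcus", "Dorea")

# Background taxa of the breastfeeding signature. Milk-adapted
# Actinobacteria rise and solid-food clostridia fall while breastfeeding is
# active; none of these is a cluster-defining dominant, so the signature
# displaces compositions (detectable on an ordination) without splitting
# the planted community types.
bf_up_taxa <- function() c("Collinsella", "Eggerthella", "Adlercreutzia",
                           "Olsenella")
bf_down_taxa <- function() c("Clostridium", "Erysipelatoclostridium",
                             "Megasphaera", "Holdemanella")

# Maturation tilt weights. Early-coloniser genera decline and
# adult-associated genera rise monotonically with age. The tilted genera
# are deliberately not the cluster-defining dominants, so the tilt is an
# age signal layered on top of the community types rather than a
# redefinition of them.
maturation_weights <- function(taxa, strength) {
  w <- setNames(numeric(length(taxa)), taxa)
  down <- c("Rothia", "Corynebacterium", "Actinomyces", "Haemophilus",
            "Citrobacter", "Enterobacter", "Intestinibacter", "Romboutsia")
  up <- c("Odoribacter", "Butyricimonas", "Barnesiella", "Flavonifractor",
          "Anaerotruncus", "Phascolarctobacterium", "Victivallis",
          "Christensenella", "Sellimonas")
  w[intersect(down, taxa)] <- -strength
  w[intersect(up, taxa)] <- strength
  w
}

gen_subjects <- function(cfg, ids) {
  n <- length(ids)
  tibble(
    subject_id = ids,
    sex = sample(c("female", "male"), n, replace = TRUE),
    site = sample(paste0("site", 1:6), n, replace = TRUE),
    hla_group = sample(paste0("HLA", 1:4), n, replace = TRUE, prob = c(.4, .3, .2, .1)),
    delivery_mode = ifelse(runif(n) < cfg$caesarean_prob, "caesarean", "vaginal"),
    gestational_weeks = round(rnorm(n, 39.5, 1.6), 1),
    siblings = sample(c("no", "yes"), n, replace = TRUE, prob = c(.45, .55)),
    furry_pets = sample(c("no", "yes"), n, replace = TRUE, prob = c(.6, .4)),
    maternal_bmi_group = sample(c("normal", "overweight", "obese"), n,
                                replace = TRUE, prob = c(.55, .3, .15)),
    maternal_weight_gain_group = sample(c("low", "normal", "high"), n,
                                        replace = TRUE, prob = c(.2, .55, .25)),
    maternal_antibiotics = sample(c("no", "yes"), n, replace = TRUE, prob = c(.75, .25)),
    maternal_probiotics = sample(c("no", "yes"), n, replace = TRUE, prob = c(.8, .2)),
    season_of_birth = sample(c("winter", "spring", "summer", "autumn"), n, replace = TRUE),
    household_smoking = sample(c("no", "yes"), n, replace = TRUE, prob = c(.85, .15)),
    breastfed = runif(n) < 0.85,
    bf_stop_day = round(rlnorm(n, log(cfg$bf_median_months * DAYS_PER_MONTH), cfg$bf_sdlog)),
    solid_food_day = pmax(90, round(rnorm(n, 5.5 * DAYS_PER_MONTH, 30))),
    case_status = "none",
    matched_pair_id = NA_character_,
    diagnosis_day = NA_real_
  ) |>
    mutate(premature = ifelse(.data$gestational_weeks <= 37, "yes", "no"),
           bf_stop_day = ifelse(.data$breastfed, .data$bf_stop_day, 0))
}

gen_events <- function(cfg, subjects) {
  max_day <- ceiling((max(cfg$months) + 1) * DAYS_PER_MONTH)
  one <- function(s) {
    ev <- list()
    if (s$breastfed) {
      ev <- c(ev, list(tibble(covariate = "breastfeeding", start_day = 1,
                              stop_day = s$bf_stop_day)))
    }
    if (runif(1) < 0.7) {
      fstart <- max(1, round(rnorm(1, 60, 40)))
      ev <- c(ev, list(tibble(covariate = "formula_feeding", start_day = fstart,
                              stop_day = round(rnorm(1, 380, 60)))))
    }
    ev <- c(ev, list(tibble(covariate = "solid_food", start_day = s$solid_food_day,
                            stop_day = NA_real_)))
    for (cv in c("antibiotics", "respiratory_infection", "gastrointestinal_infection")) {
      n_ep <- rpois(1, if (cv == "antibiotics") 1.5 else 2)
      if (n_ep > 0) {
        starts <- sort(sample(seq(90, max_day - 20), n_ep))
        # enforce non-overlap of episode windows
        starts <- starts[c(TRUE, diff(starts) > 14)]
        ev <- c(ev, list(tibble(covariate = cv, start_day = starts,
                                stop_day = starts + sample(5:10, length(starts), TRUE))))
      }
    }
    if (runif(1) < 0.3) {
      ev <- c(ev, list(tibble(covariate = "probiotics",
                              start_day = round(runif(1, 30, 300)),
                              stop_day = NA_real_)))
    }
    if (runif(1) < 0.6) {
      ev <- c(ev, list(tibble(covariate = "daycare",
                              start_day = round(runif(1, 270, 700)),
                              stop_day = NA_real_)))
    }
    if (runif(1) < 0.5) {
      ev <- c(ev, list(tibble(covariate = "vitamin_d_drops", start_day = 14,
                              stop_day = round(runif(1, 300, 500)))))
    }
    bind_rows(ev)
  }
  purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    one(subjects[i, ]) |> mutate(subject_id = subjects$subject_id[i], .before = 1)
  })
}

# Latent community-type trajectory over the scheduled months: sticky chain
# against the month-indexed target mix.
gen_trajectory <- function(months, stickiness, k) {
  targ <- cluster_targets(months, k)
  z <- integer(length(months))
  z[1] <- sample.int(k, 1, prob = targ[1, ])
  if (length(months) > 1) {
    for (t in 2:length(months)) {
      z[t] <- if (runif(1) < stickiness) z[t - 1] else sample.int(k, 1, prob = targ[t, ])
    }
  }
  z
}

# Per-sample effective Dirichlet parameters: planted component modified by
# the maturation tilt and any active covariate effects.
effective_alpha <- function(cfg, z, month, day, subj, mat_w) {
  a <- cfg$alpha[z, ]
  m_eff <- (pmin(month, cfg$maturation_cap_month) - 3) /
    (cfg$maturation_cap_month - 3)
  a <- a * exp(mat_w * m_eff)
  if (cfg$effects == "planted") {
    if (isTRUE(subj$breastfed) && day <= subj$bf_stop_day) {
      a["Bifidobacterium"] <- a["Bifidobacterium"] * cfg$bf_mult
      a[bf_up_taxa()] <- a[bf_up_taxa()] * 1.8
      a[bf_down_taxa()] <- a[bf_down_taxa()] * 0.55
    }
    if (subj$delivery_mode == "vaginal" && day <= 365) {
      a[c("Bacteroides", "Parabacteroides")] <-
        a[c("Bacteroides", "Parabacteroides")] * cfg$vaginal_mult
    }
    if (day >= subj$solid_food_day) {
      a[weaning_taxa()] <- a[weaning_taxa()] * cfg$weaning_mult
    }
  }
  a
}

rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws subjects, covariate event histories, latent community-type
#' trajectories, and Dirichlet-multinomial counts at the configured depth;
#' optionally emits per-species KEGG orthologue profiles. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list: `counts` (wide count tibble), `samples` (sample records
#'   with `subject_id`, `age_days`, `age_months`), `subjects`, `events`
#'   (dynamic covariate windows), `taxonomy`, `ko_profiles` (long tibble or
#'   `NULL`), and `truth` (per-sample planted community type, effect
#'   registry, `k_true`, phase boundaries).
#' @export
generate_cohort <- function(config = cohort_config()) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    ids <- sprintf("S%03d", seq_len(cfg$n_subjects))
    subjects <- gen_subjects(cfg, ids)
    events <- gen_events(cfg, subjects)
    mat_w <- maturation_weights(cfg$taxa$feature_id, cfg$maturation_strength)

    samples <- list(); zs <- list(); counts <- list()
    for (i in seq_len(cfg$n_subjects)) {
      subj <- subjects[i, ]
      keep <- runif(length(cfg$months)) >= cfg$missingness
      if (!any(keep)) keep[1] <- TRUE
      months_i <- cfg$months
      z_full <- gen_trajectory(months_i, cfg$stickiness, cfg$k_true)
      months_obs <- months_i[keep]
      z_obs <- z_full[keep]
      days <- round((months_obs + runif(length(months_obs), 0.1, 0.9)) * DAYS_PER_MONTH)
      sid <- sprintf("%s_m%02d", subj$subject_id, months_obs)
      cmat <- matrix(0L, length(sid), nrow(cfg$taxa),
                     dimnames = list(sid, cfg$taxa$feature_id))
      for (t in seq_along(sid)) {
        a <- effective_alpha(cfg, z_obs[t], months_obs[t], days[t], subj, mat_w)
        p <- rdirichlet_one(a)
        cmat[t, ] <- as.integer(stats::rmultinom(1, cfg$depth, p))
      }
      samples[[i]] <- tibble(sample_id = sid, subject_id = subj$subject_id,
                             age_days = as.integer(days),
                             age_months = age_to_month(days),
                             collection_day_of_life = as.integer(days))
      zs[[i]] <- tibble(sample_id = sid, true_cluster = z_obs)
      counts[[i]] <- cmat
    }
    samples <- bind_rows(samples)
    truth_z <- bind_rows(zs)
    counts <- matrix_to_counts(do.call(rbind, counts))

    ko <- if (cfg$ko_profiles) gen_ko_profiles(counts) else NULL

    list(
      counts = counts,
      samples = samples,
      subjects = subjects,
      events = events,
      taxonomy = cfg$taxa,
      ko_profiles = ko,
      truth = list(
        z = truth_z, k_true = cfg$k_true, phase_months = c(14, 30),
        effects = if (cfg$effects == "planted") {
          list(breastfeeding = list(taxa = "Bifidobacterium",
                                    multiplier = cfg$bf_mult,
                                    signature_up = bf_up_taxa(),
                                    signature_down = bf_down_taxa()),
               delivery_mode = list(taxa = c("Bacteroides", "Parabacteroides"),
                                    multiplier = cfg$vaginal_mult),
               solid_food = list(taxa = weaning_taxa(),
                                 multiplier = cfg$weaning_mult))
        } else list(),
        config = cfg
      )
    )
  })
}

#' Generate a 1:1 matched case-control cohort
#'
#' Pairs share the matching factors (site and sex). Each case receives a
#' diagnosis day strictly after its first sample; optional planted effects
#' modify cases only: a binary-exposure log odds ratio (`exposure_logor`), a
#' multiplicative pre-diagnosis abundance shift on one genus
#' (`genus`, `genus_logfc` on the natural-log scale of its Dirichlet
#' parameter), and a transition-rate increase (`instability`, which lowers
#' the case's stickiness toward `stickiness / instability`).
#'
#' @param config A [cohort_config()]; `n_subjects` is ignored.
#' @param n_pairs Number of case-control pairs.
#' @param exposure_logor Planted log odds ratio of the binary covariate
#'   `planted_exposure` (0 = no effect).
#' @param exposure_prev Control-arm exposure prevalence.
#' @param genus,genus_logfc Planted case abundance shift (genus must be on
#'   the panel).
#' @param instability Multiplier > 1 increases case transition rates.
#' @return As [generate_cohort()], with `subjects` carrying `case_status`,
#'   `matched_pair_id`, `diagnosis_day` and `planted_exposure`.
#' @export
generate_paired <- function(config = cohort_config(), n_pairs = 50,
                            exposure_logor = 0, exposure_prev = 0.3,
                            genus = NULL, genus_logfc = 0, instability = 1) {
  cfg <- config
  if (n_pairs < 1) abort("n_pairs must be >= 1")
  if (!is.null(genus) && !genus %in% cfg$taxa$feature_id) {
    abort(paste0("planted effect on unknown taxon: ", genus))
  }
  cfg$n_subjects <- 2L * n_pairs
  base <- generate_cohort(cfg)
  withr::with_seed(cfg$seed + 7L, {
    subjects <- base$subjects
    n <- nrow(subjects)
    case_idx <- seq(1, n, by = 2)
    ctrl_idx <- case_idx + 1
    pair_ids <- sprintf("P%03d", seq_len(n_pairs))
    subjects$case_status[case_idx] <- "case"
    subjects$case_status[ctrl_idx] <- "control"
    subjects$matched_pair_id[case_idx] <- pair_ids
    subjects$matched_pair_id[ctrl_idx] <- pair_ids
    # controls share the case's matching factors
    subjects$site[ctrl_idx] <- subjects$site[case_idx]
    subjects$sex[ctrl_idx] <- subjects$sex[case_idx]
    # diagnosis strictly after the case's first sample
    first_day <- base$samples |>
      group_by(.data$subject_id) |>
      summarise(first = min(.data$age_days), .groups = "drop")
    fd <- first_day$first[match(subjects$subject_id[case_idx], first_day$subject_id)]
    subjects$diagnosis_day[case_idx] <-
      pmax(fd + 30, round(runif(n_pairs, 12, 30) * DAYS_PER_MONTH))
    subjects$diagnosis_day[ctrl_idx] <- subjects$diagnosis_day[case_idx]

    p0 <- exposure_prev
    p1 <- stats::plogis(stats::qlogis(p0) + exposure_logor)
    subjects$planted_exposure <- NA_integer_
    subjects$planted_exposure[ctrl_idx] <- rbinom(n_pairs, 1, p0)
    subjects$planted_exposure[case_idx] <- rbinom(n_pairs, 1, p1)
    base$subjects <- subjects

    # planted case-only abundance shift: resample case counts with the genus
    # Dirichlet mass scaled by exp(genus_logfc) before diagnosis
    if (!is.null(genus) && genus_logfc != 0) {
      m <- count_matrix(base$counts)
      case_ids <- subjects$subject_id[case_idx]
      smp <- base$samples |> filter(.data$subject_id %in% case_ids)
      diag_day <- subjects$diagnosis_day[match(smp$subject_id, subjects$subject_id)]
      smp <- smp[smp$age_days <= diag_day, ]
      for (sid in smp$sample_id) {
        x <- m[sid, ]
        extra <- round(x[genus] * (exp(genus_logfc) - 1))
        if (extra != 0) {
          x[genus] <- x[genus] + max(extra, 5)
          m[sid, ] <- as.integer(stats::rmultinom(1, cfg$depth, x / sum(x)))
        }
      }
      base$counts <- matrix_to_counts(m)
    }

    # planted instability: regenerate case trajectories with lower stickiness
    if (instability > 1) {
      cfg2 <- cfg
      cfg2$stickiness <- cfg$stickiness / instability
      m <- count_matrix(base$counts)
      mat_w <- maturation_weights(cfg$taxa$feature_id, cfg$maturation_strength)
      for (i in case_idx) {
        subj <- subjects[i, ]
        smp <- base$samples |> filter(.data$subject_id == subj$subject_id)
        z <- gen_trajectory(smp$age_months, cfg2$stickiness, cfg$k_true)
        for (t in seq_len(nrow(smp))) {
          a <- effective_alpha(cfg, z[t], smp$age_months[t], smp$age_days[t],
                               subj, mat_w)
          m[smp$sample_id[t], ] <-
            as.integer(stats::rmultinom(1, cfg$depth, rdirichlet_one(a)))
        }
        base$truth$z$true_cluster[match(smp$sample_id, base$truth$z$sample_id)] <- z
      }
      base$counts <- matrix_to_counts(m)
    }
    base$truth$planted <- list(exposure_logor = exposure_logor, genus = genus,
                               genus_logfc = genus_logfc, instability = instability)
    base
  })
}
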