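# KEGG-module step completeness and per-species attribution.
#
# A module is an ordered list of reaction steps, each satisfiable by any of
# a set of alternative KEGG orthologues (KOs). A step is present in a
# profile when any of its alternatives has a positive read count; the module
# is called complete when at least 65% of its steps are present — evaluated
# both per detected species and for the whole metagenome.

#' Read KEGG-style module definitions from JSON
#'
#' Expected layout: an array of objects with `module_id`, `name`,
#' `pathway`, and `steps` — an array of arrays of KO ids (alternatives
#' within a step).
#'
#' @param path Path to the JSON file.
#' @return Tibble with `module_id`, `name`, `pathway` and a `steps`
#'   list-column of character vectors.
#' @export
read_module_defs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map_dfr(raw, function(m) {
    steps <- purrr::map(m$steps, ~ as.character(unlist(.x)))
    if (length(steps) == 0 || any(lengths(steps) == 0)) {
      abort(paste0("module ", m$module_id, " has an empty step"))
    }
    tibble(module_id = m$module_id, name = m$name %||% m$module_id,
           pathway = m$pathway %||% NA_character_, steps = list(steps))
  })
}

#' Example module definitions used by the synthetic cohort
#'
#' A small panel of synthetic module definitions in the flat
#' steps-with-alternatives form: a core glycolysis-like module carried by
#' every species, an HMO-utilisation-like module carried only by
#' *Bifidobacterium*, butyrate-production, LPS-biosynthesis, B12-biosynthesis
#' and mucin-degradation modules carried by characteristic species sets
#' (some deliberately partial, so incomplete calls occur).
#'
#' @return Tibble as [read_module_defs()].
#' @export
example_module_defs <- function() {
  tibble(
    module_id = c("M00010", "M00554", "M00088", "M00060", "M00122", "M00076"),
    name = c("Glycolysis core", "HMO utilisation", "Butyrate production",
             "LPS biosynthesis", "B12 biosynthesis", "Mucin degradation"),
    pathway = c("Carbohydrate", "Carbohydrate", "Fermentation",
                "Cell envelope", "Cofactor", "Glycan"),
    steps = list(
      list(c("K00844", "K12407"), "K01810", c("K00850", "K16370"),
           c("K01623", "K01624")),
      list("K17317", "K17318", "K01190", "K01788"),
      list("K00929", c("K01034", "K01035"), "K00634", "K00074"),
      list("K00748", "K02517", "K02535", "K09778"),
      list("K00798", "K02232", "K02225", "K02227", "K02231"),
      list("K01186", "K01206", "K12373")
    ) |> purrr::map(~ purrr::map(.x, as.character))
  )
}

# Which KOs each synthetic species carries. Species names are
# "<genus>_A". Partial carriers make incomplete module calls occur.
species_ko_repertoire <- function(genera) {
  defs <- example_module_defs()
  step_kos <- function(id, steps = NULL) {
    s <- defs$steps[[match(id, defs$module_id)]]
    if (!is.null(steps)) s <- s[steps]
    unlist(s)
  }
  species <- paste0(genera, "_A")
  assign <- setNames(vector("list", length(species)), species)
  for (sp in species) assign[[sp]] <- step_kos("M00010")
  add <- function(sp, kos) {
    sp <- intersect(sp, species)
    for (s in sp) assign[[s]] <<- c(assign[[s]], kos)
    invisible(NULL)
  }
  add("Bifidobacterium_A", step_kos("M00554"))
  add(paste0(c("Faecalibacterium", "Roseburia", "Eubacterium", "Anaerostipes",
               "Coprococcus"), "_A"), step_kos("M00088"))
  add(paste0(c("Escherichia", "Klebsiella", "Enterobacter", "Citrobacter"), "_A"),
      step_kos("M00060"))
  add("Bacteroides_A", step_kos("M00122"))
  add(paste0(c("Streptococcus", "Lactobacillus"), "_A"), step_kos("M00122", 1:2))
  add("Akkermansia_A", step_kos("M00076"))
  add("Bacteroides_A", step_kos("M00076", 1))
  purrr::imap_dfr(assign, ~ tibble(species = .y, ko = unique(.x)))
}

# Emit per-species KO read profiles for every sample: species are the taxa
# detected above `detect_min` reads, and each carried KO receives a Poisson
# count proportional to the taxon's read count.
gen_ko_profiles <- function(counts, detect_min = 30, rate = 0.02) {
  m <- count_matrix(counts)
  rep_tbl <- species_ko_repertoire(colnames(m))
  cells <- which(m >= detect_min, arr.ind = TRUE)
  det <- tibble(sample_id = rownames(m)[cells[, 1]],
                species = paste0(colnames(m)[cells[, 2]], "_A"),
                taxon_reads = m[cells])
  long <- inner_join(det, rep_tbl, by = "species",
                     relationship = "many-to-many")
  long$count <- rpois(nrow(long), long$taxon_reads * rate)
  long |>
    filter(.data$count > 0) |>
    select("sample_id", "species", "ko", "count")
}

as_ko_vector <- function(profile) {
  if (is.data.frame(profile)) {
    v <- tapply(profile$count, profile$ko, sum)
    setNames(as.numeric(v), names(v))
  } else profile
}

#' Step completeness of one module in one KO profile
#'
#' A step is present when any of its alternative KOs has count > 0; the
#' completeness fraction is present steps over total steps, and the module
#' is complete when the fraction reaches `threshold` (>=, so exactly 65%
#' counts as complete).
#'
#' @param profile Named numeric vector of KO counts, or a tibble with `ko`
#'   and `count` columns.
#' @param steps List of character vectors (alternatives per step), or one
#'   row of a module-definition tibble's `steps` column.
#' @param threshold Completeness threshold (default 0.65).
#' @return A list with `fraction`, `complete`, `present_steps`, `n_steps`.
#' @export
module_completeness <- function(profile, steps, threshold = 0.65) {
  if (length(steps) == 0) abort("module has no steps")
  kos <- as_ko_vector(profile)
  present <- vapply(steps, function(alts) {
    any(kos[intersect(alts, names(kos))] > 0)
  }, logical(1))
  frac <- mean(present)
  list(fraction = frac, complete = frac >= threshold,
       present_steps = sum(present), n_steps = length(steps))
}

#' Total read abundance of a module's member KOs
#'
#' Sum of the profile's counts over every KO appearing in any step.
#' Abundance is reported whether or not the module is complete; pair with
#' [module_completeness()] to flag incomplete calls.
#'
#' @inheritParams module_completeness
#' @return Total reads (scalar).
#' @export
module_abundance <- function(profile, steps) {
  kos <- as_ko_vector(profile)
  member <- unique(unlist(steps))
  sum(kos[intersect(member, names(kos))])
}

#' Completeness and abundance of every module in every profile
#'
#' Evaluates each module per (sample, species) and for the per-sample
#' metagenome (all species summed). KOs in the profiles that belong to no
#' module are ignored (their number is reported via a message).
#'
#' @param ko_profiles Long tibble: `sample_id`, `species`, `ko`, `count`.
#' @param modules Module-definition tibble ([example_module_defs()] form).
#' @param threshold Completeness threshold (default 0.65).
#' @param include_metagenome Add `species = "metagenome"` rows.
#' @return Tibble: `sample_id`, `species`, `module_id`, `fraction`,
#'   `complete`, `abundance`.
#' @export
module_table <- function(ko_profiles, modules, threshold = 0.65,
                         include_metagenome = TRUE) {
  known <- unique(unlist(modules$steps))
  unknown <- setdiff(unique(ko_profiles$ko), known)
  if (length(unknown)) {
    inform(sprintf("%d KO id(s) in profiles match no module; ignored",
                   length(unknown)))
  }
  prof <- ko_profiles
  if (include_metagenome) {
    meta <- ko_profiles |>
      group_by(.data$sample_id, .data$ko) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      mutate(species = "metagenome")
    prof <- bind_rows(prof, meta)
  }
  prof |>
    tidyr::nest(kos = c("ko", "count")) |>
    dplyr::cross_join(tibble(mi = seq_len(nrow(modules)))) |>
    mutate(module_id = modules$module_id[.data$mi]) |>
    mutate(res = purrr::map2(.data$kos, .data$mi, function(kk, i) {
      comp <- module_completeness(kk, modules$steps[[i]], threshold)
      tibble(fraction = comp$fraction, complete = comp$complete,
             abundance = module_abundance(kk, modules$steps[[i]]))
    })) |>
    select("sample_id", "species", "module_id", "res") |>
    tidyr::unnest("res")
}
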