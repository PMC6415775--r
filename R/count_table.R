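#' Read a sample-by-feature count table
#'
#' Reads a count table from TSV (default) or BIOM 2.1. The TSV layout is one
#' header row of feature ids, a first column of sample ids, and a
#' non-negative integer body; `transposed = TRUE` accepts the
#' features-as-rows layout instead. BIOM reading requires the `biomformat`
#' package.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom"`.
#' @param transposed For TSV input, set `TRUE` if rows are features and
#'   columns are samples.
#' @return A wide count tibble: a `sample_id` column followed by one integer
#'   column per feature.
#' @export
read_count_table <- function(path, format = c("tsv", "biom"), transposed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("BIOM input requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # features x samples
    m <- t(m)
    counts <- matrix_to_counts(m)
    validate_count_table(counts)
    inform(sprintf("read %d samples x %d features from %s",
                   nrow(counts), length(feature_names(counts)), path))
    return(counts)
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  if (transposed) {
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- raw$sample_id       # feature ids were in column 1
    m <- t(m)
    raw <- matrix_to_counts(m)
  }
  validate_count_table(raw)
  inform(sprintf("read %d samples x %d features from %s",
                 nrow(raw), length(feature_names(raw)), path))
  raw
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; the written file round-trips.
#'
#' @param counts Wide count tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  validate_count_table(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Validate the count-table contract
#'
#' Checks that counts are non-negative integers and ids are unique; errors
#' name the offending cell or id.
#'
#' @param counts Wide count tibble.
#' @return `counts`, invisibly.
#' @export
validate_count_table <- function(counts) {
  if (!"sample_id" %in% names(counts)) abort("count table needs a 'sample_id' column")
  if (anyDuplicated(counts$sample_id)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(counts$sample_id[duplicated(counts$sample_id)]), collapse = ", ")))
  }
  feats <- feature_names(counts)
  if (anyDuplicated(feats)) abort("duplicate feature ids")
  m <- count_matrix(counts)
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-integer or negative count at sample '%s', feature '%s'",
                  rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  invisible(counts)
}

#' Conventional rarefaction depths
#'
#' The depths used to equalise sampling effort in the two data types this
#' pipeline targets: 3,000 reads for 16S amplicon profiles and 100,000
#' reads for shotgun metagenomic profiles.
#'
#' @return Named numeric vector with elements `amplicon` and `metagenome`.
#' @export
rarefaction_depths <- function() c(amplicon = 3000, metagenome = 100000)

#' Rarefy samples to a fixed read depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth` reads, the convention used to equalise
#' sampling effort before diversity and community-typing analyses. Samples
#' with fewer than `depth` total reads are excluded and listed. Typical
#' depths are 3,000 reads for 16S profiles and 100,000 for shotgun
#' metagenomic profiles.
#'
#' @param counts Wide count tibble.
#' @param depth Target depth in reads (default 3000).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return A list: `counts` (rarefied tibble, every row summing to `depth`)
#'   and `excluded` (character vector of dropped sample ids).
#' @export
rarefy_counts <- function(counts, depth = 3000, seed = 1) {
  if (depth <= 0) abort("depth must be >= 1")
  validate_count_table(counts)
  m <- count_matrix(counts)
  totals <- rowSums(m)
  keep <- totals >= depth
  excluded <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  withr::with_seed(seed, {
    for (i in seq_len(nrow(m))) {
      x <- m[i, ]
      if (sum(x) == depth) next
      # expand reads to feature labels and draw depth of them w/o replacement
      drawn <- sample(rep.int(seq_along(x), x), depth, replace = FALSE)
      m[i, ] <- tabulate(drawn, nbins = length(x))
    }
  })
  list(counts = matrix_to_counts(m), excluded = excluded)
}

#' Collapse features to a taxonomic rank
#'
#' Sums counts of features sharing the same lineage truncated at `rank`.
#' Features unclassified at `rank` are grouped as `unclassified.<parent>`,
#' where the parent is the most specific classified rank above. Per-sample
#' totals are conserved.
#'
#' @param counts Wide count tibble.
#' @param taxonomy Tibble with a `feature_id` column and ranked lineage
#'   columns (`kingdom`, `phylum`, ..., `genus`, optionally `species`);
#'   empty string or `NA` means unclassified at that rank.
#' @param rank Rank to collapse to, e.g. `"genus"` or `"phylum"`.
#' @return Wide count tibble whose features are the collapsed lineages.
#' @export
collapse_taxonomy <- function(counts, taxonomy, rank = "genus") {
  validate_count_table(counts)
  if (!rank %in% names(taxonomy)) abort(paste0("rank '", rank, "' absent from taxonomy"))
  ranks <- intersect(c("kingdom", "phylum", "class", "order", "family", "genus", "species"),
                     names(taxonomy))
  upto <- ranks[seq_len(match(rank, ranks))]
  feats <- feature_names(counts)
  tax <- taxonomy[match(feats, taxonomy$feature_id), , drop = FALSE]
  label <- vapply(seq_along(feats), function(i) {
    lin <- as.character(tax[i, upto])
    lin[is.na(lin)] <- ""
    if (nzchar(lin[length(lin)])) return(lin[length(lin)])
    classified <- which(nzchar(lin))
    parent <- if (length(classified)) lin[max(classified)] else "root"
    paste0("unclassified.", parent)
  }, character(1))
  m <- count_matrix(counts)
  collapsed <- t(rowsum(t(m), group = label))
  matrix_to_counts(collapsed)
}

#' Relative abundance
#'
#' Converts counts to within-sample proportions; every row sums to 1.
#'
#' @param counts Wide count tibble.
#' @return Tibble of the same shape with proportions in place of counts.
#' @export
relative_abundance <- function(counts) {
  m <- count_matrix(counts)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    abort(paste0("zero-total sample(s): ",
                 paste(rownames(m)[totals == 0], collapse = ", ")))
  }
  matrix_to_counts(m / totals)
}
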