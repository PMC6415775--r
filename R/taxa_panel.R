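# Default taxon panel and planted community-type parameters for the
# synthetic cohort generator. Genus names mirror taxa commonly discussed in
# infant gut studies so fixtures read naturally; no biological realism is
# claimed beyond the planted structure.

#' Default genus panel of the synthetic cohort
#'
#' Sixty genera spanning the five dominant gut phyla, with a full ranked
#' lineage for taxonomy collapsing.
#'
#' @return Tibble with `feature_id`, `kingdom`, `phylum`, `family`, `genus`.
#' @export
default_taxa_panel <- function() {
  g <- list(
    Actinobacteria = c("Bifidobacterium", "Collinsella", "Eggerthella",
                       "Actinomyces", "Rothia", "Corynebacterium",
                       "Adlercreutzia", "Olsenella"),
    Bacteroidetes = c("Bacteroides", "Prevotella", "Parabacteroides",
                      "Alistipes", "Odoribacter", "Butyricimonas",
                      "Barnesiella", "Paraprevotella", "Dysgonomonas",
                      "Tannerella"),
    Firmicutes = c("Streptococcus", "Veillonella", "Lactobacillus",
                   "Clostridium", "Blautia", "Ruminococcus",
                   "Faecalibacterium", "Roseburia", "Dorea", "Coprococcus",
                   "Eubacterium", "Anaerostipes", "Lachnospira",
                   "Oscillibacter", "Dialister", "Enterococcus",
                   "Lactococcus", "Erysipelatoclostridium", "Flavonifractor",
                   "Subdoligranulum", "Holdemanella", "Megasphaera",
                   "Phascolarctobacterium", "Romboutsia", "Intestinibacter",
                   "Hungatella", "Fusicatenibacter", "Turicibacter",
                   "Gemmiger", "Anaerotruncus", "Sellimonas",
                   "Christensenella"),
    Proteobacteria = c("Escherichia", "Klebsiella", "Enterobacter",
                       "Citrobacter", "Haemophilus", "Sutterella",
                       "Parasutterella", "Bilophila"),
    Verrucomicrobia = c("Akkermansia", "Victivallis")
  )
  purrr::imap_dfr(g, function(genera, phy) {
    tibble(feature_id = genera, kingdom = "Bacteria", phylum = phy,
           family = paste0(phy, "_family"), genus = genera)
  })
}

# Dominant-taxon profile of each planted community type. Community types are
# ordered roughly by developmental stage: Bifidobacterium/Proteobacteria
# dominated types early, diverse Firmicutes types late.
default_dominants <- function() {
  list(
    c(Bifidobacterium = 22, Escherichia = 6, Streptococcus = 3),
    c(Escherichia = 12, Klebsiella = 6, Enterococcus = 5, Streptococcus = 3),
    c(Bifidobacterium = 15, Bacteroides = 8, Veillonella = 4),
    c(Bacteroides = 15, Parabacteroides = 5, Bifidobacterium = 4),
    c(Streptococcus = 8, Veillonella = 7, Lactobacillus = 5, Dialister = 3,
      Akkermansia = 1.5),
    c(Blautia = 8, Dorea = 6, Anaerostipes = 4, Lachnospira = 3,
      Akkermansia = 3),
    c(Prevotella = 16, Faecalibacterium = 5, Coprococcus = 3),
    c(Faecalibacterium = 12, Roseburia = 7, Eubacterium = 5),
    c(Ruminococcus = 9, Oscillibacter = 6, Subdoligranulum = 5,
      Alistipes = 3),
    c(Akkermansia = 9, Coprococcus = 6, Blautia = 5, Hungatella = 3)
  )
}

#' Dirichlet parameters of the planted community types
#'
#' One row per community type, one column per panel genus: a small
#' background mass everywhere plus large parameters on each type's dominant
#' genera, giving well-separated overdispersed compositions.
#'
#' @param taxa Character vector of feature ids (default panel order).
#' @param background Background Dirichlet mass per genus.
#' @return K x length(taxa) positive matrix.
#' @export
default_component_alpha <- function(taxa = default_taxa_panel()$feature_id,
                                    background = 0.6) {
  doms <- default_dominants()
  alpha <- matrix(background, length(doms), length(taxa),
                  dimnames = list(NULL, taxa))
  for (k in seq_along(doms)) {
    alpha[k, names(doms[[k]])] <- alpha[k, names(doms[[k]])] + doms[[k]]
  }
  alpha
}

# Month-indexed target distribution over the K = 10 planted community
# types: linear interpolation between anchor mixes at months 3, 14 and 24,
# constant from month 24 on (the planted stable phase).
cluster_targets <- function(month, k = 10) {
  a3  <- c(.50, .30, .20, 0, 0, 0, 0, 0, 0, 0)
  a14 <- c(.05, .05, .30, .25, .20, .15, 0, 0, 0, 0)
  a24 <- c(0, 0, 0, 0, 0, 0, .10, .35, .35, .20)
  m <- pmin(pmax(month, 3), 24)
  t(vapply(m, function(mm) {
    if (mm <= 14) {
      w <- (mm - 3) / 11
      (1 - w) * a3 + w * a14
    } else {
      w <- (mm - 14) / 10
      (1 - w) * a14 + w * a24
    }
  }, numeric(k)))
}
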