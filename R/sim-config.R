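#' Configure the accordion genome-evolution simulator
#'
#' The simulator evolves a root genome along a phylogeny under the accordion
#' model: genome expansion (duplication, lateral gene transfer, mobile-element
#' insertion, orphan genesis) balanced by contraction (loss, mobile-element
#' excision), plus translocations that conserve copy number. Events per branch
#' are Poisson with mean `rate * branch_length` and are applied in uniform
#' random time order along the branch.
#'
#' @param rates Named numeric vector of per-unit-branch-length event rates.
#'   Names: `duplication`, `loss`, `lgt`, `mge_insertion`, `mge_excision`,
#'   `translocation`, `orphan_genesis`. Missing names default to 0.
#' @param initial_gene_count Number of genes in the root genome.
#' @param paralog_family_count Number of root multigene (paralogous) families;
#'   each starts with `paralog_family_size` copies.
#' @param paralog_family_size Copies per root paralogous family (default 4, so
#'   members have at least three additional representatives).
#' @param mge_family_count Number of root mobile-genetic-element families
#'   (two copies each, flagged `MGE`).
#' @param mean_gene_len Mean gene length in nucleotides.
#' @param intergenic_len Fixed intergenic spacer in nucleotides used to lay
#'   out coordinates.
#' @param marker_sub_rate Marker substitution rate (substitutions/site per
#'   unit branch length) under the Jukes-Cantor model.
#' @param marker_locus_len Aligned length of each marker locus.
#' @param marker_loci Names of the marker loci; defaults to the four
#'   taxonomic markers used for giant viruses (DNA polymerase, A2L
#'   transcription factor, D5 primase-helicase, packaging ATPase).
#' @param positional_bias Probability in `[0, 1]` that a duplication or loss
#'   targets the terminal 10% of coordinates at each genome end, emulating
#'   the variation hotspots at Mimiviridae genome extremities. 0 = uniform.
#' @param duplication_family_weights Optional named weights over family ids;
#'   when supplied, duplication targets are drawn family-wise with these
#'   weights (unlisted families share the residual weight uniformly). The
#'   default (`NULL`) picks a target gene uniformly, so large families attract
#'   proportionally more duplications.
#' @param donor_weights Named weights over donor-taxon labels for LGT genes.
#' @param identifiability Event-collision guard: `"none"` (default) allows
#'   repeated hits; `"branch"` forbids hitting the same family twice on one
#'   branch; `"tree"` forbids hitting the same family twice anywhere in the
#'   tree. `"tree"` is the regime in which terminal-branch parsimony
#'   inference is exact (see the methods vignette).
#' @param seed Integer seed; a fixed seed makes [simulate_accordion()] output
#'   byte-identical.
#'
#' @return An object of class `accordion_config` (a named list).
#' @export
accordion_config <- function(rates = c(duplication = 1, loss = 1),
                             initial_gene_count = 100,
                             paralog_family_count = 8,
                             paralog_family_size = 4,
                             mge_family_count = 3,
                             mean_gene_len = 900,
                             intergenic_len = 200,
                             marker_sub_rate = 0.05,
                             marker_locus_len = 1000,
                             marker_loci = c("DNA_polymerase",
                                             "A2L_transcription_factor",
                                             "D5_primase_helicase",
                                             "packaging_ATPase"),
                             positional_bias = 0,
                             duplication_family_weights = NULL,
                             donor_weights = c("Bacteria:Proteobacteria" = 0.35,
                                               "Bacteria:Cyanobacteria" = 0.15,
                                               "Bacteria:Firmicutes" = 0.10,
                                               "Eukaryota:host" = 0.25,
                                               "Eukaryota:other" = 0.10,
                                               "Virus:phage" = 0.05),
                             identifiability = c("none", "branch", "tree"),
                             seed = 1L) {
  all_rates <- setNames(numeric(length(RATE_NAMES)), RATE_NAMES)
  if (length(rates) > 0) {
    bad <- setdiff(names(rates), RATE_NAMES)
    if (length(bad) > 0) {
      abort(paste0("unknown event rate(s): ", paste(bad, collapse = ", ")),
            class = "gvaccordion_value_error")
    }
    all_rates[names(rates)] <- rates
  }
  if (any(all_rates < 0)) {
    abort("event rates must be non-negative",
          class = "gvaccordion_value_error")
  }
  if (positional_bias < 0 || positional_bias > 1) {
    abort("positional_bias must lie in [0, 1]",
          class = "gvaccordion_value_error")
  }
  stopifnot(initial_gene_count >= 1, mean_gene_len > 0, intergenic_len >= 0,
            marker_sub_rate >= 0, marker_locus_len >= 1,
            paralog_family_count >= 0, mge_family_count >= 0,
            paralog_family_size >= 2)
  if (paralog_family_count * paralog_family_size + 2 * mge_family_count >
      initial_gene_count) {
    abort("initial_gene_count too small for the requested family structure",
          class = "gvaccordion_value_error")
  }
  structure(list(
    rates = all_rates,
    initial_gene_count = as.integer(initial_gene_count),
    paralog_family_count = as.integer(paralog_family_count),
    paralog_family_size = as.integer(paralog_family_size),
    mge_family_count = as.integer(mge_family_count),
    mean_gene_len = mean_gene_len,
    intergenic_len = as.integer(intergenic_len),
    marker_sub_rate = marker_sub_rate,
    marker_locus_len = as.integer(marker_locus_len),
    marker_loci = marker_loci,
    positional_bias = positional_bias,
    duplication_family_weights = duplication_family_weights,
    donor_weights = donor_weights / sum(donor_weights),
    identifiability = match.arg(identifiability),
    seed = as.integer(seed)
  ), class = "accordion_config")
}

RATE_NAMES <- c("duplication", "loss", "lgt", "mge_insertion", "mge_excision",
                "translocation", "orphan_genesis")

# canonical EventRecord type for each rate name
RATE_TO_EVENT <- c(duplication = "duplication", loss = "loss", lgt = "lgt",
                   mge_insertion = "insertion", mge_excision = "excision",
                   translocation = "translocation", orphan_genesis = "orphan")

#' Simulator presets emulating the five giant-virus groups
#'
#' Rate ratios follow the qualitative group-specific patterns of the
#' published 21-genome comparison: mimivirus- and megavirus-like genomes are
#' dominated by duplication and loss within multigene families with strong
#' terminal positional bias; Ostreococcus- and Micromonas-virus-like genomes
#' gain genes mainly by lateral transfer and carry no mobile elements;
#' Chlorella-virus-like genomes mix duplication/loss with recurrent
#' mobile-element insertion and excision. Rates are per unit branch length
#' and scale group mean terminal-branch event counts to a branch of length 1;
#' the source data give no absolute rates per year.
#'
#' @param group_name One of `"mimivirus_like"`, `"megavirus_like"`,
#'   `"ostreococcus_like"`, `"micromonas_like"`, `"chlorella_like"`.
#' @param ... Overrides passed on to [accordion_config()].
#' @return An `accordion_config`.
#' @export
accordion_preset <- function(group_name, ...) {
  presets <- list(
    mimivirus_like = list(
      rates = c(duplication = 5.75, loss = 9.75, lgt = 0.75,
                mge_insertion = 1, mge_excision = 0.25,
                translocation = 3, orphan_genesis = 1.5),
      positional_bias = 0.8, initial_gene_count = 120,
      paralog_family_count = 10, mge_family_count = 2),
    megavirus_like = list(
      rates = c(duplication = 9, loss = 13, lgt = 0.5,
                mge_insertion = 1.75, mge_excision = 0.5,
                translocation = 0.25, orphan_genesis = 0.5),
      positional_bias = 0.8, initial_gene_count = 120,
      paralog_family_count = 10, mge_family_count = 2),
    ostreococcus_like = list(
      rates = c(duplication = 1.2, loss = 8, lgt = 9.2,
                mge_insertion = 0, mge_excision = 0,
                translocation = 0, orphan_genesis = 4),
      positional_bias = 0, initial_gene_count = 100,
      paralog_family_count = 4, mge_family_count = 0,
      marker_sub_rate = 0.15),
    micromonas_like = list(
      rates = c(duplication = 4.3, loss = 17.7, lgt = 8.3,
                mge_insertion = 0, mge_excision = 0,
                translocation = 0, orphan_genesis = 11.3),
      positional_bias = 0, initial_gene_count = 100,
      paralog_family_count = 4, mge_family_count = 0,
      marker_sub_rate = 0.2),
    chlorella_like = list(
      rates = c(duplication = 5.4, loss = 9.6, lgt = 1.4,
                mge_insertion = 2.8, mge_excision = 3.2,
                translocation = 0, orphan_genesis = 1.6),
      positional_bias = 0, initial_gene_count = 110,
      paralog_family_count = 8, mge_family_count = 4,
      marker_sub_rate = 0.06)
  )
  if (!is.character(group_name) || length(group_name) != 1 ||
      !group_name %in% names(presets)) {
    abort(paste0("unknown preset: ", paste(group_name, collapse = ", "),
                 "; choose one of ", paste(names(presets), collapse = ", ")),
          class = "gvaccordion_value_error")
  }
  args <- utils::modifyList(presets[[group_name]], list(...))
  do.call(accordion_config, args)
}
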