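#' Draw the genomic events occurring along one branch
#'
#' Event counts per type are Poisson with mean `rate * branch_length`
#' (constant-rate accumulation, the clock-like regime of the accordion
#' model); event times are uniform along the branch and events are returned
#' in time order. Targets and placements are not chosen here — they depend on
#' the genome state and are sampled when the event is applied.
#'
#' @param config An [accordion_config()].
#' @param branch_length Non-negative branch length.
#' @return Tibble with columns `event_type` (canonical vocabulary:
#'   duplication, lgt, insertion, loss, excision, translocation, orphan)
#'   and `t` (time along the branch), sorted by `t`.
#' @export
draw_branch_events <- function(config, branch_length) {
  stopifnot(inherits(config, "accordion_config"))
  if (!is.numeric(branch_length) || length(branch_length) != 1 ||
      is.na(branch_length) || branch_length < 0) {
    abort("branch_length must be a single non-negative number",
          class = "gvaccordion_domain_error")
  }
  counts <- rpois(length(config$rates), config$rates * branch_length)
  types <- rep(unname(RATE_TO_EVENT[names(config$rates)]), counts)
  if (length(types) == 0) {
    return(tibble(event_type = character(), t = numeric()))
  }
  tibble(event_type = types, t = runif(length(types)) * branch_length) |>
    arrange(.data$t)
}

# internal order-based view of a genome: genes in coordinate order with
# lengths instead of absolute coordinates
genome_order <- function(genome) {
  as_tibble(genome) |>
    mutate(len = .data$end - .data$start) |>
    select("gene_id", "family_id", "strand", "flags", "donor_taxon", "len")
}

# lay the gene order back onto coordinates with fixed intergenic spacers
order_to_genome <- function(ord, genome_id, group = "synthetic", gap = 200L) {
  n <- nrow(ord)
  if (n == 0) {
    return(genome_record(tibble(gene_id = character(), family_id = character(),
                                start = integer(), end = integer(),
                                strand = character()),
                         genome_id = genome_id, group = group,
                         size_kb = gap / 1000))
  }
  start <- gap + c(0L, cumsum(ord$len + gap))[seq_len(n)]
  genes <- ord |>
    mutate(start = as.integer(start), end = as.integer(start + .data$len)) |>
    select("gene_id", "family_id", "start", "end", "strand", "flags",
           "donor_taxon")
  genome_record(genes, genome_id = genome_id, group = group,
                size_kb = (max(genes$end) + gap) / 1000)
}

#' Apply a single genomic event to a genome
#'
#' Event semantics: a duplication adds one copy of an existing gene (adjacent
#' to a family member with probability 0.5, otherwise at a uniform random
#' position, unless `insert_at` pins the position); an LGT inserts a new
#' donor-labelled family; a mobile-element insertion adds an `MGE`-flagged
#' gene; a loss or excision removes one gene; a translocation moves a gene
#' without changing copy number; an orphan genesis inserts a family with no
#' homolog elsewhere. Coordinates of downstream genes shift accordingly
#' (genes are re-laid out with the intergenic spacer `gap`).
#'
#' When `event` carries full placement detail (`gene_id`, `source_gene_id`,
#' `insert_at`, `len`, `strand`, `donor_taxon` as applicable) the result is
#' deterministic — this is what makes an event log replayable; missing detail
#' is sampled from the current RNG.
#'
#' @param genome A [genome_record()].
#' @param event A list or one-row data frame with at least `event_type` and
#'   `family_id`.
#' @param gap Intergenic spacer in nucleotides used for re-layout.
#' @return The modified `genome_record`.
#' @export
apply_event <- function(genome, event, gap = 200L) {
  stopifnot(inherits(genome, "genome_record"))
  event <- as.list(event)
  type <- event$event_type
  if (!type %in% setdiff(EVENT_TYPES, "ambiguous")) {
    abort(paste0("unknown event type: ", type),
          class = "gvaccordion_value_error")
  }
  ord <- genome_order(genome)
  fam <- event$family_id
  members <- which(ord$family_id == fam)
  pick <- function(x) if (length(x) == 1) x else sample(x, 1)
  get_or <- function(name, default) {
    v <- event[[name]]
    if (is.null(v) || length(v) == 0 || is.na(v)) default else v
  }

  if (type %in% c("loss", "excision")) {
    if (length(members) == 0) {
      abort(sprintf("cannot apply %s: family %s has zero copies", type, fam),
            class = "gvaccordion_inapplicable_event_error")
    }
    gid <- get_or("gene_id", ord$gene_id[pick(members)])
    idx <- which(ord$gene_id == gid)
    if (length(idx) != 1) {
      abort(sprintf("gene %s not present", gid),
            class = "gvaccordion_inapplicable_event_error")
    }
    ord <- ord[-idx, ]
  } else if (type == "translocation") {
    if (length(members) == 0) {
      abort(sprintf("cannot translocate family %s: zero copies", fam),
            class = "gvaccordion_inapplicable_event_error")
    }
    gid <- get_or("gene_id", ord$gene_id[pick(members)])
    idx <- which(ord$gene_id == gid)
    row <- ord[idx, ]
    rest <- ord[-idx, ]
    at <- get_or("insert_at", pick(setdiff(seq_len(nrow(rest) + 1L), idx)))
    ord <- insert_row(rest, row, at)
  } else if (type == "duplication") {
    if (length(members) == 0) {
      abort(sprintf("cannot duplicate family %s: zero copies", fam),
            class = "gvaccordion_inapplicable_event_error")
    }
    src <- get_or("source_gene_id", ord$gene_id[pick(members)])
    src_idx <- which(ord$gene_id == src)
    row <- ord[src_idx, ]
    row$gene_id <- get_or("gene_id", new_gene_id(ord$gene_id, src))
    at <- get_or("insert_at",
                 if (runif(1) < 0.5) src_idx + 1L else pick(seq_len(nrow(ord) + 1L)))
    ord <- insert_row(ord, row, at)
  } else { # lgt, insertion, orphan: a brand-new gene
    flags <- switch(type, lgt = "donor_labelled", insertion = "MGE",
                    orphan = "orphan_candidate")
    donor <- if (type == "lgt") get_or("donor_taxon", "Bacteria:unknown")
             else NA_character_
    row <- tibble(gene_id = get_or("gene_id", new_gene_id(ord$gene_id, fam)),
                  family_id = fam,
                  strand = get_or("strand", sample(c("+", "-"), 1)),
                  flags = flags, donor_taxon = donor,
                  len = as.integer(get_or("len", 900L)))
    at <- get_or("insert_at", pick(seq_len(nrow(ord) + 1L)))
    ord <- insert_row(ord, row, at)
  }
  order_to_genome(ord, genome_id = genome_id(genome),
                  group = genome_group(genome), gap = gap)
}

insert_row <- function(ord, row, at) {
  stopifnot(at >= 1, at <= nrow(ord) + 1L)
  dplyr::bind_rows(ord[seq_len(at - 1L), ], row,
                   ord[seq(at, length.out = nrow(ord) - at + 1L), ])
}

new_gene_id <- function(existing, stem) {
  k <- 1L
  repeat {
    cand <- sprintf("%s.c%d", stem, k)
    if (!cand %in% existing) return(cand)
    k <- k + 1L
  }
}

#' Simulate genome evolution along a phylogeny under the accordion model
#'
#' Builds a root genome from the configured family structure, evolves it
#' along every branch of `tree` by drawing Poisson event counts and applying
#' events in time order, and simultaneously evolves a concatenated
#' four-marker nucleotide alignment site-independently under the
#' Jukes-Cantor model. The returned event log is ground truth: replaying it
#' from the root genome reproduces every tip genome exactly.
#'
#' @param config An [accordion_config()].
#' @param tree A rooted `phylo` with branch lengths and at least 2 tips.
#' @return A list of class `accordion_sim` with elements `genomes` (named
#'   list of [genome_record()] per tip), `root_genome`, `events` (truth log
#'   tibble; `branch` is the label of the edge's child node), `markers`
#'   (tip [marker_alignment()]), `root_markers` (root marker sequence),
#'   `tree` (with internal node labels filled in) and `config`.
#' @export
simulate_accordion <- function(config, tree) {
  stopifnot(inherits(config, "accordion_config"), inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2) {
    abort("tree must have at least 2 tips", class = "gvaccordion_value_error")
  }
  if (is.null(tree$edge.length)) {
    abort("tree must have branch lengths", class = "gvaccordion_value_error")
  }
  if (!ape::is.rooted(tree)) {
    abort("tree must be rooted", class = "gvaccordion_value_error")
  }
  set.seed(config$seed)
  tree <- label_nodes(tree)
  root <- make_root_genome(config)
  root_markers <- random_markers(config)

  state <- new.env(parent = emptyenv())
  state$gene_counter <- config$initial_gene_count
  state$fam_counter <- list(lgt = 0L, orphan = 0L, mge = config$mge_family_count)
  state$blocked_tree <- character() # identifiability = "tree"
  state$log <- list()
  state$genomes <- list()
  state$markers <- list()

  ntip <- ape::Ntip(tree)
  root_node <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  walk <- function(node, genome, markers) {
    for (e in children[[as.character(node)]]) {
      child <- tree$edge[e, 2]
      len <- tree$edge.length[e]
      label <- node_label(tree, child)
      res <- evolve_branch(genome, config, len, label, state)
      child_markers <- evolve_jc(markers, config$marker_sub_rate * len)
      if (child <= ntip) {
        gid <- tree$tip.label[child]
        g <- res
        attr(g, "genome_id") <- gid
        state$genomes[[gid]] <- g
        state$markers[[gid]] <- child_markers
      } else {
        walk(child, res, child_markers)
      }
    }
  }
  walk(root_node, root, root_markers)

  events <- if (length(state$log) == 0) empty_event_log() else
    dplyr::bind_rows(state$log)
  genomes <- state$genomes[tree$tip.label]
  markers <- marker_alignment(
    setNames(vapply(state$markers[tree$tip.label], paste0, character(1),
                    collapse = ""),
             tree$tip.label),
    loci = marker_loci_table(config))
  list(genomes = genomes, root_genome = root, events = events,
       markers = markers,
       root_markers = paste0(root_markers, collapse = ""),
       tree = tree, config = config) |>
    structure(class = "accordion_sim")
}

empty_event_log <- function() {
  tibble(branch = character(), t = numeric(), event_type = character(),
         family_id = character(), gene_id = character(),
         source_gene_id = character(), insert_at = integer(),
         len = integer(), strand = character(), donor_taxon = character(),
         position = integer(), family_size_before = integer(),
         in_paralog_family = logical())
}

label_nodes <- function(tree) {
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    tree$node.label <- sprintf("n%d", seq_len(tree$Nnode))
  }
  tree
}

node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) tree$tip.label[node] else tree$node.label[node - ntip]
}

make_root_genome <- function(config) {
  sizes <- c(rep(config$paralog_family_size, config$paralog_family_count),
             rep(2L, config$mge_family_count))
  n_single <- config$initial_gene_count - sum(sizes)
  fam_ids <- c(sprintf("P%03d", seq_len(config$paralog_family_count)),
               sprintf("MGE%03d", seq_len(config$mge_family_count)),
               sprintf("F%04d", seq_len(n_single)))
  fams <- rep(fam_ids, times = c(sizes, rep(1L, n_single)))
  flags <- ifelse(startsWith(fams, "MGE"), "MGE", "")
  ord <- tibble(
    gene_id = sprintf("g%04d", seq_along(fams)),
    family_id = fams, strand = sample(c("+", "-"), length(fams), replace = TRUE),
    flags = flags, donor_taxon = NA_character_,
    len = draw_gene_len(length(fams), config$mean_gene_len)
  )
  ord <- ord[sample.int(nrow(ord)), ] # scatter family copies along the genome
  order_to_genome(ord, genome_id = "root", gap = config$intergenic_len)
}

draw_gene_len <- function(n, mean_len) {
  pmax(300L, as.integer(round_half_up(rgamma(n, shape = 6, rate = 6 / mean_len))))
}

# evolve one genome along one branch, appending applied events to state$log
evolve_branch <- function(genome, config, len, branch_label, state) {
  ev <- draw_branch_events(config, len)
  blocked_branch <- character()
  for (i in seq_len(nrow(ev))) {
    blocked <- switch(config$identifiability,
                      none = character(),
                      branch = blocked_branch,
                      tree = state$blocked_tree)
    detail <- sample_event_detail(genome, ev$event_type[i], config, blocked,
                                  state)
    if (is.null(detail)) next # inapplicable in the current state: skipped
    genome_after <- apply_event(genome, detail, gap = config$intergenic_len)
    fam_before <- sum(genome$family_id == detail$family_id)
    pos <- event_position(genome, genome_after, detail)
    rec <- tibble(branch = branch_label, t = ev$t[i],
                  event_type = detail$event_type,
                  family_id = detail$family_id,
                  gene_id = detail$gene_id %||% NA_character_,
                  source_gene_id = detail$source_gene_id %||% NA_character_,
                  insert_at = as.integer(detail$insert_at %||% NA_integer_),
                  len = as.integer(detail$len %||% NA_integer_),
                  strand = detail$strand %||% NA_character_,
                  donor_taxon = detail$donor_taxon %||% NA_character_,
                  position = pos,
                  family_size_before = fam_before,
                  in_paralog_family = fam_before >= 4L)
    state$log <- c(state$log, list(rec))
    blocked_branch <- c(blocked_branch, detail$family_id)
    state$blocked_tree <- c(state$blocked_tree, detail$family_id)
    genome <- genome_after
  }
  genome
}

# midpoint coordinate of the locus targeted by the event: the source copy
# for duplications, the removed gene (before removal) for losses, the
# affected gene (after application) otherwise
event_position <- function(before, after, detail) {
  if (detail$event_type == "duplication") {
    idx <- which(after$gene_id == detail$source_gene_id)
    g <- after
  } else if (detail$event_type %in% c("loss", "excision")) {
    idx <- which(before$gene_id == detail$gene_id)
    g <- before
  } else {
    idx <- which(after$gene_id == detail$gene_id)
    g <- after
  }
  if (length(idx) == 1) {
    as.integer(round_half_up((g$start[idx] + g$end[idx]) / 2))
  } else NA_integer_
}

# choose target family / gene / placement for one event; NULL if inapplicable
sample_event_detail <- function(genome, type, config, blocked, state) {
  ord <- genome_order(genome)
  n <- nrow(ord)
  size_nt <- round_half_up(genome_size_kb(genome) * 1000)
  is_mge <- has_flag(ord$flags, "MGE")
  open <- !(ord$family_id %in% blocked)
  pick <- function(x) if (length(x) == 1) x else sample(x, 1)

  edge_idx <- function(cand) {
    if (config$positional_bias > 0 && runif(1) < config$positional_bias) {
      mid <- (genome$start[cand] + genome$end[cand]) / 2
      at_edge <- cand[mid < 0.1 * size_nt | mid > 0.9 * size_nt]
      if (length(at_edge) > 0) return(at_edge)
    }
    cand
  }

  if (type == "duplication") {
    cand <- which(!is_mge & open)
    if (length(cand) == 0) return(NULL)
    if (!is.null(config$duplication_family_weights)) {
      fams <- unique(ord$family_id[cand])
      w <- config$duplication_family_weights
      known <- intersect(names(w), fams)
      wts <- setNames(rep(max(0, 1 - sum(w[known])) /
                            max(1, length(setdiff(fams, known))),
                          length(fams)), fams)
      wts[known] <- w[known]
      fam <- if (length(fams) == 1) fams else sample(fams, 1, prob = wts)
      src_idx <- pick(intersect(cand, which(ord$family_id == fam)))
    } else {
      src_idx <- pick(edge_idx(cand))
    }
    src <- ord$gene_id[src_idx]
    state$gene_counter <- state$gene_counter + 1L
    list(event_type = type, family_id = ord$family_id[src_idx],
         source_gene_id = src,
         gene_id = sprintf("g%04d", state$gene_counter),
         insert_at = if (runif(1) < 0.5) src_idx + 1L else pick(seq_len(n + 1L)))
  } else if (type == "loss") {
    cand <- which(!is_mge & open)
    if (length(cand) == 0) return(NULL)
    idx <- pick(edge_idx(cand))
    list(event_type = type, family_id = ord$family_id[idx],
         gene_id = ord$gene_id[idx])
  } else if (type == "excision") {
    cand <- which(is_mge & open)
    if (length(cand) == 0) return(NULL)
    idx <- pick(cand)
    list(event_type = type, family_id = ord$family_id[idx],
         gene_id = ord$gene_id[idx])
  } else if (type == "translocation") {
    single <- names(which(table(ord$family_id) == 1))
    cand <- which(ord$family_id %in% single & !is_mge & open)
    if (length(cand) == 0 || n < 2) return(NULL)
    idx <- pick(cand)
    list(event_type = type, family_id = ord$family_id[idx],
         gene_id = ord$gene_id[idx],
         insert_at = pick(setdiff(seq_len(n), idx)))
  } else if (type %in% c("lgt", "orphan", "insertion")) {
    state$gene_counter <- state$gene_counter + 1L
    fam <- if (type == "lgt") {
      state$fam_counter$lgt <- state$fam_counter$lgt + 1L
      sprintf("L%04d", state$fam_counter$lgt)
    } else if (type == "orphan") {
      state$fam_counter$orphan <- state$fam_counter$orphan + 1L
      sprintf("O%04d", state$fam_counter$orphan)
    } else {
      # re-insertion of a resident MGE family raises its copy number, which
      # copy-number parsimony reads as a duplication; in the identifiability
      # modes insertions therefore always found a new family
      mge_fams <- setdiff(unique(ord$family_id[is_mge]), blocked)
      if (config$identifiability == "none" && length(mge_fams) > 0 &&
          runif(1) < 0.5) {
        pick(mge_fams)
      } else {
        state$fam_counter$mge <- state$fam_counter$mge + 1L
        sprintf("MGE%03d", state$fam_counter$mge)
      }
    }
    list(event_type = type, family_id = fam,
         gene_id = sprintf("g%04d", state$gene_counter),
         len = draw_gene_len(1L, config$mean_gene_len),
         strand = sample(c("+", "-"), 1),
         donor_taxon = if (type == "lgt") {
           sample(names(config$donor_weights), 1, prob = config$donor_weights)
         } else NA_character_,
         insert_at = pick(seq_len(n + 1L)))
  }
}

#' Replay an event log from the root genome
#'
#' Applies the logged events for the given branches, in log order, starting
#' from `root_genome`. With the branches on the root-to-tip path this
#' reconstructs the tip genome exactly (the simulator's ground-truth
#' invariant).
#'
#' @param root_genome The simulator's root [genome_record()].
#' @param events Truth-log tibble from [simulate_accordion()].
#' @param branches Character vector of branch labels (child-node labels) in
#'   root-to-tip order.
#' @param gap Intergenic spacer used at simulation time.
#' @param genome_id Optional id for the reconstructed genome (defaults to the
#'   last branch label, i.e. the tip being rebuilt).
#' @return A `genome_record`.
#' @export
replay_events <- function(root_genome, events, branches, gap = 200L,
                          genome_id = NULL) {
  g <- root_genome
  for (b in branches) {
    ev <- events |> filter(.data$branch == b) |> arrange(.data$t)
    for (i in seq_len(nrow(ev))) {
      g <- apply_event(g, ev[i, ], gap = gap)
    }
  }
  attr(g, "genome_id") <- genome_id %||%
    (if (length(branches)) branches[[length(branches)]]
     else attr(root_genome, "genome_id"))
  g
}

#' @rdname replay_events
#' @param tree Labelled tree from an `accordion_sim`.
#' @param tip Tip label to reconstruct.
#' @return `path_to_tip()` returns the child-node labels on the root-to-tip
#'   path.
#' @export
path_to_tip <- function(tree, tip) {
  ntip <- ape::Ntip(tree)
  node <- match(tip, tree$tip.label)
  if (is.na(node)) {
    abort(paste0("tip not in tree: ", tip), class = "gvaccordion_value_error")
  }
  path <- character()
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0) break
    path <- c(node_label(tree, node), path)
    node <- tree$edge[e, 1]
  }
  path
}

# --- marker evolution -------------------------------------------------------

DNA_BASES <- c("A", "C", "G", "T")

random_markers <- function(config) {
  setNames(
    vapply(seq_along(config$marker_loci), function(i) {
      paste0(sample(DNA_BASES, config$marker_locus_len, replace = TRUE),
             collapse = "")
    }, character(1)),
    config$marker_loci)
}

marker_loci_table <- function(config) {
  L <- config$marker_locus_len
  k <- length(config$marker_loci)
  tibble(locus = config$marker_loci,
         start = (seq_len(k) - 1L) * L + 1L,
         end = seq_len(k) * L)
}

# Jukes-Cantor evolution of a set of locus sequences over distance d
# (expected substitutions/site); P(site differs) = 3/4 (1 - exp(-4 d / 3))
evolve_jc <- function(loci, d) {
  if (d <= 0) return(loci)
  p_diff <- 0.75 * (1 - exp(-4 * d / 3))
  vapply(loci, function(s) {
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(x)) < p_diff)
    if (length(hit) > 0) {
      x[hit] <- vapply(x[hit], function(b) sample(setdiff(DNA_BASES, b), 1),
                       character(1))
    }
    paste0(x, collapse = "")
  }, character(1))
}
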