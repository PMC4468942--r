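#' Build a family-by-genome copy-number matrix
#'
#' @param genomes Named list of [genome_record()]s sharing a family-label
#'   namespace (names are genome ids; unnamed lists use each record's own
#'   id).
#' @param max_copy Upper bound on copy numbers tolerated downstream; counts
#'   above it raise an error (default 20).
#' @return An integer matrix (class `copy_matrix`) with families as rows and
#'   genomes as columns, and a `meta` attribute tibble carrying per-family
#'   flags (`mge`, `donor_labelled`, `orphan_candidate`, majority rule over
#'   gene flags) and the modal `donor_taxon`.
#' @export
build_copy_matrix <- function(genomes, max_copy = 20L) {
  if (length(genomes) == 0) {
    abort("need at least one genome", class = "gvaccordion_value_error")
  }
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, genome_id, character(1))
  }
  long <- purrr::imap_dfr(genomes, function(g, id) {
    as_tibble(g) |> mutate(genome_id = id)
  })
  fams <- sort(unique(long$family_id))
  counts <- table(factor(long$family_id, levels = fams),
                  factor(long$genome_id, levels = names(genomes)))
  counts <- matrix(as.integer(counts), nrow = length(fams),
                   dimnames = list(fams, names(genomes)))
  if (any(counts > max_copy)) {
    abort(sprintf("copy number exceeds max_copy = %d", max_copy),
          class = "gvaccordion_value_error")
  }
  meta <- long |>
    group_by(.data$family_id) |>
    summarise(
      mge = mean(has_flag(.data$flags, "MGE")) > 0.5,
      donor_labelled = mean(has_flag(.data$flags, "donor_labelled")) > 0.5,
      orphan_candidate = mean(has_flag(.data$flags, "orphan_candidate")) > 0.5,
      donor_taxon = modal_value(.data$donor_taxon),
      mixed = dplyr::n_distinct(.data$flags) > 1,
      .groups = "drop")
  if (any(meta$mixed)) {
    warn(paste0("families with conflicting gene flags (majority rule): ",
                paste(meta$family_id[meta$mixed], collapse = ", ")))
  }
  meta <- meta |> select(-"mixed") |> arrange(.data$family_id)
  structure(counts, meta = meta, class = c("copy_matrix", "matrix", "array"))
}

modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  names(sort(table(x), decreasing = TRUE))[1]
}

#' @rdname build_copy_matrix
#' @param x A `copy_matrix`.
#' @export
copy_matrix_meta <- function(x) attr(x, "meta")

#' @exportS3Method generics::tidy
tidy.copy_matrix <- function(x, ...) {
  as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    setNames(c("family_id", "genome_id", "copies")) |>
    mutate(copies = as.integer(.data$copies)) |>
    left_join(copy_matrix_meta(x), by = "family_id")
}

#' Most-parsimonious copy-number scenarios for one family
#'
#' Runs a Sankoff-style dynamic program over ancestral copy-number states
#' `0..max_copy` with per-branch cost `|child - parent|` (each unit of copy
#' change is one event) on a rooted tree, then: the global minimum cost, the
#' exact number of co-optimal ancestral labelings (second DP pass), the set
#' of states each internal node takes in at least one co-optimal labeling,
#' and — per terminal branch — the set of signed copy-number changes across
#' all co-optimal labelings. A terminal branch is `ambiguous` when the
#' co-optimal labelings disagree on its change, the operational reading of
#' the equal-parsimony rule: genes whose scenarios tie are marked ambiguous
#' rather than typed.
#'
#' @param profile Named integer vector of copy numbers, one per tree tip.
#' @param tree Rooted `phylo`.
#' @param max_copy Cap on the ancestral state space.
#' @return List of class `scenario_set`: `min_cost`, `n_labelings`,
#'   `terminal_changes` (named list, tip -> sorted unique signed changes),
#'   `ambiguous` (named logical), `node_states` (named list of optimal state
#'   sets for internal nodes), `root_states`.
#' @export
min_cost_scenarios <- function(profile, tree, max_copy = 20L) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    abort("tree must be rooted", class = "gvaccordion_value_error")
  }
  tree <- label_nodes(tree)
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, names(profile))
  if (length(missing_tips) > 0) {
    abort(paste0("profile missing tip(s): ",
                 paste(missing_tips, collapse = ", ")),
          class = "gvaccordion_value_error")
  }
  profile <- as.integer(profile[tips])
  if (any(is.na(profile)) || any(profile < 0)) {
    abort("copy numbers must be non-negative integers",
          class = "gvaccordion_value_error")
  }
  if (any(profile > max_copy)) {
    abort(sprintf("copy number exceeds max_copy = %d", max_copy),
          class = "gvaccordion_value_error")
  }
  # with linear cost every optimal labeling lies within the observed range,
  # so the state space can be truncated at max(profile) without changing
  # either the optimum or the co-optimal count
  S <- min(max_copy, max(profile)) + 1L # states 0 .. S-1
  states <- 0:(S - 1L)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  INF <- .Machine$double.xmax / 4

  # below[v, s]: min cost of subtree of v given v has state s
  # nlab[v, s]: number of co-optimal labelings of the subtree below v
  below <- matrix(0, nnode, S)
  nlab <- matrix(1, nnode, S)
  for (i in seq_len(ntip)) {
    below[i, ] <- ifelse(states == profile[i], 0, INF)
  }
  cost_step <- abs(outer(states, states, "-")) # [parent, child]
  for (i in seq_len(nrow(edges))) {
    parent <- edges[i, 1]; child <- edges[i, 2]
    tot <- sweep(cost_step, 2, below[child, ], "+") # [s_par, s_child]
    best <- apply(tot, 1, min)
    cnt <- vapply(seq_len(S), function(s) {
      sum(nlab[child, tot[s, ] == best[s]])
    }, numeric(1))
    below[parent, ] <- below[parent, ] + best
    nlab[parent, ] <- nlab[parent, ] * cnt
  }
  min_cost <- min(below[root, ])
  root_opt <- states[below[root, ] == min_cost]
  n_labelings <- sum(nlab[root, below[root, ] == min_cost])

  # above[v, s]: min cost of everything outside the subtree of v, given v = s.
  # A state s at node v occurs in some co-optimal labeling iff
  # above[v, s] + below[v, s] == min_cost.
  above <- matrix(INF, nnode, S)
  above[root, ] <- 0
  pre <- edges[rev(seq_len(nrow(edges))), , drop = FALSE]
  child_list <- split(edges[, 2], edges[, 1])
  for (i in seq_len(nrow(pre))) {
    parent <- pre[i, 1]; child <- pre[i, 2]
    sibs <- setdiff(child_list[[as.character(parent)]], child)
    par_score <- above[parent, ]
    for (sb in sibs) {
      par_score <- par_score +
        apply(sweep(cost_step, 2, below[sb, ], "+"), 1, min)
    }
    above[child, ] <- vapply(seq_len(S), function(sc) {
      min(par_score + cost_step[, sc])
    }, numeric(1))
  }
  opt_states <- lapply(seq_len(nnode), function(v) {
    states[above[v, ] + below[v, ] <= min_cost + 1e-9]
  })
  internal_ids <- vapply((ntip + 1L):nnode, function(v) node_label(tree, v),
                         character(1))
  parent_of <- setNames(edges[, 1], edges[, 2])
  terminal_changes <- lapply(seq_len(ntip), function(i) {
    sort(unique(profile[i] - opt_states[[parent_of[[as.character(i)]]]]))
  })
  names(terminal_changes) <- tips
  structure(list(
    min_cost = as.integer(min_cost),
    n_labelings = n_labelings,
    terminal_changes = terminal_changes,
    ambiguous = vapply(terminal_changes, function(x) length(x) > 1, logical(1)),
    node_states = setNames(opt_states[(ntip + 1L):nnode], internal_ids),
    root_states = root_opt
  ), class = "scenario_set")
}

#' Classify genomic events on terminal branches
#'
#' For every family, finds the most-parsimonious copy-number scenarios on
#' the tree and classifies the signed change on each terminal branch:
#' a gain with at least one parental copy is a `duplication`; a gain from
#' zero parental copies is an `insertion` for MGE families, an `lgt` for
#' donor-labelled families, an `orphan` for orphan-candidate families, and
#' `ambiguous` (unknown origin) otherwise; a reduction is an `excision` for
#' MGE families and a `loss` otherwise. Families whose co-optimal labelings
#' disagree on a terminal branch yield a single `ambiguous` record for that
#' branch. One record is emitted per unit of copy change. Events on internal
#' branches are not emitted here (the published per-virus tables count
#' terminal branches only); use the `scenarios` element for ancestral
#' states.
#'
#' @param matrix A [build_copy_matrix()] result.
#' @param tree Rooted `phylo` whose tips are the matrix's genomes.
#' @param genomes Optional named list of [genome_record()]s used to attach
#'   nucleotide positions (coordinate of a family member in the tip genome)
#'   to gain events.
#' @param max_copy State-space cap passed to [min_cost_scenarios()].
#' @return Tibble of event records: `branch` (tip), `event_type`,
#'   `family_id`, `position`, `copies_tip`, `copies_parent`, `delta`,
#'   `in_paralog_family` (family has >= 3 additional members in that
#'   genome).
#' @export
classify_terminal_events <- function(matrix, tree, genomes = NULL,
                                     max_copy = 20L) {
  stopifnot(inherits(matrix, "copy_matrix"))
  tips <- tree$tip.label
  if (!setequal(colnames(matrix), tips)) {
    abort("matrix genomes and tree tips disagree",
          class = "gvaccordion_value_error")
  }
  meta <- copy_matrix_meta(matrix)
  counts <- unclass(matrix)[, tips, drop = FALSE]
  # families sharing a profile share the same DP
  key <- apply(counts, 1, paste, collapse = ",")
  sc_by_key <- lapply(split(seq_len(nrow(counts)), key)[unique(key)],
                      function(rows) {
    min_cost_scenarios(setNames(counts[rows[1], ], tips), tree,
                       max_copy = max_copy)
  })
  recs <- list()
  for (f in seq_len(nrow(counts))) {
    fam <- rownames(counts)[f]
    sc <- sc_by_key[[key[f]]]
    fmeta <- meta[meta$family_id == fam, ]
    for (tip in tips) {
      deltas <- sc$terminal_changes[[tip]]
      if (length(deltas) > 1) {
        recs[[length(recs) + 1L]] <-
          event_rec(tip, "ambiguous", fam, NA_integer_,
                    counts[f, tip], NA_integer_, NA_integer_, FALSE)
        next
      }
      delta <- deltas[[1]]
      if (delta == 0) next
      tip_count <- counts[f, tip]
      parent <- tip_count - delta
      type <- if (delta > 0) {
        if (parent >= 1) "duplication"
        else if (fmeta$mge) "insertion"
        else if (fmeta$donor_labelled) "lgt"
        else if (fmeta$orphan_candidate) "orphan"
        else "ambiguous" # gained from zero with homologs elsewhere: unknown origin
      } else {
        if (fmeta$mge) "excision" else "loss"
      }
      pos <- event_tip_position(genomes, tip, fam)
      in_paralog <- if (delta > 0) tip_count >= 4L else parent >= 4L
      for (k in seq_len(abs(delta))) {
        recs[[length(recs) + 1L]] <-
          event_rec(tip, type, fam, pos, tip_count, parent, delta, in_paralog)
      }
    }
  }
  events <- if (length(recs) == 0) {
    tibble(branch = character(), event_type = character(),
           family_id = character(), position = integer(),
           copies_tip = integer(), copies_parent = integer(),
           delta = integer(), in_paralog_family = logical())
  } else bind_rows(recs)
  attr(events, "scenarios") <- sc_by_key
  events
}

event_rec <- function(branch, type, fam, pos, tip_count, parent, delta,
                      in_paralog) {
  tibble(branch = branch, event_type = type, family_id = fam,
         position = as.integer(pos), copies_tip = as.integer(tip_count),
         copies_parent = as.integer(parent), delta = as.integer(delta),
         in_paralog_family = in_paralog)
}

event_tip_position <- function(genomes, tip, fam) {
  if (is.null(genomes) || is.null(genomes[[tip]])) return(NA_integer_)
  g <- genomes[[tip]]
  idx <- which(g$family_id == fam)
  if (length(idx) == 0) return(NA_integer_)
  as.integer(g$start[idx[1]])
}

#' Summarise terminal-branch events per genome
#'
#' Aggregates classified events into the per-virus summary schema: counts of
#' duplications, LGTs, MGE insertions, losses, excisions and translocations,
#' the derived totals, and the unknown/ambiguous class (orphans are reported
#' both inside `unknown` and as the `orphan` subset — an orphan has no
#' homolog to polarise its origin, so it is never counted as a gain).
#' The accounting identities hold by construction.
#'
#' @param events Event tibble from [classify_terminal_events()] (optionally
#'   with translocation records appended).
#' @param genomes Named list of [genome_record()]s (for size and group).
#' @param identities Optional tibble from [ancestor_identity()]; absent
#'   identities are reported as `NA`.
#' @return Tibble with one row per genome in the summary-table schema.
#' @export
summarize_terminal_events <- function(events, genomes, identities = NULL) {
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, genome_id, character(1))
  }
  per_type <- events |>
    count(.data$branch, .data$event_type) |>
    tidyr::pivot_wider(names_from = "event_type", values_from = "n",
                       values_fill = 0L)
  for (t in EVENT_TYPES) {
    if (!t %in% names(per_type)) per_type[[t]] <- 0L
  }
  rows <- tibble(
    genome_id = names(genomes),
    group = vapply(genomes, genome_group, character(1)),
    size_kb = vapply(genomes, genome_size_kb, numeric(1))
  ) |>
    left_join(per_type, by = c(genome_id = "branch")) |>
    mutate(across(dplyr::all_of(EVENT_TYPES),
                  ~ as.integer(dplyr::coalesce(.x, 0L)))) |>
    mutate(
      total_gain = .data$duplication + .data$lgt + .data$insertion,
      total_loss = .data$loss + .data$excision,
      unknown = .data$ambiguous + .data$orphan,
      genomic_events = .data$total_gain + .data$total_loss + .data$unknown +
        .data$translocation
    ) |>
    select(-"ambiguous")
  ids <- if (is.null(identities)) {
    tibble(genome_id = names(genomes), identity_ancestor_pct = NA_real_)
  } else identities
  rows |>
    left_join(ids, by = "genome_id") |>
    select("genome_id", "group", "identity_ancestor_pct", "size_kb",
           "duplication", "lgt", "insertion", "total_gain", "loss",
           "excision", "total_loss", "unknown", "orphan", "translocation",
           "genomic_events")
}
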