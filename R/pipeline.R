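#' Attribute translocations (and positional ties) across a genome set
#'
#' Pairwise anchor-chain analysis generalised to many genomes: a family
#' single-copy in all genomes that falls outside every maximum collinear
#' chain in each comparison involving genome `g` — and is collinear in the
#' comparisons not involving `g` — is called a translocation on `g`'s
#' terminal branch. Families that are only tied out of the chain (an
#' adjacent swap cannot tell which of the two genes moved) are reported as
#' `ambiguous` rather than typed.
#'
#' @param genomes Named list of [genome_record()]s (>= 2).
#' @return Event tibble with `event_type` `"translocation"` or
#'   `"ambiguous"`, matching the [classify_terminal_events()] schema.
#' @export
infer_translocations <- function(genomes) {
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, genome_id, character(1))
  }
  ids <- names(genomes)
  n <- length(ids)
  if (n < 2) {
    abort("need at least 2 genomes", class = "gvaccordion_value_error")
  }
  # per pair: which anchored families deviate from the maximum chains, and how
  pair_tbl <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      anc <- anchor_genes(genomes[[ids[i]]], genomes[[ids[j]]])
      if (nrow(anc) == 0) next
      pair_tbl[[length(pair_tbl) + 1L]] <-
        tibble(a = ids[i], b = ids[j], family_id = anc$family_id,
               status = anchor_chain_status(anc))
    }
  }
  if (length(pair_tbl) == 0) return(empty_event_records())
  pairs <- bind_rows(pair_tbl)
  recs <- list()
  push <- function(g, type, fam) {
    recs[[length(recs) + 1L]] <<-
      event_rec(g, type, fam, event_tip_position(genomes, g, fam),
                1L, if (type == "translocation") 1L else NA,
                if (type == "translocation") 0L else NA, FALSE)
  }
  for (fam in unique(pairs$family_id[pairs$status != "in_all"])) {
    fp <- pairs[pairs$family_id == fam, ]
    anom <- fp[fp$status != "in_all", ]
    # the culprit genome(s): present in every anomalous comparison
    cand <- Reduce(intersect, lapply(seq_len(nrow(anom)),
                                     function(k) c(anom$a[k], anom$b[k])))
    if (length(cand) == 0) {
      # conflicting evidence: flag the most-implicated genome(s) as ambiguous
      counts <- table(c(anom$a, anom$b))
      for (g in names(counts)[counts == max(counts)]) push(g, "ambiguous", fam)
      next
    }
    for (g in cand) {
      n_pairs_g <- sum(fp$a == g | fp$b == g)
      clear_move <- all(anom$status == "in_none") && nrow(anom) == n_pairs_g
      push(g, if (clear_move) "translocation" else "ambiguous", fam)
    }
  }
  if (length(recs) == 0) empty_event_records() else bind_rows(recs)
}

empty_event_records <- function() {
  tibble(branch = character(), event_type = character(),
         family_id = character(), position = integer(),
         copies_tip = integer(), copies_parent = integer(),
         delta = integer(), in_paralog_family = logical())
}

#' Run the accordion comparative-genomics pipeline
#'
#' End to end: copy-number matrix, whole-genome tree (neighbor joining on
#' the gene-content/marker distance, rooted on `outgroup`, unless a rooted
#' tree is supplied), terminal-branch event classification by copy-number
#' parsimony, synteny-based translocation attribution, marker identity to
#' the reconstructed group ancestor, the per-genome summary table, and the
#' events-per-kb clock regression. Each stage reports its counts via
#' messages (suppress with [suppressMessages()]).
#'
#' @param genomes Named list of [genome_record()]s.
#' @param markers Optional [marker_alignment()] over the same genomes.
#' @param tree Optional rooted `phylo`; inferred when `NULL`.
#' @param outgroup Outgroup id for tree rooting when `tree` is `NULL`.
#' @param max_copy Copy-number cap for the parsimony state space.
#' @param alpha Gene-content weight in [gene_content_distance()].
#' @param marker_rate Branch-length scale for [reconstruct_root()].
#' @param translocations Whether to run synteny-based translocation
#'   attribution (needs >= 3 genomes to polarise).
#' @return List of class `accordion_result`: `summary`, `events`, `matrix`,
#'   `tree`, `identities`, `regression` (a [fit_clock_regression()] result
#'   or `NULL` when identities are unavailable or constant).
#' @export
run_accordion_pipeline <- function(genomes, markers = NULL, tree = NULL,
                                   outgroup = NULL, max_copy = 20L,
                                   alpha = 0.5, marker_rate = 1,
                                   translocations = TRUE) {
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, genome_id, character(1))
  }
  mat <- build_copy_matrix(genomes, max_copy = max_copy)
  rlang::inform(sprintf("copy matrix: %d families x %d genomes",
                        nrow(mat), ncol(mat)))
  if (is.null(tree)) {
    if (is.null(outgroup)) {
      abort("no tree supplied and no outgroup to root one: build_rooted_tree needs an outgroup",
            class = "gvaccordion_value_error")
    }
    d <- gene_content_distance(mat, markers = markers, alpha = alpha)
    tree <- build_rooted_tree(d, outgroup)
    rlang::inform(sprintf("tree: neighbor joining on %d taxa, rooted on %s",
                          ncol(d), outgroup))
  }
  tree <- label_nodes(tree)
  events <- classify_terminal_events(mat, tree, genomes = genomes,
                                     max_copy = max_copy)
  rlang::inform(sprintf("parsimony: %d terminal-branch event records",
                        nrow(events)))
  if (translocations && length(genomes) >= 3) {
    tr <- infer_translocations(genomes)
    rlang::inform(sprintf("synteny: %d translocation/tie records", nrow(tr)))
    scen <- attr(events, "scenarios")
    events <- bind_rows(events, tr)
    attr(events, "scenarios") <- scen
  }
  identities <- if (!is.null(markers)) {
    ancestor_identity(markers, tree, rate = marker_rate)
  } else NULL
  summary <- summarize_terminal_events(events, genomes, identities)
  rlang::inform(sprintf("summary: %d genomes, %d genomic events",
                        nrow(summary), sum(summary$genomic_events)))
  regression <- NULL
  if (!is.null(identities) && nrow(summary) >= 3 &&
      length(unique(summary$identity_ancestor_pct)) >= 2) {
    regression <- fit_clock_regression(summary)
    rlang::inform(sprintf("clock regression: r^2 = %.3f", regression$r_squared))
  }
  structure(list(summary = summary, events = events, matrix = mat,
                 tree = tree, identities = identities,
                 regression = regression),
            class = "accordion_result")
}

#' @export
print.accordion_result <- function(x, ...) {
  cat(sprintf("<accordion_result> %d genomes, %d event records\n",
              nrow(x$summary), nrow(x$events)))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.accordion_result <- function(x, ...) as_tibble(x$events)

#' @exportS3Method generics::glance
glance.accordion_result <- function(x, ...) {
  tot <- aggregate_summary(x$summary)
  tot$r_squared <- if (is.null(x$regression)) NA_real_ else
    x$regression$r_squared
  tot
}

#' Reproduce the published 21-genome analysis surface
#'
#' Recomputes, from the bundled per-virus table (or any table in the same
#' schema), the column totals, the events-per-kb clock regression, and the
#' per-group mobile-element fractions. Nothing is transcribed from the
#' published totals row; every number is recomputed from the per-row values.
#'
#' @param path Summary TSV path; defaults to the bundled table.
#' @return List of class `table1_reproduction`: `rows`, `totals`,
#'   `regression` (a `clock_fit`), `group_mge` (tibble of per-group
#'   mobile-element percentages, full precision and rounded).
#' @export
reproduce_table1 <- function(path = table1_path()) {
  rows <- read_summary_table(path)
  totals <- aggregate_summary(rows)
  fit <- fit_clock_regression(rows)
  groups <- unique(rows$group)
  group_mge <- tibble(
    group = groups,
    mge_pct = vapply(groups, function(g) group_mge_fraction(rows, g),
                     numeric(1))
  ) |>
    mutate(mge_pct_rounded = as.integer(round_half_up(.data$mge_pct)))
  structure(list(rows = rows, totals = totals, regression = fit,
                 group_mge = group_mge),
            class = "table1_reproduction")
}

#' @export
print.table1_reproduction <- function(x, ...) {
  cat("Per-virus event totals (recomputed):\n")
  print(as.data.frame(x$totals), row.names = FALSE)
  print(x$regression)
  cat("Mobile-element fraction of events by group (%):\n")
  print(as.data.frame(x$group_mge), row.names = FALSE)
  invisible(x)
}

#' Genomic event map in the style of per-genome mutation tracks
#'
#' Gains (duplication, LGT, insertion) are drawn above each genome line and
#' losses (loss, excision) below; translocations and ambiguous records sit
#' on the line. Events without positions are dropped from the plot.
#'
#' @param events Event tibble with `branch`, `event_type`, `position`.
#' @param genomes Named list of [genome_record()]s supplying genome lengths.
#' @return A ggplot object.
#' @export
plot_event_map <- function(events, genomes) {
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, genome_id, character(1))
  }
  sizes <- tibble(branch = names(genomes),
                  size_nt = vapply(genomes, function(g) {
                    round_half_up(genome_size_kb(g) * 1000)
                  }, numeric(1)))
  dat <- events |>
    filter(!is.na(.data$position)) |>
    mutate(side = dplyr::case_when(
      .data$event_type %in% c("duplication", "lgt", "insertion", "orphan") ~ 1,
      .data$event_type %in% c("loss", "excision") ~ -1,
      TRUE ~ 0))
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(data = sizes,
                          ggplot2::aes(x = 0, xend = .data$size_nt / 1000,
                                       y = 0, yend = 0),
                          linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(x = .data$position / 1000,
                                     y = 0.4 * .data$side,
                                     colour = .data$event_type,
                                     shape = .data$event_type),
                        size = 2) +
    ggplot2::facet_wrap(~branch, ncol = 1, strip.position = "left") +
    ggplot2::scale_y_continuous(limits = c(-1, 1), breaks = NULL) +
    ggplot2::labs(x = "position (kb)", y = NULL,
                  title = "Genomic events along each genome") +
    ggplot2::theme_minimal()
}
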