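#' Read a per-virus genomic-event summary table
#'
#' Reads the TSV schema used for per-virus event summaries: one row per
#' genome with the marker identity to the group ancestor, genome size, and
#' counts of each event class on the terminal branch. Every row is checked
#' against the accounting identities
#' `total_gain = duplication + lgt + insertion`,
#' `total_loss = loss + excision`, and
#' `genomic_events = total_gain + total_loss + unknown + translocation`
#' (orphans are a subset of the unknown/ambiguous class, not of the gains).
#'
#' @param path Path to a summary TSV. Defaults to the bundled transcription of
#'   the published 21-genome giant-virus table.
#' @return A tibble with one row per genome.
#' @export
read_summary_table <- function(path = table1_path()) {
  rows <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            virus_name = readr::col_character(),
                            accession = readr::col_character(),
                            group = readr::col_character(),
                            .default = readr::col_double()
                          ))
  validate_summary_rows(rows)
  rows
}

#' @rdname read_summary_table
#' @export
table1_path <- function() {
  system.file("extdata", "table1.tsv", package = "gvaccordion",
              mustWork = TRUE)
}

count_cols <- c("duplication", "lgt", "insertion", "total_gain", "loss",
                "excision", "total_loss", "unknown", "orphan",
                "translocation", "genomic_events")

#' Validate summary-row accounting identities
#'
#' @param rows Summary tibble as returned by [read_summary_table()] or
#'   [summarize_terminal_events()].
#' @return `rows`, invisibly, if all identities hold; otherwise an error
#'   naming the first offending row.
#' @export
validate_summary_rows <- function(rows) {
  needed <- c("identity_ancestor_pct", "size_kb", count_cols)
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols) > 0) {
    abort(paste0("missing summary column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gvaccordion_format_error")
  }
  counts <- rows[setdiff(count_cols, "orphan")]
  if (any(vapply(counts, function(x) any(x < 0 | x != floor(x)), logical(1)))) {
    abort("event counts must be non-negative integers",
          class = "gvaccordion_consistency_error")
  }
  label <- if ("virus_name" %in% names(rows)) rows$virus_name else
    if ("genome_id" %in% names(rows)) rows$genome_id else as.character(seq_len(nrow(rows)))
  bad_gain <- which(rows$total_gain != rows$duplication + rows$lgt + rows$insertion)
  bad_loss <- which(rows$total_loss != rows$loss + rows$excision)
  bad_tot <- which(rows$genomic_events !=
                     rows$total_gain + rows$total_loss + rows$unknown + rows$translocation)
  bad_orphan <- which(!is.na(rows$orphan) & rows$orphan > rows$unknown)
  for (bad in list(bad_gain, bad_loss, bad_tot, bad_orphan)) {
    if (length(bad) > 0) {
      abort(sprintf("summary accounting identity violated in row '%s'",
                    label[bad[1]]),
            class = "gvaccordion_consistency_error")
    }
  }
  ids <- rows$identity_ancestor_pct
  if (any(!is.na(ids) & (ids < 0 | ids > 100))) {
    abort("identity_ancestor_pct must lie in [0, 100]",
          class = "gvaccordion_consistency_error")
  }
  invisible(rows)
}
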