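#' Column totals of a per-virus event summary
#'
#' Totals are always recomputed from the per-row values, never transcribed
#' from a printed totals row (whose unknown/orphan cell is internally
#' inconsistent in the published table).
#'
#' @param rows Summary tibble ([read_summary_table()] /
#'   [summarize_terminal_events()]).
#' @return One-row tibble of integer column sums (orphans summed over the
#'   rows where they are recorded).
#' @export
aggregate_summary <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  validate_summary_rows(rows)
  rows |>
    summarise(across(dplyr::all_of(count_cols),
                     ~ as.integer(sum(.x, na.rm = TRUE))))
}

#' Genomic events per kilobase
#'
#' The normalised mutation load plotted against marker identity in the
#' molecular-clock regression.
#'
#' @param rows Summary tibble with `genomic_events` and `size_kb`.
#' @return `rows` with an added `events_per_kb` column.
#' @export
events_per_kb <- function(rows) {
  if (any(rows$size_kb <= 0)) {
    abort("size_kb must be positive", class = "gvaccordion_domain_error")
  }
  mutate(rows, events_per_kb = .data$genomic_events / .data$size_kb)
}

#' Molecular-clock regression of event density on marker identity
#'
#' Ordinary least squares of events-per-kb on the percent identity of the
#' concatenated marker genes to the reconstructed group ancestor. Under
#' clock-like accumulation of genomic mutations the relation is linear with
#' negative slope: lower identity (longer divergence) means more events per
#' kb. `r_squared` is the squared Pearson correlation of the simple fit.
#'
#' @param rows Summary tibble with `identity_ancestor_pct`, `size_kb` and
#'   `genomic_events`.
#' @return Object of class `clock_fit` wrapping the `lm` fit, with
#'   `slope`, `intercept`, `r_squared`, `n` and the plotting data.
#' @export
fit_clock_regression <- function(rows) {
  if (nrow(rows) < 3) {
    abort("need at least 3 rows to fit the clock regression",
          class = "gvaccordion_value_error")
  }
  data <- events_per_kb(rows)
  if (length(unique(data$identity_ancestor_pct)) < 2) {
    abort("identity is constant across rows: regression undefined",
          class = "gvaccordion_undefined_fit_error")
  }
  fit <- lm(events_per_kb ~ identity_ancestor_pct, data = data)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    n = nrow(data),
    fit = fit,
    data = data
  ), class = "clock_fit")
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf(
    "<clock_fit> events/kb = %.4f %+.4f * identity%%  (r^2 = %.3f, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.clock_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "identity_ancestor_pct"),
         estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.clock_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope,
         intercept = x$intercept, n = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.clock_fit <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$identity_ancestor_pct,
                                    y = .data$events_per_kb)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2.5) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "blue") +
    ggplot2::labs(
      x = "% identity of markers to group ancestor",
      y = "genomic events per kb",
      title = sprintf("Clock-like accumulation of genomic events (r² = %.2f)",
                      object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Mobile-element fraction of a group's genomic events
#'
#' `100 * sum(insertion + excision) / sum(genomic_events)` over the group's
#' rows; rounding to the nearest integer percent happens only at report
#' time via `round_half_up`.
#'
#' @param rows Summary tibble with a `group` column.
#' @param group Group label to aggregate.
#' @return Percentage (full precision).
#' @export
group_mge_fraction <- function(rows, group) {
  sel <- rows[rows$group == group, , drop = FALSE]
  if (nrow(sel) == 0) {
    abort(paste0("no rows for group ", group),
          class = "gvaccordion_value_error")
  }
  tot <- sum(sel$genomic_events)
  if (tot == 0) {
    abort("group has zero genomic events: fraction undefined",
          class = "gvaccordion_undefined_error")
  }
  100 * sum(sel$insertion + sel$excision) / tot
}

#' Multigene-family context of duplications and losses
#'
#' Measures how strongly genomic turnover targets paralogous families:
#' the fraction of duplication events whose family has at least three
#' additional representatives in that genome, and the fraction of losses
#' hitting families with at least two members (parental copy number >= 2).
#'
#' @param events Classified event tibble with `in_paralog_family` and
#'   `copies_parent`.
#' @return Tibble with `frac_dup_in_big_families`,
#'   `frac_loss_in_dup_families` and the event counts; a fraction with no
#'   qualifying events is `NA`, not 0.
#' @export
duplication_family_context <- function(events) {
  dups <- filter(events, .data$event_type == "duplication")
  losses <- filter(events, .data$event_type %in% c("loss", "excision"))
  tibble(
    frac_dup_in_big_families =
      if (nrow(dups) == 0) NA_real_ else mean(dups$in_paralog_family),
    frac_loss_in_dup_families =
      if (nrow(losses) == 0) NA_real_ else mean(losses$copies_parent >= 2,
                                                na.rm = TRUE),
    n_duplications = nrow(dups),
    n_losses = nrow(losses)
  )
}

#' Fraction of events at the genome extremities
#'
#' Terminal hotspot statistic: the fraction of positioned events lying in
#' the first or last `edge_frac` of the genome length.
#'
#' @param events Event tibble with `position` (nucleotide coordinates) —
#'   either a truth log or classified events for one genome.
#' @param genome The [genome_record()] the positions refer to, or a genome
#'   size in nucleotides.
#' @param edge_frac Width of each terminal window as a fraction of genome
#'   length (default 0.1).
#' @return Fraction in `[0, 1]`.
#' @export
hotspot_fraction <- function(events, genome, edge_frac = 0.1) {
  size_nt <- if (inherits(genome, "genome_record")) {
    round_half_up(genome_size_kb(genome) * 1000)
  } else as.numeric(genome)
  pos <- events$position[!is.na(events$position)]
  if (length(pos) == 0) {
    abort("no positioned events: hotspot fraction undefined",
          class = "gvaccordion_undefined_error")
  }
  mean(pos < edge_frac * size_nt | pos > (1 - edge_frac) * size_nt)
}
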