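#' Construct a genome record
#'
#' A genome record is the package's unit of annotation: one row per gene, in
#' genome coordinate order, with the family label used for positional homology
#' and the flags used by the event-classification rules. Coordinates follow
#' the 0-based half-open convention (`start` inclusive, `end` exclusive).
#'
#' @param genes Data frame with columns `gene_id`, `family_id`, `start`,
#'   `end`, `strand` and optionally `flags` (comma-joined subset of
#'   `"MGE"`, `"donor_labelled"`, `"orphan_candidate"`) and `donor_taxon`.
#' @param genome_id Single string identifying the genome.
#' @param group Virus group; one of `"mimivirus"`, `"megavirus"`,
#'   `"ostreococcus"`, `"micromonas"`, `"chlorella"`, `"synthetic"`.
#' @param size_kb Genome size in kilobases. Defaults to the end of the last
#'   gene plus 200 nt, rounded up to the next 0.001 kb.
#' @param sequence Optional nucleotide string of length `round(size_kb * 1000)`.
#'
#' @return A tibble of genes (class `genome_record`) sorted by `start`, with
#'   `genome_id`, `group`, `size_kb` and `sequence` stored as attributes.
#' @export
genome_record <- function(genes, genome_id, group = "synthetic",
                          size_kb = NULL, sequence = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  group <- match.arg(group, GENOME_GROUPS)
  genes <- as_tibble(genes)
  required <- c("gene_id", "family_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required gene column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gvaccordion_format_error")
  }
  if (!"flags" %in% names(genes)) genes$flags <- ""
  if (!"donor_taxon" %in% names(genes)) genes$donor_taxon <- NA_character_
  genes <- genes |>
    mutate(
      gene_id = as.character(.data$gene_id),
      family_id = as.character(.data$family_id),
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      strand = as.character(.data$strand),
      flags = dplyr::coalesce(as.character(.data$flags), ""),
      donor_taxon = as.character(.data$donor_taxon)
    ) |>
    select(dplyr::all_of(c(required, "flags", "donor_taxon"))) |>
    arrange(.data$start, .data$gene_id)

  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    abort(paste0("duplicate gene_id(s): ", paste(dup, collapse = ", ")),
          class = "gvaccordion_duplicate_id_error")
  }
  if (nrow(genes) > 0) {
    if (any(genes$start >= genes$end)) {
      abort("gene coordinates must satisfy start < end (0-based half-open)",
            class = "gvaccordion_format_error")
    }
    if (!all(genes$strand %in% c("+", "-"))) {
      abort("strand must be '+' or '-'", class = "gvaccordion_format_error")
    }
    bad_flags <- setdiff(unlist(strsplit(genes$flags[genes$flags != ""], ",")),
                         GENE_FLAGS)
    if (length(bad_flags) > 0) {
      abort(paste0("unknown gene flag(s): ", paste(bad_flags, collapse = ", ")),
            class = "gvaccordion_format_error")
    }
    labelled <- has_flag(genes$flags, "donor_labelled")
    has_donor <- !is.na(genes$donor_taxon) & genes$donor_taxon != ""
    if (any(labelled != has_donor)) {
      abort("donor_taxon must be present iff the donor_labelled flag is set",
            class = "gvaccordion_format_error")
    }
  }
  if (is.null(size_kb)) {
    size_kb <- if (nrow(genes) == 0) 0.2 else (max(genes$end) + 200) / 1000
  }
  size_nt <- round_half_up(size_kb * 1000)
  if (nrow(genes) > 0 && any(genes$end > size_nt)) {
    abort("gene coordinates exceed the genome size",
          class = "gvaccordion_format_error")
  }
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (nchar(sequence) != size_nt) {
      abort("sequence length must equal round(size_kb * 1000)",
            class = "gvaccordion_format_error")
    }
  }
  structure(genes,
            genome_id = genome_id, group = group,
            size_kb = as.numeric(size_kb), sequence = sequence,
            class = c("genome_record", class(tibble())))
}

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

has_flag <- function(flags, flag) {
  vapply(strsplit(dplyr::coalesce(flags, ""), ","),
         function(f) flag %in% f, logical(1))
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s), %.1f kb, %d genes\n",
              genome_id(x), genome_group(x), genome_size_kb(x), nrow(x)))
  NextMethod()
}

#' Accessors for genome-record metadata
#'
#' @param genome A `genome_record`.
#' @return The genome id, group label, size in kb, or optional sequence.
#' @export
genome_id <- function(genome) attr(genome, "genome_id")

#' @rdname genome_id
#' @export
genome_group <- function(genome) attr(genome, "group")

#' @rdname genome_id
#' @export
genome_size_kb <- function(genome) attr(genome, "size_kb")

#' @rdname genome_id
#' @export
genome_sequence <- function(genome) attr(genome, "sequence")

#' Read and write gene-order genome tables
#'
#' Gene tables are plain TSV with one row per gene and a header naming the
#' `genome_record` columns. Genome-level metadata is carried in `#key value`
#' comment lines before the header.
#'
#' @param path File path.
#' @return For `read_genome_table()`, a [genome_record()]; `write_genome_table()`
#'   returns `path` invisibly.
#' @export
read_genome_table <- function(path) {
  header_lines <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0 || !startsWith(line, "#")) break
    header_lines <- c(header_lines, line)
  }
  meta <- parse_meta_lines(header_lines)
  genes <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  genome_record(genes,
                genome_id = meta$genome_id %||% basename(path),
                group = meta$group %||% "synthetic",
                size_kb = if (is.null(meta$size_kb)) NULL else as.numeric(meta$size_kb))
}

parse_meta_lines <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  parts <- strsplit(lines, "\t| ")
  out <- lapply(parts, function(p) paste(p[-1], collapse = " "))
  names(out) <- vapply(parts, `[[`, character(1), 1)
  out
}

#' @rdname read_genome_table
#' @param genome A `genome_record` to serialise.
#' @export
write_genome_table <- function(genome, path) {
  stopifnot(inherits(genome, "genome_record"))
  meta <- c(
    sprintf("#genome_id %s", genome_id(genome)),
    sprintf("#group %s", genome_group(genome)),
    sprintf("#size_kb %.6g", genome_size_kb(genome))
  )
  writeLines(meta, path)
  readr::write_tsv(as_tibble(genome), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and write Newick trees
#'
#' Thin wrappers around \pkg{ape} that normalise what downstream code expects:
#' trees are returned as `phylo` objects; unrooted input is accepted and kept
#' with its basal multifurcation until [build_rooted_tree()] roots it.
#'
#' @param path File path to a Newick file.
#' @return `read_newick()` returns an \pkg{ape} `phylo`; `write_newick()`
#'   returns `path` invisibly.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) abort(paste0("Newick parse error: ",
                                                    conditionMessage(e)),
                                             class = "gvaccordion_parse_error"))
  if (is.null(tree)) {
    abort("Newick parse error: no tree found",
          class = "gvaccordion_parse_error")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort("tip labels must be unique", class = "gvaccordion_format_error")
  }
  tree
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
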