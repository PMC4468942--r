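#' Candidate positional-homology anchors between two genomes
#'
#' An anchor is a gene family present in both genomes and single-copy in
#' each: only such families identify orthologs unambiguously by position,
#' which is the basis of synteny-driven orthology in gene-dense viral
#' genomes rich in paralogs.
#'
#' @param a,b [genome_record()]s carrying family labels.
#' @return Tibble with one row per anchor: `family_id`, `gene_id_a`,
#'   `gene_id_b`, `pos_a`, `pos_b` (gene-order indices), sorted by `pos_a`.
#'   The source genome ids are stored as attributes `genome_a`/`genome_b`.
#' @export
anchor_genes <- function(a, b) {
  stopifnot(inherits(a, "genome_record"), inherits(b, "genome_record"))
  single <- function(g) {
    tab <- table(g$family_id)
    names(tab)[tab == 1]
  }
  shared <- intersect(single(a), single(b))
  ia <- match(shared, a$family_id)
  ib <- match(shared, b$family_id)
  out <- tibble(family_id = shared,
                gene_id_a = a$gene_id[ia], gene_id_b = b$gene_id[ib],
                pos_a = ia, pos_b = ib) |>
    arrange(.data$pos_a)
  structure(out, genome_a = genome_id(a), genome_b = genome_id(b))
}

# one longest strictly monotone subsequence of y (patience sorting,
# O(n log n)); decreasing = TRUE finds the longest strictly decreasing run.
# Returns indices into y.
longest_run <- function(y, decreasing = FALSE) {
  if (decreasing) y <- -y
  n <- length(y)
  if (n == 0) return(integer())
  tails <- integer(0)   # index of smallest tail of each length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) { # first position with tail value >= y[i] (strict LIS)
      mid <- (lo + hi) %/% 2L
      if (y[tails[mid]] < y[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(length(tails))
  k <- tails[length(tails)]
  for (j in rev(seq_along(tails))) {
    out[j] <- k
    k <- prev[k]
  }
  out
}

#' Chain anchors into collinear synteny blocks
#'
#' A stand-in for whole-genome aligner blocks: with anchors ordered by
#' position in genome A, collinear runs are found by repeatedly extracting
#' the longest strictly increasing (orientation `"same"`) or strictly
#' decreasing (orientation `"inverted"`) subsequence of genome-B positions
#' from the anchors not yet assigned. Runs of fewer than 2 anchors are
#' discarded; every anchor belongs to at most one block.
#'
#' @param anchors Anchor table from [anchor_genes()].
#' @return The anchor table with added columns `block_id` (`NA` for
#'   unassigned anchors) and `orientation`.
#' @export
chain_blocks <- function(anchors) {
  anchors <- anchors |> arrange(.data$pos_a)
  n <- nrow(anchors)
  block_id <- rep(NA_integer_, n)
  orientation <- rep(NA_character_, n)
  remaining <- seq_len(n)
  next_id <- 1L
  while (length(remaining) >= 2) {
    y <- anchors$pos_b[remaining]
    inc <- longest_run(y, decreasing = FALSE)
    dec <- longest_run(y, decreasing = TRUE)
    run <- if (length(inc) >= length(dec)) inc else dec
    if (length(run) < 2) break
    idx <- remaining[run]
    block_id[idx] <- next_id
    orientation[idx] <- if (length(inc) >= length(dec)) "same" else "inverted"
    next_id <- next_id + 1L
    remaining <- setdiff(remaining, idx)
  }
  out <- anchors |> mutate(block_id = block_id, orientation = orientation)
  structure(out, genome_a = attr(anchors, "genome_a"),
            genome_b = attr(anchors, "genome_b"))
}

# classify each anchor's membership in maximum-length increasing chains:
# "in_all" (in every longest chain), "in_some" (in at least one), "in_none".
# Used to separate clear positional displacement from tie ambiguity.
anchor_chain_status <- function(anchors) {
  y <- anchors$pos_b[order(anchors$pos_a)]
  n <- length(y)
  if (n == 0) return(character())
  up <- integer(n); down <- integer(n)
  for (i in seq_len(n)) {
    earlier <- which(y[seq_len(i - 1)] < y[i])
    up[i] <- 1L + if (length(earlier)) max(up[earlier]) else 0L
  }
  for (i in rev(seq_len(n))) {
    later <- which(y[seq(i, n)] > y[i]) + i - 1L
    down[i] <- 1L + if (length(later)) max(down[later]) else 0L
  }
  L <- max(up + down - 1L)
  in_some <- (up + down - 1L) == L
  rank_counts <- table(up[in_some])
  in_all <- in_some & rank_counts[as.character(up)] == 1L
  status <- ifelse(in_all, "in_all", ifelse(in_some, "in_some", "in_none"))
  status[order(order(anchors$pos_a))]
}

#' Extract variable segments between synteny blocks
#'
#' Complements the block-anchored gene spans over the genome and reports
#' maximal uncovered intervals longer than `min_len` that contain at least
#' one ORF. When the genome carries a nucleotide sequence, ORFs are found de
#' novo with [find_orfs()]; otherwise presence of at least one fully
#' contained annotated gene stands in for the ORF requirement.
#'
#' @param genome A [genome_record()] that is one side of the block
#'   computation.
#' @param blocks Block table from [chain_blocks()].
#' @param min_len Minimum segment length in nucleotides (default 300, the
#'   published filter for unaligned segments).
#' @return Tibble of segments: `genome_id`, `start`, `end`,
#'   `contained_genes` (list column), `has_orf`.
#' @export
extract_variable_segments <- function(genome, blocks, min_len = 300L) {
  if (!is.numeric(min_len) || min_len <= 0) {
    abort("min_len must be positive", class = "gvaccordion_domain_error")
  }
  gid <- genome_id(genome)
  gene_col <- if (identical(attr(blocks, "genome_a"), gid)) "gene_id_a"
              else if (identical(attr(blocks, "genome_b"), gid)) "gene_id_b"
              else abort("genome was not part of this block computation",
                         class = "gvaccordion_value_error")
  anchored <- blocks[[gene_col]][!is.na(blocks$block_id)]
  size_nt <- round_half_up(genome_size_kb(genome) * 1000)
  covered <- genome |>
    as_tibble() |>
    filter(.data$gene_id %in% anchored) |>
    select("start", "end")
  gaps <- interval_complement(covered, size_nt)
  gaps <- gaps[gaps$end - gaps$start > min_len, , drop = FALSE]
  if (nrow(gaps) == 0) {
    return(tibble(genome_id = character(), start = integer(), end = integer(),
                  contained_genes = list(), has_orf = logical()))
  }
  seqs <- genome_sequence(genome)
  out <- purrr::map_dfr(seq_len(nrow(gaps)), function(i) {
    s <- gaps$start[i]; e <- gaps$end[i]
    inside <- genome$gene_id[genome$start >= s & genome$end <= e]
    has_orf <- if (!is.null(seqs)) {
      nrow(find_orfs(substr(seqs, s + 1L, e), min_nt = min_len)) > 0
    } else {
      length(inside) > 0
    }
    tibble(genome_id = gid, start = s, end = e,
           contained_genes = list(inside), has_orf = has_orf)
  })
  out |> filter(.data$has_orf)
}

# maximal intervals of [0, size) not covered by the given intervals
interval_complement <- function(iv, size) {
  if (nrow(iv) == 0) return(tibble(start = 0L, end = as.integer(size)))
  iv <- iv |> arrange(.data$start)
  merged_start <- integer(); merged_end <- integer()
  cs <- iv$start[1]; ce <- iv$end[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= ce) {
      ce <- max(ce, iv$end[i])
    } else {
      merged_start <- c(merged_start, cs); merged_end <- c(merged_end, ce)
      cs <- iv$start[i]; ce <- iv$end[i]
    }
  }
  merged_start <- c(merged_start, cs); merged_end <- c(merged_end, ce)
  starts <- c(0L, merged_end)
  ends <- c(merged_start, as.integer(size))
  keep <- ends > starts
  tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Find open reading frames in all six frames
#'
#' An ORF is an `ATG`-to-stop span under the standard genetic code (stops
#' `TAA`, `TAG`, `TGA`): for each in-frame stop, the most upstream `ATG`
#' after the previous in-frame stop opens the ORF. The span from the start
#' codon through the stop codon inclusive must be at least `min_nt`.
#' Codons containing `N` match neither start nor stop.
#'
#' @param seq Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param min_nt Minimum ORF span in nucleotides.
#' @return Tibble with columns `start`, `end` (0-based half-open, on the
#'   forward strand coordinate system) and `strand`.
#' @export
find_orfs <- function(seq, min_nt = 300L) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  L <- nchar(seq)
  fwd <- orfs_one_strand(seq, min_nt)
  rc <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  rev_orfs <- orfs_one_strand(rc, min_nt)
  out <- bind_rows(
    if (nrow(fwd)) mutate(fwd, strand = "+"),
    if (nrow(rev_orfs)) tibble(start = L - rev_orfs$end,
                               end = L - rev_orfs$start, strand = "-")
  )
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(start = integer(), end = integer(), strand = character()))
  }
  arrange(out, .data$start, .data$end)
}

# forward-strand ORFs in the 3 reading frames; 0-based half-open coordinates
orfs_one_strand <- function(seq, min_nt) {
  L <- nchar(seq)
  starts <- integer(); ends <- integer()
  for (frame in 0:2) {
    ncod <- (L - frame) %/% 3
    if (ncod < 2) next
    codons <- substring(seq, frame + 3 * (seq_len(ncod) - 1) + 1,
                        frame + 3 * seq_len(ncod))
    is_start <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    open_from <- 1L
    for (k in which(is_stop)) {
      cand <- which(is_start[seq(open_from, k)]) + open_from - 1L
      if (length(cand) > 0) {
        a <- cand[1]
        span <- (k - a + 1L) * 3L
        if (span >= min_nt) {
          starts <- c(starts, frame + 3L * (a - 1L))
          ends <- c(ends, frame + 3L * k)
        }
      }
      open_from <- k + 1L
    }
  }
  tibble(start = starts, end = ends)
}

#' Detect translocated genes between two genomes
#'
#' Reports gene families that are single-copy and present in both genomes
#' (hence anchors) but whose anchor could not be assigned to any collinear
#' block: positionally displaced genes with conserved copy number. Families
#' absent from one genome are losses/gains, not translocations, and are
#' never reported here.
#'
#' @param a,b The two [genome_record()]s.
#' @param blocks Block table from [chain_blocks()] on `anchor_genes(a, b)`.
#' @return Tibble with `family_id`, `gene_id_a`, `gene_id_b`.
#' @export
detect_translocations <- function(a, b, blocks) {
  blocks |>
    filter(is.na(.data$block_id)) |>
    select("family_id", "gene_id_a", "gene_id_b") |>
    as_tibble()
}
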