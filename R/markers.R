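#' Construct a marker alignment
#'
#' A marker alignment holds equal-length aligned nucleotide rows (gaps as
#' `-`), one per genome, a table of locus boundaries for the concatenated
#' markers, and a logical column mask produced by
#' [filter_conserved_columns()] (all `TRUE` until filtering).
#'
#' @param seqs Named character vector of aligned sequences.
#' @param loci Optional tibble with columns `locus`, `start`, `end` (1-based
#'   inclusive column ranges). Defaults to one locus spanning everything.
#' @param mask Optional logical vector, one entry per column.
#' @return An object of class `marker_alignment`.
#' @export
marker_alignment <- function(seqs, loci = NULL, mask = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1, !is.null(names(seqs)))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    abort("all alignment rows must have equal length",
          class = "gvaccordion_format_error")
  }
  w <- widths[[1]]
  if (is.null(loci)) {
    loci <- tibble(locus = "concatenated", start = 1L, end = as.integer(w))
  }
  if (is.null(mask)) mask <- rep(TRUE, w)
  if (length(mask) != w) {
    abort("mask length must equal the alignment length",
          class = "gvaccordion_format_error")
  }
  structure(toupper(seqs), loci = as_tibble(loci), mask = mask,
            class = "marker_alignment")
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat(sprintf("<marker_alignment> %d rows x %d columns (%d retained), %d locus/loci\n",
              length(x), nchar(x[[1]]), sum(alignment_mask(x)),
              nrow(attr(x, "loci"))))
  invisible(x)
}

#' @rdname marker_alignment
#' @param x A `marker_alignment`.
#' @export
alignment_mask <- function(x) attr(x, "mask")

#' @rdname marker_alignment
#' @export
alignment_loci <- function(x) attr(x, "loci")

# alignment as a character matrix (rows = genomes)
alignment_matrix <- function(x) {
  do.call(rbind, strsplit(unclass(x), "", fixed = TRUE))
}

#' Read and write aligned FASTA
#'
#' @param path FASTA file path.
#' @return `read_marker_fasta()` returns a [marker_alignment()];
#'   `write_marker_fasta()` returns `path` invisibly.
#' @export
read_marker_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  marker_alignment(setNames(as.character(seqs), names(seqs)))
}

#' @rdname read_marker_fasta
#' @param aln A `marker_alignment` (or named character vector).
#' @export
write_marker_fasta <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(unclass(aln)), path)
  invisible(path)
}

#' Select conserved alignment columns
#'
#' A Gblocks-style two-criterion filter: a column is kept iff its gap
#' fraction is at most `max_gap_frac` and its majority-residue frequency
#' (most common non-gap residue over all rows) is at least `min_majority`;
#' kept columns must additionally lie in runs of at least `min_block`
#' consecutive kept columns, otherwise the whole short run is dropped.
#'
#' @param aln A [marker_alignment()].
#' @param max_gap_frac Maximum fraction of gap characters per column.
#' @param min_majority Minimum frequency of the most common residue.
#' @param min_block Minimum run length of kept columns.
#' @return The alignment with its column mask updated.
#' @export
filter_conserved_columns <- function(aln, max_gap_frac = 0.0,
                                     min_majority = 0.5, min_block = 10L) {
  m <- alignment_matrix(aln)
  if (nrow(m) == 0 || ncol(m) == 0) {
    abort("empty alignment", class = "gvaccordion_value_error")
  }
  nrows <- nrow(m)
  keep <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    is_gap <- col %in% c("-", ".")
    if (sum(is_gap) / nrows > max_gap_frac) return(FALSE)
    tab <- table(col[!is_gap])
    length(tab) > 0 && max(tab) / nrows >= min_majority
  }, logical(1))
  # drop runs of kept columns shorter than min_block
  r <- rle(keep)
  r$values[r$values & r$lengths < min_block] <- FALSE
  mask <- inverse.rle(r)
  marker_alignment(unclass(aln), loci = alignment_loci(aln), mask = mask)
}

#' Concatenate per-locus alignments
#'
#' @param locus_alignments Named list of [marker_alignment()] (or named
#'   character vectors), all over the same genome set.
#' @return A single `marker_alignment` with locus boundary bookkeeping.
#' @export
concat_markers <- function(locus_alignments) {
  stopifnot(length(locus_alignments) >= 1, !is.null(names(locus_alignments)))
  rows <- lapply(locus_alignments, function(a) unclass(a)[order(names(a))])
  ids <- lapply(rows, names)
  if (length(unique(ids)) != 1) {
    abort("all loci must cover the same genome set",
          class = "gvaccordion_value_error")
  }
  widths <- vapply(rows, function(r) nchar(r[[1]]), integer(1))
  ends <- cumsum(widths)
  loci <- tibble(locus = names(locus_alignments),
                 start = as.integer(ends - widths + 1L),
                 end = as.integer(ends))
  seqs <- Reduce(function(a, b) paste0(a, b), rows)
  names(seqs) <- ids[[1]]
  marker_alignment(seqs, loci = loci)
}

#' Split a concatenated alignment back into loci
#'
#' @param aln A concatenated [marker_alignment()].
#' @return Named list of per-locus `marker_alignment`s.
#' @export
split_markers <- function(aln) {
  loci <- alignment_loci(aln)
  out <- lapply(seq_len(nrow(loci)), function(i) {
    marker_alignment(vapply(unclass(aln), substr, character(1),
                            loci$start[i], loci$end[i]))
  })
  setNames(out, loci$locus)
}

#' Marginal ancestral reconstruction at the root
#'
#' Computes per-site marginal posterior probabilities of the root state
#' under the Jukes-Cantor model by Felsenstein's pruning algorithm, on the
#' retained (masked) columns of the alignment. The reconstructed sequence
#' takes the maximum-posterior base per site, ties broken in the fixed order
#' A < C < G < T. Gap and `N` characters contribute a flat partial
#' likelihood.
#'
#' @param aln A [marker_alignment()] whose row names match the tree tips.
#' @param tree Rooted `phylo` with branch lengths.
#' @param rate Scale factor converting branch lengths to expected
#'   substitutions per site.
#' @return A list of class `ancestral_sequence` with elements `sequence`
#'   (root sequence over retained columns), `posterior` (max posterior per
#'   site), `posterior_matrix` (4 x sites), and `columns` (retained column
#'   indices).
#' @export
reconstruct_root <- function(aln, tree, rate = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    abort("tree must be rooted", class = "gvaccordion_value_error")
  }
  mask <- alignment_mask(aln)
  if (sum(mask) == 0) {
    abort("no retained columns to reconstruct",
          class = "gvaccordion_value_error")
  }
  m <- alignment_matrix(aln)[, mask, drop = FALSE]
  tips <- names(unclass(aln))
  if (!setequal(tips, tree$tip.label)) {
    abort("alignment rows and tree tips disagree",
          class = "gvaccordion_value_error")
  }
  m <- m[match(tree$tip.label, tips), , drop = FALSE]
  nsite <- ncol(m)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode

  # tip partial likelihoods: 4 x sites per tip; ambiguity -> flat
  tip_like <- lapply(seq_len(ntip), function(i) {
    L <- matrix(0, 4, nsite)
    hit <- match(m[i, ], DNA_BASES)
    known <- !is.na(hit)
    L[cbind(hit[known], which(known))] <- 1
    L[, !known] <- 1
    L
  })

  po <- ape::reorder.phylo(tree, "postorder")
  down <- vector("list", nnode) # partial likelihoods below each node
  down[seq_len(ntip)] <- tip_like
  for (i in seq_len(nrow(po$edge))) {
    parent <- po$edge[i, 1]; child <- po$edge[i, 2]
    P <- jc_matrix(po$edge.length[i] * rate)
    msg <- P %*% down[[child]]
    down[[parent]] <- if (is.null(down[[parent]])) msg else down[[parent]] * msg
  }
  root <- ntip + 1L
  post <- down[[root]] * 0.25
  post <- sweep(post, 2, colSums(post), "/")
  best <- apply(post, 2, which.max) # which.max breaks ties by A<C<G<T order
  structure(list(sequence = paste0(DNA_BASES[best], collapse = ""),
                 posterior = post[cbind(best, seq_len(nsite))],
                 posterior_matrix = post,
                 columns = which(mask)),
            class = "ancestral_sequence")
}

# JC transition probability matrix for branch length d (subs/site)
jc_matrix <- function(d) {
  same <- 0.25 + 0.75 * exp(-4 * d / 3)
  diff <- 0.25 - 0.25 * exp(-4 * d / 3)
  m <- matrix(diff, 4, 4)
  diag(m) <- same
  m
}

#' Percent identity between two aligned sequences
#'
#' Positions where either sequence has a gap (`-` or `.`) or `N` are
#' excluded; identity is 100 times the fraction of matching positions among
#' the compared ones. Values are kept at full precision; rounding to the
#' integer grain of the published table happens only at reporting time.
#'
#' @param a,b Equal-length character strings.
#' @return A number in `[0, 100]` (`NaN` if no positions are comparable).
#' @export
percent_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) {
    abort("sequences must have equal length",
          class = "gvaccordion_value_error")
  }
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  skip <- x %in% c("-", ".", "N") | y %in% c("-", ".", "N")
  100 * sum(x[!skip] == y[!skip]) / sum(!skip)
}

#' Percent identity of every tip to the reconstructed group ancestor
#'
#' Convenience wrapper: filters the alignment (optionally), reconstructs the
#' root, and reports the identity of each row to the root sequence on the
#' retained columns.
#'
#' @param aln A [marker_alignment()].
#' @param tree Rooted `phylo` covering the alignment rows.
#' @param rate Branch-length scale passed to [reconstruct_root()].
#' @return Tibble with columns `genome_id` and `identity_ancestor_pct`.
#' @export
ancestor_identity <- function(aln, tree, rate = 1) {
  anc <- reconstruct_root(aln, tree, rate = rate)
  mask <- alignment_mask(aln)
  tibble(
    genome_id = names(unclass(aln)),
    identity_ancestor_pct = vapply(unclass(aln), function(s) {
      kept <- paste0(strsplit(s, "", fixed = TRUE)[[1]][mask], collapse = "")
      percent_identity(kept, anc$sequence)
    }, numeric(1))
  )
}
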