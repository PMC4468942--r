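#' Combined gene-content / marker-substitution distance
#'
#' Pairwise distance used as input for whole-genome tree building:
#' `d(a, b) = alpha * (1 - Jaccard(presence_a, presence_b)) +
#' (1 - alpha) * p(a, b)`, where Jaccard is on family presence/absence and
#' `p` is the marker p-distance (fraction of differing, comparable sites).
#' With no marker alignment supplied the gene-content term is used alone.
#'
#' @param matrix A [build_copy_matrix()] result.
#' @param markers Optional [marker_alignment()] covering the same genomes.
#' @param alpha Weight of the gene-content term, in `[0, 1]`.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
gene_content_distance <- function(matrix, markers = NULL, alpha = 0.5) {
  stopifnot(inherits(matrix, "copy_matrix"))
  stopifnot(alpha >= 0, alpha <= 1)
  ids <- colnames(matrix)
  if (length(ids) < 2) {
    abort("need at least 2 genomes", class = "gvaccordion_value_error")
  }
  pres <- unclass(matrix) > 0
  n <- length(ids)
  jac <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      inter <- sum(pres[, i] & pres[, j])
      uni <- sum(pres[, i] | pres[, j])
      d <- if (uni == 0) 0 else 1 - inter / uni
      jac[i, j] <- jac[j, i] <- d
    }
  }
  if (is.null(markers)) return(jac)
  seqs <- unclass(markers)[ids]
  pd <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    x <- strsplit(toupper(seqs[[i]]), "")[[1]]
    for (j in seq(i + 1, n)) {
      y <- strsplit(toupper(seqs[[j]]), "")[[1]]
      ok <- x %in% DNA_BASES & y %in% DNA_BASES
      p <- if (sum(ok) == 0) 0 else sum(x[ok] != y[ok]) / sum(ok)
      pd[i, j] <- pd[j, i] <- p
    }
  }
  alpha * jac + (1 - alpha) * pd
}

#' Neighbor-joining tree rooted on an outgroup
#'
#' Builds a neighbor-joining tree from the distance matrix and roots it on
#' the branch leading to `outgroup`, the rooting rule of the whole-genome
#' trees (each group's tree is rooted with its closest relative: mimiviruses
#' with a megavirus and vice versa).
#'
#' @param distances Symmetric distance matrix with taxon dimnames.
#' @param outgroup_id Taxon to root on; must be present in the matrix.
#' @return A rooted `phylo`.
#' @export
build_rooted_tree <- function(distances, outgroup_id) {
  ids <- rownames(distances)
  if (is.null(ids) || length(ids) < 3) {
    abort("build_rooted_tree: need at least 3 taxa for neighbor joining",
          class = "gvaccordion_value_error")
  }
  if (!outgroup_id %in% ids) {
    abort(paste0("build_rooted_tree: outgroup not in distance matrix: ",
                 outgroup_id),
          class = "gvaccordion_value_error")
  }
  tree <- ape::nj(as.dist(distances))
  tree$edge.length <- pmax(tree$edge.length, 0) # NJ can emit tiny negatives
  ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
}
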