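# Independent brute-force oracles used to freeze expected values.
# These deliberately share no code with the package implementations.

# --- exhaustive copy-number parsimony ---------------------------------------

# enumerate every assignment of states 0..max_copy to the internal nodes of a
# rooted tree and tally the minimum total |child - parent| cost and the number
# of assignments achieving it
enumerate_parsimony <- function(profile, tree, max_copy) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1):nnode
  states <- 0:max_copy
  grid <- as.matrix(expand.grid(rep(list(states), length(internal))))
  edge <- tree$edge
  tipv <- as.integer(profile[tree$tip.label])
  best <- Inf; count <- 0
  for (r in seq_len(nrow(grid))) {
    assign_all <- c(tipv, grid[r, ])
    cost <- sum(abs(assign_all[edge[, 1]] - assign_all[edge[, 2]]))
    if (cost < best) { best <- cost; count <- 1 }
    else if (cost == best) count <- count + 1
  }
  list(min_cost = best, n_labelings = count)
}

# vectorised variant: min cost and labeling count for EVERY tip profile at
# once (profiles as a ntip x nprofile matrix); used for the full sweep
enumerate_parsimony_all <- function(tree, max_copy, profiles) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1):nnode
  states <- 0:max_copy
  grid <- as.matrix(expand.grid(rep(list(states), length(internal))))
  edge <- tree$edge
  tip_edge <- edge[edge[, 2] <= ntip, , drop = FALSE]
  int_edge <- edge[edge[, 2] > ntip, , drop = FALSE]
  nprof <- ncol(profiles)
  best <- rep(Inf, nprof); count <- rep(0, nprof)
  for (r in seq_len(nrow(grid))) {
    node_state <- integer(nnode)
    node_state[internal] <- grid[r, ]
    fixed <- if (nrow(int_edge)) {
      sum(abs(node_state[int_edge[, 1]] - node_state[int_edge[, 2]]))
    } else 0
    cost <- rep(fixed, nprof)
    for (k in seq_len(nrow(tip_edge))) {
      cost <- cost + abs(profiles[tip_edge[k, 2], ] -
                           node_state[tip_edge[k, 1]])
    }
    lower <- cost < best
    equal <- !lower & cost == best
    best[lower] <- cost[lower]
    count[lower] <- 1
    count[equal] <- count[equal] + 1
  }
  list(min_cost = best, n_labelings = count)
}

# all rooted binary tree shapes with n leaves, as newick strings with
# placeholder leaves; the sweep enumerates every leaf profile, so leaf
# labelling is immaterial and shapes cover all labelled topologies
all_tree_shapes <- function(n) {
  memo <- new.env()
  shapes <- function(k) {
    key <- as.character(k)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- if (k == 1) "x" else {
      res <- character()
      for (a in 1:(k %/% 2)) {
        for (l in shapes(a)) for (r in shapes(k - a)) {
          res <- c(res, paste0("(", l, ",", r, ")"))
        }
      }
      unique(res)
    }
    memo[[key]] <- out
    out
  }
  vapply(shapes(n), function(s) {
    i <- 0
    while (grepl("x", s, fixed = TRUE)) {
      i <- i + 1
      s <- sub("x", paste0("t", i, ":1"), s, fixed = TRUE)
    }
    paste0(s, ";")
  }, character(1), USE.NAMES = FALSE)
}

shape_tree <- function(newick) {
  tr <- ape::read.tree(text = newick)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# --- brute-force ORF scan ----------------------------------------------------

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

brute_orfs <- function(seq, min_nt = 300) {
  seq <- toupper(seq)
  scan1 <- function(s) {
    L <- nchar(s)
    hits <- list()
    for (frame in 0:2) {
      pos <- seq(frame + 1, L - 2, by = 3)
      if (length(pos) < 2) next
      cod <- substring(s, pos, pos + 2)
      prev_stop <- 0
      for (k in seq_along(cod)) {
        if (cod[k] %in% c("TAA", "TAG", "TGA")) {
          window <- seq(prev_stop + 1, k)
          starts <- window[cod[window] == "ATG"]
          if (length(starts) > 0) {
            a <- starts[1]
            if ((k - a + 1) * 3 >= min_nt) {
              hits[[length(hits) + 1]] <- c(pos[a] - 1, pos[k] + 2)
            }
          }
          prev_stop <- k
        }
      }
    }
    hits
  }
  L <- nchar(seq)
  fwd <- scan1(seq)
  rev <- scan1(revcomp_chr(seq))
  rows <- rbind(
    if (length(fwd)) cbind(do.call(rbind, fwd), 1) else NULL,
    if (length(rev)) {
      m <- do.call(rbind, rev)
      cbind(L - m[, 2], L - m[, 1], -1)
    } else NULL
  )
  if (is.null(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  }
  out <- data.frame(start = rows[, 1], end = rows[, 2],
                    strand = ifelse(rows[, 3] > 0, "+", "-"))
  out[order(out$start, out$end), , drop = FALSE]
}

# --- brute-force longest increasing subsequence ------------------------------

brute_lis_length <- function(y) {
  n <- length(y)
  if (n == 0) return(0L)
  best <- rep(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (y[j] < y[i] && best[j] + 1 > best[i]) best[i] <- best[j] + 1L
    }
  }
  max(best)
}

# --- brute-force conserved-column filter -------------------------------------

brute_mask <- function(rows, max_gap_frac, min_majority, min_block) {
  m <- do.call(rbind, strsplit(rows, ""))
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gapf <- mean(col %in% c("-", "."))
    res <- col[!col %in% c("-", ".")]
    maj <- if (length(res) == 0) 0 else max(table(res)) / nrow(m)
    keep[j] <- gapf <= max_gap_frac && maj >= min_majority
  }
  # second pass: kill runs shorter than min_block
  out <- keep
  j <- 1
  while (j <= length(keep)) {
    if (keep[j]) {
      k <- j
      while (k <= length(keep) && keep[k]) k <- k + 1
      if (k - j < min_block) out[j:(k - 1)] <- FALSE
      j <- k
    } else j <- j + 1
  }
  out
}

# --- brute-force root posterior under Jukes-Cantor ---------------------------

jc_p <- function(d) {
  same <- 0.25 + 0.75 * exp(-4 * d / 3)
  diff <- 0.25 - 0.25 * exp(-4 * d / 3)
  m <- matrix(diff, 4, 4); diag(m) <- same
  m
}

# sum over all internal-node state assignments of prod(edge transition probs)
brute_root_posterior <- function(tree, pattern, rate = 1) {
  bases <- c("A", "C", "G", "T")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1):nnode
  tip_state <- match(pattern[tree$tip.label], bases)
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  edge <- tree$edge
  post <- numeric(4)
  for (r in seq_len(nrow(grid))) {
    st <- integer(nnode)
    st[seq_len(ntip)] <- tip_state
    st[internal] <- grid[r, ]
    p <- 0.25 # flat root prior
    for (k in seq_len(nrow(edge))) {
      P <- jc_p(tree$edge.length[k] * rate)
      p <- p * P[st[edge[k, 1]], st[edge[k, 2]]]
    }
    root_state <- st[ntip + 1]
    post[root_state] <- post[root_state] + p
  }
  post / sum(post)
}

# --- misc --------------------------------------------------------------------

# random unaligned genome for property tests
random_genome <- function(id, n_genes, n_families = n_genes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fams <- sample(sprintf("F%03d", seq_len(n_families)), n_genes, replace = TRUE)
  len <- sample(300:1500, n_genes, replace = TRUE)
  start <- cumsum(c(100, head(len + 100, -1)))
  genome_record(
    tibble::tibble(gene_id = sprintf("%s_g%03d", id, seq_len(n_genes)),
                   family_id = fams, start = start, end = start + len,
                   strand = sample(c("+", "-"), n_genes, replace = TRUE)),
    genome_id = id)
}

# balanced 6-tip tree with every root child internal (terminal events on all
# tips are then identifiable); branch lengths settable
balanced6 <- function(terminal = 0.1, internal = 0.1) {
  txt <- sprintf("((A:%f,B:%f):%f,((C:%f,D:%f):%f,(E:%f,F:%f):%f):%f);",
                 terminal, terminal, internal, terminal, terminal, internal,
                 terminal, terminal, internal, internal)
  ape::read.tree(text = txt)
}
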