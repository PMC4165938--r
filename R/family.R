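# Family classification: p-distance matrices from global alignments, an
# in-package neighbor-joining implementation with deterministic
# tie-breaking, star progressive alignment, column-resampling bootstrap,
# and anchor-based family assignment.

#' Pairwise p-distance matrix of mature peptides
#'
#' Distances are `1 - identity` from optimal global (Needleman-Wunsch,
#' affine gap) alignments; identity counts matches over all alignment
#' columns.
#'
#' @param peptides Named character vector of mature peptides.
#' @inheritParams smith_waterman
#' @return Symmetric matrix with zero diagonal, values in \[0, 1\].
#' @export
distance_matrix <- function(peptides, matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 1) {
  n <- length(peptides)
  stopifnot(n >= 2, !is.null(names(peptides)))
  d <- base::matrix(0, n, n, dimnames = list(names(peptides), names(peptides)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- 1 - pairwise_identity(peptides[[i]], peptides[[j]],
                                                  matrix, gap_open, gap_extend)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration minimising the Q criterion. Ties are broken
#' deterministically towards the lexicographically smallest pair of node
#' labels. Negative branch lengths are clamped to zero with the deficit
#' transferred to the sister branch (total path length preserved).
#'
#' @param dm Symmetric distance matrix with labelled rows/columns, n >= 3.
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop_fmt("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  }
  if (max(abs(dm - t(dm))) > 1e-8) stop_fmt("distance matrix not symmetric")
  labels <- rownames(dm)
  nodes <- labels           # newick substrings of active nodes
  names_active <- labels    # tie-break keys
  D <- dm

  fmt_bl <- function(x) formatC(max(x, 0), digits = 10, format = "g")

  while (length(nodes) > 3L) {
    m <- length(nodes)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      paste(sort(c(names_active[ij[1]], names_active[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newnode <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt_bl(li),
                       nodes[j], fmt_bl(lj))
    newname <- min(names_active[i], names_active[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], newnode)
    names_active <- c(names_active[keep], newname)
    rownames(D) <- colnames(D) <- NULL
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt_bl(l1),
                 nodes[2], fmt_bl(l2), nodes[3], fmt_bl(l3))
  ape::read.tree(text = nwk)
}

#' Star progressive multiple alignment
#'
#' Aligns every sequence to the longest member (the guide) with global
#' affine-gap alignments and merges the pairwise alignments
#' ("once a gap, always a gap"). Adequate for the short, well-conserved
#' mature defensins this package handles.
#'
#' @param peptides Named character vector.
#' @inheritParams smith_waterman
#' @return Character matrix (one row per sequence, one column per
#'   alignment position).
#' @export
align_star <- function(peptides, matrix = "BLOSUM62",
                       gap_open = 10, gap_extend = 1) {
  stopifnot(length(peptides) >= 2, !is.null(names(peptides)))
  guide_i <- which.max(nchar(peptides))
  guide <- peptides[[guide_i]]
  g <- nchar(guide)
  parsed <- lapply(seq_along(peptides), function(k) {
    if (k == guide_i) {
      return(list(ins = rep("", g + 1L),
                  col = strsplit(guide, "")[[1]]))
    }
    aln <- needleman_wunsch(peptides[[k]], guide, matrix, gap_open, gap_extend)
    pa <- strsplit(aln$aligned_a, "")[[1]]
    pg <- strsplit(aln$aligned_b, "")[[1]]
    ins <- rep("", g + 1L)
    col <- character(g)
    gi <- 0L
    for (q in seq_along(pg)) {
      if (pg[q] == "-") {
        ins[gi + 1L] <- paste0(ins[gi + 1L], pa[q])
      } else {
        gi <- gi + 1L
        col[gi] <- pa[q]
      }
    }
    list(ins = ins, col = col)
  })
  ins_len <- sapply(parsed, function(p) nchar(p$ins))
  ins_len <- base::matrix(ins_len, nrow = g + 1L)
  master <- apply(ins_len, 1, max)
  rows <- lapply(parsed, function(p) {
    out <- character(0)
    for (i in seq_len(g + 1L)) {
      pad <- paste0(p$ins[i],
                    strrep("-", master[i] - nchar(p$ins[i])))
      out <- c(out, strsplit(pad, "")[[1]])
      if (i <= g) out <- c(out, p$col[i])
    }
    out
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(peptides)
  m
}

# p-distances from an alignment matrix: mismatches over columns where
# both rows are ungapped; 1 when nothing is comparable
alignment_pdist <- function(am) {
  n <- nrow(am)
  d <- base::matrix(0, n, n, dimnames = list(rownames(am), rownames(am)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- am[i, ] != "-" & am[j, ] != "-"
      d[i, j] <- d[j, i] <- if (any(ok)) {
        mean(am[i, ok] != am[j, ok])
      } else 1
    }
  }
  d
}

#' Bootstrap support for the NJ family tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate and reports, for each internal node of the full-data tree,
#' the percentage of replicates containing that bipartition. Values below
#' 50 are conventionally masked in reports.
#'
#' @param alignment Character matrix from [align_star()] (or any multiple
#'   alignment with named rows).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; identical seeds give identical supports.
#' @return List with `tree` (full-data NJ `phylo`), `support` (numeric
#'   per internal node, percent) and `n_reps`.
#' @export
bootstrap_support <- function(alignment, n_reps = 500L, seed = 1L) {
  if (n_reps < 1L) stop_fmt("n_reps must be >= 1")
  main <- neighbor_joining(alignment_pdist(alignment))
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(alignment), ncol(alignment), replace = TRUE)
      neighbor_joining(alignment_pdist(alignment[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  list(tree = main, support = 100 * counts / n_reps, n_reps = n_reps)
}

#' Assign a peptide to a defensin family from the NJ tree
#'
#' The query receives the family of the anchors inside its smallest
#' enclosing well-supported clade. A query whose best identity to every
#' anchor is below `new_identity_max` and which sits in a well-supported
#' clade containing no anchors is labelled `"new"` (the situation that
#' defined family fDEF8).
#'
#' @param tree A `phylo` containing the query and anchor leaves.
#' @param anchors Named character vector: `family[anchor_leaf_name]`.
#' @param query Query leaf name.
#' @param support Per-internal-node support (percent) as returned by
#'   [bootstrap_support()]; `NULL` treats every edge as supported.
#' @param identity Optional named vector of query-anchor identities.
#' @param min_support Support threshold (percent) for a usable clade.
#' @param new_identity_max Identity ceiling below which an anchor-free
#'   supported clade is called a new family.
#' @return A family label or `"new"`.
#' @export
assign_family <- function(tree, anchors, query, support = NULL,
                          identity = NULL, min_support = 50,
                          new_identity_max = 0.30) {
  tips <- tree$tip.label
  if (!query %in% tips) stop_fmt("query '%s' not in tree", query)
  if (query %in% names(anchors)) return(unname(anchors[[query]]))
  ntip <- length(tips)
  root <- ntip + 1L
  qtip <- match(query, tips)
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  clade_tips <- function(node) {
    tips[intersect(seq_len(ntip),
                   c(node, phangorn_descendants(tree, node)))]
  }
  node_support <- function(node) {
    if (is.null(support)) return(100)
    s <- support[node - ntip]
    if (is.na(s)) 0 else s
  }
  best_id <- if (!is.null(identity)) max(identity) else NA_real_

  node <- qtip
  anchored_family <- NULL
  new_clade <- FALSE
  repeat {
    par <- parent_of(node)
    if (length(par) == 0L) break
    node <- par
    if (node == root || node_support(node) < min_support) {
      if (node == root) break else next
    }
    members <- clade_tips(node)
    fams <- anchors[intersect(members, names(anchors))]
    if (length(fams) == 0L) {
      if (length(members) >= 2L) new_clade <- TRUE
      next
    }
    # only a clade whose anchors agree on one family is informative;
    # a mixed-family clade (e.g. near the root) carries no signal and
    # assignment falls back to best pairwise identity
    if (length(unique(fams)) == 1L) {
      anchored_family <- unique(unname(fams))
    }
    break
  }
  if (!is.na(best_id) && best_id < new_identity_max && new_clade) {
    return("new")
  }
  if (!is.null(anchored_family)) return(anchored_family)
  if (!is.na(best_id)) {
    if (best_id >= new_identity_max) {
      return(unname(anchors[[names(which.max(identity))]]))
    }
    return("new")
  }
  "unassigned"
}

# internal: all descendants of a node (tips and internal), iterative DFS
phangorn_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > length(tree$tip.label)])
  }
  out
}
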