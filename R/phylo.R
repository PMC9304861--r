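# BfuB distance tree and clade partitioning. The tree is a neighbor-joining
# tree on pairwise global-alignment distances (the downstream computation -
# threshold partition and clade/class association - needs only a tree with
# branch lengths). Clades are the leaf-containing components left after
# cutting every edge at or above the branch-length threshold; singleton
# clades are flagged orphan.

#' Pairwise alignment distance matrix
#'
#' Base distance between two sequences is one minus the fraction of
#' identical aligned columns, over columns where neither sequence has a
#' gap, from a global pairwise alignment. With `correction = "poisson"`
#' the p-distance is transformed to an expected substitutions-per-site
#' scale, `d = -(19/20) log(1 - (20/19) p)` (20-letter Poisson multiple-hit
#' correction, capped at 10 where the argument is non-positive). The tree
#' stage uses the corrected scale because the clade threshold is defined
#' on branch lengths in substitutions per site, where raw identity
#' saturates.
#'
#' @param sequences Named character vector of amino-acid sequences (>= 2).
#' @param config Alignment scoring configuration.
#' @param correction `"none"` (raw p-distance, default) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = names.
#' @export
distance_matrix <- function(sequences, config = alignment_config(),
                            correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  n <- length(sequences)
  stopifnot(n >= 2)
  if (any(nchar(sequences) == 0)) stop("sequence of length 0")
  if (is.null(names(sequences))) names(sequences) <- paste0("s", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      aln <- align_to_reference(sequences[[i]], sequences[[j]], config)
      q <- strsplit(aln$query_aln, "")[[1]]
      r <- strsplit(aln$ref_aln, "")[[1]]
      keep <- q != "-" & r != "-"
      d <- 1 - sum(q[keep] == r[keep]) / sum(keep)
      if (correction == "poisson") {
        arg <- 1 - d * 20 / 19
        d <- if (arg <= 0) 10 else -(19 / 20) * log(arg)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining with deterministic tie-breaking: when several
#' pairs minimize the Q criterion, the lexicographically smallest pair of
#' leaf labels (each subtree represented by its smallest leaf) is joined.
#' Negative estimated branch lengths are clamped to zero. The returned
#' tree is unrooted with the conventional trifurcating root.
#'
#' @param D Symmetric distance matrix with dimnames (n >= 3).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  n <- nrow(D)
  if (is.null(dimnames(D))) {
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
  }
  if (n < 3) stop("need at least 3 leaves for neighbor joining")
  if (!isTRUE(all.equal(D, t(D)))) stop("distance matrix must be symmetric")
  labels <- rownames(D)
  # each active element: a newick fragment and its smallest leaf label
  frag <- labels
  rep_leaf <- labels
  fmt <- function(x) sprintf("%.10g", max(0, x))
  while (n > 3) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keypair <- apply(cand, 1, function(ij) {
      p <- sort(c(rep_leaf[ij[1]], rep_leaf[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keypair)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    new_frag <- paste0("(", frag[i], ":", fmt(li), ",",
                       frag[j], ":", fmt(lj), ")")
    new_rep <- min(rep_leaf[i], rep_leaf[j])
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_leaf <- c(rep_leaf[keep], new_rep)
    D <- D2
    n <- n - 1
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(l1), ",", frag[2], ":", fmt(l2),
                ",", frag[3], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

#' Partition a tree into clades at a branch-length threshold
#'
#' Deletes every edge with length >= `threshold`; each remaining
#' leaf-containing connected component is a clade. Clade ids are assigned
#' deterministically by each clade's smallest leaf label; singleton clades
#' are flagged orphan.
#'
#' @param tree An [ape::phylo] with edge lengths.
#' @param threshold Positive cut threshold (default 0.33).
#' @return List: `leaf_clade` (named character leaf -> clade id), `clades`
#'   (data.frame: clade_id, n, is_orphan, members), `threshold`.
#' @export
partition_clades <- function(tree, threshold = 0.33) {
  if (threshold <= 0) stop("threshold must be positive")
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  n_tip <- length(tree$tip.label)
  keep <- tree$edge.length < threshold
  n_nodes <- max(tree$edge)
  g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  if (any(keep)) {
    g <- igraph::add_edges(g, t(tree$edge[keep, , drop = FALSE]))
  }
  comp <- igraph::components(g)$membership[seq_len(n_tip)]
  leaves_by_comp <- split(tree$tip.label, comp)
  ord <- order(vapply(leaves_by_comp, min, ""))
  leaves_by_comp <- leaves_by_comp[ord]
  clade_ids <- sprintf("clade%02d", seq_along(leaves_by_comp))
  leaf_clade <- character(n_tip)
  names(leaf_clade) <- tree$tip.label
  for (k in seq_along(leaves_by_comp)) {
    leaf_clade[leaves_by_comp[[k]]] <- clade_ids[k]
  }
  clades <- data.frame(
    clade_id = clade_ids,
    n = lengths(leaves_by_comp),
    is_orphan = lengths(leaves_by_comp) == 1L,
    members = vapply(leaves_by_comp, function(x)
      paste(sort(x), collapse = ","), ""),
    stringsAsFactors = FALSE)
  rownames(clades) <- NULL
  list(leaf_clade = leaf_clade, clades = clades, threshold = threshold)
}

#' Per-clade class composition
#'
#' Contingency table of clade by functional class (the clade/function
#' association summary). Leaves without a classification are counted as
#' Unknown with a warning. An optional outgroup leaf is excluded.
#'
#' @param partition From [partition_clades()].
#' @param classifications data.frame with columns `bfub_protein` and
#'   `class_name` (as from [classify_dataset()]), or a named character
#'   vector leaf -> class.
#' @param outgroup Optional leaf id excluded from counting.
#' @return A `table` clade x class.
#' @export
clade_summary <- function(partition, classifications, outgroup = NULL) {
  leaf_clade <- partition$leaf_clade
  if (!is.null(outgroup)) {
    leaf_clade <- leaf_clade[setdiff(names(leaf_clade), outgroup)]
  }
  if (length(leaf_clade) == 0) {
    return(table(clade = character(), class = character()))
  }
  if (is.data.frame(classifications)) {
    cls <- stats::setNames(classifications$class_name,
                           classifications$bfub_protein)
  } else {
    cls <- classifications
  }
  class_of <- cls[names(leaf_clade)]
  if (anyNA(class_of)) {
    warning("leaves without classification counted as Unknown: ",
            paste(names(leaf_clade)[is.na(class_of)], collapse = ", "))
    class_of[is.na(class_of)] <- "Unknown"
  }
  table(clade = leaf_clade, class = class_of)
}
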