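# Independent oracles used across the suite. These are deliberately naive
# implementations (direct recursions, hand BFS, enumeration) kept separate
# from the code paths they check.

AA_ORACLE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA_ORACLE, n, replace = TRUE),
                               collapse = "")

# Brute-force affine-gap global alignment score (Gotoh three-state DP,
# written independently of Biostrings). A gap of length L costs
# open + L * ext; terminal gaps are penalized (true global alignment).
oracle_align_score <- function(a, b, submat, open = 10, ext = 0.5) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consume x)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consume y)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[x[i], y[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Hand BFS over the edge-filtered tree graph: returns the set of leaf
# groups (each sorted, list sorted by first member) left after removing
# edges with length >= threshold.
oracle_clades <- function(tree, threshold) {
  keep <- tree$edge.length < threshold
  edges <- tree$edge[keep, , drop = FALSE]
  n_nodes <- max(tree$edge)
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n_nodes)
  groups <- list()
  for (v in seq_len(n_nodes)) {
    if (seen[v]) next
    queue <- v; comp <- integer()
    seen[v] <- TRUE
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]]) {
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    leaves <- comp[comp <= length(tree$tip.label)]
    if (length(leaves) > 0) {
      groups[[length(groups) + 1]] <- sort(tree$tip.label[leaves])
    }
  }
  groups[order(vapply(groups, `[`, "", 1))]
}

clade_groups_from_partition <- function(partition) {
  g <- split(names(partition$leaf_clade), partition$leaf_clade)
  g <- lapply(g, sort)
  unname(g[order(vapply(g, `[`, "", 1))])
}

# Random unrooted binary tree with branch lengths bounded away from zero,
# plus its exact additive (path-length) distance matrix.
random_additive_case <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# Electron bookkeeping oracle for mechanism events: electrons entering the
# enzyme (core + bound carriers) minus electrons leaving, per event.
oracle_event_flux <- c(
  oxidize_H2 = 2, produce_H2 = -2,
  bind_NADH = 2, release_NADH = -2,
  bind_Fd_red = 2, release_Fd_red = -2,
  relay_electron = 0, relay_back = 0,
  bind_NAD = 0, release_NAD = 0,
  reduce_Fd = 0, oxidize_Fd_red = 0,
  b1_to_fmn = 0, fmn_to_b1 = 0)

mech_total_electrons <- function(state) {
  core_electrons(state) + 2L * as.integer("Fd_red" %in% state$bound)
}
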