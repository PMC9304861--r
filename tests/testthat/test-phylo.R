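test_that("alignment distances match hand-computed values", {
  expect_equal(unname(distance_matrix(c(a = "MKVL", b = "MKVL"))["a", "b"]),
               0)
  D <- distance_matrix(c(a = "AAAA", b = "AAAT"))
  expect_equal(unname(D["a", "b"]), 0.25)
  set.seed(71)
  seqs <- vapply(1:8, function(i) random_aa(40), "")
  names(seqs) <- paste0("s", 1:8)
  M <- distance_matrix(seqs)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_error(distance_matrix(c(a = "AA", b = "")), "length 0")
})

test_that("three leaves give the closed-form star", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(lens["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(lens["c"]), (4 + 5 - 3) / 2)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers additive topologies and matches ape", {
  set.seed(72)
  for (rep in 1:40) {
    case <- random_additive_case(sample(4:12, 1))
    tr <- nj_tree(case$D)
    expect_equal(ape::dist.topo(ape::unroot(case$tree), tr), 0,
                 ignore_attr = TRUE)
    # independent cross-check: classic NJ from ape on the same matrix
    expect_equal(ape::dist.topo(ape::nj(case$D), tr), 0,
                 ignore_attr = TRUE)
    # branch lengths reproduce the additive distances exactly
    expect_equal(ape::cophenetic.phylo(tr)[rownames(case$D),
                                           colnames(case$D)],
                 case$D, tolerance = 1e-8)
  }
})

test_that("leaf order permutation leaves the unrooted topology unchanged", {
  set.seed(73)
  for (rep in 1:10) {
    case <- random_additive_case(8)
    perm <- sample(8)
    tr1 <- nj_tree(case$D)
    tr2 <- nj_tree(case$D[perm, perm])
    expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
  }
})

test_that("clade partition handles the simple hand cases", {
  all_short <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  p <- partition_clades(all_short, 0.33)
  expect_equal(nrow(p$clades), 1)
  expect_false(any(p$clades$is_orphan))

  # star with two long stems: two orphans plus one clade of the rest
  star <- ape::read.tree(text = "(a:0.5,b:0.4,c:0.1,d:0.1,e:0.1);")
  p2 <- partition_clades(star, 0.33)
  expect_equal(sum(p2$clades$is_orphan), 2)
  expect_equal(sort(p2$clades$n), c(1L, 1L, 3L))
  expect_error(partition_clades(star, 0), "positive")
})

test_that("clade partition equals the BFS components oracle", {
  set.seed(74)
  for (rep in 1:60) {
    tr <- ape::rtree(sample(4:30, 1),
                     br = function(k) stats::runif(k, 0, 0.6))
    thr <- stats::runif(1, 0.05, 0.5)
    p <- partition_clades(tr, thr)
    expect_equal(clade_groups_from_partition(p), oracle_clades(tr, thr))
  }
})

test_that("raising the threshold never increases the number of clades", {
  set.seed(75)
  for (rep in 1:15) {
    tr <- ape::rtree(12, br = function(k) stats::runif(k, 0, 0.6))
    thresholds <- sort(stats::runif(5, 0.05, 0.6))
    n_clades <- vapply(thresholds, function(th)
      nrow(partition_clades(tr, th)$clades), 0L)
    expect_true(all(diff(n_clades) <= 0))
  }
})

test_that("clade summaries tabulate class composition", {
  part <- list(leaf_clade = c(x1 = "clade01", x2 = "clade01",
                              y1 = "clade02"),
               clades = NULL, threshold = 0.33)
  cls <- c(x1 = "FeFe", x2 = "FeFe", y1 = "Nfn")
  tab <- clade_summary(part, cls)
  expect_equal(unname(tab["clade01", "FeFe"]), 2L)
  expect_equal(unname(tab["clade02", "Nfn"]), 1L)
  expect_equal(sum(tab), 3L)
  # missing classification counted as Unknown with a warning
  expect_warning(tab2 <- clade_summary(part, cls[-3]), "Unknown")
  expect_equal(unname(tab2["clade02", "Unknown"]), 1L)
  # outgroup excluded
  tab3 <- clade_summary(part, cls, outgroup = "y1")
  expect_equal(sum(tab3), 2L)
  empty <- clade_summary(list(leaf_clade = character()), cls)
  expect_equal(length(empty), 0L)
})

test_that("the designed cohort separates templates into intended clades", {
  co <- generate_cohort(n_per_template = 3,
                        templates = c("FeFe", "NiFe", "Rub"),
                        divergence_within = 0.05,
                        divergence_between = 0.45, seed = 76)
  seqs <- setNames(
    co$proteins$sequence[match(co$truth$bfub_id, co$proteins$protein_id)],
    co$truth$bfub_id)
  D <- distance_matrix(seqs, correction = "poisson")
  p <- partition_clades(nj_tree(D), 0.33)
  groups <- split(co$truth$bfub_id, co$truth$clade_id)
  expect_equal(nrow(p$clades), 3)
  for (g in groups) {
    expect_length(unique(p$leaf_clade[g]), 1)
  }
})
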