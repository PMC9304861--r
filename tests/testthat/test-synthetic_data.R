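test_that("reference subunits carry the planted B2 and FMN signatures", {
  ref <- make_reference_proteins(seed = 1)
  b <- strsplit(ref$sequences[["BfuB"]], "")[[1]]
  expect_equal(b[525], "H")
  expect_equal(b[476], "C")
  expect_equal(b[c(438, 531, 536)], c("C", "C", "C"))
  expect_equal(b[c(182, 202, 204)], c("F", "A", "M"))
  thr <- make_reference_proteins(seed = 1, b2_variant = "thr")
  expect_equal(strsplit(thr$sequences[["BfuB"]], "")[[1]][476], "T")
  expect_identical(make_reference_proteins(seed = 1),
                   make_reference_proteins(seed = 1))
  expect_false(identical(ref$sequences, make_reference_proteins(2)$sequences))
})

test_that("operon templates satisfy their structural constraints", {
  tl <- operon_templates()
  expect_length(tl, 15)
  expect_false("bfuA" %in% tl$Rub$roles)
  # Codh catalytic genes sit between bfuB and bfuA
  r <- tl$Codh$roles
  expect_true(all(which(r %in% c("codh_d", "codh_e", "codh_f")) >
                    which(r == "bfuB")))
  expect_true(all(which(r %in% c("codh_d", "codh_e", "codh_f")) <
                    which(r == "bfuA")))
  count_holo <- function(t) sum(!t$roles %in% c("hisK", "hydD"))
  expect_equal(count_holo(tl$Nuo), 14)
  expect_equal(count_holo(tl$Bam), 8)
  # every template has exactly one bfuB
  expect_true(all(vapply(tl, function(t) sum(t$roles == "bfuB"), 0L) == 1L))
})

test_that("generated genomes follow their template layout", {
  rub <- generate_genome("Rub", seed = 5, n_decoy_genes = 2)
  roles <- rub$features$role_label
  expect_false("bfuA" %in% roles)
  expect_equal(roles[which(roles == "bfuB") + 1L], "rub")
  codh <- generate_genome("Codh", seed = 5)
  r <- codh$features$role_label
  expect_true(all(which(r %in% c("codh_d", "codh_e", "codh_f")) >
                    which(r == "bfuB")))
  expect_true(all(which(r %in% c("codh_d", "codh_e", "codh_f")) <
                    which(r == "bfuA")))
  expect_error(generate_genome("NotATemplate"), "unknown template")
})

test_that("divergence zero reproduces the reference outside fusions", {
  g <- generate_genome("NiFe", seed = 9, divergence = 0)
  frame <- default_reference_frame()
  seq_of <- function(id) g$proteins$sequence[g$proteins$protein_id == id]
  expect_equal(seq_of(g$truth$bfub_id), unname(frame$sequences[["BfuB"]]))
  expect_equal(seq_of(g$truth$bfuc_id), unname(frame$sequences[["BfuC"]]))
  # FeFe bfuA is the reference core plus a fused extension
  fe <- generate_genome("FeFe", seed = 9, divergence = 0)
  a <- fe$proteins$sequence[fe$proteins$protein_id == fe$truth$bfua_id]
  core <- default_reference_frame()$sequences[["BfuA"]]
  chars <- strsplit(core, "")[[1]]
  # A3/A5 are outside the FeFe profile: knocked to Ala in the planted gene
  for (cl in c("A3", "A5")) {
    chars[frame$ligands$BfuA[[cl]]$pos] <- "A"
  }
  expect_equal(substr(a, 1, nchar(core)), paste(chars, collapse = ""))
})

test_that("generation is deterministic per seed and varies across seeds", {
  a <- generate_genome("Wor", seed = 11, divergence = 0.1)
  b <- generate_genome("Wor", seed = 11, divergence = 0.1)
  expect_identical(a, b)
  c <- generate_genome("Wor", seed = 12, divergence = 0.1)
  expect_false(identical(a$proteins$sequence, c$proteins$sequence))
})

test_that("ablation removes exactly the named signal and updates truth", {
  g <- generate_genome("FeFe", seed = 13)
  for (cl in paste0("B", 2:5)) g <- ablate(g, cl)
  expect_equal(g$truth$expected_type, "NonBifurcating")
  hit <- g$motifs[g$motifs$cluster == "B3", ]
  expect_true(all(hit$residue == "A"))
  # untouched cluster still intact
  expect_true(all(g$motifs$residue[g$motifs$cluster == "B1"] == "C"))

  w <- ablate(generate_genome("Wor", seed = 13), "bfuA")
  expect_equal(w$truth$expected_type, "Unclassified")
  expect_false(any(w$features$role_label == "bfuA"))

  f <- ablate(generate_genome("FeFe", seed = 13), "A4")
  expect_equal(f$truth$entry_cluster, "none")  # FeFe profile has no A3

  n <- ablate(generate_genome("NiFe", seed = 13), "A3")
  expect_equal(n$truth$expected_type, "T2")
  expect_equal(n$truth$entry_cluster, "A4")

  expect_error(ablate(generate_genome("Rub", seed = 13), "bfuA"),
               "not present")
  # ablate o generate is reproducible
  expect_identical(ablate(generate_genome("FeFe", seed = 13), "His525"),
                   ablate(generate_genome("FeFe", seed = 13), "His525"))
})

test_that("cohorts carry intended clade structure in their truth", {
  co <- generate_cohort(n_per_template = 4,
                        templates = c("FeFe", "NiFe", "Rub"), seed = 21)
  expect_equal(nrow(co$truth), 12)
  expect_equal(sort(unique(co$truth$clade_id)), c("FeFe", "NiFe", "Rub"))
  expect_equal(unname(table(co$truth$clade_id)), rep(4L, 3),
               ignore_attr = TRUE)
  one <- generate_cohort(n_per_template = 1,
                         templates = c("FeFe", "Wor"), seed = 22)
  expect_equal(unname(table(one$truth$clade_id)), rep(1L, 2),
               ignore_attr = TRUE)
  alt <- generate_cohort(n_per_template = 4,
                         templates = c("FeFe", "NiFe", "Rub"), seed = 23)
  expect_false(identical(co$proteins$sequence, alt$proteins$sequence))
})
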