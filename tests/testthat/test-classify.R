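mk_calls <- function(present) {
  data.frame(cluster = paste0("A", 1:5),
             status = ifelse(paste0("A", 1:5) %in% present,
                             "present", "absent"),
             stringsAsFactors = FALSE)
}
core_ok <- list(bifurcating = TRUE, reasons = character())
core_bad <- list(bifurcating = FALSE, reasons = "B2 absent")

test_that("the decision table is total and deterministic", {
  profiles <- list(character(), c("A1", "A2"), c("A1", "A2", "A4"),
                   c("A1", "A2", "A3", "A5"), paste0("A", 1:5))
  n <- 0
  for (core in list(core_ok, core_bad)) {
    for (bfua in c(TRUE, FALSE)) {
      for (fused in c(TRUE, FALSE)) {
        for (extra in c(TRUE, FALSE)) {
          for (cls in c("FeFe", "Rub", "Unknown")) {
            for (prof in profiles) {
              if (fused && cls == "Rub") next  # contradictory by contract
              v <- assign_type(core, bfua, mk_calls(prof),
                               bfuA_has_fused_catalytic = fused,
                               extra_catalytic_subunits = extra,
                               call = list(class_name = cls))
              n <- n + 1
              expect_true(v$type %in% c("T1", "T2", "T3", "T4",
                                        "NonBifurcating", "Unclassified"))
              expect_true(v$entry %in% c("A3", "A4", "direct", "none"))
              # invariants of the verdict type
              if (v$type == "T4") expect_equal(v$entry, "direct")
              if (v$type == "T2") expect_equal(v$entry, "A4")
              if (v$type == "T3") expect_equal(v$entry, "A3")
              if (v$type == "NonBifurcating") expect_equal(v$entry, "none")
              # repeat call gives the identical verdict
              expect_identical(v, assign_type(
                core, bfua, mk_calls(prof),
                bfuA_has_fused_catalytic = fused,
                extra_catalytic_subunits = extra,
                call = list(class_name = cls)))
            }
          }
        }
      }
    }
  }
  # 2 cores x 2 bfuA x 2 fused x 2 extra x 3 classes x 5 profiles,
  # minus the 40 contradictory fused-Rub combinations skipped above
  expect_equal(n, 240 - 40)
  expect_error(assign_type(core_ok, TRUE, mk_calls("A4"),
                           bfuA_has_fused_catalytic = TRUE,
                           extra_catalytic_subunits = FALSE,
                           call = list(class_name = "Rub")),
               "contradictory")
})

test_that("the printed prototypes map to their published types", {
  expect_equal(assign_type(core_ok, TRUE, mk_calls(c("A1", "A2", "A4")),
                           TRUE, FALSE, list(class_name = "FeFe"))[
                             c("type", "entry")],
               list(type = "T1", entry = "A4"))
  # Tsib-style Nfn: no A4, fused catalytic domain
  expect_equal(assign_type(core_ok, TRUE, mk_calls(c("A1", "A2", "A3", "A5")),
                           TRUE, FALSE, list(class_name = "Nfn"))[
                             c("type", "entry")],
               list(type = "T1", entry = "A3"))
  expect_equal(assign_type(core_ok, TRUE, mk_calls(paste0("A", 1:5)),
                           FALSE, TRUE, list(class_name = "NiFe"))[
                             c("type", "entry")],
               list(type = "T3", entry = "A3"))
  expect_equal(assign_type(core_ok, TRUE, mk_calls(c("A1", "A2", "A4")),
                           FALSE, TRUE, list(class_name = "Wor"))[
                             c("type", "entry")],
               list(type = "T2", entry = "A4"))
  expect_equal(assign_type(core_bad, TRUE, mk_calls(paste0("A", 1:5)),
                           FALSE, TRUE, list(class_name = "NiFe"))$type,
               "NonBifurcating")
  expect_equal(assign_type(core_ok, FALSE, NULL, FALSE, TRUE,
                           list(class_name = "Rub"))[c("type", "entry")],
               list(type = "T4", entry = "direct"))
  expect_equal(assign_type(core_ok, FALSE, NULL, FALSE, FALSE,
                           list(class_name = "Unknown"))$type,
               "Unclassified")
})

test_that("an empty dataset gives an empty classification table", {
  empty <- list(proteins = data.frame(protein_id = character(),
                                      sequence = character(),
                                      genome_id = character(),
                                      is_metagenomic = logical()),
                features = bfuscan:::empty_features(),
                domains = data.frame(protein_id = character(),
                                     domain_id = character(),
                                     start = integer(), end = integer(),
                                     score = numeric()))
  out <- classify_dataset(empty)
  expect_equal(nrow(out), 0)
})

test_that("a non-bifurcating homolog in a cohort is demoted, not classified", {
  g <- generate_genome("FeFe", seed = 61, include_nonbifurcating = TRUE)
  cls <- classify_dataset(g)
  expect_equal(nrow(cls), 2)
  nq <- cls[cls$bfub_protein == g$truth$nonbif_id, ]
  expect_equal(nq$type, "NonBifurcating")
  expect_false(nq$bifurcating)
  real <- cls[cls$bfub_protein == g$truth$bfub_id, ]
  expect_equal(real$type, "T1")
})
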