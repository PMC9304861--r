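frame <- default_reference_frame()

test_that("alignment position map handles identity and deletions", {
  s <- "MKVLACDEFGH"
  aln <- align_to_reference(s, s)
  expect_equal(aln$map, seq_len(nchar(s)))
  # delete residue 5 from the query: later positions shift back by one
  del <- paste0(substr(s, 1, 4), substr(s, 6, nchar(s)))
  aln2 <- align_to_reference(del, s)
  expect_equal(aln2$map[1:4], 1:4)
  expect_true(is.na(aln2$map[5]))
  expect_equal(aln2$map[6:11], 5:10)
})

test_that("alignment score equals the brute-force DP oracle", {
  submat <- get("get_submat", asNamespace("bfuscan"))("BLOSUM62")
  set.seed(41)
  for (rep in 1:30) {
    a <- random_aa(sample(3:12, 1))
    b <- random_aa(sample(3:12, 1))
    expect_equal(align_to_reference(a, b)$score,
                 oracle_align_score(a, b, submat), tolerance = 1e-9)
  }
})

test_that("cluster calls recover planted content and ablations", {
  q <- frame$sequences[["BfuB"]]
  aln <- align_to_reference(q, q)
  calls <- call_clusters(aln, q, frame, "BfuB")
  expect_true(all(calls$status == "present"))

  a <- frame$sequences[["BfuA"]]
  chars <- strsplit(a, "")[[1]]
  chars[frame$ligands$BfuA$A4$pos] <- "A"
  mut <- paste(chars, collapse = "")
  calls_a <- call_clusters(align_to_reference(mut, a), mut, frame, "BfuA")
  expect_equal(calls_a$status[calls_a$cluster == "A4"], "absent")
  expect_equal(calls_a$status[calls_a$cluster == "A3"], "present")
  expect_error(call_clusters(aln, q, frame, "BfuX"), "no reference")
})

test_that("presence status follows the threshold rule over all ablation depths", {
  a <- frame$sequences[["BfuA"]]
  pos <- frame$ligands$BfuA$A1$pos
  for (k in 0:4) {
    chars <- strsplit(a, "")[[1]]
    if (k > 0) chars[pos[seq_len(k)]] <- "A"
    mut <- paste(chars, collapse = "")
    calls <- call_clusters(align_to_reference(mut, a), mut, frame, "BfuA")
    frac <- (4 - k) / 4
    want <- if (frac >= 0.75) "present" else if (frac == 0) "absent"
            else "partial"
    expect_equal(calls$status[calls$cluster == "A1"], want,
                 label = paste("k =", k))
    expect_equal(calls$match_fraction[calls$cluster == "A1"], frac)
  }
})

test_that("restoring an ablated ligand never demotes a cluster", {
  a <- frame$sequences[["BfuA"]]
  pos <- frame$ligands$BfuA$A2$pos
  rank <- c(absent = 0, partial = 1, present = 2)
  prev <- -1
  for (k in 4:0) {  # restore one ligand at a time
    chars <- strsplit(a, "")[[1]]
    if (k > 0) chars[pos[seq_len(k)]] <- "A"
    mut <- paste(chars, collapse = "")
    calls <- call_clusters(align_to_reference(mut, a), mut, frame, "BfuA")
    now <- rank[[calls$status[calls$cluster == "A2"]]]
    expect_gte(now, prev)
    prev <- now
  }
})

test_that("B2 signature reads His525 and the FeA ligand variant", {
  q <- frame$sequences[["BfuB"]]
  sig <- b2_signature(align_to_reference(q, q), q, frame)
  expect_true(sig$his525_present)
  expect_equal(sig$feA476_residue, "C")
  expect_true(sig$canonical)

  thr <- default_reference_frame(b2_variant = "thr")$sequences[["BfuB"]]
  sig_t <- b2_signature(align_to_reference(thr, q), thr, frame)
  expect_true(sig_t$his525_present)
  expect_equal(sig_t$feA476_residue, "T")

  chars <- strsplit(q, "")[[1]]; chars[525] <- "A"
  mut <- paste(chars, collapse = "")
  sig_h <- b2_signature(align_to_reference(mut, q), mut, frame)
  expect_false(sig_h$his525_present)
})

test_that("core verdict requires B2-B5, C1 and His525", {
  q <- frame$sequences[["BfuB"]]
  c_seq <- frame$sequences[["BfuC"]]
  alnB <- align_to_reference(q, q)
  callsB <- call_clusters(alnB, q, frame, "BfuB")
  callsC <- call_clusters(align_to_reference(c_seq, c_seq), c_seq, frame,
                          "BfuC")
  sig <- b2_signature(alnB, q, frame)
  expect_true(core_verdict(callsB, callsC, sig)$bifurcating)

  # Nqo-style homolog: B2-B5 substituted to Ala
  chars <- strsplit(q, "")[[1]]
  for (cl in paste0("B", 2:5)) chars[frame$ligands$BfuB[[cl]]$pos] <- "A"
  nqo <- paste(chars, collapse = "")
  alnN <- align_to_reference(nqo, q)
  v <- core_verdict(call_clusters(alnN, nqo, frame, "BfuB"), callsC,
                    b2_signature(alnN, nqo, frame))
  expect_false(v$bifurcating)
  expect_true(any(grepl("B2", v$reasons)))
  expect_true(any(grepl("His525", v$reasons)))

  # losing only C1 is enough to break the core
  cc <- strsplit(c_seq, "")[[1]]
  cc[frame$ligands$BfuC$C1$pos] <- "A"
  c_mut <- paste(cc, collapse = "")
  v2 <- core_verdict(callsB,
                     call_clusters(align_to_reference(c_mut, c_seq), c_mut,
                                   frame, "BfuC"), sig)
  expect_false(v2$bifurcating)
  expect_equal(v2$reasons, "C1 absent")
})

test_that("entry cluster prefers A4, falls back to A3, flags neither", {
  mk <- function(present) {
    data.frame(cluster = paste0("A", 1:5),
               status = ifelse(paste0("A", 1:5) %in% present,
                               "present", "absent"),
               stringsAsFactors = FALSE)
  }
  expect_equal(entry_cluster(mk(c("A1", "A2", "A4"))), "A4")
  expect_equal(entry_cluster(mk(c("A1", "A2", "A3", "A5"))), "A3")
  expect_equal(entry_cluster(mk(c("A1", "A2"))), "none")
})
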