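# Synthetic genomes with planted Bfu operons.
#
# The generator is first-class, tested code: it defines the ground truth
# (class, structural type, entry cluster, ligand-motif positions, intended
# clade) that every downstream stage is validated against. Operon layouts
# follow the published gene-cluster organisations of the fifteen packaged
# templates; sequence divergence is i.i.d. substitution outside planted
# signal positions.

BFUB_DOMAINS <- c("IPR011538", "IPR019554", "IPR019575", "IPR017896")
BFUC_DOMAIN <- "IPR002023"
BFUA_DOMAINS <- c("IPR017896", "IPR001041")

# Synthetic accessions for catalytic domains fused to BfuA (Type 1 markers).
FUSED_DOMAIN_IDS <- c(
  h_cluster = "SYND_HCLUSTER",
  nfn_fad = "SYND_NFNFAD",
  pterin = "SYND_PTERIN",
  f420_fad = "SYND_F420FAD"
)

#' Packaged operon templates
#'
#' One template per gene-cluster organisation: ordered gene roles, the
#' catalytic domain fused to BfuA (Type 1 enzymes only), the BfuA
#' iron-sulfur cluster profile, the B2 ligand variant (Thr at the FeA
#' position in FeFe-style enzymes), and the expected class/type/entry
#' ground truth. The three Fdh templates (fused, Type 2 and Type 3
#' configurations) all map to functional class Fdh.
#'
#' @return Named list of templates.
#' @export
operon_templates <- function() {
  t <- list(
    FeFe = list(class_name = "FeFe",
                roles = c("bfuB", "bfuC", "bfuA"),
                fused = "h_cluster", profile = c("A1", "A2", "A4"),
                b2_variant = "thr", expected_type = "T1", entry = "A4"),
    NiFe = list(class_name = "NiFe",
                roles = c("bfuA", "bfuB", "bfuC", "nife_s", "nife_l",
                          "hisK", "hydD"),
                fused = NULL, profile = paste0("A", 1:5),
                b2_variant = "cys", expected_type = "T3", entry = "A3"),
    Fdh1 = list(class_name = "Fdh",
                roles = c("bfuB", "bfuC", "bfuA"),
                fused = "pterin", profile = paste0("A", 1:5),
                b2_variant = "cys", expected_type = "T1", entry = "A4"),
    Fdh2 = list(class_name = "Fdh",
                roles = c("bfuB", "bfuC", "bfuA", "fdh_a"),
                fused = NULL, profile = c("A1", "A2", "A4"),
                b2_variant = "cys", expected_type = "T2", entry = "A4"),
    Fdh3 = list(class_name = "Fdh",
                roles = c("bfuB", "bfuC", "bfuA", "fdh_a"),
                fused = NULL, profile = paste0("A", 1:5),
                b2_variant = "cys", expected_type = "T3", entry = "A3"),
    FdhFeFe = list(class_name = "FdhFeFe",
                   roles = c("bfuB", "bfuC", "bfuA", "fdh_a", "hyt_a"),
                   fused = NULL, profile = c("A1", "A2", "A4"),
                   b2_variant = "thr", expected_type = "T2", entry = "A4"),
    Nfn = list(class_name = "Nfn",
               roles = c("bfuB", "bfuC", "bfuA"),
               fused = "nfn_fad", profile = c("A1", "A2", "A3", "A5"),
               b2_variant = "cys", expected_type = "T1", entry = "A3"),
    F420 = list(class_name = "F420",
                roles = c("bfuB", "bfuC", "bfuA"),
                fused = "f420_fad", profile = c("A1", "A2", "A4"),
                b2_variant = "cys", expected_type = "T1", entry = "A4"),
    Wor = list(class_name = "Wor",
               roles = c("bfuA", "bfuB", "bfuC", "wor_s", "wor_l"),
               fused = NULL, profile = c("A1", "A2", "A4"),
               b2_variant = "cys", expected_type = "T2", entry = "A4"),
    Bam = list(class_name = "Bam",
               roles = c("bam_b", "bam_c", "bam_d", "bam_e", "bam_f",
                         "bfuC", "bfuB", "bfuA"),
               fused = NULL, profile = c("A1", "A2", "A4"),
               b2_variant = "cys", expected_type = "T2", entry = "A4"),
    Por = list(class_name = "Por",
               roles = c("bfuA", "bfuB", "bfuC", "por_d", "por_e",
                         "por_f", "por_g"),
               fused = NULL, profile = c("A1", "A2", "A4"),
               b2_variant = "cys", expected_type = "T2", entry = "A4"),
    Codh = list(class_name = "Codh",
                roles = c("bfuB", "codh_d", "codh_e", "codh_f", "bfuA",
                          "bfuC"),
                fused = NULL, profile = c("A1", "A2", "A4"),
                b2_variant = "cys", expected_type = "T2", entry = "A4"),
    Mbh = list(class_name = "Mbh",
               roles = c("mbh_a", "mbh_b", "mbh_c", "bfuA", "bfuB", "bfuC",
                         "mbh_d", "mbh_e", "mbh_f"),
               fused = NULL, profile = c("A1", "A2", "A4"),
               b2_variant = "cys", expected_type = "T2", entry = "A4"),
    Nuo = list(class_name = "Nuo",
               roles = c("nuo_a", "nuo_b", "nuo_c", "nuo_d", "bfuA",
                         "bfuB", "bfuC", "nuo_h", "nuo_i", "nuo_j",
                         "nuo_k", "nuo_l", "nuo_m", "nuo_n"),
               fused = NULL, profile = paste0("A", 1:5),
               b2_variant = "cys", expected_type = "T3", entry = "A3"),
    Rub = list(class_name = "Rub",
               roles = c("bfuC", "bfuB", "rub"),
               fused = NULL, profile = character(),
               b2_variant = "cys", expected_type = "T4", entry = "direct")
  )
  for (nm in names(t)) t[[nm]]$template <- nm
  t
}

# Roles excluded from the holoenzyme (processing/regulatory genes that sit
# in the operon but are not subunits).
NON_HOLOENZYME_ROLES <- c("hisK", "hydD")

mutate_seq <- function(chars, rate, protected = integer()) {
  if (rate <= 0) return(chars)
  n <- length(chars)
  hit <- which(stats::runif(n) < rate)
  hit <- setdiff(hit, protected)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  chars
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

protected_positions <- function(frame, subunit) {
  p <- unlist(lapply(frame$ligands[[subunit]], `[[`, "pos"))
  if (subunit == "BfuB") p <- c(p, frame$fmn_site$pos)
  sort(unique(p))
}

# Build the three diverged core subunits for one operon, with absent
# A-clusters knocked to Ala so the scanner reads a clean absence.
core_subunits <- function(frame, template, divergence) {
  out <- list()
  for (su in c("BfuB", "BfuA", "BfuC")) {
    chars <- strsplit(frame$sequences[[su]], "")[[1]]
    if (su == "BfuB" && template$b2_variant == "thr") chars[476L] <- "T"
    if (su == "BfuA") {
      absent <- setdiff(paste0("A", 1:5), template$profile)
      for (cl in absent) chars[frame$ligands$BfuA[[cl]]$pos] <- "A"
    }
    out[[su]] <- mutate_seq(chars, divergence, protected_positions(frame, su))
  }
  out
}

# Internal generator: consumes the current RNG stream (callers wrap with
# with_seed for the public, seed-taking API).
generate_genome_impl <- function(template, frame, genome_id,
                                 n_decoy_genes = 5L, divergence = 0,
                                 include_nonbifurcating = FALSE,
                                 decoy_codh = FALSE) {
  stopifnot(divergence >= 0, divergence <= 0.5)
  core <- core_subunits(frame, template, divergence)
  has_bfua <- "bfuA" %in% template$roles

  roles <- template$roles
  proteins <- list(); domains <- list(); feats <- list()
  motif_rows <- list()
  pid <- function(i) sprintf("%s_p%02d", genome_id, i)
  gid <- function(i) sprintf("%s_g%02d", genome_id, i)

  add_domains <- function(protein_id, ids, len) {
    k <- length(ids)
    bounds <- round(seq(0, len, length.out = k + 1))
    data.frame(protein_id = protein_id, domain_id = ids,
               start = as.integer(bounds[-(k + 1)]),
               end = as.integer(bounds[-1]),
               score = NA_real_, stringsAsFactors = FALSE)
  }

  idx <- 0L
  subunit_pid <- c(bfuB = NA_character_, bfuA = NA_character_,
                   bfuC = NA_character_)
  for (role in roles) {
    idx <- idx + 1L
    id <- pid(idx)
    if (role == "bfuB") {
      seq <- paste(core$BfuB, collapse = "")
      domains[[id]] <- add_domains(id, BFUB_DOMAINS, nchar(seq))
      subunit_pid["bfuB"] <- id
    } else if (role == "bfuC") {
      seq <- paste(core$BfuC, collapse = "")
      domains[[id]] <- add_domains(id, BFUC_DOMAIN, nchar(seq))
      subunit_pid["bfuC"] <- id
    } else if (role == "bfuA") {
      base <- paste(core$BfuA, collapse = "")
      dom <- add_domains(id, BFUA_DOMAINS, nchar(base))
      if (!is.null(template$fused)) {
        ext <- random_protein(200L)
        dom <- rbind(dom, data.frame(
          protein_id = id, domain_id = FUSED_DOMAIN_IDS[[template$fused]],
          start = nchar(base), end = nchar(base) + 200L,
          score = NA_real_, stringsAsFactors = FALSE))
        base <- paste0(base, ext)
      }
      seq <- base
      domains[[id]] <- dom
      subunit_pid["bfuA"] <- id
    } else {
      seq <- random_protein(sample(250:650, 1L))
      if (role == "hyt_a") {
        domains[[id]] <- add_domains(id, FUSED_DOMAIN_IDS[["h_cluster"]],
                                     nchar(seq))
      } else if (role == "fdh_a") {
        domains[[id]] <- add_domains(id, FUSED_DOMAIN_IDS[["pterin"]],
                                     nchar(seq))
      }
    }
    proteins[[id]] <- data.frame(protein_id = id, sequence = seq,
                                 genome_id = genome_id,
                                 is_metagenomic = FALSE,
                                 stringsAsFactors = FALSE)
    feats[[id]] <- data.frame(genome_id = genome_id, contig = "c1",
                              gene_id = gid(idx), start = NA_integer_,
                              end = NA_integer_, strand = "+",
                              protein_id = id, role_label = role,
                              stringsAsFactors = FALSE)
  }

  # planted ligand motif truth for the core subunits
  for (su in c("bfuB", "bfuA", "bfuC")) {
    if (is.na(subunit_pid[[su]])) next
    SU <- c(bfuB = "BfuB", bfuA = "BfuA", bfuC = "BfuC")[[su]]
    chars <- core[[SU]]
    for (cl in names(frame$ligands[[SU]])) {
      p <- frame$ligands[[SU]][[cl]]$pos
      motif_rows[[paste(su, cl)]] <- data.frame(
        genome_id = genome_id, protein_id = subunit_pid[[su]],
        subunit = SU, cluster = cl, pos = p, residue = chars[p],
        stringsAsFactors = FALSE)
    }
  }

  # decoys: neutral genes with no informative domains
  n_decoy <- n_decoy_genes
  if (decoy_codh && n_decoy < 20L) n_decoy <- 20L
  for (k in seq_len(n_decoy)) {
    idx <- idx + 1L
    id <- pid(idx)
    seq <- random_protein(sample(120:400, 1L))
    proteins[[id]] <- data.frame(protein_id = id, sequence = seq,
                                 genome_id = genome_id,
                                 is_metagenomic = FALSE,
                                 stringsAsFactors = FALSE)
    feats[[id]] <- data.frame(genome_id = genome_id, contig = "c1",
                              gene_id = gid(idx), start = NA_integer_,
                              end = NA_integer_, strand = "+",
                              protein_id = id, role_label = "hypothetical",
                              stringsAsFactors = FALSE)
  }

  nonbif_pid <- NA_character_
  if (include_nonbifurcating) {
    # BfuB-like homolog carrying the full domain architecture but with the
    # B2-B5 ligands substituted to Ala (Nqo-style non-bifurcating core),
    # paired with a BfuC homolog so the anchor yields a complete row.
    for (part in c("nqo_b", "nqo_c")) {
      idx <- idx + 1L
      id <- pid(idx)
      su <- if (part == "nqo_b") "BfuB" else "BfuC"
      chars <- strsplit(frame$sequences[[su]], "")[[1]]
      if (part == "nqo_b") {
        for (cl in paste0("B", 2:5)) {
          chars[frame$ligands$BfuB[[cl]]$pos] <- "A"
        }
      }
      chars <- mutate_seq(chars, divergence, protected_positions(frame, su))
      seq <- paste(chars, collapse = "")
      dom_ids <- if (part == "nqo_b") BFUB_DOMAINS else BFUC_DOMAIN
      domains[[id]] <- add_domains(id, dom_ids, nchar(seq))
      proteins[[id]] <- data.frame(protein_id = id, sequence = seq,
                                   genome_id = genome_id,
                                   is_metagenomic = FALSE,
                                   stringsAsFactors = FALSE)
      feats[[id]] <- data.frame(genome_id = genome_id, contig = "c1",
                                gene_id = gid(idx), start = NA_integer_,
                                end = NA_integer_, strand = "+",
                                protein_id = id, role_label = part,
                                stringsAsFactors = FALSE)
      if (part == "nqo_b") nonbif_pid <- id
    }
  }

  if (decoy_codh) {
    for (part in c("codh_d", "codh_e", "codh_f")) {
      idx <- idx + 1L
      id <- pid(idx)
      seq <- random_protein(sample(250:650, 1L))
      proteins[[id]] <- data.frame(protein_id = id, sequence = seq,
                                   genome_id = genome_id,
                                   is_metagenomic = FALSE,
                                   stringsAsFactors = FALSE)
      feats[[id]] <- data.frame(genome_id = genome_id, contig = "c1",
                                gene_id = gid(idx), start = NA_integer_,
                                end = NA_integer_, strand = "+",
                                protein_id = id, role_label = part,
                                stringsAsFactors = FALSE)
    }
  }

  proteins <- do.call(rbind, unname(proteins))
  features <- do.call(rbind, unname(feats))
  domains <- if (length(domains) > 0) {
    do.call(rbind, unname(domains))
  } else {
    data.frame(protein_id = character(), domain_id = character(),
               start = integer(), end = integer(), score = numeric(),
               stringsAsFactors = FALSE)
  }

  # lay genes sequentially on the contig: 3*aa + 3 nt, 50 nt gaps
  lens <- 3L * nchar(proteins$sequence[match(features$protein_id,
                                             proteins$protein_id)]) + 3L
  starts <- cumsum(c(0L, head(lens + 50L, -1L)))
  features$start <- as.integer(starts)
  features$end <- as.integer(starts + lens)

  truth <- data.frame(
    genome_id = genome_id, template = template$template,
    class_name = template$class_name,
    expected_type = template$expected_type,
    entry_cluster = template$entry,
    bfub_id = subunit_pid[["bfuB"]], bfua_id = subunit_pid[["bfuA"]],
    bfuc_id = subunit_pid[["bfuC"]],
    nonbif_id = nonbif_pid,
    clade_id = template$template,
    stringsAsFactors = FALSE)

  structure(list(proteins = proteins, features = features,
                 domains = domains, truth = truth,
                 motifs = do.call(rbind, unname(motif_rows)),
                 frame = frame),
            class = "bfu_genome")
}

#' Generate one synthetic genome with a planted Bfu operon
#'
#' @param template Template name (see [operon_templates()]) or a template
#'   list.
#' @param n_decoy_genes Number of neutral decoy genes appended after the
#'   operon.
#' @param divergence Per-site substitution probability applied outside
#'   planted signal positions (0 to 0.5).
#' @param seed Integer seed; output is byte-identical per seed.
#' @param genome_id Genome identifier.
#' @param include_nonbifurcating Add a non-bifurcating BfuB-like homolog
#'   (full domain architecture, B2-B5 ligands substituted to Ala).
#' @param decoy_codh Add a standalone Codh gene trio at least 20 genes away
#'   from the bfuB anchor (neighborhood-window control).
#' @param frame Reference frame; defaults to the packaged frame.
#' @return A `bfu_genome`: list with `proteins`, `features`, `domains`,
#'   `truth`, `motifs`.
#' @export
generate_genome <- function(template, n_decoy_genes = 5L, divergence = 0,
                            seed = 1L, genome_id = NULL,
                            include_nonbifurcating = FALSE,
                            decoy_codh = FALSE,
                            frame = default_reference_frame()) {
  if (is.character(template)) {
    tl <- operon_templates()
    if (!template %in% names(tl)) stop("unknown template: ", template)
    template <- tl[[template]]
  }
  if (is.null(genome_id)) genome_id <- paste0("g_", template$template)
  with_seed(seed, generate_genome_impl(
    template, frame, genome_id, n_decoy_genes = n_decoy_genes,
    divergence = divergence,
    include_nonbifurcating = include_nonbifurcating,
    decoy_codh = decoy_codh))
}

#' Remove one planted signal from a synthetic genome
#'
#' Exactly the named signal is removed and the ground truth updated:
#' ligand residues are substituted to Ala (`"B2"`..`"B5"`, `"A1"`..`"A5"`,
#' `"C1"`, or `"His525"`), the whole bfuA gene is deleted (`"bfuA"`), or a
#' domain-annotation row is dropped (any domain accession).
#'
#' @param genome A `bfu_genome`.
#' @param target Ablation target (see Details).
#' @return The mutated genome with updated truth.
#' @export
ablate <- function(genome, target) {
  stopifnot(inherits(genome, "bfu_genome"))
  truth <- genome$truth
  set_residues <- function(protein_id, pos, to = "A") {
    i <- match(protein_id, genome$proteins$protein_id)
    chars <- strsplit(genome$proteins$sequence[i], "")[[1]]
    chars[pos] <- to
    genome$proteins$sequence[i] <<- paste(chars, collapse = "")
    sel <- genome$motifs$protein_id == protein_id & genome$motifs$pos %in% pos
    genome$motifs$residue[sel] <<- to
  }
  clusters <- c(paste0("A", 1:5), paste0("B", 1:5), "C1")
  if (target %in% clusters) {
    hit <- genome$motifs[genome$motifs$cluster == target &
                           genome$motifs$protein_id %in%
                             c(truth$bfub_id, truth$bfua_id, truth$bfuc_id), ]
    if (nrow(hit) == 0) stop("target not present in genome: ", target)
    set_residues(hit$protein_id[1], hit$pos)
    if (target %in% c(paste0("B", 2:5), "C1")) {
      truth$expected_type <- "NonBifurcating"
      truth$entry_cluster <- "none"
    } else if (target == "A4" && truth$expected_type == "T1") {
      prof <- genome$motifs[genome$motifs$protein_id == truth$bfua_id, ]
      a3_intact <- any(prof$cluster == "A3" & prof$residue == "C")
      truth$entry_cluster <- if (a3_intact) "A3" else "none"
    } else if (target == "A3" && truth$expected_type == "T3") {
      truth$expected_type <- "T2"
      truth$entry_cluster <- "A4"
    }
  } else if (target == "His525") {
    if (is.na(truth$bfub_id)) stop("target not present in genome: His525")
    set_residues(truth$bfub_id, 525L)
    sel <- genome$motifs$protein_id == truth$bfub_id & genome$motifs$pos == 525L
    genome$motifs$residue[sel] <- "A"
    truth$expected_type <- "NonBifurcating"
    truth$entry_cluster <- "none"
  } else if (target == "bfuA") {
    if (is.na(truth$bfua_id)) stop("target not present in genome: bfuA")
    id <- truth$bfua_id
    genome$proteins <- genome$proteins[genome$proteins$protein_id != id, ]
    genome$features <- genome$features[genome$features$protein_id != id, ]
    genome$domains <- genome$domains[genome$domains$protein_id != id, ]
    genome$motifs <- genome$motifs[genome$motifs$protein_id != id, ]
    truth$bfua_id <- NA_character_
    truth$expected_type <- "Unclassified"
    truth$entry_cluster <- "none"
  } else if (target %in% genome$domains$domain_id) {
    genome$domains <- genome$domains[genome$domains$domain_id != target, ]
  } else {
    stop("target not present in genome: ", target)
  }
  genome$truth <- truth
  genome
}

#' Generate a multi-genome cohort with planted clade structure
#'
#' Each template is seeded from a distinct ancestor (the packaged reference
#' diverged at `divergence_between`), and the `n_per_template` genome copies
#' diverge from that ancestor at `divergence_within`, so BfuB sequences
#' cluster by template and the intended clades are recoverable from the
#' tree.
#'
#' @param n_per_template Copies per template (>= 1).
#' @param templates Template names; default all fifteen.
#' @param divergence_within Within-template substitution rate.
#' @param divergence_between Ancestor substitution rate from the reference.
#' @param seed Integer seed.
#' @param n_decoy_genes Decoy genes per genome.
#' @param frame Reference frame.
#' @return A `bfu_cohort`: pooled `proteins`, `features`, `domains`,
#'   per-genome `truth`, `motifs`.
#' @export
generate_cohort <- function(n_per_template = 1L,
                            templates = names(operon_templates()),
                            divergence_within = 0.05,
                            divergence_between = 0.45,
                            seed = 1L, n_decoy_genes = 3L,
                            frame = default_reference_frame()) {
  stopifnot(n_per_template >= 1)
  tl <- operon_templates()
  unknown <- setdiff(templates, names(tl))
  if (length(unknown) > 0) stop("unknown template: ",
                                paste(unknown, collapse = ", "))
  with_seed(seed, {
    genomes <- list()
    for (tn in templates) {
      # distinct ancestor per template: diverge the reference once
      anc <- frame
      for (su in names(anc$sequences)) {
        chars <- strsplit(anc$sequences[[su]], "")[[1]]
        chars <- mutate_seq(chars, divergence_between,
                            protected_positions(frame, su))
        anc$sequences[su] <- paste(chars, collapse = "")
      }
      for (k in seq_len(n_per_template)) {
        gidn <- sprintf("g_%s_%02d", tn, k)
        genomes[[gidn]] <- generate_genome_impl(
          tl[[tn]], anc, gidn, n_decoy_genes = n_decoy_genes,
          divergence = divergence_within)
        genomes[[gidn]]$truth$clade_id <- tn
      }
    }
    pool <- function(field) do.call(rbind, lapply(genomes, `[[`, field))
    structure(list(proteins = pool("proteins"), features = pool("features"),
                   domains = pool("domains"), truth = pool("truth"),
                   motifs = pool("motifs"), frame = frame),
              class = "bfu_cohort")
  })
}
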