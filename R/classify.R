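# Structural Type assignment: the central decision table combining the
# bifurcating-core verdict, the BfuA cluster profile and the functional
# call.
#
#   (a) core non-bifurcating            -> NonBifurcating / none
#   (b) no BfuA: Rub partner            -> T4 / direct
#       no BfuA: otherwise              -> Unclassified / none
#   (c) catalytic domain fused to BfuA  -> T1 / entry cluster (A4, else A3)
#   (d) extra catalytic subunits, no A3 -> T2 / A4
#   (e) extra catalytic subunits, A3    -> T3 / A3
#   (f) otherwise                       -> Unclassified / none

#' Assign the structural Type of a Bfu gene cluster
#'
#' @param core Core verdict from [core_verdict()].
#' @param bfuA_present Is a BfuA candidate present in the cluster?
#' @param bfuA_calls Cluster-call table for BfuA (ignored when absent).
#' @param bfuA_has_fused_catalytic Does BfuA carry a fused catalytic
#'   domain?
#' @param extra_catalytic_subunits Are matched non-BfuABC holoenzyme
#'   subunits present?
#' @param call Functional call from [match_signature()].
#' @return List: `type` (T1..T4, NonBifurcating, Unclassified), `entry`
#'   (A3, A4, direct, none), `rationale`.
#' @export
assign_type <- function(core, bfuA_present, bfuA_calls = NULL,
                        bfuA_has_fused_catalytic = FALSE,
                        extra_catalytic_subunits = FALSE, call) {
  if (bfuA_has_fused_catalytic && identical(call$class_name, "Rub")) {
    stop("contradictory input: fused catalytic domain with class Rub")
  }
  verdict <- function(type, entry, why) {
    list(type = type, entry = entry, rationale = why)
  }
  if (!isTRUE(core$bifurcating)) {
    return(verdict("NonBifurcating", "none",
                   paste("core incomplete:",
                         paste(core$reasons, collapse = "; "))))
  }
  if (!bfuA_present) {
    if (identical(call$class_name, "Rub")) {
      return(verdict("T4", "direct",
                     "no BfuA; rubrerythrin partner feeds the core directly"))
    }
    return(verdict("Unclassified", "none",
                   "no BfuA and no recognized Type 4 partner"))
  }
  a_present <- character()
  if (!is.null(bfuA_calls)) {
    a_present <- bfuA_calls$cluster[bfuA_calls$status == "present"]
  }
  if (bfuA_has_fused_catalytic) {
    entry <- if ("A4" %in% a_present) "A4"
             else if ("A3" %in% a_present) "A3" else "none"
    return(verdict("T1", entry, "catalytic domain fused to BfuA"))
  }
  if (extra_catalytic_subunits) {
    if (!("A3" %in% a_present)) {
      return(verdict("T2", "A4",
                     "extra catalytic subunits; BfuA lacks A3"))
    }
    return(verdict("T3", "A3",
                   "extra catalytic subunits; BfuA contains A3"))
  }
  verdict("Unclassified", "none",
          "no fused domain and no extra catalytic subunits")
}

#' Classify every bfuB anchor in a dataset
#'
#' Runs the full per-anchor pipeline: candidate selection by domain
#' architecture, neighborhood extraction, reference-frame cofactor calls,
#' signature matching and Type assignment. Metagenomic records are
#' excluded; exact-duplicate collapsing applies to the tree stage (see
#' [run_all()]), not to anchors.
#'
#' @param dataset A `bfu_genome`, `bfu_cohort`, or list with `proteins`,
#'   `features`, `domains`.
#' @param frame Reference frame.
#' @param window Neighborhood window (gene positions either side).
#' @param presence_threshold Cluster presence threshold.
#' @param role_map Role-vocabulary map.
#' @param config Alignment scoring configuration.
#' @return data.frame: one row per anchor, ordered by (genome, contig,
#'   start), with class, type, entry, core verdict and evidence columns.
#' @export
classify_dataset <- function(dataset, frame = default_reference_frame(),
                             window = 10L, presence_threshold = 0.75,
                             role_map = default_role_map(),
                             config = alignment_config()) {
  proteins <- dataset$proteins
  features <- dataset$features
  domains <- dataset$domains
  empty <- data.frame(genome_id = character(), anchor = character(),
                      contig = character(), start = integer(),
                      bfub_protein = character(), class_name = character(),
                      type = character(), entry = character(),
                      bifurcating = logical(), core_reasons = character(),
                      his525 = logical(), feA476 = character(),
                      holoenzyme = character(), n_holoenzyme = integer(),
                      note = character(), stringsAsFactors = FALSE)
  if (is.null(domains) || nrow(domains) == 0) return(empty)

  cand <- list(bfuB_ids = select_bfub(domains),
               bfuC_ids = select_bfuc(domains),
               bfuA_ids = select_bfua(domains))
  # exclude metagenomic records from candidacy
  meta_ids <- proteins$protein_id[isTRUE_vec(proteins$is_metagenomic)]
  cand <- lapply(cand, setdiff, meta_ids)
  # BfuB is defined by a strict superset of the BfuA architecture; a
  # protein carrying the full BfuB architecture is an anchor, not a BfuA.
  cand$bfuA_ids <- setdiff(cand$bfuA_ids, cand$bfuB_ids)

  anchors <- features[features$protein_id %in% cand$bfuB_ids, , drop = FALSE]
  if (nrow(anchors) == 0) return(empty)
  anchors <- anchors[order(anchors$genome_id, anchors$contig,
                           anchors$start), ]

  seq_of <- function(id) proteins$sequence[match(id, proteins$protein_id)]
  rows <- lapply(seq_len(nrow(anchors)), function(i) {
    anc <- anchors[i, ]
    cluster <- extract_cluster(features, anc$gene_id, window = window,
                               bfua_ids = cand$bfuA_ids)
    members <- cluster$members
    pick_nearest <- function(ids) {
      pos <- which(members$protein_id %in% ids &
                     members$gene_id != anc$gene_id)
      if (length(pos) == 0) return(NA_character_)
      apos <- which(members$gene_id == anc$gene_id)
      members$protein_id[pos[which.min(abs(pos - apos))]]
    }
    bfuc_id <- pick_nearest(cand$bfuC_ids)
    bfua_id <- if (is.na(cluster$bfua_gene)) NA_character_ else
      members$protein_id[members$gene_id == cluster$bfua_gene]

    alnB <- align_to_reference(seq_of(anc$protein_id),
                               frame$sequences[["BfuB"]], config)
    callsB <- call_clusters(alnB, seq_of(anc$protein_id), frame, "BfuB",
                            presence_threshold)
    b2 <- b2_signature(alnB, seq_of(anc$protein_id), frame)
    if (!is.na(bfuc_id)) {
      alnC <- align_to_reference(seq_of(bfuc_id), frame$sequences[["BfuC"]],
                                 config)
      callsC <- call_clusters(alnC, seq_of(bfuc_id), frame, "BfuC",
                              presence_threshold)
    } else {
      callsC <- data.frame(cluster = "C1", status = "absent",
                           match_fraction = 0, evidence = "no BfuC",
                           stringsAsFactors = FALSE)
    }
    core <- core_verdict(callsB, callsC, b2)

    callsA <- NULL
    fused <- FALSE
    bfuA_dom <- NULL
    if (!is.na(bfua_id)) {
      alnA <- align_to_reference(seq_of(bfua_id), frame$sequences[["BfuA"]],
                                 config)
      callsA <- call_clusters(alnA, seq_of(bfua_id), frame, "BfuA",
                              presence_threshold)
      bfuA_dom <- domains[domains$protein_id == bfua_id, , drop = FALSE]
      fused <- any(strip_version(bfuA_dom$domain_id) %in% FUSED_DOMAIN_IDS)
    }

    call <- match_signature(cluster, cand, bfuA_domains = bfuA_dom,
                            role_map = role_map)
    extra <- FALSE
    if (call$class_name != "Unknown") {
      matched_genes <- names(call$matched_roles)
      matched_prot <- members$protein_id[members$gene_id %in% matched_genes]
      core_prot <- c(anc$protein_id, bfuc_id, bfua_id)
      roles <- resolve_roles(members$role_label, role_map)
      names(roles) <- members$gene_id
      extra <- any(!(matched_prot %in% core_prot) &
                     !(roles[matched_genes] %in% NON_HOLOENZYME_ROLES))
    }
    tc <- assign_type(core, bfuA_present = !is.na(bfua_id),
                      bfuA_calls = callsA,
                      bfuA_has_fused_catalytic = fused,
                      extra_catalytic_subunits = extra, call = call)
    holo <- if (call$class_name != "Unknown") {
      holoenzyme_subunits(cluster, call, cand, role_map)
    } else character()
    data.frame(genome_id = anc$genome_id, anchor = anc$gene_id,
               contig = anc$contig, start = anc$start,
               bfub_protein = anc$protein_id,
               class_name = call$class_name, type = tc$type,
               entry = tc$entry, bifurcating = core$bifurcating,
               core_reasons = paste(core$reasons, collapse = "; "),
               his525 = b2$his525_present, feA476 = b2$feA476_residue,
               holoenzyme = paste(holo, collapse = ","),
               n_holoenzyme = length(holo),
               note = paste(c(call$note, tc$rationale), collapse = " | "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
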