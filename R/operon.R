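# Gene-neighborhood context: the window of genes around each bfuB anchor,
# the sandwich set (genes strictly between bfuB and bfuA), and functional
# signature matching against the packaged operon templates.

#' Default role-vocabulary map
#'
#' Maps raw role labels (gene product annotations) to the controlled role
#' vocabulary used by the signature templates. Synthetic data emits
#' controlled roles directly, so the default is an identity map; real
#' annotations can be plugged in by supplying label -> role pairs.
#'
#' @param extra Named character vector of additional label -> role pairs.
#' @return Named character vector (possibly empty; unmapped labels are used
#'   as-is).
#' @export
default_role_map <- function(extra = character()) {
  extra
}

resolve_roles <- function(labels, role_map) {
  hit <- match(labels, names(role_map))
  ifelse(is.na(hit), labels, unname(role_map[hit]))
}

#' Extract the gene cluster around a bfuB anchor
#'
#' Members are the genes on the anchor's contig within `window` gene
#' positions either side of the anchor, ordered by start coordinate
#' (strand does not affect order). When a bfuA candidate is present among
#' the members, the sandwich set is the genes strictly between the anchor
#' and the nearest bfuA.
#'
#' @param features Gene-feature data.frame.
#' @param anchor `gene_id` of the bfuB anchor.
#' @param window Number of gene positions either side (>= 1).
#' @param bfua_ids Protein ids accepted as BfuA (for the sandwich set).
#' @return List: `anchor`, `anchor_protein`, `members` (ordered feature
#'   rows), `sandwich` (gene ids), `bfua_gene`.
#' @export
extract_cluster <- function(features, anchor, window = 10L,
                            bfua_ids = character()) {
  stopifnot(window >= 1)
  i <- which(features$gene_id == anchor)
  if (length(i) != 1) stop("anchor not in features: ", anchor)
  same <- features[features$genome_id %in% features$genome_id[i] &
                     features$contig == features$contig[i], ]
  same <- same[order(same$start), ]
  pos <- which(same$gene_id == anchor)
  keep <- seq(max(1L, pos - window), min(nrow(same), pos + window))
  members <- same[keep, ]
  anchor_pos <- which(members$gene_id == anchor)
  bfua_pos <- which(members$protein_id %in% bfua_ids)
  sandwich <- character()
  bfua_gene <- NA_character_
  if (length(bfua_pos) > 0) {
    bfua_pos <- bfua_pos[which.min(abs(bfua_pos - anchor_pos))]
    bfua_gene <- members$gene_id[bfua_pos]
    if (abs(bfua_pos - anchor_pos) > 1) {
      between <- seq(min(anchor_pos, bfua_pos) + 1L,
                     max(anchor_pos, bfua_pos) - 1L)
      sandwich <- members$gene_id[between]
    }
  }
  list(anchor = anchor, anchor_protein = features$protein_id[i],
       members = members, sandwich = sandwich, bfua_gene = bfua_gene)
}

# Signature templates in priority order. Band 1: composite (bifunctional)
# templates; band 2: subunit-count templates, most subunits first; band 3:
# BfuA-fused catalytic domains; band 4: the BfuA-less Rub partner rule.
signature_table <- function() {
  list(
    list(class = "FdhFeFe", band = 1L, rank = 1L,
         roles = c("fdh_a", "hyt_a")),
    list(class = "Nuo", band = 2L, rank = 1L,
         roles = c("nuo_a", "nuo_b", "nuo_c", "nuo_d", "nuo_h", "nuo_i",
                   "nuo_j", "nuo_k", "nuo_l", "nuo_m", "nuo_n")),
    list(class = "Mbh", band = 2L, rank = 2L,
         roles = c("mbh_a", "mbh_b", "mbh_c", "mbh_d", "mbh_e", "mbh_f")),
    list(class = "Bam", band = 2L, rank = 3L,
         roles = c("bam_b", "bam_c", "bam_d", "bam_e", "bam_f")),
    list(class = "Por", band = 2L, rank = 4L,
         roles = c("por_d", "por_e", "por_f", "por_g")),
    list(class = "Codh", band = 2L, rank = 5L,
         roles = c("codh_d", "codh_e", "codh_f")),
    list(class = "NiFe", band = 2L, rank = 6L,
         roles = c("nife_s", "nife_l")),
    list(class = "Wor", band = 2L, rank = 7L,
         roles = c("wor_s", "wor_l")),
    list(class = "Fdh", band = 2L, rank = 8L, roles = "fdh_a"),
    list(class = "FeFe", band = 3L, rank = 1L,
         fused = FUSED_DOMAIN_IDS[["h_cluster"]]),
    list(class = "Nfn", band = 3L, rank = 1L,
         fused = FUSED_DOMAIN_IDS[["nfn_fad"]]),
    list(class = "F420", band = 3L, rank = 1L,
         fused = FUSED_DOMAIN_IDS[["f420_fad"]]),
    list(class = "Fdh", band = 3L, rank = 1L,
         fused = FUSED_DOMAIN_IDS[["pterin"]]),
    list(class = "Rub", band = 4L, rank = 1L, special = "rub_downstream")
  )
}

#' Match the functional signature of a gene cluster
#'
#' Evaluates every signature template against the cluster's resolved roles
#' and the domains fused to its BfuA subunit, and returns the unique best
#' match under the priority rule (composite > subunit-count-heavy > fused >
#' Rub; within a band more matched roles wins). A residual tie yields class
#' `Unknown` with a tie note rather than a silent pick.
#'
#' @param cluster Cluster from [extract_cluster()].
#' @param candidate_sets List with `bfuB_ids`, `bfuC_ids`, `bfuA_ids`.
#' @param bfuA_domains Domain-annotation rows for the cluster's BfuA
#'   protein (may be empty).
#' @param role_map Role-vocabulary map (see [default_role_map()]).
#' @return List: `class_name`, `matched_roles` (named character:
#'   gene_id -> role), `note`.
#' @export
match_signature <- function(cluster, candidate_sets,
                            bfuA_domains = NULL,
                            role_map = default_role_map()) {
  members <- cluster$members
  roles <- resolve_roles(members$role_label, role_map)
  names(roles) <- members$gene_id
  has_bfua <- !is.na(cluster$bfua_gene)
  fused_ids <- character()
  if (!is.null(bfuA_domains) && nrow(bfuA_domains) > 0) {
    fused_ids <- intersect(strip_version(bfuA_domains$domain_id),
                           FUSED_DOMAIN_IDS)
  }
  anchor_pos <- which(members$gene_id == cluster$anchor)

  evaluate <- function(sig) {
    if (!is.null(sig$roles)) {
      hit <- roles[roles %in% sig$roles]
      if (!all(sig$roles %in% roles)) return(NULL)
      list(sig = sig, matched = hit)
    } else if (!is.null(sig$fused)) {
      if (!has_bfua || !(sig$fused %in% fused_ids)) return(NULL)
      m <- stats::setNames(sig$fused, cluster$bfua_gene)
      list(sig = sig, matched = m)
    } else if (identical(sig$special, "rub_downstream")) {
      if (has_bfua) return(NULL)
      if (anchor_pos >= nrow(members)) return(NULL)
      down <- roles[anchor_pos + 1L]
      if (!identical(unname(down), "rub")) return(NULL)
      list(sig = sig, matched = down)
    } else {
      NULL
    }
  }

  hits <- Filter(Negate(is.null), lapply(signature_table(), evaluate))
  if (length(hits) == 0) {
    return(list(class_name = "Unknown", matched_roles = character(),
                note = "no signature matched"))
  }
  key <- vapply(hits, function(h) {
    c(h$sig$band, h$sig$rank, -length(h$matched))
  }, numeric(3))
  ord <- order(key[1, ], key[2, ], key[3, ])
  best <- hits[[ord[1]]]
  if (length(ord) > 1 &&
      all(key[, ord[1]] == key[, ord[2]])) {
    tied <- vapply(hits[ord[1:2]], function(h) h$sig$class, "")
    return(list(class_name = "Unknown", matched_roles = character(),
                note = paste("priority tie:", paste(tied, collapse = " vs "))))
  }
  list(class_name = best$sig$class, matched_roles = best$matched,
       note = "")
}

#' Holoenzyme gene ids for a classified cluster
#'
#' The BfuABC genes plus the matched catalytic/accessory role genes;
#' processing and regulatory genes (hisK/hydD analogues) are excluded even
#' when they sit inside the operon.
#'
#' @param cluster Cluster from [extract_cluster()].
#' @param call Functional call from [match_signature()] (class not
#'   `Unknown`).
#' @param candidate_sets List with `bfuB_ids`, `bfuC_ids`, `bfuA_ids`.
#' @param role_map Role-vocabulary map.
#' @return Character vector of gene ids in cluster order.
#' @export
holoenzyme_subunits <- function(cluster, call, candidate_sets,
                                role_map = default_role_map()) {
  stopifnot(call$class_name != "Unknown")
  members <- cluster$members
  roles <- resolve_roles(members$role_label, role_map)
  is_core <- members$protein_id %in% unlist(candidate_sets[c(
    "bfuB_ids", "bfuC_ids", "bfuA_ids")])
  is_matched <- members$gene_id %in% names(call$matched_roles) &
    !(roles %in% NON_HOLOENZYME_ROLES)
  members$gene_id[is_core | is_matched]
}
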