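# Candidate selection by domain architecture, mirroring the retrieval step:
# BfuB requires all four of IPR011538/IPR019554/IPR019575/IPR017896, BfuC
# requires IPR002023, BfuA requires at least IPR017896 + IPR001041 (extra
# domains permitted - they mark Type 1 fusions). Version suffixes on
# accessions are stripped before matching.

strip_version <- function(ids) sub("\\.\\d+$", "", ids)

domains_by_protein <- function(annotations) {
  ids <- strip_version(annotations$domain_id)
  split(ids, annotations$protein_id)
}

select_by_architecture <- function(annotations, required) {
  by_prot <- domains_by_protein(annotations)
  hit <- vapply(by_prot, function(d) all(required %in% d), logical(1))
  sort(names(by_prot)[hit])
}

#' Select BfuB candidates (all four defining domains)
#' @param annotations Domain-annotation data.frame.
#' @return Character vector of protein ids.
#' @export
select_bfub <- function(annotations) {
  select_by_architecture(annotations, BFUB_DOMAINS)
}

#' Select BfuC candidates (IPR002023)
#' @inheritParams select_bfub
#' @export
select_bfuc <- function(annotations) {
  select_by_architecture(annotations, BFUC_DOMAIN)
}

#' Select BfuA candidates (at minimum IPR017896 and IPR001041)
#' @inheritParams select_bfub
#' @export
select_bfua <- function(annotations) {
  select_by_architecture(annotations, BFUA_DOMAINS)
}

#' Rejection reasons for a selection
#'
#' For every annotated protein not selected, lists the missing required
#' domains.
#' @param annotations Domain-annotation data.frame.
#' @param required Required accession set.
#' @return Named list protein_id -> missing ids.
#' @export
rejection_reasons <- function(annotations, required) {
  by_prot <- domains_by_protein(annotations)
  out <- lapply(by_prot, function(d) setdiff(required, d))
  out[lengths(out) > 0]
}

#' Collapse duplicates and drop metagenomic records
#'
#' Exact-sequence duplicates are collapsed to the lexicographically
#' smallest protein id; records flagged metagenomic are removed. Rejection
#' reasons are recorded per dropped id.
#'
#' @param records Protein records data.frame (must cover every candidate).
#' @param candidates List with elements `bfuB_ids`, `bfuC_ids`, `bfuA_ids`.
#' @return List `bfuB_ids`, `bfuC_ids`, `bfuA_ids` (filtered),
#'   `rejected` (named character: id -> reason).
#' @export
dedup_and_filter <- function(records, candidates) {
  all_ids <- unique(unlist(candidates))
  missing <- setdiff(all_ids, records$protein_id)
  if (length(missing) > 0) {
    stop("candidate id with no record: ", paste(missing, collapse = ", "))
  }
  rejected <- character()
  filter_set <- function(ids) {
    ids <- sort(ids)
    rec <- records[match(ids, records$protein_id), ]
    meta <- isTRUE_vec(rec$is_metagenomic)
    rejected[ids[meta]] <<- "metagenomic"
    ids <- ids[!meta]
    rec <- rec[!meta, ]
    keep <- !duplicated(rec$sequence)  # ids sorted, so first = smallest id
    rejected[ids[!keep]] <<- "duplicate"
    ids[keep]
  }
  out <- list(bfuB_ids = filter_set(candidates$bfuB_ids),
              bfuC_ids = filter_set(candidates$bfuC_ids),
              bfuA_ids = filter_set(candidates$bfuA_ids))
  out$rejected <- rejected
  out
}
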