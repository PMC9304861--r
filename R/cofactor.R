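# Reference-frame cofactor scanning: align each candidate subunit to the
# packaged reference globally, read the residues mapped to the ligand
# positions, and call cluster presence by the fraction of ligand positions
# carrying an allowed residue (>= threshold -> present, 0 -> absent,
# otherwise partial).

#' Default pairwise-alignment scoring configuration
#'
#' Global (Needleman-Wunsch/Gotoh) alignment with BLOSUM62 and affine gap
#' penalties. Recorded in output provenance so runs are auditable.
#'
#' @param matrix Substitution matrix name (dataset in Biostrings).
#' @param gap_opening,gap_extension Affine gap penalties (a gap of length L
#'   costs `gap_opening + L * gap_extension`).
#' @return Named list.
#' @export
alignment_config <- function(matrix = "BLOSUM62", gap_opening = 10,
                             gap_extension = 0.5) {
  list(matrix = matrix, gap_opening = gap_opening,
       gap_extension = gap_extension)
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Globally align a query to a reference sequence
#'
#' @param query,reference Amino-acid strings (non-empty).
#' @param config Scoring configuration from [alignment_config()].
#' @return List with `score`, `query_aln`/`ref_aln` (gapped strings) and
#'   `map`: an integer vector over reference positions (1-based) giving the
#'   aligned query position, NA where the reference residue faces a gap.
#' @export
align_to_reference <- function(query, reference, config = alignment_config()) {
  stopifnot(nchar(query) > 0, nchar(reference) > 0)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    substitutionMatrix = get_submat(config$matrix),
    gapOpening = config$gap_opening, gapExtension = config$gap_extension,
    type = "global")
  q <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  r <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  map <- rep(NA_integer_, nchar(reference))
  qi <- 0L; ri <- 0L
  for (k in seq_along(q)) {
    if (q[k] != "-") qi <- qi + 1L
    if (r[k] != "-") {
      ri <- ri + 1L
      if (q[k] != "-") map[ri] <- qi
    }
  }
  list(score = Biostrings::score(pa), query_aln = paste(q, collapse = ""),
       ref_aln = paste(r, collapse = ""), map = map)
}

residue_at <- function(query, map, ref_pos) {
  qp <- map[ref_pos]
  ifelse(is.na(qp), "-", substring(query, qp, qp))
}

#' Call FeS cluster presence for one subunit
#'
#' For each cluster of the subunit's reference table, computes the fraction
#' of ligand positions whose mapped query residue is in the allowed set:
#' `present` at fraction >= `threshold`, `absent` at 0, else `partial`.
#'
#' @param position_map Map from [align_to_reference()] (`$map` or the list).
#' @param query Query amino-acid string.
#' @param frame Reference frame.
#' @param subunit `"BfuA"`, `"BfuB"` or `"BfuC"`.
#' @param threshold Presence threshold (fraction of ligand positions).
#' @return data.frame: cluster, status, match_fraction, evidence (matched
#'   residues as a string).
#' @export
call_clusters <- function(position_map, query, frame, subunit,
                          threshold = 0.75) {
  if (is.list(position_map)) position_map <- position_map$map
  lig <- frame$ligands[[subunit]]
  if (is.null(lig)) stop("no reference for subunit: ", subunit)
  rows <- lapply(names(lig), function(cl) {
    pos <- lig[[cl]]$pos
    allowed <- lig[[cl]]$allowed
    res <- residue_at(query, position_map, pos)
    ok <- mapply(function(r, a) r %in% a, res, allowed)
    frac <- mean(ok)
    status <- if (frac >= threshold) "present"
              else if (frac == 0) "absent" else "partial"
    data.frame(cluster = cl, status = status, match_fraction = frac,
               evidence = paste0(pos, res, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read the B2 coordination signature of a BfuB query
#'
#' Reports whether the conserved His at reference position 525 is present
#' and which residue occupies the FeA ligand position 476 (Cys canonical,
#' Thr in FeFe-style enzymes; anything else is non-canonical).
#'
#' @inheritParams call_clusters
#' @return List: `his525_present`, `feA476_residue`, `canonical`.
#' @export
b2_signature <- function(position_map, query, frame) {
  if (is.list(position_map)) position_map <- position_map$map
  h <- residue_at(query, position_map, 525L)
  a <- residue_at(query, position_map, 476L)
  list(his525_present = identical(h, "H"), feA476_residue = a,
       canonical = a %in% c("C", "T"))
}

#' Bifurcating-core verdict from BfuB/BfuC cluster calls
#'
#' The conserved bifurcating core requires B2-B5 in BfuB, C1 in BfuC and
#' the B2 His ligand; homologs missing any of these are called
#' non-bifurcating with the failures enumerated.
#'
#' @param bfuB_calls,bfuC_calls Cluster-call tables from [call_clusters()].
#' @param b2sig B2 signature from [b2_signature()].
#' @return List: `bifurcating` (logical), `reasons` (character).
#' @export
core_verdict <- function(bfuB_calls, bfuC_calls, b2sig) {
  reasons <- character()
  for (cl in paste0("B", 2:5)) {
    st <- bfuB_calls$status[bfuB_calls$cluster == cl]
    if (!identical(st, "present")) reasons <- c(reasons, paste(cl, st))
  }
  st <- bfuC_calls$status[bfuC_calls$cluster == "C1"]
  if (!identical(st, "present")) reasons <- c(reasons, paste("C1", st))
  if (!isTRUE(b2sig$his525_present)) reasons <- c(reasons, "His525 absent")
  list(bifurcating = length(reasons) == 0, reasons = reasons)
}

#' Electron entry cluster of a BfuA subunit
#'
#' A4 takes priority when present (the Type 1/2 default); otherwise A3
#' (the Tsib-style exception); `none` flags a BfuA with neither.
#'
#' @param bfuA_calls Cluster-call table for BfuA.
#' @return `"A4"`, `"A3"` or `"none"`.
#' @export
entry_cluster <- function(bfuA_calls) {
  present <- bfuA_calls$cluster[bfuA_calls$status == "present"]
  if ("A4" %in% present) "A4" else if ("A3" %in% present) "A3" else "none"
}
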