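#' @importFrom utils read.delim write.table
#' @importFrom stats setNames
NULL

# Coordinate conventions
# ----------------------
# Intervals (domain annotations, gene features) are 0-based half-open
# internally; GFF3 (1-based inclusive) is converted at the read/write
# boundary and nowhere else. Single-residue positions (ligands, FMN-site
# residues) are 1-based biological numbering, as the field prints them
# (e.g. H525 means the 525th residue of the reference subunit).

#' Read a protein FASTA file
#'
#' Headers are split on the first whitespace: the leading token becomes the
#' `protein_id`, the remainder is scanned for `key=value` pairs. A
#' `genome=<id>` pair sets `genome_id`; a `metagenome=true` pair (or a bare
#' `metagenome` token) sets the metagenomic flag. Sequences must be
#' non-empty and ids unique.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A data.frame with columns `protein_id`, `sequence`, `genome_id`,
#'   `is_metagenomic`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate protein_id in FASTA: ", paste(dup, collapse = ", "))
  }
  seqs <- as.character(aa)
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for: ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  desc <- sub("^\\S+\\s*", "", headers)
  get_kv <- function(d, key) {
    m <- regmatches(d, regexec(paste0("(^|\\s)", key, "=(\\S+)"), d))
    vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
  }
  genome <- get_kv(desc, "genome")
  meta <- tolower(get_kv(desc, "metagenome"))
  is_meta <- !is.na(meta) & meta %in% c("true", "1", "yes")
  data.frame(protein_id = ids, sequence = unname(seqs),
             genome_id = ifelse(is.na(genome), NA_character_, genome),
             is_metagenomic = is_meta, stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]: emits `genome=` and `metagenome=` key-value
#' pairs in the description so a round trip reproduces the records.
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  desc <- character(nrow(records))
  if ("genome_id" %in% names(records)) {
    g <- records$genome_id
    desc <- ifelse(!is.na(g) & nzchar(g), paste0(" genome=", g), "")
  }
  if ("is_metagenomic" %in% names(records)) {
    desc <- paste0(desc,
                   ifelse(isTRUE_vec(records$is_metagenomic),
                          " metagenome=true", ""))
  }
  aa <- Biostrings::AAStringSet(setNames(records$sequence,
                                         paste0(records$protein_id, desc)))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

feature_cols <- c("genome_id", "contig", "gene_id", "start", "end",
                  "strand", "protein_id", "role_label")

#' Read gene features (GFF3 or TSV)
#'
#' GFF3 uses 1-based inclusive coordinates, converted here to the internal
#' 0-based half-open convention; the TSV dialect is already 0-based
#' half-open and is read as-is. GFF3 attributes `ID`, `protein_id`,
#' `role_label` and `genome_id` are honoured.
#'
#' @param path Input file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return data.frame with columns genome_id, contig, gene_id, start, end,
#'   strand, protein_id, role_label; start/end 0-based half-open.
#' @export
read_features <- function(path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    unknown <- setdiff(names(df), feature_cols)
    if (length(unknown) > 0) {
      stop("unknown column in feature TSV: ", paste(unknown, collapse = ", "))
    }
    feats <- df
  } else {
    lines <- readLines(path)
    keep <- which(!grepl("^#", lines) & nzchar(lines))
    if (length(keep) == 0) {
      return(empty_features())
    }
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 9)
    if (length(bad) > 0) {
      stop("malformed GFF3 at line ", keep[bad[1]])
    }
    attr_get <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(^|;)", key, "=([^;]+)"), a))
      vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
    }
    col <- function(i) vapply(parts, `[[`, "", i)
    attrs <- col(9)
    feats <- data.frame(
      genome_id = attr_get(attrs, "genome_id"),
      contig = col(1),
      gene_id = attr_get(attrs, "ID"),
      start = as.integer(col(4)) - 1L,  # 1-based inclusive -> 0-based half-open
      end = as.integer(col(5)),
      strand = col(7),
      protein_id = attr_get(attrs, "protein_id"),
      role_label = attr_get(attrs, "role_label"),
      stringsAsFactors = FALSE
    )
    feats$line <- keep
  }
  bad <- which(feats$start >= feats$end)
  if (length(bad) > 0) {
    where <- if (!is.null(feats$line)) feats$line[bad[1]] else bad[1]
    stop("start >= end after normalization at line ", where)
  }
  feats$line <- NULL
  feats[, feature_cols]
}

empty_features <- function() {
  as.data.frame(setNames(
    list(character(), character(), character(), integer(), integer(),
         character(), character(), character()), feature_cols),
    stringsAsFactors = FALSE)
}

#' Write gene features
#'
#' @param features Feature data.frame (internal 0-based half-open).
#' @param path Output path.
#' @param dialect `"tsv"` (written as-is) or `"gff3"` (converted to 1-based
#'   inclusive on output).
#' @export
write_features <- function(features, path, dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    write.table(features[, feature_cols], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    na2dot <- function(x) ifelse(is.na(x) | !nzchar(x), NA, x)
    attrs <- paste0(
      "ID=", features$gene_id,
      ifelse(!is.na(na2dot(features$protein_id)),
             paste0(";protein_id=", features$protein_id), ""),
      ifelse(!is.na(na2dot(features$role_label)),
             paste0(";role_label=", features$role_label), ""),
      ifelse(!is.na(na2dot(features$genome_id)),
             paste0(";genome_id=", features$genome_id), ""))
    lines <- paste(features$contig, "bfuscan", "gene",
                   features$start + 1L, features$end, ".",
                   features$strand, ".", attrs, sep = "\t")
    writeLines(c("##gff-version 3", lines), path)
  }
  invisible(path)
}

domain_cols <- c("protein_id", "domain_id", "start", "end", "score")

#' Read a domain-annotation TSV
#'
#' Columns: protein_id, domain_id, start, end, score (score may be empty).
#' Coordinates are 0-based half-open residue intervals.
#'
#' @param path Input TSV.
#' @return data.frame of domain annotations.
#' @export
read_domains <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(df), domain_cols)
  if (length(unknown) > 0) {
    stop("unknown column in domain TSV: ", paste(unknown, collapse = ", "))
  }
  if (!"score" %in% names(df)) df$score <- NA_real_
  bad <- which(df$start >= df$end)
  if (length(bad) > 0) stop("start >= end in domain row ", bad[1])
  df[, domain_cols]
}

#' Write a domain-annotation TSV
#' @param domains Domain data.frame.
#' @param path Output path.
#' @export
write_domains <- function(domains, path) {
  if (!"score" %in% names(domains)) domains$score <- NA_real_
  write.table(domains[, domain_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' Branch lengths are printed with six decimal places (canonical form used
#' throughout the package so that identical trees serialize identically).
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path; `NULL` returns the string invisibly.
#' @return The Newick string, invisibly.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(node, edge_idx) {
    if (node <= n_tip) {
      lab <- tree$tip.label[node]
    } else {
      kids <- children[[as.character(node)]]
      lab <- paste0("(", paste(vapply(kids, function(e) {
        fmt(tree$edge[e, 2], e)
      }, ""), collapse = ","), ")")
    }
    if (!is.null(edge_idx) && !is.null(tree$edge.length)) {
      lab <- paste0(lab, ":", sprintf("%.6f", tree$edge.length[edge_idx]))
    }
    lab
  }
  s <- paste0(fmt(root, NULL), ";")
  if (!is.null(path)) writeLines(s, path)
  invisible(s)
}

#' Write the classification report as TSV and JSON
#'
#' @param classifications Classification table from [classify_dataset()].
#' @param path Base output path; `<path>.tsv` and `<path>.json` are written.
#' @param provenance Optional named list recorded in the JSON header (e.g.
#'   thresholds and seed used).
#' @return Paths of the two files, invisibly.
#' @export
write_report <- function(classifications, path, provenance = list()) {
  tsv <- paste0(path, ".tsv")
  jsn <- paste0(path, ".json")
  write.table(classifications, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(provenance = provenance,
                            classifications = classifications),
                       jsn, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(tsv = tsv, json = jsn))
}
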