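AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Subunit lengths chosen so every reference position below fits with margin.
REF_LENGTHS <- c(BfuB = 560L, BfuA = 320L, BfuC = 120L)

# FeS ligand positions on the A. mobile reference frame (1-based residue
# numbering). The B2 cluster and the FMN-site residues carry the positions
# reported for the A. mobile NiFe enzyme; all other clusters use synthetic
# canonical Cys quartets at fixed positions (their true ligands come from
# the cryo-EM structure, not from sequence analysis) and are configurable
# through the frame object.
default_ligand_table <- function() {
  quartet <- function(p) list(pos = p, allowed = rep(list("C"), 4))
  list(
    BfuB = list(
      B1 = quartet(c(60L, 63L, 66L, 70L)),
      B2 = list(pos = c(438L, 476L, 525L, 531L, 536L),
                allowed = list("C", c("C", "T"), "H", "C", "C")),
      B3 = quartet(c(120L, 123L, 126L, 130L)),
      B4 = quartet(c(250L, 253L, 256L, 260L)),
      B5 = quartet(c(300L, 303L, 306L, 310L))
    ),
    BfuA = list(
      A1 = quartet(c(40L, 43L, 46L, 50L)),
      A2 = quartet(c(90L, 93L, 96L, 100L)),
      A3 = quartet(c(150L, 153L, 156L, 160L)),
      A4 = quartet(c(210L, 213L, 216L, 220L)),
      A5 = quartet(c(270L, 273L, 276L, 280L))
    ),
    BfuC = list(
      C1 = quartet(c(50L, 53L, 56L, 60L))
    )
  )
}

FMN_SITE <- list(pos = c(182L, 202L, 204L),
                 residue = c("F", "A", "M"))

#' Build deterministic reference BfuB/BfuC/BfuA subunit sequences
#'
#' Generates the packaged reference frame: random amino-acid backbones with
#' the iron-sulfur cluster ligands, the pentacoordinate B2 signature
#' (C438, C476/T476, H525, C531, C536) and the FMN-site residues
#' (F182, A202, M204) planted at their reference positions. Output is
#' byte-identical for a given seed.
#'
#' @param seed Integer RNG seed.
#' @param b2_variant `"cys"` for the canonical Cys at position 476 or
#'   `"thr"` for the FeFe-style Thr replacement.
#' @return An object of class `bfu_reference_frame`: list with `sequences`
#'   (named character: BfuB, BfuA, BfuC), `ligands` (per-subunit cluster
#'   position/allowed-residue table), `fmn_site`, and `positions` (a
#'   data.frame of every planted position for the truth table).
#' @export
make_reference_proteins <- function(seed = 1L, b2_variant = c("cys", "thr")) {
  b2_variant <- match.arg(b2_variant)
  ligands <- default_ligand_table()
  seqs <- with_seed(seed, {
    lapply(REF_LENGTHS, function(n) sample(AA20, n, replace = TRUE))
  })
  plant <- function(subunit) {
    s <- seqs[[subunit]]
    for (cl in ligands[[subunit]]) {
      for (i in seq_along(cl$pos)) {
        s[cl$pos[i]] <- cl$allowed[[i]][1]
      }
    }
    s
  }
  planted <- lapply(names(REF_LENGTHS), plant)
  names(planted) <- names(REF_LENGTHS)
  planted$BfuB[FMN_SITE$pos] <- FMN_SITE$residue
  if (b2_variant == "thr") planted$BfuB[476L] <- "T"
  pos_tab <- do.call(rbind, lapply(names(ligands), function(su) {
    do.call(rbind, lapply(names(ligands[[su]]), function(cl) {
      p <- ligands[[su]][[cl]]$pos
      data.frame(subunit = su, cluster = cl, pos = p,
                 residue = planted[[su]][p], stringsAsFactors = FALSE)
    }))
  }))
  pos_tab <- rbind(pos_tab,
                   data.frame(subunit = "BfuB", cluster = "FMN",
                              pos = FMN_SITE$pos, residue = FMN_SITE$residue,
                              stringsAsFactors = FALSE))
  frame <- list(
    sequences = vapply(planted, paste, "", collapse = ""),
    ligands = ligands,
    fmn_site = FMN_SITE,
    b2_variant = b2_variant,
    positions = pos_tab,
    seed = seed
  )
  class(frame) <- "bfu_reference_frame"
  validate_reference_frame(frame)
  frame
}

validate_reference_frame <- function(frame) {
  need <- list(BfuA = paste0("A", 1:5), BfuB = paste0("B", 1:5), BfuC = "C1")
  for (su in names(need)) {
    missing <- setdiff(need[[su]], names(frame$ligands[[su]]))
    if (length(missing) > 0) {
      stop("reference frame missing clusters: ", paste(missing, collapse = ", "))
    }
    for (cl in frame$ligands[[su]]) {
      if (is.unsorted(cl$pos, strictly = TRUE)) {
        stop("ligand positions must be strictly increasing")
      }
    }
  }
  invisible(frame)
}

# The packaged default frame (fixed internal seed so that the synthetic
# generator and the scanner agree on one reference).
#' Packaged default reference frame
#' @param b2_variant Passed to [make_reference_proteins()].
#' @return A `bfu_reference_frame`.
#' @export
default_reference_frame <- function(b2_variant = "cys") {
  make_reference_proteins(seed = 104729L, b2_variant = b2_variant)
}
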