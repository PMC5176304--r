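AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Average (isotope-weighted) residue masses, Da (Expasy convention)
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_AVG_MASS <- 18.01524

check_protein <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) stop("empty protein sequence")
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), AA_ALPHABET)
  if (length(bad)) {
    stop("non-standard residue letter(s): ", paste(bad, collapse = ", "))
  }
  invisible(seq)
}

#' Read protein sequences from FASTA
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write protein sequences to FASTA (60-column wrap)
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Global pairwise percent identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, gap extend 0.5
#' by default) followed by an explicit identity computation: identical
#' aligned columns divided by the full alignment length (gap columns
#' included), times 100. The denominator convention matters - published
#' identity tables rarely state theirs - so it is fixed and documented here.
#'
#' @param a,b Protein sequences (plain strings, no gaps).
#' @param gap_opening,gap_extension Gap penalties.
#' @param substitution_matrix Name of the substitution matrix.
#' @return Percent identity, rounded to one decimal.
#' @export
global_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5,
                            substitution_matrix = "BLOSUM62") {
  check_protein(a); check_protein(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ident <- sum(pa == pb & pa != "-")
  round(100 * ident / length(pa), 1)
}

#' Pairwise identity matrix over a sequence set
#'
#' @param seqs Named character vector of protein sequences.
#' @param ... Passed to [global_identity()].
#' @return Symmetric matrix of percent identities with diagonal 100.
#' @export
identity_matrix <- function(seqs, ...) {
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- global_identity(seqs[[i]], seqs[[j]], ...)
      }
    }
  }
  m
}

#' Consensus sequence from a gapped alignment
#'
#' Per column, the most frequent non-gap residue; a frequency tie goes to the
#' residue earliest in alphabetical order (a fixed, documented rule - the
#' choice is arbitrary but must be deterministic). Columns where gaps are the
#' majority are dropped entirely, so the consensus contains no gap characters.
#'
#' @param alignment Character vector of equal-length gapped sequences
#'   (gap = `-`).
#' @return Ungapped consensus sequence (single string).
#' @export
build_consensus <- function(alignment) {
  stopifnot(length(alignment) >= 2)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(alignment, ""))
  cols <- apply(mat, 2, function(col) {
    n_gap <- sum(col == "-")
    if (n_gap > length(col) / 2) return(NA_character_)
    col <- col[col != "-"]
    if (!length(col)) return(NA_character_)
    tab <- table(col)
    winners <- names(tab)[tab == max(tab)]
    sort(winners)[1]
  })
  cols <- cols[!is.na(cols)]
  if (!length(cols)) stop("alignment is all gaps")
  paste(cols, collapse = "")
}

#' Find a sequence motif and substitute a residue within it
#'
#' Scans for every occurrence of `motif` (e.g. the integrin-binding tripeptide
#' RGD) and substitutes `new_residue` at offset `replace_offset` within each
#' occurrence (0 = first motif residue), e.g. R -> S turning RGD into SGD. If
#' the motif is absent, the sequence is returned unchanged with a warning
#' when a replacement was requested.
#'
#' @param seq Protein sequence.
#' @param motif Motif string (plain residues, no regex).
#' @param replace_offset 0-based offset within the motif to substitute, or
#'   `NULL` to only report positions.
#' @param new_residue Replacement residue (single letter).
#' @param occurrence `"all"` (default) or a 1-based index choosing which
#'   occurrence to edit.
#' @return List: `positions` (1-based start positions of each occurrence) and
#'   `sequence` (edited, same length as input).
#' @export
scan_and_replace_motif <- function(seq, motif = "RGD", replace_offset = 0,
                                   new_residue = "S", occurrence = "all") {
  check_protein(seq)
  stopifnot(nchar(motif) >= 1)
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  positions <- if (hits[1] == -1) integer(0) else as.integer(hits)
  out <- seq
  if (!is.null(replace_offset)) {
    if (!length(positions)) {
      warning("motif '", motif, "' not found; sequence unchanged")
    } else {
      stopifnot(replace_offset >= 0, replace_offset < nchar(motif))
      edit_at <- if (identical(occurrence, "all")) positions else
        positions[as.integer(occurrence)]
      for (p in edit_at) {
        substr(out, p + replace_offset, p + replace_offset) <- new_residue
      }
    }
  }
  list(positions = positions, sequence = out)
}

#' Remove an exact C-terminal peptide
#'
#' Truncates `seq` by the suffix `peptide` (e.g. removing an unneeded
#' C-terminal extension carrying an unpaired cysteine). The peptide must
#' match the C-terminus exactly; no fuzzy matching.
#'
#' @param seq Protein sequence.
#' @param peptide Suffix to remove (may be empty).
#' @return The truncated sequence.
#' @export
truncate_cterm <- function(seq, peptide) {
  check_protein(seq)
  if (nchar(peptide) == 0) return(seq)
  n <- nchar(seq); k <- nchar(peptide)
  if (k > n || substr(seq, n - k + 1, n) != peptide) {
    stop("peptide '", peptide, "' is not the C-terminal suffix of the sequence")
  }
  substr(seq, 1, n - k)
}

#' Average molecular mass of a protein
#'
#' Sum of standard average residue masses plus one water, in kDa.
#'
#' @param seq Protein sequence.
#' @param digits Decimals to round the kDa value to (default 2, the
#'   convention for predicted-mass tables).
#' @return Mass in kDa.
#' @export
average_mass <- function(seq, digits = 2) {
  check_protein(seq)
  aa <- strsplit(seq, "")[[1]]
  da <- sum(AA_AVG_MASS[aa]) + WATER_AVG_MASS
  round(da / 1000, digits)
}

#' Molar extinction coefficient at 280 nm (Gill & von Hippel)
#'
#' `e280 = 5500 * nTrp + 1490 * nTyr + 125 * n_cystine` in 1/(M cm). The
#' cystine count is supplied by the caller (the sequence alone cannot know
#' the disulfide state); it may not exceed floor(nCys / 2).
#'
#' @param seq Protein sequence.
#' @param cystines Number of disulfide bonds (default 0, i.e. all Cys
#'   reduced).
#' @return Extinction coefficient, 1/(M cm).
#' @export
extinction_coefficient <- function(seq, cystines = 0) {
  check_protein(seq)
  aa <- strsplit(seq, "")[[1]]
  n_cys <- sum(aa == "C")
  if (cystines < 0 || cystines > floor(n_cys / 2)) {
    stop("invalid cystine count: ", cystines, " (sequence has ", n_cys,
         " Cys)")
  }
  5500 * sum(aa == "W") + 1490 * sum(aa == "Y") + 125 * cystines
}
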