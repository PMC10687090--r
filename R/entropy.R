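.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read an aligned FASTA file
#'
#' Loads a multiple sequence alignment from FASTA. Sequences are
#' uppercased; `.` gaps become `-`; characters outside the 20 standard
#' amino acids and the gap (e.g. `X`, `B`, `Z`) are mapped to gap with a
#' warning. Ragged alignments and single-sequence files are errors.
#'
#' @param path Path to the aligned FASTA file.
#' @return An `msa_alignment` with fields `ids`, `seqs` (character matrix,
#'   rows = sequences, columns = alignment positions), `length`.
#' @export
read_fasta_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) stop("alignment needs at least 2 sequences")
  widths <- Biostrings::width(set)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequence '", names(set)[which(widths != widths[1])[1]],
         "' has length ", widths[widths != widths[1]][1],
         " but the first sequence has ", widths[1])
  seqs <- toupper(as.character(set))
  mat <- do.call(rbind, strsplit(seqs, ""))
  mat[mat == "."] <- "-"
  bad <- !(mat %in% c(.AA20, "-"))
  if (any(bad)) {
    warning(sum(bad), " non-standard residue symbol(s) mapped to gap")
    mat[bad] <- "-"
  }
  rownames(mat) <- names(set)
  structure(list(ids = names(set), seqs = mat, length = ncol(mat)),
            class = "msa_alignment")
}

#' Shannon entropy of one alignment column
#'
#' `H = -sum p_i log2 p_i` over the amino-acid frequencies of the column,
#' computed on non-gap symbols only (gaps do not count as a 21st state).
#' Ranges from 0 (monomorphic) to log2(20) = 4.32 bits (uniform over the
#' 20 residues). An all-gap column has no defined entropy and returns `NA`.
#'
#' @param column_symbols Character vector of single-letter residue codes
#'   and `-` gaps.
#' @return Entropy in bits, or `NA` for an all-gap column.
#' @export
column_entropy <- function(column_symbols) {
  res <- column_symbols[column_symbols != "-"]
  if (length(res) == 0L) return(NA_real_)
  p <- table(res) / length(res)
  -sum(p * log2(p))
}

#' Per-residue conservation profile of an alignment
#'
#' Computes the Shannon entropy of every alignment column and maps the
#' columns where the reference sequence is ungapped to consecutive
#' reference residue numbers. Residues with `H` below the threshold are
#' flagged conserved (2.0 bits is the conventional cutoff for mapping
#' variability onto structures).
#'
#' @param alignment An `msa_alignment`.
#' @param reference_id Identifier of the reference sequence (must be in
#'   the alignment).
#' @param threshold Conservation threshold on H, bits.
#' @param offset Residue number of the reference's first residue (use the
#'   precursor numbering offset when the aligned construct is a mature
#'   fragment).
#' @return An `entropy_profile`: data frame `columns` with per-column
#'   `column`, `H_bits`, `gap_fraction`; data frame `residues` with the
#'   reference mapping (`reference_residue`, `column`, `H_bits`,
#'   `gap_fraction`, `conserved`); plus `threshold`, `reference_id`.
#' @export
conservation_profile <- function(alignment, reference_id, threshold = 2.0,
                                 offset = 1) {
  stopifnot(inherits(alignment, "msa_alignment"))
  if (!reference_id %in% alignment$ids)
    stop("reference '", reference_id, "' not found in alignment")
  mat <- alignment$seqs
  H <- apply(mat, 2, column_entropy)
  gapf <- colMeans(mat == "-")
  ref <- mat[reference_id, ]
  ref_cols <- which(ref != "-")
  residues <- data.frame(
    reference_residue = seq_along(ref_cols) + offset - 1,
    column = ref_cols,
    H_bits = H[ref_cols],
    gap_fraction = gapf[ref_cols],
    conserved = !is.na(H[ref_cols]) & H[ref_cols] < threshold)
  structure(list(
    columns = data.frame(column = seq_len(ncol(mat)), H_bits = H,
                         gap_fraction = gapf),
    residues = residues,
    threshold = threshold, reference_id = reference_id,
    gap_handling = "excluded from frequencies; reported as gap_fraction"),
    class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("Entropy profile: %d columns, %d mapped residues of '%s', %d conserved (H < %.1f bits)\n",
              nrow(x$columns), nrow(x$residues), x$reference_id,
              sum(x$residues$conserved), x$threshold))
  invisible(x)
}

#' Write a conservation profile as CSV
#'
#' One row per mapped reference residue with columns
#' `reference_residue, column, H_bits, gap_fraction, conserved` — a format
#' ready for B-factor-style colouring of structures downstream.
#'
#' @param profile An `entropy_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "entropy_profile"))
  df <- profile$residues
  df$H_bits <- round(df$H_bits, 6)
  df$gap_fraction <- round(df$gap_fraction, 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
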