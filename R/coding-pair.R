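# standard genetic code as a named codon -> residue vector ("*" = stop)
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

split_codons <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L) {
    orevo_abort("aligned sequence length must be divisible by 3",
                "orevo_alignment_error")
  }
  substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a codon-aware aligned nucleotide sequence
#'
#' Translates with the standard genetic code. Gap codons (`---`) map to the
#' gap residue `-`; a stop codon at the terminal position is stripped; an
#' internal stop codon is an error reporting the offending codon index.
#' Gaps must occupy whole codons (codon-aware alignment).
#'
#' @param nt Aligned nucleotide string (`A/C/G/T/-`), length divisible by 3.
#' @return Aligned amino-acid string (one residue per codon).
#' @export
translate_codon_alignment <- function(nt) {
  codons <- split_codons(nt)
  has_gap <- grepl("-", codons, fixed = TRUE)
  partial <- has_gap & codons != "---"
  if (any(partial)) {
    orevo_abort(
      sprintf("partial-codon gap at codon %d ('%s'); gaps must cover whole codons",
              which(partial)[1], codons[which(partial)[1]]),
      "orevo_alignment_error")
  }
  code <- genetic_code()
  aa <- ifelse(has_gap, "-", unname(code[codons]))
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1]
    orevo_abort(sprintf("unrecognized codon %d ('%s')", bad, codons[bad]),
                "orevo_alignment_error")
  }
  n <- length(aa)
  if (n > 0L && aa[n] == "*") aa <- aa[-n]
  internal_stop <- which(aa == "*")
  if (length(internal_stop) > 0L) {
    orevo_abort(sprintf("internal stop codon at codon %d ('%s')",
                        internal_stop[1], codons[internal_stop[1]]),
                "orevo_stop_codon_error")
  }
  paste(aa, collapse = "")
}

#' Build a codon-aligned coding-sequence pair
#'
#' The container used by all pairwise sequence metrics: two codon-aligned
#' nucleotide sequences of equal length plus their translations. If either
#' sequence ends in a stop codon the terminal codon is trimmed from both.
#'
#' @param nt_a,nt_b Aligned nucleotide strings (equal length, divisible by
#'   3, gaps in whole-codon units).
#' @param id_a,id_b Sequence labels.
#' @return An object of class `coding_pair` with fields `id_a`, `id_b`,
#'   `nt_a`, `nt_b`, `aa_a`, `aa_b`.
#' @export
coding_pair <- function(nt_a, nt_b, id_a = "a", id_b = "b") {
  nt_a <- toupper(nt_a); nt_b <- toupper(nt_b)
  if (nchar(nt_a) != nchar(nt_b)) {
    orevo_abort("aligned sequences must have equal length",
                "orevo_alignment_error")
  }
  aa_a <- translate_codon_alignment(nt_a)
  aa_b <- translate_codon_alignment(nt_b)
  # strip a terminal stop consistently from both members
  n_cod <- nchar(nt_a) %/% 3L
  keep <- min(nchar(aa_a), nchar(aa_b))
  if (keep < n_cod) {
    nt_a <- substr(nt_a, 1L, 3L * keep)
    nt_b <- substr(nt_b, 1L, 3L * keep)
    aa_a <- substr(aa_a, 1L, keep)
    aa_b <- substr(aa_b, 1L, keep)
  }
  structure(
    list(id_a = id_a, id_b = id_b, nt_a = nt_a, nt_b = nt_b,
         aa_a = aa_a, aa_b = aa_b),
    class = "coding_pair")
}

#' @export
print.coding_pair <- function(x, ...) {
  cat("<coding_pair> ", x$id_a, " vs ", x$id_b,
      " (", nchar(x$nt_a), " nt aligned)\n", sep = "")
  invisible(x)
}

# codon-level pairwise deletion: indices of codons ungapped in both members
comparable_codons <- function(pair) {
  ca <- split_codons(pair$nt_a)
  cb <- split_codons(pair$nt_b)
  keep <- ca != "---" & cb != "---"
  list(a = ca[keep], b = cb[keep])
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file of aligned sequences (nucleotide or amino acid).
#' @return Named character vector of uppercase sequences.
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
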