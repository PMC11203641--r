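# Coding consequences of a deletion: CDS manipulation, translation, effect
# classification, and protein comparison.

#' Protein length encoded by a CDS
#'
#' Number of amino acids encoded by a coding sequence of `cds_len`
#' nucleotides, excluding the terminal stop codon: `cds_len / 3 - 1`. A
#' 990 bp coding region thus encodes 329 residues.
#'
#' @param cds_len CDS length in nucleotides (multiple of 3, `>= 6`).
#' @return Number of amino acids.
#' @examples
#' protein_length_from_cds(990)  # 329
#' @export
protein_length_from_cds <- function(cds_len) {
  stopifnot_scalar_number(cds_len, "cds_len", 6)
  if (cds_len %% 3 != 0) {
    stop("CDS length must be a multiple of 3", call. = FALSE)
  }
  cds_len / 3 - 1
}

#' Translate a coding sequence
#'
#' Standard-genetic-code translation of a CDS. The trailing stop codon is
#' dropped; an internal stop (as a frameshift routinely creates) truncates
#' the product and sets the `truncated` attribute rather than erroring.
#'
#' @param cds A/C/G/T string whose length is a multiple of 3.
#' @return Protein string with attribute `truncated` (logical).
#' @examples
#' translate_cds("ATGGCTTAA")  # "MA"
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  bad <- regexpr("[^ACGT]", cds)
  if (bad > 0L) {
    stop("ambiguous or invalid base at position ", bad, call. = FALSE)
  }
  if (nchar(cds) %% 3 != 0 || nchar(cds) < 3L) {
    stop("CDS length must be a positive multiple of 3", call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at < 0L) {
    protein <- aa
    truncated <- FALSE
  } else {
    protein <- substr(aa, 1L, stop_at - 1L)
    truncated <- stop_at < nchar(aa)  # a trailing stop is the normal terminus
  }
  attr(protein, "truncated") <- truncated
  protein
}

#' Apply a deletion to a CDS
#'
#' @param cds A/C/G/T string.
#' @param start 1-based offset of the first deleted base within the CDS.
#' @param length Number of bases deleted; `start + length - 1` must not
#'   exceed the CDS length.
#' @return The mutated CDS (flanks preserved byte for byte).
#' @export
apply_deletion <- function(cds, start, length) {
  stopifnot_scalar_number(start, "start", 1)
  stopifnot_scalar_number(length, "length", 1)
  if (start + length - 1 > nchar(cds)) {
    stop("deletion exceeds CDS bounds", call. = FALSE)
  }
  paste0(substr(cds, 1L, start - 1L),
         substr(cds, start + length, nchar(cds)))
}

#' Classify the reading-frame effect of a deletion
#'
#' A deletion whose length is not a multiple of 3 shifts the downstream
#' reading frame (`frameshift`); otherwise it removes whole codons
#' (`inframe_deletion`). The causal 10 bp deletion is a frameshift.
#'
#' @param length Deletion length in nucleotides (`>= 1`).
#' @return `"frameshift"` or `"inframe_deletion"`.
#' @export
classify_deletion_effect <- function(length) {
  stopifnot_scalar_number(length, "length", 1)
  if (length %% 3 == 0) "inframe_deletion" else "frameshift"
}

#' Compare two protein sequences from a single-indel perspective
#'
#' Trims the longest common prefix and suffix of the two proteins and
#' compares the remaining cores: `n_deleted` is the net residue loss (the
#' length difference of the cores, from the first protein's perspective) and
#' `n_substituted` counts aligned mismatches within the shorter core. For
#' proteins differing by one indel plus local substitutions this matches a
#' global alignment; it is deterministic and assumption-free.
#'
#' @param wt_protein,mut_protein Non-empty protein strings.
#' @return List with `n_substituted`, `n_deleted`, `n_changed`
#'   (`n_substituted + n_deleted`) and a `description` string.
#' @export
diff_proteins <- function(wt_protein, mut_protein) {
  if (!nzchar(wt_protein) || !nzchar(mut_protein)) {
    stop("proteins must be non-empty", call. = FALSE)
  }
  a <- strsplit(wt_protein, "")[[1L]]
  b <- strsplit(mut_protein, "")[[1L]]
  np <- 0L
  while (np < min(length(a), length(b)) && a[np + 1L] == b[np + 1L]) {
    np <- np + 1L
  }
  ns <- 0L
  while (ns < min(length(a), length(b)) - np &&
         a[length(a) - ns] == b[length(b) - ns]) {
    ns <- ns + 1L
  }
  core_a <- if (length(a) - ns >= np + 1L) a[(np + 1L):(length(a) - ns)] else character()
  core_b <- if (length(b) - ns >= np + 1L) b[(np + 1L):(length(b) - ns)] else character()
  n_deleted <- max(0L, length(core_a) - length(core_b))
  k <- min(length(core_a), length(core_b))
  n_sub <- if (k > 0L) sum(core_a[seq_len(k)] != core_b[seq_len(k)]) else 0L
  list(n_substituted = as.integer(n_sub), n_deleted = as.integer(n_deleted),
       n_changed = as.integer(n_sub + n_deleted),
       description = sprintf(
         "%d residue(s) changed: %d substituted, %d deleted (net)",
         n_sub + n_deleted, n_sub, n_deleted))
}

#' Read coding sequences from a FASTA file
#'
#' @param path FASTA file of nucleotide sequences.
#' @return Named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
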