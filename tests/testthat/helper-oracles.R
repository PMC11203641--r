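# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Minimum-likelihood two-sided binomial p-value by explicit enumeration,
# with the pmf computed from log-binomial coefficients (not dbinom).
enum_binom_p <- function(alt, n, p0) {
  if (p0 == 1) return(if (alt == n) 1 else 0)
  if (p0 == 0) return(if (alt == 0) 1 else 0)
  k <- 0:n
  logpmf <- lchoose(n, k) + k * log(p0) + (n - k) * log1p(-p0)
  pmf <- exp(logpmf)
  sum(pmf[pmf <= pmf[alt + 1L] * (1 + 1e-07)])
}

# Standard genetic code, hand-tabulated.
codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Translate with the hand table: trailing stop dropped, truncate at an
# internal stop.
oracle_translate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- unname(codon_table[codons])
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

# A random stop-free CDS of n_codons codons plus a terminal stop.
random_cds <- function(n_codons, seed) {
  stopfree <- names(codon_table)[codon_table != "*"]
  bulkseg:::with_seed(seed, paste0(
    paste(sample(stopfree, n_codons, replace = TRUE), collapse = ""), "TAA"))
}

# Small record-table builder with sensible defaults for filter tests.
toy_record <- function(chrom = "chr01", pos = 100L, ref = "A", alt = "T",
                       qual = 90, gt = "hom_alt", ref_depth = 0L,
                       alt_depth = 30L, gq = 99, qd = NA_real_,
                       ann = "missense|geneA") {
  variant_records(chrom, pos, ref, alt, qual, gt, ref_depth, alt_depth,
                  gq, qd, ann, "EFF")
}
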