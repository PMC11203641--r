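# Bulk variant filtering (BVF) core: effect-class restriction, bulk
# subtraction, SNP indices, segregation-aware candidate ranking and IGV batch
# script emission.

#' Restrict records to damaging effect classes
#'
#' Keeps records carrying at least one annotation whose effect class falls in
#' `classes` (any-match rule over a record's annotations). The default —
#' missense plus frameshift — is the first-round restriction used when
#' screening induced mutations for a causal candidate.
#'
#' @param records Data frame of variant records.
#' @param classes Character vector of effect classes to retain.
#' @return The retained records.
#' @export
select_effect_classes <- function(records,
                                  classes = c("missense", "frameshift")) {
  if (nrow(records) == 0L) return(records)
  keep <- vapply(records$ann, function(a) {
    anns <- parse_effect_annotations(a)
    any(anns$effect_class %in% classes)
  }, logical(1), USE.NAMES = FALSE)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract variants shared between two bulks
#'
#' Removes, from each bulk's variant set, every variant also present in the
#' other bulk, leaving the bulk-specific variants. Identity is the full
#' `(chrom, pos, ref, alt)` key after multi-allelic splitting.
#'
#' @param mutant_set,wt_set Data frames of variant records (one per bulk).
#' @return List with `mutant_specific` and `wt_specific` record tables.
#' @export
subtract_common <- function(mutant_set, wt_set) {
  km <- variant_key(mutant_set)
  kw <- variant_key(wt_set)
  if (anyDuplicated(km) || anyDuplicated(kw)) {
    stop("variant keys must be unique within each bulk", call. = FALSE)
  }
  ms <- mutant_set[!km %in% kw, , drop = FALSE]
  ws <- wt_set[!kw %in% km, , drop = FALSE]
  rownames(ms) <- rownames(ws) <- NULL
  list(mutant_specific = ms, wt_specific = ws)
}

#' SNP index of a record
#'
#' Fraction of reads supporting the alternative allele,
#' `alt_depth / (ref_depth + alt_depth)`. A bulk fixed for the mutant allele
#' has SNP index 1; a wild-type-selected bulk segregating a recessive
#' mutation is expected at 1/3.
#'
#' @param ref_depth,alt_depth Read depths supporting each allele.
#' @return Numeric SNP index in `[0, 1]`; `NA` with a warning when total
#'   depth is zero (undefined, deliberately not 0).
#' @examples
#' snp_index(0, 27)   # 1
#' snp_index(18, 9)   # 1/3
#' @export
snp_index <- function(ref_depth, alt_depth) {
  total <- ref_depth + alt_depth
  out <- ifelse(total > 0, alt_depth / total, NA_real_)
  if (anyNA(out)) warning("SNP index undefined at zero depth; returning NA")
  out
}

#' Rank bulk-specific candidates by segregation consistency
#'
#' Scores each mutant-bulk-specific variant by how consistent its read
#' support in both bulks is with the expectation of a causal locus under the
#' cross design: the mutant bulk should be fixed for the alternative allele
#' and the wild-type bulk should sit at the design's conditional frequency
#' (1/3 for a recessive mutation). Consistency is assessed per bulk with the
#' exact two-sided binomial test ([binom_consistency()]) and combined as the
#' product `p_mutant * p_wt`; candidates are ranked by descending score.
#' Ties are broken by the distance of the observed SNP-index difference from
#' its expectation, then by genomic position, making the order a
#' deterministic total order.
#'
#' The binomial test is applied to read counts, so the design's allele
#' frequencies are folded with the per-read miscall rate before testing:
#' a bulk fixed for the mutant allele is expected at read-level frequency
#' `1 - read_error`, not exactly 1, which keeps a single miscalled read from
#' annihilating an otherwise perfect candidate under the degenerate
#' `p0 = 1` distribution.
#'
#' A candidate with no wild-type-bulk coverage cannot be tested on that side:
#' `p_wt` is recorded as 1 and the candidate is flagged `wt_untestable`
#' rather than treated as maximally consistent evidence.
#'
#' @param records Mutant-bulk-specific variant records (depths are the mutant
#'   bulk's).
#' @param wt_depths Data frame keyed by `chrom, pos, ref, alt` with the
#'   wild-type bulk's `ref_depth` and `alt_depth` at any site (typically the
#'   unfiltered wild-type VCF).
#' @param design A [cross_design()].
#' @param read_error Per-read miscall probability used to fold the expected
#'   allele frequencies to read-level frequencies.
#' @return Data frame of candidates: `chrom, pos, ref, alt, gene_id,
#'   mutant_index, wt_index, p_mutant, p_wt, score, wt_untestable, rank`,
#'   ordered by rank.
#' @export
rank_candidates <- function(records, wt_depths, design, read_error = 0.001) {
  stopifnot(inherits(design, "cross_design"),
            read_error >= 0, read_error < 0.5)
  if (nrow(records) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene_id = character(),
                      mutant_index = numeric(), wt_index = numeric(),
                      p_mutant = numeric(), p_wt = numeric(),
                      score = numeric(), wt_untestable = logical(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  fold <- function(p) p * (1 - read_error) + (1 - p) * read_error
  p0_mut <- fold(expected_bulk_af(design, "mutant"))
  p0_wt <- fold(expected_bulk_af(design, "wild_type"))
  expected_delta <- p0_mut - p0_wt

  wt_idx <- match(variant_key(records), variant_key(wt_depths))
  wt_ref <- wt_depths$ref_depth[wt_idx]
  wt_alt <- wt_depths$alt_depth[wt_idx]
  wt_total <- ifelse(is.na(wt_idx), 0L, wt_ref + wt_alt)

  n <- nrow(records)
  p_mut <- numeric(n)
  p_wt <- numeric(n)
  untestable <- wt_total == 0 | is.na(wt_total)
  for (i in seq_len(n)) {
    p_mut[i] <- binom_consistency(records$alt_depth[i],
                                  records$ref_depth[i] + records$alt_depth[i],
                                  p0_mut)
    p_wt[i] <- if (untestable[i]) 1 else
      binom_consistency(wt_alt[i], wt_total[i], p0_wt)
  }
  mut_index <- records$alt_depth / (records$ref_depth + records$alt_depth)
  wt_index <- ifelse(untestable, NA_real_, wt_alt / wt_total)
  gene <- vapply(records$ann, function(a) {
    anns <- parse_effect_annotations(a)
    g <- anns$gene_id[!is.na(anns$gene_id)]
    if (length(g)) g[[1L]] else NA_character_
  }, character(1), USE.NAMES = FALSE)

  out <- data.frame(chrom = records$chrom, pos = records$pos,
                    ref = records$ref, alt = records$alt, gene_id = gene,
                    mutant_index = mut_index, wt_index = wt_index,
                    p_mutant = p_mut, p_wt = p_wt, score = p_mut * p_wt,
                    wt_untestable = untestable, stringsAsFactors = FALSE)
  delta_dev <- abs((out$mutant_index - out$wt_index) - expected_delta)
  delta_dev[is.na(delta_dev)] <- Inf
  ord <- order(-out$score, delta_dev, out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  out
}

#' Count distinct loci and annotated genes
#'
#' @param records Data frame of variant records.
#' @param classes Effect classes whose annotations contribute genes; a locus
#'   annotating two genes contributes to both.
#' @return List with `n_loci` and `n_genes`.
#' @export
summarize_loci_genes <- function(records,
                                 classes = c("missense", "frameshift")) {
  if (nrow(records) == 0L) return(list(n_loci = 0L, n_genes = 0L))
  genes <- unlist(lapply(records$ann, function(a) {
    anns <- parse_effect_annotations(a)
    anns$gene_id[anns$effect_class %in% classes & !is.na(anns$gene_id)]
  }), use.names = FALSE)
  list(n_loci = length(unique(variant_key(records))),
       n_genes = length(unique(genes)))
}

.affected_interval <- function(pos, ref, alt) {
  # VCF indel records carry an anchor base: the affected bases of a deletion
  # start one past the record position.
  if (nchar(ref) > 1L) {
    c(pos + 1L, pos + nchar(ref) - 1L)
  } else if (nchar(alt) > 1L) {
    c(pos, pos + 1L)
  } else {
    c(pos, pos)
  }
}

#' Emit an IGV batch script for candidate review
#'
#' Generates a script in the IGV batch command language (`new`, `genome`,
#' `load`, `snapshotDirectory`, then per candidate a `goto` spanning the
#' affected interval plus flanks and a `snapshot`), so ranked candidates can
#' be screenshotted non-interactively with IGV's "Run Batch Script".
#'
#' @param candidates Data frame with `chrom, pos, ref, alt` and optionally
#'   `gene_id` columns (e.g. from [rank_candidates()]).
#' @param flank Bases of context either side of the affected interval.
#' @param genome_id IGV genome identifier.
#' @param track_paths Character vector of alignment/track files to load.
#' @param snapshot_dir Directory IGV should write snapshots into.
#' @return The script as a single character string.
#' @export
igv_batch_script <- function(candidates, flank = 500, genome_id = "genome",
                             track_paths = character(),
                             snapshot_dir = "snapshots") {
  stopifnot(flank >= 0)
  lines <- c("new", paste("genome", genome_id),
             if (length(track_paths)) paste("load", track_paths),
             paste("snapshotDirectory", snapshot_dir))
  for (i in seq_len(nrow(candidates))) {
    iv <- .affected_interval(candidates$pos[i], candidates$ref[i],
                             candidates$alt[i])
    start <- max(1L, iv[1L] - as.integer(flank))
    end <- iv[2L] + as.integer(flank)
    gene <- if ("gene_id" %in% names(candidates) &&
                !is.na(candidates$gene_id[i])) candidates$gene_id[i] else "unknown"
    lines <- c(lines,
               sprintf("goto %s:%d-%d", candidates$chrom[i], start, end),
               sprintf("snapshot %s_%s_%d.png", gene, candidates$chrom[i],
                       candidates$pos[i]))
  }
  paste(lines, collapse = "\n")
}

#' Run the full bulk-variant-filtering pipeline
#'
#' Chains the stages applied to two phenotype-selected bulk VCFs: record-level
#' filtering ([filter_records()]), restriction to damaging effect classes
#' ([select_effect_classes()]), reduction of each bulk to its homozygous
#' alternative-allele calls (a pooled bulk's consensus variants — a
#' heterozygous bulk call means the pool segregates and is not treated as a
#' bulk variant), subtraction of shared variants ([subtract_common()]), and
#' segregation-aware ranking of the mutant-bulk-specific candidates
#' ([rank_candidates()]) using the wild-type bulk's raw depths as evidence.
#'
#' @param mutant_records,wt_records Variant record tables for the two bulks
#'   (e.g. from [read_vcf()]); the two tables may share keys.
#' @param design A [cross_design()].
#' @param classes Effect classes retained in the first-round restriction.
#' @param min_ab,min_dp,min_gq,min_qd Filter thresholds, see
#'   [filter_records()].
#' @param read_error Per-read miscall probability passed to
#'   [rank_candidates()].
#' @return List with `candidates` (ranked data frame), `mutant_specific`,
#'   `wt_specific`, and `summary` (loci/gene counts per bulk-specific set).
#' @export
run_bvf_pipeline <- function(mutant_records, wt_records, design,
                             classes = c("missense", "frameshift"),
                             min_ab = 0.8, min_dp = 6, min_gq = 0,
                             min_qd = 2, read_error = 0.001) {
  fm <- filter_records(mutant_records, min_ab, min_dp, min_gq, min_qd)
  fw <- filter_records(wt_records, min_ab, min_dp, min_gq, min_qd)
  em <- select_effect_classes(fm, classes)
  ew <- select_effect_classes(fw, classes)
  hm <- em[em$gt == "hom_alt", , drop = FALSE]
  hw <- ew[ew$gt == "hom_alt", , drop = FALSE]
  sub <- subtract_common(hm, hw)
  candidates <- rank_candidates(sub$mutant_specific, wt_records, design,
                                read_error = read_error)
  list(candidates = candidates,
       mutant_specific = sub$mutant_specific,
       wt_specific = sub$wt_specific,
       summary = list(mutant = summarize_loci_genes(sub$mutant_specific, classes),
                      wt = summarize_loci_genes(sub$wt_specific, classes)))
}
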