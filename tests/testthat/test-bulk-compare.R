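design <- cross_design("recessive_mutant")

test_that("effect-class restriction keeps any-match records", {
  recs <- rbind(
    toy_record(pos = 1L, ann = "synonymous|g1"),
    toy_record(pos = 2L, ann = "intron|g2,missense|g2"),
    toy_record(pos = 3L, ann = "frameshift|g3"),
    toy_record(pos = 4L, ann = ""))
  out <- select_effect_classes(recs)
  expect_equal(out$pos, c(2L, 3L))
  # hand count over a larger set: 8 of 20 records carry a target class
  classes <- c(rep("missense", 5), rep("frameshift", 3), rep("intron", 7),
               rep("synonymous", 5))
  big <- do.call(rbind, lapply(seq_along(classes), function(i) {
    toy_record(pos = i * 10L, ann = paste0(classes[i], "|g", i))
  }))
  expect_equal(nrow(select_effect_classes(big)), 8L)
})

test_that("bulk subtraction equals set-difference algebra", {
  mk <- function(pos) do.call(rbind, lapply(pos, function(p) toy_record(pos = p)))
  res <- subtract_common(mk(c(1, 2, 3)), mk(2))
  expect_equal(res$mutant_specific$pos, c(1L, 3L))
  expect_equal(nrow(res$wt_specific), 0L)
  same <- subtract_common(mk(1:5), mk(1:5))
  expect_equal(nrow(same$mutant_specific), 0L)
  expect_equal(nrow(same$wt_specific), 0L)
  # random key sets against a brute-force set-difference oracle
  for (s in 1:5) {
    keys <- bulkseg:::with_seed(s, list(a = sample.int(2000, 1000),
                                        b = sample.int(2000, 1000)))
    res <- subtract_common(mk(keys$a), mk(keys$b))
    expect_equal(sort(res$mutant_specific$pos), sort(setdiff(keys$a, keys$b)))
    expect_equal(sort(res$wt_specific$pos), sort(setdiff(keys$b, keys$a)))
    # outputs are disjoint and jointly partition the symmetric difference
    expect_length(intersect(res$mutant_specific$pos, res$wt_specific$pos), 0)
    expect_setequal(c(res$mutant_specific$pos, res$wt_specific$pos),
                    c(setdiff(keys$a, keys$b), setdiff(keys$b, keys$a)))
  }
})

test_that("SNP index is the alt-read fraction, undefined at zero depth", {
  expect_equal(snp_index(0, 27), 1)
  expect_equal(snp_index(18, 9), 1 / 3, tolerance = 1e-4)
  expect_equal(snp_index(13, 7), 0.35)
  expect_warning(ix <- snp_index(0, 0), "zero depth")
  expect_true(is.na(ix))
})

test_that("candidate ranking is consistency-ordered with deterministic ties", {
  wt_depths <- variant_records(
    chrom = c("chr01", "chr01", "chr02"), pos = c(100L, 200L, 300L),
    ref = "A", alt = "T", ref_depth = c(20L, 0L, 20L),
    alt_depth = c(10L, 0L, 10L))
  recs <- rbind(
    toy_record(chrom = "chr01", pos = 100L, ref_depth = 0L, alt_depth = 30L),
    toy_record(chrom = "chr01", pos = 200L, ref_depth = 15L, alt_depth = 15L),
    toy_record(chrom = "chr02", pos = 300L, ref_depth = 0L, alt_depth = 30L))
  ranked <- rank_candidates(recs, wt_depths, design)
  # a fixed mutant bulk with a 1/3 WT index is the textbook causal pattern
  expect_equal(ranked$pos[1], 100L)
  expect_equal(ranked$rank, 1:3)
  # index 0.5 in the mutant bulk scores below index 1.0, all else equal
  expect_lt(ranked$score[ranked$pos == 200L], ranked$score[ranked$pos == 100L])
  # a candidate with no WT coverage is flagged untestable with p_wt = 1
  expect_true(ranked$wt_untestable[ranked$pos == 200L])
  expect_equal(ranked$p_wt[ranked$pos == 200L], 1)
  # exact ties order by (chrom, pos)
  tie <- rbind(
    toy_record(chrom = "chr02", pos = 500L, ref_depth = 0L, alt_depth = 30L),
    toy_record(chrom = "chr01", pos = 900L, ref_depth = 0L, alt_depth = 30L))
  tie_wt <- variant_records(chrom = c("chr02", "chr01"), pos = c(500L, 900L),
                            ref = "A", alt = "T", ref_depth = c(20L, 20L),
                            alt_depth = c(10L, 10L))
  tied <- rank_candidates(tie, tie_wt, design)
  expect_equal(tied$chrom, c("chr01", "chr02"))
  # score is invariant under input order
  flipped <- rank_candidates(tie[2:1, ], tie_wt, design)
  expect_equal(flipped$score, tied$score)
  expect_equal(flipped$pos, tied$pos)
  expect_equal(nrow(rank_candidates(recs[0, ], wt_depths, design)), 0L)
})

test_that("loci and gene counts follow the counting rules", {
  recs <- rbind(
    toy_record(pos = 1L, ann = "missense|gA"),
    toy_record(pos = 2L, ann = "missense|gA"),
    toy_record(pos = 3L, ann = "frameshift|gB"),
    toy_record(pos = 4L, ann = "missense|gC,frameshift|gD"),  # 1 locus, 2 genes
    toy_record(pos = 5L, ann = "intron|gE"))
  out <- summarize_loci_genes(recs)
  expect_equal(out$n_loci, 5L)
  expect_equal(out$n_genes, 4L)  # gA gB gC gD; gE is not a retained class
  # random annotation table against a hand tally
  genes <- sprintf("g%02d", 1:12)
  tbl <- bulkseg:::with_seed(11L, {
    cls <- sample(c("missense", "frameshift", "intron"), 60, replace = TRUE)
    gn <- sample(genes, 60, replace = TRUE)
    do.call(rbind, lapply(1:60, function(i) {
      toy_record(pos = i * 7L, ann = paste0(cls[i], "|", gn[i]))
    }))
  })
  out2 <- summarize_loci_genes(tbl)
  ann <- do.call(rbind, lapply(tbl$ann, parse_effect_annotations))
  expect_equal(out2$n_loci, 60L)
  expect_equal(out2$n_genes,
               length(unique(ann$gene_id[ann$effect_class %in%
                                           c("missense", "frameshift")])))
})

test_that("IGV batch script spans the affected interval plus flanks", {
  # a 10 bp deletion whose VCF record anchors one base upstream
  cand <- data.frame(chrom = "chr02", pos = 47983484L,
                     ref = "GACTTGCCTAA", alt = "G", gene_id = "geneZ",
                     stringsAsFactors = FALSE)
  script <- igv_batch_script(cand, flank = 500, genome_id = "Gmax",
                             track_paths = c("mutant.bam", "wt.bam"),
                             snapshot_dir = "shots")
  lines <- strsplit(script, "\n")[[1]]
  expect_equal(lines[1:5], c("new", "genome Gmax", "load mutant.bam",
                             "load wt.bam", "snapshotDirectory shots"))
  expect_true("goto chr02:47982985-47983994" %in% lines)
  expect_true("snapshot geneZ_chr02_47983484.png" %in% lines)
  # zero candidates: header only
  empty <- igv_batch_script(cand[0, ], genome_id = "Gmax")
  expect_equal(strsplit(empty, "\n")[[1]],
               c("new", "genome Gmax", "snapshotDirectory snapshots"))
  # n candidates produce exactly n goto and n snapshot lines, clamped at 1
  many <- data.frame(chrom = "chr01", pos = c(50L, 1000L, 2000L), ref = "A",
                     alt = "T", gene_id = NA_character_,
                     stringsAsFactors = FALSE)
  mlines <- strsplit(igv_batch_script(many, flank = 200), "\n")[[1]]
  expect_equal(sum(startsWith(mlines, "goto")), 3L)
  expect_equal(sum(startsWith(mlines, "snapshot ")), 3L)
  expect_true("goto chr01:1-250" %in% mlines)
})

test_that("the pipeline ranks a planted causal variant first on synthetic bulks", {
  sim <- simulate_bulk_experiment(seed = 2024L)
  res <- run_bvf_pipeline(sim$records_mutant, sim$records_wt, design)
  causal <- sim$truth[sim$truth$is_causal, ]
  top <- res$candidates[1, ]
  expect_equal(top$chrom, causal$chrom)
  expect_equal(top$pos, causal$pos)
  # the mutant-specific set never overlaps the WT-specific set
  expect_length(intersect(bulkseg:::variant_key(res$mutant_specific),
                          bulkseg:::variant_key(res$wt_specific)), 0)
  # only damaging effect classes reach the candidate list
  keys <- bulkseg:::variant_key(res$mutant_specific)
  cls <- sim$truth$effect_class[match(keys, bulkseg:::variant_key(sim$truth))]
  expect_true(all(cls %in% c("missense", "frameshift")))
})
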