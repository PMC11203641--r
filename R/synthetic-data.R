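# Forward simulators: segregating families, phenotype-selected bulk read
# depths, annotated two-bulk VCFs, spectrophotometer readings and cultivar
# haplotype matrices. Every simulator is a pure function of its explicit seed.

#' Simulate a segregating family
#'
#' Draws `n` individuals i.i.d. from the design's genotype prior (1:2:1 by
#' default, a selfed heterozygote) and assigns phenotypes deterministically
#' from genotype under the design's inheritance mode, so a recessive mutation
#' segregates 3:1 wild-type:mutant in expectation.
#'
#' @param design A [cross_design()].
#' @param n Number of individuals (`n >= 0`).
#' @param seed Integer seed; identical seeds give identical families.
#' @return Data frame with columns `id`, `genotype`, `phenotype`.
#' @export
simulate_family <- function(design, n, seed) {
  stopifnot(inherits(design, "cross_design"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    stop("`n` must be a non-negative count", call. = FALSE)
  }
  n <- as.integer(n)
  genos <- with_seed(seed, sample(names(design$genotype_prior), n,
                                  replace = TRUE,
                                  prob = design$genotype_prior))
  data.frame(id = sprintf("ind%04d", seq_len(n)),
             genotype = if (n) genos else character(),
             phenotype = if (n) phenotype_from_genotype(genos, design$inheritance)
                         else character(),
             stringsAsFactors = FALSE)
}

#' Specify a phenotype-selected sequencing bulk
#'
#' @param selected_phenotype `"mutant"` or `"wild_type"`.
#' @param n_plants Number of plants pooled into the bulk.
#' @param mean_depth Mean site read depth.
#' @param error_rate Per-read symmetric allele miscall probability in
#'   `[0, 0.5)`.
#' @param seed Integer seed for the bulk's read sampling.
#' @param depth_model `"poisson"` (site depth Poisson with floor 1, the
#'   standard shotgun assumption) or `"fixed"` (every site at `mean_depth`).
#' @return An object of class `bulk_spec`.
#' @export
bulk_spec <- function(selected_phenotype = c("mutant", "wild_type"), n_plants,
                      mean_depth, error_rate = 0.001, seed = 1L,
                      depth_model = c("poisson", "fixed")) {
  selected_phenotype <- match.arg(selected_phenotype)
  depth_model <- match.arg(depth_model)
  stopifnot_scalar_number(n_plants, "n_plants", 1)
  stopifnot_scalar_number(mean_depth, "mean_depth", 0)
  if (mean_depth <= 0) stop("`mean_depth` must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("`error_rate` must be in [0, 0.5)", call. = FALSE)
  }
  structure(list(selected_phenotype = selected_phenotype,
                 n_plants = as.integer(n_plants), mean_depth = mean_depth,
                 error_rate = error_rate, seed = as.integer(seed),
                 depth_model = depth_model),
            class = "bulk_spec")
}

#' Build a truth table of causal and background variants
#'
#' Defines the causal variant and a set of unlinked background induced
#' variants with per-bulk true allele frequencies. Background variants are,
#' by default, homozygous differences between the two bulks' sub-lineages:
#' specific to the mutant bulk, specific to the wild-type bulk, or shared,
#' with effect classes drawn uniformly from missense, frameshift, synonymous,
#' intron and intergenic (only the first two survive the downstream effect
#' restriction).
#'
#' @param n_background Number of background variants.
#' @param seed Integer seed.
#' @param causal Named list describing the causal variant: `chrom`, `pos`,
#'   `ref`, `alt`, `gene`.
#' @param p_carrier Probabilities that a background variant is specific to
#'   the mutant bulk, specific to the wild-type bulk, or shared by both.
#' @param n_chrom Number of chromosomes positions are scattered over.
#' @return Data frame of class `truth_table`: `chrom, pos, ref, alt, gene_id,
#'   effect_class, is_causal, af_mutant, af_wt` (`NA` allele frequency for
#'   the causal row: it is determined by the sampled plants at simulation
#'   time).
#' @export
truth_table <- function(n_background = 500, seed = 1L,
                        causal = list(chrom = "chr02", pos = 47983484L,
                                      ref = "GACTTGCCTAA", alt = "G",
                                      gene = "gene_causal"),
                        p_carrier = c(mutant = 0.4, wild_type = 0.4,
                                      both = 0.2),
                        n_chrom = 20L) {
  stopifnot_scalar_number(n_background, "n_background", 0)
  n_background <- as.integer(n_background)
  bases <- c("A", "C", "G", "T")
  classes <- c("missense", "frameshift", "synonymous", "intron", "intergenic")
  bg <- with_seed(seed, {
    chrom <- sprintf("chr%02d", sample.int(n_chrom, n_background, replace = TRUE))
    pos <- sample.int(5e7, n_background, replace = TRUE)
    while (anyDuplicated(cbind(chrom, pos)) ||
           any(chrom == causal$chrom & pos == causal$pos)) {
      dup <- duplicated(cbind(chrom, pos)) |
        (chrom == causal$chrom & pos == causal$pos)
      pos[dup] <- sample.int(5e7, sum(dup), replace = TRUE)
    }
    ref <- sample(bases, n_background, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1),
                  USE.NAMES = FALSE)
    carrier <- sample(names(p_carrier), n_background, replace = TRUE,
                      prob = p_carrier)
    data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
               gene_id = sprintf("gene%05d", sample.int(60000, n_background)),
               effect_class = sample(classes, n_background, replace = TRUE),
               is_causal = rep(FALSE, n_background),
               af_mutant = as.numeric(carrier %in% c("mutant", "both")),
               af_wt = as.numeric(carrier %in% c("wild_type", "both")),
               stringsAsFactors = FALSE)
  })
  causal_row <- data.frame(chrom = causal$chrom, pos = as.integer(causal$pos),
                           ref = causal$ref, alt = causal$alt,
                           gene_id = causal$gene, effect_class = "frameshift",
                           is_causal = TRUE, af_mutant = NA_real_,
                           af_wt = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(causal_row, bg)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Simulate pooled read depths for a phenotype-selected bulk
#'
#' Samples `spec$n_plants` plants of the selected phenotype from the family
#' without replacement (so finite-bulk composition varies between
#' replicates), sets each variant's true bulk allele frequency — the mean
#' genotype dosage of the sampled plants at the causal locus, the truth
#' table's per-bulk frequency at background loci — then draws a site depth
#' (Poisson with floor 1, or fixed) and a binomial alternative-read count at
#' the error-folded frequency `f (1 - e) + (1 - f) e`.
#'
#' @param family Data frame from [simulate_family()].
#' @param spec A [bulk_spec()].
#' @param truth A [truth_table()].
#' @return Data frame keyed by `chrom, pos, ref, alt` with `ref_depth`,
#'   `alt_depth` and the true bulk frequency `af_true`.
#' @export
simulate_bulk_depths <- function(family, spec, truth) {
  stopifnot(inherits(spec, "bulk_spec"), inherits(truth, "truth_table"))
  pool <- family[family$phenotype == spec$selected_phenotype, , drop = FALSE]
  if (nrow(pool) < spec$n_plants) {
    stop(sprintf("family has %d plants of phenotype '%s' but the bulk needs %d",
                 nrow(pool), spec$selected_phenotype, spec$n_plants),
         call. = FALSE)
  }
  dosage <- c(hom_ref = 0, het = 0.5, hom_alt = 1)
  with_seed(spec$seed, {
    picked <- pool[sample.int(nrow(pool), spec$n_plants), , drop = FALSE]
    causal_af <- mean(dosage[picked$genotype])
    af_col <- if (spec$selected_phenotype == "mutant") truth$af_mutant else truth$af_wt
    f <- ifelse(truth$is_causal, causal_af, af_col)
    n <- nrow(truth)
    depth <- if (spec$depth_model == "fixed") {
      rep(as.integer(round(spec$mean_depth)), n)
    } else {
      pmax(1L, stats::rpois(n, spec$mean_depth))
    }
    e <- spec$error_rate
    p_read <- f * (1 - e) + (1 - f) * e
    alt <- stats::rbinom(n, depth, p_read)
    data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
               alt = truth$alt, ref_depth = depth - alt, alt_depth = alt,
               af_true = f, stringsAsFactors = FALSE)
  })
}

.depths_to_records <- function(depths, truth, qual_per_read = 3) {
  # Genotype the pooled sample with a naive threshold caller, mirroring what
  # a diploid caller reports on a pool: alt fraction >= 0.8 -> hom_alt,
  # <= 0.2 -> hom_ref, else het.
  total <- depths$ref_depth + depths$alt_depth
  frac <- depths$alt_depth / total
  gt <- ifelse(frac >= 0.8, "hom_alt", ifelse(frac <= 0.2, "hom_ref", "het"))
  key_t <- variant_key(truth)
  idx <- match(variant_key(depths), key_t)
  ann <- paste(truth$effect_class[idx], truth$gene_id[idx], sep = "|")
  variant_records(chrom = depths$chrom, pos = depths$pos, ref = depths$ref,
                  alt = depths$alt, qual = round(qual_per_read * total, 2),
                  gt = gt, ref_depth = depths$ref_depth,
                  alt_depth = depths$alt_depth, gq = 99, qd = NA_real_,
                  ann = ann, ann_key = "EFF")
}

#' Write synthetic two-bulk VCFs and a truth TSV
#'
#' Converts the two bulks' simulated depths into single-sample VCF files
#' (shared variant keys, naive pooled genotype calls, simplified
#' `EFF=class|gene` annotations) plus a tab-separated truth table, so the
#' whole downstream pipeline can be exercised from files.
#'
#' @param depths_mutant,depths_wt Data frames from [simulate_bulk_depths()]
#'   over identical variant keys.
#' @param truth The [truth_table()] used for both bulks.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths written
#'   (`mutant`, `wt`, `truth`), invisibly.
#' @export
write_synthetic_bulk_vcfs <- function(depths_mutant, depths_wt, truth, dir) {
  if (!setequal(variant_key(depths_mutant), variant_key(depths_wt))) {
    stop("the two bulks cover different variant keys", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(mutant = file.path(dir, "mutant.vcf"),
             wt = file.path(dir, "wt.vcf"),
             truth = file.path(dir, "truth.tsv"))
  write_vcf(.depths_to_records(depths_mutant, truth), paths[["mutant"]],
            sample_name = "MUTANT_BULK")
  write_vcf(.depths_to_records(depths_wt, truth), paths[["wt"]],
            sample_name = "WT_BULK")
  utils::write.table(
    truth[, c("chrom", "pos", "ref", "alt", "is_causal", "effect_class")],
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate a complete two-bulk experiment
#'
#' Convenience wrapper reproducing the study design end to end: a segregating
#' family, a mutant-selected and a wild-type-selected bulk, and their read
#' depths over a causal variant plus background induced variants.
#'
#' @param n_family Family size genotyped before bulking.
#' @param n_mutant,n_wt Plants pooled into each bulk.
#' @param mean_depth Mean site read depth per bulk.
#' @param n_background Background induced variants.
#' @param error_rate Per-read miscall probability.
#' @param seed Integer master seed (sub-seeds are derived from it).
#' @param design A [cross_design()].
#' @param depth_model Passed to [bulk_spec()].
#' @return List with `family`, `truth`, `depths_mutant`, `depths_wt`,
#'   `records_mutant`, `records_wt`.
#' @export
simulate_bulk_experiment <- function(n_family = 120, n_mutant = 12, n_wt = 28,
                                     mean_depth = 30, n_background = 500,
                                     error_rate = 0.001, seed = 1L,
                                     design = cross_design("recessive_mutant"),
                                     depth_model = "poisson") {
  seed <- as.integer(seed)
  family <- simulate_family(design, n_family, seed)
  truth <- truth_table(n_background, seed = seed + 1L)
  dm <- simulate_bulk_depths(
    family, bulk_spec("mutant", n_mutant, mean_depth, error_rate,
                      seed = seed + 2L, depth_model = depth_model), truth)
  dw <- simulate_bulk_depths(
    family, bulk_spec("wild_type", n_wt, mean_depth, error_rate,
                      seed = seed + 3L, depth_model = depth_model), truth)
  list(family = family, truth = truth, depths_mutant = dm, depths_wt = dw,
       records_mutant = .depths_to_records(dm, truth),
       records_wt = .depths_to_records(dw, truth))
}

# Forward spectrophotometry coefficients (mg/L from absorbances in 80%
# acetone): chl a = 9.784 A663 - 0.990 A645; chl b = 21.426 A645 - 4.650 A663;
# carotenoid = 4.695 A440 - 0.268 (chl a + chl b).
.pigment_matrix <- matrix(c(9.784, -0.990, -4.650, 21.426), nrow = 2,
                          byrow = TRUE)

#' Simulate spectrophotometer OD readings from true pigment contents
#'
#' Inverts the linear chlorophyll/carotenoid equations to find the
#' absorbances that would produce the given true contents, then adds
#' Gaussian read noise. With `noise_sd = 0`, applying
#' [pigment_concentrations()] to the result recovers the inputs exactly.
#'
#' @param true_chla,true_chlb,true_car True contents in mg/L (non-negative).
#' @param noise_sd Gaussian absorbance noise standard deviation.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Named numeric vector `c(od663, od645, od440)`.
#' @export
simulate_pigment_readings <- function(true_chla, true_chlb, true_car,
                                      noise_sd = 0, seed = 1L) {
  if (any(c(true_chla, true_chlb, true_car) < 0)) {
    stop("true pigment contents must be non-negative", call. = FALSE)
  }
  stopifnot_scalar_number(noise_sd, "noise_sd", 0)
  od <- solve(.pigment_matrix, c(true_chla, true_chlb))
  od440 <- (true_car + 0.268 * (true_chla + true_chlb)) / 4.695
  out <- c(od663 = od[1L], od645 = od[2L], od440 = od440)
  if (noise_sd > 0) {
    out <- out + with_seed(seed, stats::rnorm(3, 0, noise_sd))
  }
  out
}

#' Simulate a cultivar-panel haplotype matrix
#'
#' Builds a genotype matrix in which each planted haplotype (an allele tuple
#' across the loci) is carried by a stated number of cultivars, plus
#' singleton cultivars carrying unique tuples; [classify_haplotypes()] with
#' `min_carriers = 2` recovers exactly the planted haplotypes. Origins and
#' maturity groups are attached as metadata, either as stated per planted
#' haplotype or sampled.
#'
#' @param n_loci Number of loci (tuple length).
#' @param planted_haplotypes List; each element a list with `alleles`
#'   (character vector of length `n_loci`), `n_carriers` (`>= 2`), and
#'   optionally `origins` (character, recycled to `n_carriers`).
#' @param n_singletons Cultivars carrying unique one-off tuples.
#' @param seed Integer seed.
#' @param origin_pool Origins sampled for cultivars without stated origins.
#' @param maturity_pool Maturity groups sampled for all cultivars.
#' @return A `genotype_matrix` (see [genotype_matrix()]).
#' @export
simulate_haplotype_matrix <- function(n_loci, planted_haplotypes,
                                      n_singletons = 0, seed = 1L,
                                      origin_pool = c("Asia", "America",
                                                      "Europe", "Africa"),
                                      maturity_pool = paste0("MG", 0:9)) {
  stopifnot_scalar_number(n_loci, "n_loci", 1)
  bases <- c("A", "C", "G", "T")
  planted_tuples <- lapply(planted_haplotypes, function(h) {
    if (length(h$alleles) != n_loci) {
      stop("planted allele tuples must have length n_loci", call. = FALSE)
    }
    as.character(h$alleles)
  })
  planted_strings <- vapply(planted_tuples, paste, character(1), collapse = "/")
  if (anyDuplicated(planted_strings)) {
    stop("planted haplotypes must be distinct", call. = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    origins <- character()
    for (i in seq_along(planted_haplotypes)) {
      h <- planted_haplotypes[[i]]
      if (h$n_carriers < 1) stop("n_carriers must be >= 1", call. = FALSE)
      rows <- c(rows, rep(planted_tuples[i], h$n_carriers))
      o <- if (!is.null(h$origins)) rep_len(as.character(h$origins), h$n_carriers)
           else sample(origin_pool, h$n_carriers, replace = TRUE)
      origins <- c(origins, o)
    }
    taken <- planted_strings
    for (s in seq_len(n_singletons)) {
      repeat {
        tup <- sample(bases, n_loci, replace = TRUE)
        key <- paste(tup, collapse = "/")
        if (!key %in% taken) { taken <- c(taken, key); break }
      }
      rows <- c(rows, list(tup))
      origins <- c(origins, sample(origin_pool, 1L))
    }
    n <- length(rows)
    calls <- do.call(rbind, rows)
    ids <- sprintf("cv%04d", seq_len(n))
    rownames(calls) <- ids
    colnames(calls) <- sprintf("locus%02d", seq_len(n_loci))
    genotype_matrix(
      calls,
      loci = data.frame(locus_id = colnames(calls), chrom = "chr02",
                        pos = seq(1000L, by = 1000L, length.out = n_loci),
                        stringsAsFactors = FALSE),
      metadata = data.frame(cultivar = ids, origin = origins,
                            maturity_group = sample(maturity_pool, n,
                                                    replace = TRUE),
                            stringsAsFactors = FALSE))
  })
}
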