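design <- cross_design("recessive_mutant")

test_that("family simulation is seeded, empty-safe and 3:1 in law", {
  expect_equal(nrow(simulate_family(design, 0, 1)), 0L)
  expect_error(simulate_family(design, -1, 1), "non-negative")
  f1 <- simulate_family(design, 472, 99)
  f2 <- simulate_family(design, 472, 99)
  expect_identical(f1, f2)
  expect_false(identical(f1, simulate_family(design, 472, 100)))
  # phenotype is a deterministic function of genotype
  expect_equal(f1$phenotype,
               phenotype_from_genotype(f1$genotype, "recessive_mutant"))
  # chi-square of simulated counts vs 1:3 rejects at about the nominal 5% rate
  rejections <- vapply(1:400, function(s) {
    fam <- simulate_family(design, 472, s)
    n_mut <- sum(fam$phenotype == "mutant")
    chi2_gof(c(n_mut, 472 - n_mut), c(1, 3))$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.10)
})

test_that("mutant fraction concentrates around 1/4 at large n", {
  fracs <- vapply(1:40, function(s) {
    mean(simulate_family(design, 10000, s)$phenotype == "mutant")
  }, numeric(1))
  expect_gt(mean(abs(fracs - 0.25) <= 0.015), 0.9)
})

test_that("bulk depths follow the plants' dosages and the error model", {
  fam <- simulate_family(design, 200, 5)
  truth <- truth_table(n_background = 10, seed = 6)
  # error-free mutant bulk: the causal site is all alt reads
  dm <- simulate_bulk_depths(
    fam, bulk_spec("mutant", 12, 30, error_rate = 0, seed = 7), truth)
  causal <- dm[truth$is_causal[match(bulkseg:::variant_key(dm),
                                     bulkseg:::variant_key(truth))], ]
  expect_equal(causal$ref_depth, 0L)
  expect_gt(causal$alt_depth, 0L)
  expect_equal(causal$af_true, 1)
  # a site absent from both bulks yields no alt reads without error
  zero <- truth
  zero$af_mutant[!zero$is_causal] <- 0
  dm0 <- simulate_bulk_depths(
    fam, bulk_spec("mutant", 12, 30, error_rate = 0, seed = 8), zero)
  expect_true(all(dm0$alt_depth[!zero$is_causal] == 0L))
  # depths are a pure function of the bulk seed
  expect_identical(dm, simulate_bulk_depths(
    fam, bulk_spec("mutant", 12, 30, error_rate = 0, seed = 7), truth))
  # requesting more plants than the phenotype class holds errors
  expect_error(simulate_bulk_depths(
    fam, bulk_spec("mutant", 1000, 30, seed = 1), truth), "needs 1000")
})

test_that("WT-selected bulk allele frequency at the causal locus is 1/3 in law", {
  truth <- truth_table(n_background = 0, seed = 1)
  ratios <- vapply(1:2000, function(s) {
    fam <- simulate_family(design, 80, s)
    d <- simulate_bulk_depths(
      fam, bulk_spec("wild_type", 28, 27, error_rate = 0, seed = s,
                     depth_model = "fixed"), truth)
    d$alt_depth / (d$ref_depth + d$alt_depth)
  }, numeric(1))
  expect_equal(mean(ratios), 1 / 3, tolerance = 0.02)
})

test_that("synthetic bulk VCFs round-trip depths and count records exactly", {
  sim <- simulate_bulk_experiment(n_background = 40, seed = 3)
  dir <- tempfile()
  paths <- write_synthetic_bulk_vcfs(sim$depths_mutant, sim$depths_wt,
                                     sim$truth, dir)
  expect_true(all(file.exists(paths)))
  for (bulk in c("mutant", "wt")) {
    back <- read_vcf(paths[[bulk]])
    depths <- sim[[paste0("depths_", bulk)]]
    expect_equal(nrow(back), 41L)
    expect_equal(back[, c("chrom", "pos", "ref", "alt")],
                 depths[, c("chrom", "pos", "ref", "alt")])
    expect_equal(back$ref_depth, depths$ref_depth)
    expect_equal(back$alt_depth, depths$alt_depth)
  }
  truth_back <- read.delim(paths[["truth"]])
  expect_equal(nrow(truth_back), 41L)
  expect_equal(sum(truth_back$is_causal), 1L)
  # mismatched keys are rejected
  expect_error(write_synthetic_bulk_vcfs(sim$depths_mutant,
                                         sim$depths_wt[-1, ], sim$truth, dir),
               "different variant keys")
})

test_that("pigment reading simulation inverts the forward equations", {
  expect_equal(unname(simulate_pigment_readings(0, 0, 0)), c(0, 0, 0))
  od <- simulate_pigment_readings(4.694, 1.9602, 0.564174)
  expect_equal(unname(od), c(0.5, 0.2, 0.5), tolerance = 1e-6)
  expect_error(simulate_pigment_readings(-1, 0, 0), "non-negative")
  # noise-free round trip across random contents
  for (s in 1:100) {
    truth <- bulkseg:::with_seed(s, runif(3, 0, 25))
    od <- simulate_pigment_readings(truth[1], truth[2], truth[3])
    back <- pigment_concentrations(od[1], od[2], od[3])
    expect_equal(unname(back), truth, tolerance = 1e-9)
  }
  # noisy readings are seed-deterministic
  a <- simulate_pigment_readings(5, 2, 1, noise_sd = 0.01, seed = 4)
  expect_identical(a, simulate_pigment_readings(5, 2, 1, noise_sd = 0.01,
                                                seed = 4))
  expect_false(identical(a, simulate_pigment_readings(5, 2, 1,
                                                      noise_sd = 0.01,
                                                      seed = 5)))
})

test_that("haplotype matrix simulation plants recoverable haplotypes", {
  planted <- list(
    list(alleles = rep("A", 6), n_carriers = 10, origins = "America"),
    list(alleles = rep("C", 6), n_carriers = 5, origins = "Asia"))
  gm <- simulate_haplotype_matrix(6, planted, n_singletons = 3, seed = 9)
  expect_equal(nrow(gm$calls), 18L)
  haps <- classify_haplotypes(gm, min_carriers = 2)
  expect_equal(nrow(haps), 2L)
  expect_equal(haps$n_carriers, c(10L, 5L))
  expect_equal(attr(haps, "n_dropped"), 3L)
  # determinism
  expect_identical(gm, simulate_haplotype_matrix(6, planted,
                                                 n_singletons = 3, seed = 9))
  expect_error(simulate_haplotype_matrix(4, planted), "length n_loci")
})

test_that("a panel-scale simulation recovers exactly the planted haplotypes", {
  planted <- bulkseg:::with_seed(21L, lapply(1:30, function(i) {
    list(alleles = sample(c("A", "C", "G", "T"), 10, replace = TRUE),
         n_carriers = sample(2:120, 1))
  }))
  # de-duplicate any colliding tuples deterministically
  strs <- vapply(planted, function(h) paste(h$alleles, collapse = "/"), "")
  planted <- planted[!duplicated(strs)]
  gm <- simulate_haplotype_matrix(10, planted, n_singletons = 50, seed = 22)
  haps <- classify_haplotypes(gm, min_carriers = 2)
  expect_equal(nrow(haps), length(planted))
  expect_setequal(haps$alleles,
                  vapply(planted, function(h) paste(h$alleles, collapse = "/"), ""))
  expect_equal(sum(haps$n_carriers) + attr(haps, "n_dropped"), nrow(gm$calls))
})
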