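# Cross-design expectations, exact binomial consistency tests, segregation
# chi-square tests and marker-phenotype cosegregation.

#' Define a single-locus cross design
#'
#' A cross design captures the inheritance mode of the causal locus and the
#' genotype prior of an unselected progeny. The default prior is the 1:2:1
#' Mendelian expectation for a selfed heterozygote (an M3 line derived from a
#' heterozygous M2 plant, or an F2 population), which yields the classical 3:1
#' phenotype ratio under a recessive mutation.
#'
#' @param inheritance `"recessive_mutant"` (mutant phenotype requires two
#'   mutant alleles) or `"dominant_mutant"`.
#' @param generation_label Free-text label, e.g. `"M3 selfed line"` or `"F2"`.
#' @param genotype_prior Numeric probabilities over genotypes
#'   `(hom_ref, het, hom_alt)`; must sum to 1.
#' @return An object of class `cross_design`.
#' @examples
#' cross_design("recessive_mutant", "M3 selfed line")
#' @export
cross_design <- function(inheritance = c("recessive_mutant", "dominant_mutant"),
                         generation_label = "selfed line",
                         genotype_prior = c(0.25, 0.5, 0.25)) {
  inheritance <- match.arg(inheritance)
  if (length(genotype_prior) != 3L || any(genotype_prior < 0) ||
      any(genotype_prior > 1) || abs(sum(genotype_prior) - 1) > 1e-12) {
    stop("`genotype_prior` must be 3 probabilities summing to 1", call. = FALSE)
  }
  structure(
    list(inheritance = inheritance,
         generation_label = as.character(generation_label),
         genotype_prior = stats::setNames(as.numeric(genotype_prior),
                                          c("hom_ref", "het", "hom_alt"))),
    class = "cross_design"
  )
}

#' @export
print.cross_design <- function(x, ...) {
  cat("<cross_design> ", x$inheritance, " (", x$generation_label, ")\n",
      "  genotype prior: ",
      paste(names(x$genotype_prior), sprintf("%.3g", x$genotype_prior),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Phenotype implied by a causal genotype
#'
#' @param genotype Character vector over `hom_ref`, `het`, `hom_alt`.
#' @param inheritance Inheritance mode of the mutant allele.
#' @return Character vector over `mutant`, `wild_type`.
#' @export
phenotype_from_genotype <- function(genotype,
                                    inheritance = c("recessive_mutant",
                                                    "dominant_mutant")) {
  inheritance <- match.arg(inheritance)
  ok <- genotype %in% c("hom_ref", "het", "hom_alt")
  if (!all(ok)) stop("unknown genotype: ", genotype[!ok][1L], call. = FALSE)
  mutant <- if (inheritance == "recessive_mutant") {
    genotype == "hom_alt"
  } else {
    genotype %in% c("het", "hom_alt")
  }
  ifelse(mutant, "mutant", "wild_type")
}

#' Expected mutant-allele frequency in a phenotype-selected bulk
#'
#' Conditions the design's genotype prior on the selected phenotype and
#' returns the dosage-weighted mean mutant-allele frequency. Under the default
#' 1:2:1 prior and a recessive mutation, a mutant-selected bulk is fixed for
#' the mutant allele (frequency 1), while wild-type-phenotype plants are
#' 1/3 homozygous reference : 2/3 heterozygous, giving an expected bulk
#' frequency of 1/3.
#'
#' @param design A [cross_design()].
#' @param selected_phenotype `"mutant"` or `"wild_type"`.
#' @return Expected alternative-allele frequency in `[0, 1]`.
#' @examples
#' d <- cross_design("recessive_mutant")
#' expected_bulk_af(d, "mutant")     # 1
#' expected_bulk_af(d, "wild_type")  # 1/3
#' @export
expected_bulk_af <- function(design, selected_phenotype = c("mutant",
                                                            "wild_type")) {
  stopifnot(inherits(design, "cross_design"))
  selected_phenotype <- match.arg(selected_phenotype)
  genos <- c("hom_ref", "het", "hom_alt")
  dosage <- c(hom_ref = 0, het = 0.5, hom_alt = 1)
  pheno <- phenotype_from_genotype(genos, design$inheritance)
  keep <- pheno == selected_phenotype
  w <- design$genotype_prior[keep]
  if (sum(w) == 0) {
    stop("no genotype with prior mass yields phenotype ", selected_phenotype,
         call. = FALSE)
  }
  sum(w * dosage[keep]) / sum(w)
}

#' Exact two-sided binomial consistency p-value
#'
#' Tests whether an observed allele-depth split is consistent with an expected
#' allele frequency, using the minimum-likelihood two-sided rule: the p-value
#' is the sum of binomial probabilities over all outcomes no more likely than
#' the observed one. This formalises the read-ratio reasoning used to judge
#' whether a bulk's SNP index matches its Mendelian expectation.
#'
#' A degenerate expectation `p0 = 1` (or `0`) admits a single outcome: the
#' p-value is 1 when the observation matches it and the (zero) probability
#' mass of the impossible outcomes otherwise.
#'
#' @param alt Observed alternative-allele read count.
#' @param n Total read depth (must be positive).
#' @param p0 Expected alternative-allele frequency under the design.
#' @return p-value in `[0, 1]`.
#' @examples
#' binom_consistency(9, 27, 1/3)   # 1: 9/27 is the modal outcome
#' binom_consistency(0, 27, 1/3)   # ~1.8e-5
#' @export
binom_consistency <- function(alt, n, p0) {
  stopifnot_scalar_number(alt, "alt", 0)
  stopifnot_scalar_number(n, "n", 0)
  stopifnot_scalar_number(p0, "p0", 0)
  if (p0 > 1) stop("`p0` must be in [0, 1]", call. = FALSE)
  if (n == 0) stop("undefined for zero depth (n = 0)", call. = FALSE)
  if (alt > n) stop("`alt` cannot exceed `n`", call. = FALSE)
  if (p0 == 1) return(if (alt == n) 1 else 0)
  if (p0 == 0) return(if (alt == 0) 1 else 0)
  d <- stats::dbinom(0:n, n, p0)
  # relative tolerance guards against ties broken by floating-point noise,
  # as in the conventional exact-test implementation
  sum(d[d <= d[alt + 1L] * (1 + 1e-07)])
}

#' Chi-square goodness of fit to a segregation ratio
#'
#' Pearson chi-square test of observed class counts against expected Mendelian
#' weights (e.g. 1:3 for a recessive single gene in a selfed family). No
#' continuity correction is applied by default; Yates' correction is available
#' for two classes.
#'
#' @param observed Non-negative integer counts per phenotype class.
#' @param expected_ratio Positive weights, same length as `observed`; internally
#'   normalised, so `c(1, 3)` and `c(0.25, 0.75)` are equivalent.
#' @param yates Apply Yates' continuity correction (two classes only).
#' @return List with `statistic`, `df`, `p.value`, and `expected` counts.
#' @examples
#' chi2_gof(c(111, 361), c(1, 3))  # statistic ~0.554, p ~0.457
#' @export
chi2_gof <- function(observed, expected_ratio, yates = FALSE) {
  observed <- as.numeric(observed)
  if (length(observed) < 2L || any(observed < 0)) {
    stop("`observed` must be >= 2 non-negative counts", call. = FALSE)
  }
  if (length(expected_ratio) != length(observed) || any(expected_ratio <= 0)) {
    stop("`expected_ratio` must be positive weights matching `observed`",
         call. = FALSE)
  }
  total <- sum(observed)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  expected <- total * expected_ratio / sum(expected_ratio)
  dev <- abs(observed - expected)
  if (yates) {
    if (length(observed) != 2L) {
      stop("Yates' correction applies to two classes only", call. = FALSE)
    }
    dev <- pmax(dev - 0.5, 0)
  }
  statistic <- sum(dev^2 / expected)
  df <- length(observed) - 1L
  list(statistic = statistic, df = df,
       p.value = stats::pchisq(statistic, df, lower.tail = FALSE),
       expected = expected)
}

#' Marker-phenotype cosegregation check
#'
#' Verifies that a candidate marker cosegregates perfectly with the phenotype
#' in a genotyped family: under a recessive model every mutant-phenotype
#' individual must be homozygous for the mutant allele and no wild-type
#' individual may be. Also tabulates the genotype classes among wild-type
#' plants (expected 1 homozygous reference : 2 heterozygous in a segregating
#' family).
#'
#' @param genotypes Data frame with columns `id` and `genotype`
#'   (`hom_ref`/`het`/`hom_alt`).
#' @param phenotypes Data frame with columns `id` and `phenotype`
#'   (`mutant`/`wild_type`).
#' @param inheritance Inheritance mode of the mutant allele.
#' @return List with `consistent` (logical), `class_counts` (genotype counts
#'   split by phenotype), and `discordant_ids`.
#' @export
cosegregation_check <- function(genotypes, phenotypes,
                                inheritance = c("recessive_mutant",
                                                "dominant_mutant")) {
  inheritance <- match.arg(inheritance)
  stopifnot(all(c("id", "genotype") %in% names(genotypes)),
            all(c("id", "phenotype") %in% names(phenotypes)))
  if (anyDuplicated(genotypes$id) || anyDuplicated(phenotypes$id)) {
    stop("duplicated individual ids", call. = FALSE)
  }
  if (!setequal(genotypes$id, phenotypes$id)) {
    stop("genotype and phenotype tables cover different individuals",
         call. = FALSE)
  }
  tab <- merge(genotypes, phenotypes, by = "id")
  predicted <- phenotype_from_genotype(tab$genotype, inheritance)
  discordant <- tab$id[predicted != tab$phenotype]
  counts <- table(phenotype = tab$phenotype,
                  genotype = factor(tab$genotype,
                                    levels = c("hom_ref", "het", "hom_alt")))
  list(consistent = length(discordant) == 0L,
       class_counts = counts,
       discordant_ids = sort(discordant))
}
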