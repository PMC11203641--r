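# Haplotype classification of a cultivar panel and tabulation by origin or
# maturity group.

#' Construct a genotype matrix for a cultivar panel
#'
#' @param calls Character matrix of allele calls, cultivars in rows (row
#'   names are cultivar ids), loci in columns (column names are locus ids).
#'   `NA` marks a missing call.
#' @param loci Data frame with columns `locus_id`, `chrom`, `pos` (one row
#'   per column of `calls`, positions unique).
#' @param metadata Data frame with columns `cultivar`, `origin`,
#'   `maturity_group`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci, metadata) {
  stopifnot(is.matrix(calls),
            all(c("locus_id", "chrom", "pos") %in% names(loci)),
            all(c("cultivar", "origin", "maturity_group") %in% names(metadata)))
  if (nrow(loci) != ncol(calls)) {
    stop("`loci` must describe every column of `calls`", call. = FALSE)
  }
  if (anyDuplicated(loci[, c("chrom", "pos")])) {
    stop("locus positions must be unique", call. = FALSE)
  }
  if (!setequal(metadata$cultivar, rownames(calls))) {
    stop("`metadata` must cover exactly the cultivars in `calls`",
         call. = FALSE)
  }
  structure(list(calls = calls, loci = loci, metadata = metadata),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$calls), " cultivars x ", ncol(x$calls),
      " loci\n", sep = "")
  invisible(x)
}

#' Exclude loci inside a genomic region
#'
#' Removes loci whose position falls inside `[start, end]` on `chrom` —
#' e.g. variants belonging to an overlapping gene on the opposite strand that
#' must not contribute to the haplotype definition. Allele calls at retained
#' loci are untouched.
#'
#' @param gm A [genotype_matrix()].
#' @param chrom Chromosome of the excluded region.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return A `genotype_matrix` without the in-region loci.
#' @export
exclude_region_loci <- function(gm, chrom, start, end) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (start > end) stop("`start` must be <= `end`", call. = FALSE)
  drop <- gm$loci$chrom == chrom & gm$loci$pos >= start & gm$loci$pos <= end
  genotype_matrix(gm$calls[, !drop, drop = FALSE],
                  gm$loci[!drop, , drop = FALSE], gm$metadata)
}

#' Classify haplotypes in a cultivar panel
#'
#' Groups cultivars by exact identity of their allele tuple across the loci
#' (missing calls count as their own distinct symbol, so cultivars with
#' missing data are never merged by imputation), drops groups carried by
#' fewer than `min_carriers` cultivars, and labels the survivors `Hap_1`,
#' `Hap_2`, ... in descending carrier count, ties broken by lexicographic
#' allele tuple. The result is invariant to the row order of the matrix.
#'
#' @param gm A [genotype_matrix()].
#' @param min_carriers Minimum carriers for a haplotype to be retained
#'   (default 2: haplotypes seen in a single accession are discarded).
#' @return Data frame with columns `label`, `alleles` (tuple collapsed with
#'   `/`), `n_carriers`, and a list column `carrier_ids`; attribute
#'   `n_dropped` counts cultivars in discarded groups.
#' @export
classify_haplotypes <- function(gm, min_carriers = 2) {
  stopifnot(inherits(gm, "genotype_matrix"), min_carriers >= 1)
  calls <- gm$calls
  calls[is.na(calls)] <- "."
  tuples <- apply(calls, 1L, paste, collapse = "/")
  groups <- split(rownames(gm$calls), tuples)
  sizes <- lengths(groups)
  keep <- sizes >= min_carriers
  n_dropped <- sum(sizes[!keep])
  groups <- groups[keep]
  sizes <- sizes[keep]
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  sizes <- sizes[ord]
  out <- data.frame(label = sprintf("Hap_%d", seq_along(groups)),
                    alleles = names(groups),
                    n_carriers = as.integer(sizes),
                    stringsAsFactors = FALSE)
  out$carrier_ids <- lapply(groups, sort)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Tabulate haplotype carriers by origin or maturity group
#'
#' @param haplotypes Data frame from [classify_haplotypes()].
#' @param metadata Data frame with columns `cultivar` and the grouping field.
#' @param group_field `"origin"` or `"maturity_group"`.
#' @return A contingency `table` (haplotype x group) with carriers lacking
#'   metadata counted under `"unknown"` (a message reports how many).
#' @export
tabulate_by_group <- function(haplotypes, metadata,
                              group_field = c("origin", "maturity_group")) {
  group_field <- match.arg(group_field)
  carrier <- rep(haplotypes$label, lengths(haplotypes$carrier_ids))
  ids <- unlist(haplotypes$carrier_ids, use.names = FALSE)
  grp <- metadata[[group_field]][match(ids, metadata$cultivar)]
  n_unknown <- sum(is.na(grp))
  if (n_unknown > 0L) {
    message(n_unknown, " carrier(s) with missing ", group_field,
            " counted as 'unknown'")
    grp[is.na(grp)] <- "unknown"
  }
  table(haplotype = factor(carrier, levels = haplotypes$label),
        group = grp)
}

#' Chi-square test of haplotype-group independence
#'
#' Pearson chi-square test of independence between haplotype and group in a
#' contingency table, `df = (r - 1)(c - 1)` — e.g. to ask whether haplotypes
#' are distributed differently across maturity groups.
#'
#' @param tab Contingency table (at least 2 rows and 2 columns with positive
#'   margins), e.g. from [tabulate_by_group()].
#' @return List with `statistic`, `df`, `p.value`.
#' @export
haplotype_group_association <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: need >= 2 rows and columns with positive margins",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value)
}
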