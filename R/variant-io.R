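# VCF input/output and record-level filtering.
#
# Records are held as a plain data frame with one row per (site, alt allele)
# after multi-allelic splitting:
#   chrom, pos, ref, alt, qual, gt, ref_depth, alt_depth, gq, qd,
#   ann (raw annotation value), ann_key ("ANN" or "EFF").
# Coordinates are 1-based VCF-style; deletions carry the anchor base in `ref`.

.record_cols <- c("chrom", "pos", "ref", "alt", "qual", "gt",
                  "ref_depth", "alt_depth", "gq", "qd", "ann", "ann_key")

#' Construct a variant record table
#'
#' Lightweight constructor used by the simulators and tests; fills optional
#' fields with defaults and validates invariants.
#'
#' @param chrom,pos,ref,alt Variant identity (1-based position; the reference
#'   allele of a deletion includes the anchor base, VCF-style).
#' @param qual Phred-scaled site quality.
#' @param gt Genotype call: `hom_ref`, `het`, `hom_alt` or `missing`.
#' @param ref_depth,alt_depth Per-allele read depths.
#' @param gq Genotype quality.
#' @param qd Quality by depth; `NA` means "derive as qual/depth when needed".
#' @param ann Raw annotation value (SnpEff `ANN` dialect or simplified
#'   `class|gene` pairs); `""` for none.
#' @param ann_key INFO key the annotation was read from (`"ANN"` or `"EFF"`).
#' @return Data frame of variant records.
#' @export
variant_records <- function(chrom, pos, ref, alt, qual = NA_real_,
                            gt = "missing", ref_depth = NA_integer_,
                            alt_depth = NA_integer_, gq = NA_real_,
                            qd = NA_real_, ann = "", ann_key = "EFF") {
  if (length(chrom) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(), gt = character(),
                      ref_depth = integer(), alt_depth = integer(),
                      gq = numeric(), qd = numeric(), ann = character(),
                      ann_key = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   qual = as.numeric(qual), gt = as.character(gt),
                   ref_depth = as.integer(ref_depth),
                   alt_depth = as.integer(alt_depth),
                   gq = as.numeric(gq), qd = as.numeric(qd),
                   ann = as.character(ann), ann_key = as.character(ann_key),
                   stringsAsFactors = FALSE)
  if (any(df$pos < 1L)) stop("positions must be >= 1", call. = FALSE)
  if (any(!nzchar(df$ref)) || any(!nzchar(df$alt)) || any(df$ref == df$alt)) {
    stop("ref and alt must be non-empty and differ", call. = FALSE)
  }
  bad_gt <- !df$gt %in% c("hom_ref", "het", "hom_alt", "missing")
  if (any(bad_gt)) stop("unknown genotype call: ", df$gt[bad_gt][1L],
                        call. = FALSE)
  if (any(stats::na.omit(c(df$ref_depth, df$alt_depth)) < 0L)) {
    stop("depths must be non-negative", call. = FALSE)
  }
  df
}

.gt_from_string <- function(gt_string, allele_index) {
  alleles <- strsplit(gt_string, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0L || any(a == ".") || any(is.na(a))) return("missing")
    n_alt <- sum(a == as.character(allele_index))
    c("hom_ref", "het", "hom_alt")[n_alt + 1L]
  }, character(1))
}

.info_field <- function(info, key) {
  pattern <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pattern, info))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1))
}

#' Read a VCF file into a variant record table
#'
#' Parses a VCF 4.x file with `vcfR`, splitting multi-allelic sites into one
#' record per alternative allele. `AD`-style per-sample depths are used when
#' present; depths of alternative alleles other than the one under
#' consideration are pooled into the reference depth. Annotations are taken
#' from the INFO key `ANN` (SnpEff dialect) or the simplified key `EFF`.
#'
#' @param path Path to a VCF file.
#' @param sample Sample name or index to read genotype fields from
#'   (default: first sample).
#' @return Data frame of variant records (see [variant_records()]).
#' @export
read_vcf <- function(path, sample = 1L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    return(variant_records(character(), integer(), character(), character()))
  }
  info <- vcf@fix[, "INFO"]
  ann_val <- .info_field(info, "ANN")
  eff_val <- .info_field(info, "EFF")
  ann <- ifelse(!is.na(ann_val), ann_val, ifelse(!is.na(eff_val), eff_val, ""))
  ann_key <- ifelse(!is.na(ann_val), "ANN",
                    ifelse(!is.na(eff_val), "EFF", NA_character_))

  has_gt <- nrow(vcf@gt) > 0L && ncol(vcf@gt) >= 2L
  if (has_gt) {
    samples <- colnames(vcf@gt)[-1L]
    sample <- if (is.numeric(sample)) samples[sample] else match.arg(sample, samples)
    gt_raw <- vcfR::extract.gt(vcf, element = "GT")[, sample]
    ad_raw <- if (any(grepl("AD", vcf@gt[, "FORMAT"]))) {
      vcfR::extract.gt(vcf, element = "AD")[, sample]
    } else rep(NA_character_, n)
    gq_raw <- if (any(grepl("GQ", vcf@gt[, "FORMAT"]))) {
      suppressWarnings(as.numeric(vcfR::extract.gt(vcf, element = "GQ")[, sample]))
    } else rep(NA_real_, n)
  } else {
    gt_raw <- rep(NA_character_, n)
    ad_raw <- rep(NA_character_, n)
    gq_raw <- rep(NA_real_, n)
  }
  qd_raw <- suppressWarnings(as.numeric(.info_field(info, "QD")))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  out <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    ad <- if (!is.na(ad_raw[i])) {
      suppressWarnings(as.integer(strsplit(ad_raw[i], ",", fixed = TRUE)[[1L]]))
    } else NULL
    rows <- lapply(seq_along(alts), function(j) {
      if (!is.null(ad) && length(ad) >= j + 1L && !anyNA(ad)) {
        alt_d <- ad[j + 1L]
        ref_d <- sum(ad) - alt_d
      } else {
        alt_d <- NA_integer_
        ref_d <- NA_integer_
      }
      gt <- if (!is.na(gt_raw[i])) .gt_from_string(gt_raw[i], j) else "missing"
      variant_records(chrom = fix[i, "CHROM"],
                      pos = as.integer(fix[i, "POS"]),
                      ref = fix[i, "REF"], alt = alts[j], qual = qual[i],
                      gt = gt, ref_depth = ref_d, alt_depth = alt_d,
                      gq = gq_raw[i], qd = qd_raw[i],
                      ann = if (is.na(ann[i])) "" else ann[i],
                      ann_key = ann_key[i])
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a variant record table to a VCF file
#'
#' Emits a minimal single-sample VCF 4.2 file (FORMAT fields `GT`, `AD`, `GQ`;
#' annotations under INFO key `ANN` or `EFF`) that round-trips through
#' [read_vcf()] with identical identity, depth and annotation fields.
#'
#' @param records Data frame of variant records.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_name = "BULK") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bulkseg",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##INFO=<ID=EFF,Number=.,Type=String,Description=\"Simplified effect annotation: class|gene\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  lines <- header
  if (nrow(records) > 0L) {
    gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                 missing = "./.")[records$gt]
    ad <- ifelse(is.na(records$ref_depth) | is.na(records$alt_depth), ".",
                 paste(records$ref_depth, records$alt_depth, sep = ","))
    gq <- ifelse(is.na(records$gq), ".", format(records$gq, trim = TRUE))
    info <- ifelse(nzchar(records$ann) & !is.na(records$ann_key),
                   paste0(records$ann_key, "=", records$ann), ".")
    qual <- ifelse(is.na(records$qual), ".",
                   format(records$qual, trim = TRUE, scientific = FALSE))
    body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                  qual, "PASS", info, "GT:AD:GQ",
                  paste(gt_code, ad, gq, sep = ":"), sep = "\t")
    lines <- c(lines, body)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# Effect-term synonym map: SnpEff sequence-ontology terms, the free-text
# variants used in reports, and the simplified dialect all collapse onto one
# enum; unknown terms map to "other".
.effect_synonyms <- c(
  "missense_variant" = "missense", "missense variation" = "missense",
  "missense" = "missense",
  "frameshift_variant" = "frameshift", "frameshift variation" = "frameshift",
  "frameshift" = "frameshift",
  "synonymous_variant" = "synonymous", "synonymous" = "synonymous",
  "stop_gained" = "stop_gained",
  "5_prime_utr_variant" = "utr5", "5_prime_utr_premature_start_codon_gain_variant" = "utr5",
  "utr5" = "utr5",
  "3_prime_utr_variant" = "utr3", "utr3" = "utr3",
  "intron_variant" = "intron", "intron" = "intron",
  "intergenic_region" = "intergenic", "intergenic_variant" = "intergenic",
  "intergenic" = "intergenic"
)

.map_effect_term <- function(term) {
  hits <- .effect_synonyms[tolower(strsplit(term, "&", fixed = TRUE)[[1L]])]
  hits <- hits[!is.na(hits)]
  if (length(hits)) hits[[1L]] else "other"
}

#' Parse effect annotations from an annotation string
#'
#' Splits a comma-separated annotation value into individual entries and maps
#' effect terms onto a small canonical enum (`missense`, `frameshift`,
#' `synonymous`, `stop_gained`, `utr5`, `utr3`, `intron`, `intergenic`,
#' `other`). Both the SnpEff `ANN` sub-field layout
#' (`allele|term|impact|gene|...`) and the simplified `class|gene` dialect are
#' understood; unrecognised terms map to `other` with the raw entry preserved.
#'
#' @param ann_string Raw annotation value (the text after `ANN=` or `EFF=`);
#'   `""` or `NA` yield an empty result.
#' @return Data frame with columns `effect_class`, `gene_id`, `raw`.
#' @examples
#' parse_effect_annotations("T|missense_variant|MODERATE|GeneX|GeneX.1")
#' @export
parse_effect_annotations <- function(ann_string) {
  empty <- data.frame(effect_class = character(), gene_id = character(),
                      raw = character(), stringsAsFactors = FALSE)
  if (length(ann_string) != 1L) stop("one annotation string at a time",
                                     call. = FALSE)
  if (is.na(ann_string) || !nzchar(ann_string)) return(empty)
  entries <- strsplit(ann_string, ",", fixed = TRUE)[[1L]]
  rows <- lapply(entries, function(e) {
    f <- strsplit(e, "|", fixed = TRUE)[[1L]]
    if (length(f) >= 4L) {          # SnpEff ANN: allele|term|impact|gene|...
      cls <- .map_effect_term(f[2L])
      gene <- f[4L]
    } else if (length(f) == 2L) {   # simplified: class|gene
      cls <- .map_effect_term(f[1L])
      gene <- f[2L]
    } else {
      cls <- "other"
      gene <- NA_character_
    }
    data.frame(effect_class = cls, gene_id = gene, raw = e,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter variant records on depth, quality and allele balance
#'
#' Applies the record-level thresholds used before bulk comparison: total
#' depth `>= min_dp`, genotype quality `>= min_gq`, quality-by-depth
#' `>= min_qd` (derived as `qual / depth` when the VCF carries no `QD`
#' annotation), and — for homozygous calls — an allele-balance floor
#' `>= min_ab` on the fraction of reads supporting the called allele.
#' Heterozygous calls are exempt from the allele-balance test. All thresholds
#' are inclusive. A record missing a tested field fails that test
#' conservatively and is dropped (a message reports the count); a test whose
#' threshold is 0 is vacuous and never drops a record.
#'
#' @param records Data frame of variant records.
#' @param min_ab Allele-balance floor for homozygous calls.
#' @param min_dp Minimum total read depth.
#' @param min_gq Minimum genotype quality.
#' @param min_qd Minimum quality by depth.
#' @return The retained records.
#' @export
filter_records <- function(records, min_ab = 0.8, min_dp = 6, min_gq = 0,
                           min_qd = 2) {
  stopifnot(min_ab >= 0, min_dp >= 0, min_gq >= 0, min_qd >= 0)
  if (nrow(records) == 0L) return(records)
  dp <- records$ref_depth + records$alt_depth

  test <- function(value, threshold) {
    if (threshold <= 0) rep(TRUE, nrow(records)) else !is.na(value) & value >= threshold
  }
  qd <- ifelse(!is.na(records$qd), records$qd, records$qual / dp)
  ab <- ifelse(records$gt == "hom_alt", records$alt_depth / dp,
               ifelse(records$gt == "hom_ref", records$ref_depth / dp, NA_real_))
  pass_ab <- if (min_ab <= 0) rep(TRUE, nrow(records)) else {
    ifelse(records$gt == "het", TRUE, !is.na(ab) & ab >= min_ab)
  }
  keep <- test(dp, min_dp) & test(records$gq, min_gq) & test(qd, min_qd) & pass_ab
  n_missing <- sum(!keep & (is.na(dp) | records$gt == "missing"))
  if (n_missing > 0L) {
    message(n_missing, " record(s) dropped for missing depth or genotype fields")
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
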