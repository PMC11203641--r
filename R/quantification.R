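# Pigment quantification from spectrophotometer readings, delta-delta-Ct
# relative expression, and two-group comparison.

#' Pigment concentrations from absorbance readings
#'
#' Converts 80%-acetone-extract absorbances to concentrations in mg/L via the
#' linear spectrophotometric equations:
#' chlorophyll a `= 9.784 A663 - 0.990 A645`,
#' chlorophyll b `= 21.426 A645 - 4.650 A663`,
#' carotenoid `= 4.695 A440 - 0.268 (chl a + chl b)`.
#' Noisy readings can produce negative concentrations; these are returned
#' unclamped with a warning so that round trips through the reading simulator
#' stay exact.
#'
#' @param od663,od645,od440 Absorbances (non-negative).
#' @return Named numeric vector `c(chl_a, chl_b, carotenoid)` in mg/L.
#' @examples
#' pigment_concentrations(0.5, 0.2, 0.5)
#' @export
pigment_concentrations <- function(od663, od645, od440) {
  if (any(c(od663, od645, od440) < 0)) {
    stop("absorbances must be non-negative", call. = FALSE)
  }
  chl_a <- 9.784 * od663 - 0.990 * od645
  chl_b <- 21.426 * od645 - 4.650 * od663
  car <- 4.695 * od440 - 0.268 * (chl_a + chl_b)
  out <- c(chl_a = chl_a, chl_b = chl_b, carotenoid = car)
  if (any(out < 0)) {
    warning("negative concentration(s) from noisy readings; not clamped")
  }
  out
}

#' Convert a concentration to content per gram fresh weight
#'
#' @param conc_mgL Concentration in the extract, mg/L.
#' @param extract_volume_L Extract volume in liters (required: the tissue
#'   mass alone does not determine the conversion).
#' @param fresh_mass_g Fresh tissue mass in grams.
#' @return Content in mg per g fresh weight: `conc * volume / mass`.
#' @export
per_gram <- function(conc_mgL, extract_volume_L, fresh_mass_g) {
  if (any(extract_volume_L <= 0)) stop("extract volume must be > 0",
                                       call. = FALSE)
  if (any(fresh_mass_g <= 0)) stop("fresh mass must be > 0", call. = FALSE)
  conc_mgL * extract_volume_L / fresh_mass_g
}

#' Total chlorophyll content
#'
#' @param chl_a,chl_b Chlorophyll a and b contents (any common unit).
#' @return Their sum (`chl a + chl b`); summaries conventionally report it at
#'   two decimals.
#' @examples
#' total_pigments(9.854, 2.269)  # 12.123
#' @export
total_pigments <- function(chl_a, chl_b) {
  chl_a + chl_b
}

#' Quantify a table of pigment readings
#'
#' Applies [pigment_concentrations()] and [per_gram()] to a readings table —
#' one row per replicate with absorbances, extract volume and fresh mass —
#' returning per-replicate contents in mg per g fresh weight.
#'
#' @param readings Data frame with columns `od663`, `od645`, `od440`,
#'   `volume_l`, `mass_g` (additional columns such as `sample`/`replicate`
#'   are carried through).
#' @return `readings` with added columns `chl_a`, `chl_b`, `total_chl`,
#'   `carotenoid` (mg/g fresh weight).
#' @export
quantify_pigments <- function(readings) {
  needed <- c("od663", "od645", "od440", "volume_l", "mass_g")
  if (!all(needed %in% names(readings))) {
    stop("readings need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  conc <- t(mapply(pigment_concentrations, readings$od663, readings$od645,
                   readings$od440))
  readings$chl_a <- per_gram(conc[, "chl_a"], readings$volume_l, readings$mass_g)
  readings$chl_b <- per_gram(conc[, "chl_b"], readings$volume_l, readings$mass_g)
  readings$total_chl <- total_pigments(readings$chl_a, readings$chl_b)
  readings$carotenoid <- per_gram(conc[, "carotenoid"], readings$volume_l,
                                  readings$mass_g)
  readings
}

#' Relative expression by the minus-delta-delta-Ct method
#'
#' `ddCt = (Ct_target,sample - Ct_reference,sample) -
#'         (Ct_target,control - Ct_reference,control)`; the fold change is
#' `2^(-ddCt)`, so one cycle earlier amplification in the sample doubles the
#' reported expression.
#'
#' @param ct_target_sample,ct_reference_sample Target and reference-gene Ct
#'   values in the sample of interest.
#' @param ct_target_control,ct_reference_control The same in the calibrator.
#' @return Fold change (positive number).
#' @examples
#' ddct_fold_change(24, 20, 25, 20)  # 2
#' @export
ddct_fold_change <- function(ct_target_sample, ct_reference_sample,
                             ct_target_control, ct_reference_control) {
  cts <- c(ct_target_sample, ct_reference_sample, ct_target_control,
           ct_reference_control)
  if (any(!is.finite(cts))) stop("all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' Two-sample comparison by Student's t-test
#'
#' Pooled-variance (equal-variance) two-sided Student t-test,
#' `df = n_a + n_b - 2`; Welch's unequal-variance form is available behind a
#' flag. Degenerate inputs with zero pooled variance return `t = 0, p = 1`
#' when the means agree, and a flagged `p = 0` when they differ.
#'
#' @param group_a,group_b Numeric vectors, each of length `>= 2`.
#' @param welch Use Welch's test instead of the pooled-variance form.
#' @return List with `t`, `df`, `p.value`, and `degenerate` (logical).
#' @export
two_sample_t <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2L,
                  p.value = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = length(group_a) + length(group_b) - 2L,
                p.value = 0, degenerate = TRUE))
  }
  res <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value, degenerate = FALSE)
}
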