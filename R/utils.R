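# Internal helpers shared across modules.

#' Evaluate an expression under a private RNG state
#'
#' Seeds the random number generator, evaluates `code`, and restores the
#' caller's RNG state afterwards, so every simulator is a pure function of its
#' explicit seed and never perturbs the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

#' Variant key strings
#'
#' @param df data frame with chrom, pos, ref, alt columns.
#' @return character vector of "chrom:pos:ref:alt" keys.
#' @keywords internal
#' @noRd
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower) {
    stop(sprintf("`%s` must be a single number >= %s", name, lower),
         call. = FALSE)
  }
  invisible(x)
}
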