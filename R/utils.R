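#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so simulations are reproducible without
#' clobbering the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a deterministic child seed from a root seed
#'
#' Used for per-liver simulation streams so that any liver can be
#' regenerated on its own from the cohort root seed.
#'
#' @param root Integer root seed.
#' @param index Positive integer (e.g. liver index).
#' @keywords internal
child_seed <- function(root, index) {
  as.integer((as.numeric(root) * 1009 + as.numeric(index) * 7919) %% 2147483647L)
}

#' Percentage share of a count
#'
#' Cohort bookkeeping helper: `n` of `total` expressed in percent.
#'
#' @param n Count in the category.
#' @param total Denominator count.
#' @param digits Rounding digits (default 0, matching clinical tables).
#' @return Percentage (0-100 scale).
#' @export
#' @examples
#' cohort_share(37, 50) # 74
cohort_share <- function(n, total, digits = 0) {
  stopifnot(total > 0, n >= 0, n <= total)
  round(100 * n / total, digits)
}
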