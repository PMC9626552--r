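#' Adenylate energy charge
#'
#' Atkinson's energy charge, `(ATP + 0.5 * ADP) / (ATP + ADP + AMP)`: the
#' fraction of the adenylate pool's phosphoanhydride capacity that is
#' charged. 1 when the pool is all ATP, 0 when all AMP; healthy tissue
#' sits around 0.7-0.9. Units cancel, so any consistent concentration or
#' amount scale works.
#'
#' @param amp,adp,atp Non-negative amounts (same units within a panel).
#'   Vectorized.
#' @return Energy charge in `[0, 1]`.
#' @export
#' @examples
#' energy_charge(1, 1, 1) # 0.5
energy_charge <- function(amp, adp, atp) {
  if (any(amp < 0 | adp < 0 | atp < 0)) {
    stop("adenylate amounts must be non-negative")
  }
  total <- amp + adp + atp
  if (any(total <= 0)) {
    stop("energy charge undefined for an all-zero adenylate panel")
  }
  (atp + 0.5 * adp) / total
}

#' ATP:ADP ratio
#'
#' @param adp,atp Non-negative amounts; `adp` must be positive. Vectorized.
#' @return `atp / adp`.
#' @export
atp_adp_ratio <- function(adp, atp) {
  if (any(adp <= 0)) stop("ATP:ADP ratio undefined for ADP <= 0")
  atp / adp
}
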