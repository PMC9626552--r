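#' Coupling states from a SUIT02 step-flux table
#'
#' Collapses a step-flux table into the four coupling states of the
#' succinate pathway: L (LEAK, substrates without ADP), P (OXPHOS at
#' saturating ADP), Pc (OXPHOS after exogenous cytochrome c) and E (ET
#' capacity). E is the maximum over the recorded uncoupler (CCCP) steps,
#' so a declining final titration -- uncoupler overshoot -- does not lower
#' it.
#'
#' @param table Step-flux table from [evaluate_protocol()] (or any tibble
#'   with `step` and `flux`).
#' @param pathway Pathway label carried along (default `"S"`).
#' @return A `coupling_profile`: list with `L`, `P`, `Pc`, `E`, `pathway`,
#'   and `uncoupler_steps` (the individual CCCP fluxes).
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   step = c("LEAK", "OXPHOS", "OXPHOS_cytc", "CCCP1", "CCCP2", "CCCP3"),
#'   flux = c(8.21, 40.49, 43.48, 65, 70.33, 68)
#' )
#' coupling_states(tbl)
coupling_states <- function(table, pathway = "S") {
  role <- step_role(table$step)
  need <- c("L", "P", "Pc", "E")
  have <- need %in% role
  if (!all(have)) {
    stop("step-flux table is missing required step(s): ",
         paste(c("LEAK", "OXPHOS", "OXPHOS_cytc", "uncoupler")[!have],
               collapse = ", "))
  }
  unc <- table$flux[role == "E" & !is.na(role)]
  structure(
    list(
      L = table$flux[role == "L"][1],
      P = table$flux[role == "P"][1],
      Pc = table$flux[role == "Pc"][1],
      E = max(unc),
      pathway = pathway,
      uncoupler_steps = unc
    ),
    class = "coupling_profile"
  )
}

#' @export
print.coupling_profile <- function(x, ...) {
  cat(sprintf("<coupling_profile> %s-pathway: L=%.2f P=%.2f Pc=%.2f E=%.2f\n",
              x$pathway, x$L, x$P, x$Pc, x$E))
  invisible(x)
}

#' P-L control efficiency (1 - L/P)
#'
#' Fraction of OXPHOS-state respiration coupled to phosphorylation: 1 for a
#' perfectly coupled system, 0 when all flux is dissipative LEAK. A proxy
#' for the efficiency of mitochondrial ATP production.
#'
#' @param L LEAK-state flux.
#' @param P OXPHOS-state flux; must be positive.
#' @return `1 - L/P`. Values below 0 (L exceeding P) are returned
#'   unchanged with a warning -- they diagnose titration problems and must
#'   not be clipped away.
#' @export
#' @examples
#' pl_control_efficiency(8.21, 40.49) # ~0.797, i.e. 0.8 at one decimal
pl_control_efficiency <- function(L, P) {
  if (any(P <= 0)) stop("OXPHOS flux P must be positive")
  out <- 1 - L / P
  if (any(out < 0)) {
    warning("negative P-L control efficiency (L > P): check titrations")
  }
  out
}

#' Cytochrome c control efficiency (1 - P/Pc)
#'
#' Relative stimulation of OXPHOS respiration by exogenous cytochrome c.
#' An intact mitochondrial outer membrane retains its cytochrome c and
#' shows ~0; a damaged one lets the exogenous pool restore electron flow,
#' pushing the efficiency up (values around 0.4 mark severe damage).
#'
#' @param P OXPHOS flux before cytochrome c.
#' @param Pc OXPHOS flux after cytochrome c; must be positive.
#' @return `1 - P/Pc` (negative values returned with a warning).
#' @export
cytc_control_efficiency <- function(P, Pc) {
  if (any(Pc <= 0)) stop("post-cytochrome-c flux Pc must be positive")
  out <- 1 - P / Pc
  if (any(out < 0)) {
    warning("negative cytochrome c control efficiency (P > Pc)")
  }
  out
}

#' E-P control efficiency
#'
#' Control of the phosphorylation system over electron-transfer capacity.
#' Two conventions exist: variant `"A"` uses the pre-cytochrome-c OXPHOS
#' flux (`1 - P/E`); variant `"B"` uses the post-cytochrome-c flux
#' (`1 - Pc/E`). Both are computed; `variant` selects which one is
#' returned.
#'
#' @param profile A `coupling_profile` from [coupling_states()], or a list
#'   with `P`, `Pc`, `E`.
#' @param variant `"A"` (default) or `"B"`.
#' @return The selected efficiency, with both variants in attributes
#'   `variant_A` and `variant_B`. Negative values (E below the OXPHOS
#'   reference, an uncoupler titration failure signature) warn.
#' @export
ep_control_efficiency <- function(profile, variant = c("A", "B")) {
  variant <- match.arg(variant)
  if (profile$E <= 0) stop("ET capacity E must be positive")
  va <- 1 - profile$P / profile$E
  vb <- 1 - profile$Pc / profile$E
  out <- if (variant == "A") va else vb
  if (out < 0) {
    warning("negative E-P control efficiency (E below OXPHOS flux): ",
            "uncoupler titration may have failed")
  }
  attr(out, "variant_A") <- va
  attr(out, "variant_B") <- vb
  attr(out, "variant") <- variant
  out
}

#' Efficiency panel for one coupling profile
#'
#' @param profile A `coupling_profile`.
#' @param variant E-P convention passed to [ep_control_efficiency()].
#' @return One-row tibble: `pl_eff`, `cytc_eff`, `ep_eff`, `ep_eff_A`,
#'   `ep_eff_B`, `variant`, `qc` (`"ok"` or `"negative"`).
#' @export
efficiency_panel <- function(profile, variant = c("A", "B")) {
  variant <- match.arg(variant)
  pl <- suppressWarnings(pl_control_efficiency(profile$L, profile$P))
  cy <- suppressWarnings(cytc_control_efficiency(profile$P, profile$Pc))
  ep <- suppressWarnings(ep_control_efficiency(profile, variant))
  vals <- c(pl, cy, as.numeric(ep))
  tibble::tibble(
    pl_eff = pl, cytc_eff = cy, ep_eff = as.numeric(ep),
    ep_eff_A = attr(ep, "variant_A"), ep_eff_B = attr(ep, "variant_B"),
    variant = variant,
    qc = if (any(vals < 0)) "negative" else "ok"
  )
}

#' Flux control ratios of the substrate pathways
#'
#' Normalizes the OXPHOS-state pathway fluxes (fatty-acid-, NADH- and
#' succinate-linked) to the internal reference -- the maximum OXPHOS
#' capacity reached with all substrates in the same run -- giving
#' dimensionless flux control ratios (FCR). An FCR of 1 means that pathway
#' alone saturates OXPHOS capacity.
#'
#' @param F_P,N_P,S_P Pathway OXPHOS fluxes (pmol O2 s-1 mg-1).
#' @param ref_max Internal reference flux (all substrates); must be
#'   positive.
#' @return Named numeric vector `c(F = , N = , S = )`.
#' @export
#' @examples
#' flux_control_ratios(12.54, 4.81, 40.23, ref_max = 40.23)
flux_control_ratios <- function(F_P, N_P, S_P, ref_max) {
  if (any(ref_max <= 0)) stop("internal reference flux must be positive")
  c(F = F_P / ref_max, N = N_P / ref_max, S = S_P / ref_max)
}
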