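#' SUIT titration protocols
#'
#' A SUIT (substrate-uncoupler-inhibitor titration) protocol is an ordered
#' table of chamber additions, each defining a respiratory step. `"SUIT02"`
#' is the succinate coupling-control protocol: LEAK respiration with
#' succinate + rotenone in the absence of ADP, OXPHOS capacity after
#' saturating ADP, the cytochrome-c integrity test, and stepwise CCCP
#' titration to electron-transfer (ET) capacity. `"SUIT01"` is the pathway
#' protocol building fatty-acid- (F), NADH- (N) and succinate-linked (S)
#' OXPHOS states against an all-substrate internal reference.
#'
#' @param id Protocol name, `"SUIT02"` or `"SUIT01"`.
#' @param step_duration Nominal seconds between titrations (default 300 s;
#'   long enough for a post-titration transient with a 20 s time constant to
#'   decay and a 120 s plateau window to fit).
#'
#' @return A tibble with columns `step`, `titrant`, `concentration` (display
#'   string) and `duration_s`, plus a `protocol_id` attribute.
#' @export
suit_protocol <- function(id = c("SUIT02", "SUIT01"), step_duration = 300) {
  id <- match.arg(id)
  steps <- switch(id,
    SUIT02 = tibble::tribble(
      ~step,          ~titrant,                ~concentration,
      "LEAK",         "succinate + rotenone",  "10 mM + 0.5 uM",
      "OXPHOS",       "ADP",                   "5 mM",
      "OXPHOS_cytc",  "cytochrome c",          "10 uM",
      "CCCP1",        "CCCP",                  "0.5 uM",
      "CCCP2",        "CCCP",                  "1.0 uM",
      "CCCP3",        "CCCP",                  "1.5 uM"
    ),
    SUIT01 = tibble::tribble(
      ~step,          ~titrant,                          ~concentration,
      "F_LEAK",       "octanoylcarnitine + malate",      "0.5 mM + 0.1 mM",
      "F_OXPHOS",     "ADP",                             "5 mM",
      "FN_OXPHOS",    "pyruvate + malate + glutamate",   "5 mM + 2 mM + 10 mM",
      "FNS_OXPHOS",   "succinate",                       "10 mM",
      "S_OXPHOS",     "rotenone",                        "0.5 uM"
    )
  )
  steps$duration_s <- step_duration
  attr(steps, "protocol_id") <- id
  steps
}

#' Role of each SUIT02 step in coupling-control analysis
#'
#' Maps step labels to the coupling states L (LEAK), P (OXPHOS),
#' Pc (OXPHOS after cytochrome c) and the uncoupler steps whose maximum
#' defines ET capacity E. Steps matching `^CCCP` or `^ET` count as
#' uncoupler steps.
#'
#' @param step Character vector of step labels.
#' @return Character vector of roles: `"L"`, `"P"`, `"Pc"`, `"E"` or `NA`.
#' @keywords internal
step_role <- function(step) {
  out <- rep(NA_character_, length(step))
  out[step == "LEAK"] <- "L"
  out[step == "OXPHOS"] <- "P"
  out[step == "OXPHOS_cytc"] <- "Pc"
  out[grepl("^(CCCP|ET)", step)] <- "E"
  out
}
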