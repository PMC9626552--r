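#' Transplantability criteria configuration
#'
#' The decision rules used during NMP: (1) prompt lactate clearance to at
#' most 2.5 mmol/L (by default within the first 2 h of perfusion),
#' (2) stable physiological pH 7.30-7.45 without repeated sodium
#' bicarbonate supplementation (fewer than 2 additions), and (3) no
#' excessive hepatocyte-injury enzyme release (AST, ALT, LDH each at most
#' 20,000 U/L). IL-6 carries no hard threshold and is surfaced only as a
#' warning.
#'
#' @param lactate_max mmol/L (default 2.5).
#' @param lactate_deadline_h Hours by which clearance must occur (default 2).
#' @param ph_range Acceptable pH interval (default `c(7.30, 7.45)`).
#' @param max_bicarbonate Maximum bicarbonate additions before "repeated"
#'   (default 1, i.e. a second addition fails the criterion).
#' @param enzyme_max U/L ceiling for AST, ALT and LDH (default 20000).
#' @param il6_warn IL-6 level above which a caution note is attached
#'   (default `Inf`: never).
#' @return A `viability_criteria` list.
#' @export
viability_criteria <- function(lactate_max = 2.5, lactate_deadline_h = 2,
                               ph_range = c(7.30, 7.45),
                               max_bicarbonate = 1,
                               enzyme_max = 20000, il6_warn = Inf) {
  stopifnot(lactate_max > 0, lactate_deadline_h > 0,
            length(ph_range) == 2, ph_range[1] < ph_range[2],
            max_bicarbonate >= 0, enzyme_max > 0)
  structure(
    list(lactate_max = lactate_max, lactate_deadline_h = lactate_deadline_h,
         ph_range = ph_range, max_bicarbonate = max_bicarbonate,
         enzyme_max = enzyme_max, il6_warn = il6_warn),
    class = "viability_criteria"
  )
}

#' Assess transplantability from a perfusate series
#'
#' Applies the NMP decision rules to one liver's perfusate trajectory. The
#' overall decision is `"accept"` exactly when all three criterion flags
#' hold.
#'
#' @param series Tibble with columns `time_h`, `lactate`, `ph`, `ast`,
#'   `alt`, `ldh`, optionally `il6` and logical `bicarbonate_given`; times
#'   non-decreasing.
#' @param criteria A [viability_criteria()] object.
#' @return A `viability_decision` list: logical `lactate_cleared`,
#'   `ph_stable`, `enzymes_ok`; `overall` (`"accept"`/`"reject"`);
#'   `reasons` (failed criteria); `warnings` (e.g. IL-6 caution).
#' @export
assess_viability <- function(series, criteria = viability_criteria()) {
  if (nrow(series) == 0) stop("empty perfusate series")
  if (is.unsorted(series$time_h)) stop("perfusate times must be non-decreasing")
  early <- series$time_h <= criteria$lactate_deadline_h
  if (!any(early)) {
    stop("no perfusate sample at or before the lactate deadline (",
         criteria$lactate_deadline_h, " h)")
  }
  lactate_cleared <- any(series$lactate[early] <= criteria$lactate_max)

  n_bicarb <- if ("bicarbonate_given" %in% names(series)) {
    sum(series$bicarbonate_given, na.rm = TRUE)
  } else {
    0L
  }
  ph_stable <- all(series$ph >= criteria$ph_range[1] &
                     series$ph <= criteria$ph_range[2]) &&
    n_bicarb <= criteria$max_bicarbonate

  enzymes <- c(ast = max(series$ast, na.rm = TRUE),
               alt = max(series$alt, na.rm = TRUE),
               ldh = max(series$ldh, na.rm = TRUE))
  enzymes_ok <- all(enzymes <= criteria$enzyme_max)

  flags <- c(lactate_cleared = lactate_cleared, ph_stable = ph_stable,
             enzymes_ok = enzymes_ok)
  warnings <- character()
  if ("il6" %in% names(series) &&
      any(series$il6 > criteria$il6_warn, na.rm = TRUE)) {
    warnings <- "il6_high"
  }
  structure(
    list(lactate_cleared = lactate_cleared, ph_stable = ph_stable,
         enzymes_ok = enzymes_ok,
         overall = if (all(flags)) "accept" else "reject",
         reasons = names(flags)[!flags], warnings = warnings),
    class = "viability_decision"
  )
}

#' @export
print.viability_decision <- function(x, ...) {
  cat("<viability_decision>", toupper(x$overall))
  if (length(x$reasons)) cat(" (failed:", paste(x$reasons, collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

#' Median/IQR summary of perfusate trajectories
#'
#' Summarizes observed analyte values per time point (and optional group)
#' as median and interquartile range, exactly as clinical perfusion tables
#' report them. Only observed sampling times are used -- no interpolation.
#'
#' @param cohort Long tibble with columns `liver_id`, `time_h`, `analyte`,
#'   `value`, and optionally a grouping column.
#' @param group Optional name of a grouping column (e.g. transplanted vs
#'   discarded).
#' @return Tibble with `analyte`, `time_h`, optional group, `n`, `median`,
#'   `q25`, `q75`.
#' @export
summarize_trajectories <- function(cohort, group = NULL) {
  keys <- c(group, "analyte", "time_h")
  cohort |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$value, na.rm = TRUE),
      q25 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q75 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
}
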