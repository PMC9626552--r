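#' Write / read a respirometry trace as CSV
#'
#' A trace is stored as two plain-text files: `<prefix>_o2.csv` with
#' columns `time_s`, `o2_uM`, and `<prefix>_events.csv` with the titration
#' events (`time_s`, `step`, `titrant`, `concentration`).
#'
#' @param trace A [respiro_trace()].
#' @param prefix Path prefix for the two files.
#' @return `write_trace_csv` returns the two paths invisibly;
#'   `read_trace_csv` returns a `respiro_trace`.
#' @export
write_trace_csv <- function(trace, prefix) {
  stopifnot(inherits(trace, "respiro_trace"))
  p1 <- paste0(prefix, "_o2.csv")
  p2 <- paste0(prefix, "_events.csv")
  utils::write.csv(data.frame(time_s = trace$time, o2_uM = trace$o2),
                   p1, row.names = FALSE)
  utils::write.csv(as.data.frame(trace$events), p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_trace_csv
#' @param chamber_volume,mass_density,chamber_id Chamber metadata (not
#'   stored in the CSVs).
#' @export
read_trace_csv <- function(prefix, chamber_volume = 2, mass_density = 1,
                           chamber_id = "A") {
  o2 <- utils::read.csv(paste0(prefix, "_o2.csv"))
  ev <- utils::read.csv(paste0(prefix, "_events.csv"))
  respiro_trace(time = o2$time_s, o2 = o2$o2_uM,
                events = tibble::as_tibble(ev),
                chamber_volume = chamber_volume,
                mass_density = mass_density, chamber_id = chamber_id)
}

#' Write / read a simulated cohort as tidy CSVs
#'
#' The biomarker trajectories go to `<prefix>_biomarkers.csv` (long
#' format: `liver_id`, `time_h`, `timepoint`, `parameter`, `value`) and
#' the outcome table to `<prefix>_outcomes.csv` (`liver_id`, AUC columns,
#' `lgraft`, `meaf`, `ead`).
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param prefix Path prefix.
#' @return Paths invisibly; `read_cohort_csv` returns a list with
#'   `biomarkers` and `cohort` tibbles.
#' @export
write_cohort_csv <- function(bundle, prefix) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  p1 <- paste0(prefix, "_biomarkers.csv")
  p2 <- paste0(prefix, "_outcomes.csv")
  utils::write.csv(as.data.frame(cohort_biomarkers(bundle)), p1,
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$cohort), p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(prefix) {
  list(
    biomarkers = tibble::as_tibble(
      utils::read.csv(paste0(prefix, "_biomarkers.csv"))
    ),
    cohort = tibble::as_tibble(
      utils::read.csv(paste0(prefix, "_outcomes.csv"))
    )
  )
}
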