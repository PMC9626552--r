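#' Construct a respirometry trace
#'
#' Container for one chamber recording: oxygen concentration versus time
#' plus the ordered titration events that delimit SUIT steps.
#'
#' @param time Numeric vector of seconds, strictly increasing.
#' @param o2 Oxygen concentration, uM; finite, same length as `time`.
#' @param events Tibble with columns `time_s`, `step`, `titrant`,
#'   `concentration`, sorted by time.
#' @param chamber_volume Chamber volume, mL.
#' @param mass_density Wet tissue mass per chamber volume, mg mL-1.
#' @param chamber_id Chamber label.
#' @param o2_true Optional noiseless concentration (simulation diagnostics).
#'
#' @return An object of class `respiro_trace`.
#' @export
respiro_trace <- function(time, o2, events, chamber_volume = 2,
                          mass_density = 1, chamber_id = "A",
                          o2_true = NULL) {
  stopifnot(length(time) == length(o2), all(is.finite(o2)),
            mass_density > 0, chamber_volume > 0)
  if (any(diff(time) <= 0)) stop("trace time must be strictly increasing")
  if (!all(c("time_s", "step") %in% names(events))) {
    stop("events must have columns time_s and step")
  }
  if (is.unsorted(events$time_s)) stop("events must be sorted by time")
  structure(
    list(time = time, o2 = o2, events = tibble::as_tibble(events),
         chamber_volume = chamber_volume, mass_density = mass_density,
         chamber_id = chamber_id, o2_true = o2_true),
    class = "respiro_trace"
  )
}

#' @export
print.respiro_trace <- function(x, ...) {
  cat("<respiro_trace> chamber", x$chamber_id, "-",
      length(x$time), "samples over", round(max(x$time) - min(x$time)), "s,",
      nrow(x$events), "events\n")
  invisible(x)
}

#' Flux-extraction settings
#'
#' Settings for turning a trace into per-step steady-state fluxes; the
#' analysis re-implements what oxygraph vendor software does with marked
#' plateau regions, but with an explicit, deterministic plateau detector.
#'
#' @param skip_after_event Seconds to discard after each titration before
#'   looking for a plateau (default 60; covers mixing and the chemical
#'   transient).
#' @param window_length Plateau window length in seconds (default 120).
#' @param slope_tolerance Maximum admissible relative drift of the flux,
#'   as a fraction of the flux magnitude per minute (default 0.01).
#' @param cv_max Maximum coefficient of variation of the flux inside the
#'   window (default 0.05).
#' @param max_wait Give up looking for a plateau this many seconds after
#'   the event (default 600).
#' @param smoothing_halfwidth Half-width, in samples, of the local
#'   linear-regression window used for the concentration derivative
#'   (default 5, i.e. about 10 s at a 2 s recording interval).
#' @param background_a,background_b Instrumental background flux
#'   coefficients `a + b * C` in pmol s-1 mL-1 (defaults 0, 0).
#'
#' @return A `flux_extraction_config` list.
#' @export
flux_extraction_config <- function(skip_after_event = 60,
                                   window_length = 120,
                                   slope_tolerance = 0.01,
                                   cv_max = 0.05,
                                   max_wait = 600,
                                   smoothing_halfwidth = 5,
                                   background_a = 0,
                                   background_b = 0) {
  stopifnot(skip_after_event > 0, window_length > 0, slope_tolerance > 0,
            cv_max > 0, max_wait > 0, smoothing_halfwidth >= 1,
            window_length <= max_wait)
  structure(
    list(skip_after_event = skip_after_event, window_length = window_length,
         slope_tolerance = slope_tolerance, cv_max = cv_max,
         max_wait = max_wait, smoothing_halfwidth = smoothing_halfwidth,
         background_a = background_a, background_b = background_b),
    class = "flux_extraction_config"
  )
}

#' Pointwise oxygen flux from a concentration trace
#'
#' Estimates the mass-specific flux at every sample as
#' `J(t) = (-dC/dt * 1000 - Jbg(C)) / mass_density`, with the derivative
#' from a windowed local linear regression (half-width
#' `smoothing_halfwidth` samples) and the instrumental background
#' `Jbg(C) = background_a + background_b * C` per mL. Edge samples whose
#' regression window is truncated are flagged.
#'
#' @param trace A [respiro_trace()].
#' @param config A [flux_extraction_config()].
#' @return Tibble with columns `time_s`, `o2_uM`, `flux`
#'   (pmol O2 s-1 mg-1) and `edge` (logical).
#' @export
compute_flux_series <- function(trace, config = flux_extraction_config()) {
  stopifnot(inherits(trace, "respiro_trace"))
  h <- config$smoothing_halfwidth
  t <- trace$time
  y <- trace$o2
  n <- length(t)
  if (n < 2 * h + 1) {
    stop("trace too short for derivative window: need at least ",
         2 * h + 1, " samples")
  }
  slope <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    tt <- t[lo:hi]
    yy <- y[lo:hi]
    tc <- tt - mean(tt)
    slope[i] <- sum(tc * (yy - mean(yy))) / sum(tc^2)
  }
  bg <- config$background_a + config$background_b * y
  flux <- (-slope * 1000 - bg) / trace$mass_density
  edge <- seq_len(n) <= h | seq_len(n) > n - h
  tibble::tibble(time_s = t, o2_uM = y, flux = flux, edge = edge)
}

#' Detect the steady-state plateau after one titration
#'
#' Scans candidate windows of `window_length` seconds, starting
#' `skip_after_event` seconds after the event, and accepts the earliest one
#' in which the fitted flux drift is at most `slope_tolerance` of the flux
#' magnitude per minute and the coefficient of variation is at most
#' `cv_max`. The step flux is the 10% trimmed mean of the window: like the
#' median it resists the decaying titration transient and marked outliers,
#' but under white recording noise it is nearly as efficient as the plain
#' mean, which the median is not. If no
#' window qualifies before the next event (or `max_wait`), the last
#' candidate window is reported with `qc = "no_plateau"`; a window running
#' past the end of the trace is reported from the available samples with
#' `qc = "short_window"`.
#'
#' @param flux_series Output of [compute_flux_series()].
#' @param event_time Time of the titration, s.
#' @param limit_time Do not search past this time (next event or trace
#'   end), s.
#' @param config A [flux_extraction_config()].
#' @return One-row tibble: `flux`, `t_start`, `t_end`, `cv`, `qc`.
#' @export
detect_plateau <- function(flux_series, event_time, limit_time = Inf,
                           config = flux_extraction_config()) {
  t <- flux_series$time_s
  if (event_time < min(t) || event_time > max(t)) {
    stop("event time ", event_time, " outside trace span")
  }
  usable <- !flux_series$edge
  limit <- min(limit_time, event_time + config$max_wait, max(t))
  first_start <- event_time + config$skip_after_event
  wl <- config$window_length

  short <- first_start + wl > max(t)
  starts_idx <- which(t >= first_start & usable)
  if (length(starts_idx) == 0) {
    return(tibble::tibble(flux = NA_real_, t_start = NA_real_,
                          t_end = NA_real_, cv = NA_real_,
                          qc = "short_window"))
  }

  eval_window <- function(i0) {
    t0 <- t[i0]
    idx <- which(t >= t0 & t <= t0 + wl & usable)
    if (length(idx) < 3) return(NULL)
    f <- flux_series$flux[idx]
    tt <- t[idx]
    tc <- tt - mean(tt)
    drift <- sum(tc * (f - mean(f))) / sum(tc^2)      # flux units per s
    m <- mean(f, trim = 0.1)
    rel_drift <- abs(drift) * 60 / max(abs(m), .Machine$double.eps)
    cv <- stats::sd(f) / max(abs(mean(f)), .Machine$double.eps)
    list(flux = m, t_start = tt[1], t_end = tt[length(tt)],
         cv = cv, ok = rel_drift <= config$slope_tolerance &&
           cv <= config$cv_max)
  }

  if (short) {
    w <- eval_window(starts_idx[1])
    if (is.null(w)) {
      return(tibble::tibble(flux = NA_real_, t_start = NA_real_,
                            t_end = NA_real_, cv = NA_real_,
                            qc = "short_window"))
    }
    return(tibble::tibble(flux = w$flux, t_start = w$t_start,
                          t_end = w$t_end, cv = w$cv, qc = "short_window"))
  }

  last <- NULL
  for (i0 in starts_idx) {
    if (t[i0] + wl > limit) break
    w <- eval_window(i0)
    if (is.null(w)) next
    last <- w
    if (w$ok) {
      return(tibble::tibble(flux = w$flux, t_start = w$t_start,
                            t_end = w$t_end, cv = w$cv, qc = "ok"))
    }
  }
  if (is.null(last)) {
    # no full window fits before the limit: use what is available
    w <- eval_window(starts_idx[1])
    return(tibble::tibble(flux = if (is.null(w)) NA_real_ else w$flux,
                          t_start = if (is.null(w)) NA_real_ else w$t_start,
                          t_end = if (is.null(w)) NA_real_ else w$t_end,
                          cv = if (is.null(w)) NA_real_ else w$cv,
                          qc = "short_window"))
  }
  tibble::tibble(flux = last$flux, t_start = last$t_start,
                 t_end = last$t_end, cv = last$cv, qc = "no_plateau")
}

#' Evaluate a full SUIT protocol on one trace
#'
#' Extracts one steady-state flux per protocol step, in protocol order,
#' using the events recorded in the trace to delimit steps.
#'
#' @param trace A [respiro_trace()].
#' @param protocol Protocol tibble from [suit_protocol()]; defaults to the
#'   protocol implied by the trace events.
#' @param config A [flux_extraction_config()].
#' @param liver_id,timepoint Labels carried into the output table.
#' @return A step-flux table: tibble with `liver_id`, `timepoint`,
#'   `protocol_id`, `step`, `flux`, `t_start`, `t_end`, `cv`, `qc`.
#' @export
evaluate_protocol <- function(trace, protocol = NULL,
                              config = flux_extraction_config(),
                              liver_id = NA_character_,
                              timepoint = NA_character_) {
  stopifnot(inherits(trace, "respiro_trace"))
  ev <- trace$events
  if (anyDuplicated(ev$step)) {
    stop("duplicate event names in trace: ",
         paste(ev$step[duplicated(ev$step)], collapse = ", "))
  }
  steps <- if (is.null(protocol)) ev$step else protocol$step
  missing <- setdiff(steps, ev$step)
  if (length(missing) > 0) {
    stop("protocol step(s) missing from trace events: ",
         paste(missing, collapse = ", "))
  }
  proto_id <- if (is.null(protocol)) "from_events" else {
    attr(protocol, "protocol_id") %||% "custom"
  }
  fs <- compute_flux_series(trace, config)
  rows <- lapply(seq_along(steps), function(k) {
    e_t <- ev$time_s[ev$step == steps[k]]
    later <- ev$time_s[ev$time_s > e_t]
    lim <- if (length(later) > 0) min(later) else Inf
    if (e_t + config$skip_after_event >= max(trace$time)) {
      stop("trace ends before a plateau can form for step '", steps[k], "'")
    }
    p <- detect_plateau(fs, e_t, lim, config)
    p$step <- steps[k]
    p
  })
  out <- dplyr::bind_rows(rows)
  tibble::tibble(
    liver_id = liver_id, timepoint = timepoint, protocol_id = proto_id,
    step = out$step, flux = out$flux, t_start = out$t_start,
    t_end = out$t_end, cv = out$cv, qc = out$qc
  )
}

#' Merge duplicate-chamber step-flux tables
#'
#' Respirometry runs are performed in duplicate chambers; this averages the
#' two step-flux tables and flags steps whose duplicates disagree by more
#' than `cv_threshold` of their mean. QC flags are propagated as the worse
#' of the two (`ok` < `short_window` < `no_plateau`).
#'
#' @param a,b Step-flux tables from [evaluate_protocol()] for the same
#'   liver, timepoint and protocol.
#' @param cv_threshold Relative discordance threshold (default 0.15).
#' @return Merged step-flux table with an added logical `discordant`.
#' @export
merge_duplicates <- function(a, b, cv_threshold = 0.15) {
  same <- function(col) {
    ua <- unique(a[[col]])
    ub <- unique(b[[col]])
    identical(ua, ub) || (all(is.na(ua)) && all(is.na(ub)))
  }
  if (!same("liver_id") || !same("timepoint") || !same("protocol_id")) {
    stop("duplicate chambers must share liver, timepoint and protocol")
  }
  if (!identical(sort(a$step), sort(b$step))) {
    stop("mismatched step sets between duplicate chambers")
  }
  b <- b[match(a$step, b$step), ]
  qc_rank <- c(ok = 1, short_window = 2, no_plateau = 3)
  worst <- ifelse(qc_rank[a$qc] >= qc_rank[b$qc], a$qc, b$qc)
  m <- (a$flux + b$flux) / 2
  disc <- abs(a$flux - b$flux) / abs(m) > cv_threshold
  tibble::tibble(
    liver_id = a$liver_id, timepoint = a$timepoint,
    protocol_id = a$protocol_id, step = a$step, flux = m,
    t_start = pmin(a$t_start, b$t_start),
    t_end = pmax(a$t_end, b$t_end),
    cv = pmax(a$cv, b$cv), qc = unname(worst), discordant = disc
  )
}
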