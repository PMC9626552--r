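#' Parameters for simulating an oxygraph trace
#'
#' Describes one closed-chamber high-resolution respirometry run: the SUIT
#' protocol, the true mass-specific flux at each step, chamber geometry and
#' instrument characteristics. Defaults emulate the clinical setup: 2 mL
#' chambers, tissue homogenate at 1 mg wet mass per mL, a 2 s recording
#' interval, and air-calibrated starting oxygen around 185 uM at 37 degC.
#'
#' @param protocol Protocol tibble from [suit_protocol()].
#' @param true_fluxes Named numeric vector, one mass-specific flux
#'   (pmol O2 s-1 mg-1) per protocol step.
#' @param chamber_volume Chamber volume in mL (default 2).
#' @param mass_density Wet mass per chamber volume, mg mL-1 (default 1).
#' @param o2_start Initial O2 concentration, uM (default 185).
#' @param sample_interval Recording interval in seconds (default 2).
#' @param equilibration_tau Time constant (s) of the first-order flux
#'   transient after each titration (default 20). Zero gives instantaneous
#'   steps.
#' @param noise_sd Additive Gaussian noise on the recorded concentration,
#'   uM (default 0).
#' @param background_a,background_b Instrumental background flux, modelled
#'   as `a + b * C` pmol s-1 mL-1 with C in uM (defaults 0, 0).
#' @param chamber_id Label for the chamber (default `"A"`).
#' @param seed Integer RNG seed.
#'
#' @return A `trace_sim_params` list.
#' @export
trace_sim_params <- function(protocol = suit_protocol("SUIT02"),
                             true_fluxes,
                             chamber_volume = 2,
                             mass_density = 1,
                             o2_start = 185,
                             sample_interval = 2,
                             equilibration_tau = 20,
                             noise_sd = 0,
                             background_a = 0,
                             background_b = 0,
                             chamber_id = "A",
                             seed = 1L) {
  stopifnot(
    chamber_volume > 0, mass_density > 0, o2_start > 0,
    sample_interval > 0, equilibration_tau >= 0, noise_sd >= 0
  )
  missing_steps <- setdiff(protocol$step, names(true_fluxes))
  if (length(missing_steps) > 0) {
    stop("no true flux given for protocol step(s): ",
         paste(missing_steps, collapse = ", "))
  }
  structure(
    list(
      protocol = protocol,
      protocol_id = attr(protocol, "protocol_id") %||% "custom",
      true_fluxes = true_fluxes[protocol$step],
      chamber_volume = chamber_volume,
      mass_density = mass_density,
      o2_start = o2_start,
      sample_interval = sample_interval,
      equilibration_tau = equilibration_tau,
      noise_sd = noise_sd,
      background_a = background_a,
      background_b = background_b,
      chamber_id = chamber_id,
      seed = as.integer(seed)
    ),
    class = "trace_sim_params"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a respirometry oxygen trace
#'
#' Integrates chamber oxygen concentration under the plateau-then-titrate
#' structure of a SUIT run. Within each step the volume-specific oxygen
#' consumption is `J_step * mass_density + background(C)` pmol s-1 mL-1
#' (i.e. the concentration declines at that rate divided by 1000, in
#' uM s-1); after each titration the effective flux relaxes exponentially
#' from its pre-event value to the new step flux with time constant
#' `equilibration_tau`, so the concentration is continuous and kink-free at
#' events. Gaussian recording noise is added afterwards.
#'
#' @param params A [trace_sim_params()] object.
#' @return A [respiro_trace()] object; the noiseless concentration is kept
#'   in the `o2_true` column for diagnostics.
#' @export
#' @examples
#' p <- trace_sim_params(
#'   true_fluxes = c(LEAK = 8.21, OXPHOS = 40.49, OXPHOS_cytc = 43.48,
#'                   CCCP1 = 65, CCCP2 = 70.33, CCCP3 = 68),
#'   noise_sd = 1, seed = 7
#' )
#' tr <- simulate_trace(p)
simulate_trace <- function(params) {
  stopifnot(inherits(params, "trace_sim_params"))
  proto <- params$protocol
  n_steps <- nrow(proto)
  starts <- cumsum(c(0, proto$duration_s[-n_steps]))
  total_t <- sum(proto$duration_s)
  time <- seq(0, total_t, by = params$sample_interval)

  rho <- params$mass_density
  a <- params$background_a
  b <- params$background_b
  tau <- params$equilibration_tau
  J <- unname(params$true_fluxes)

  # effective flux at each instant: step flux plus decaying carry-over of
  # the flux level at the moment of the previous titration
  j_start <- numeric(n_steps)  # flux level carried into each step
  j_start[1] <- J[1]           # chamber already respiring at step-1 flux
  if (n_steps > 1 && tau > 0) {
    for (i in 2:n_steps) {
      dt_prev <- proto$duration_s[i - 1]
      j_start[i] <- J[i - 1] +
        (j_start[i - 1] - J[i - 1]) * exp(-dt_prev / tau)
    }
  } else if (n_steps > 1) {
    j_start[2:n_steps] <- J[1:(n_steps - 1)]
  }

  step_of <- findInterval(time, starts)
  dt_in <- time - starts[step_of]

  # closed-form time integral of the effective flux from step start,
  # used for exact integration when the background has no C-dependence
  j_eff <- J[step_of] + if (tau > 0) {
    (j_start[step_of] - J[step_of]) * exp(-dt_in / tau)
  } else {
    0
  }

  o2 <- numeric(length(time))
  o2[1] <- params$o2_start
  if (b == 0) {
    # exact: C(t) = C(start) - [J-integral * rho + a * dt] / 1000 per step
    j_int <- J[step_of] * dt_in + if (tau > 0) {
      (j_start[step_of] - J[step_of]) * tau * (1 - exp(-dt_in / tau))
    } else {
      0
    }
    c_at_start <- numeric(n_steps)
    c_at_start[1] <- params$o2_start
    if (n_steps > 1) {
      for (i in 2:n_steps) {
        dtp <- proto$duration_s[i - 1]
        jint_full <- J[i - 1] * dtp + if (tau > 0) {
          (j_start[i - 1] - J[i - 1]) * tau * (1 - exp(-dtp / tau))
        } else {
          0
        }
        c_at_start[i] <- c_at_start[i - 1] - (jint_full * rho + a * dtp) / 1000
      }
    }
    o2 <- c_at_start[step_of] - (j_int * rho + a * dt_in) / 1000
  } else {
    # linear ODE dC/dt = -(j_eff*rho + a + b*C)/1000, exponential step with
    # the effective flux frozen at the sample midpoint
    dt <- diff(time)
    k_decay <- exp(-b * dt / 1000)
    t_mid <- time[-length(time)] + dt / 2
    sm <- findInterval(t_mid, starts)
    j_mid <- J[sm] + if (tau > 0) {
      (j_start[sm] - J[sm]) * exp(-(t_mid - starts[sm]) / tau)
    } else {
      0
    }
    k_mid <- j_mid * rho + a
    for (i in seq_along(dt)) {
      c_inf <- -k_mid[i] / b
      o2[i + 1] <- c_inf + (o2[i] - c_inf) * k_decay[i]
    }
  }

  if (any(o2 <= 0)) {
    bad <- step_of[which(o2 <= 0)[1]]
    stop("chamber oxygen exhausted during step '", proto$step[bad],
         "'; lower fluxes or raise o2_start")
  }

  o2_obs <- if (params$noise_sd > 0) {
    with_seed(params$seed, o2 + stats::rnorm(length(o2), 0, params$noise_sd))
  } else {
    o2
  }

  respiro_trace(
    time = time,
    o2 = o2_obs,
    events = tibble::tibble(
      time_s = starts,
      step = proto$step,
      titrant = proto$titrant,
      concentration = proto$concentration
    ),
    chamber_volume = params$chamber_volume,
    mass_density = rho,
    chamber_id = params$chamber_id,
    o2_true = o2
  )
}
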