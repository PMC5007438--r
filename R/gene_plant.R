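## Continuous-time simulation of the CcaS/CcaR expression system.
##
## Fold-change coordinates (R, P, G), rest state (1,1,1):
##   dR/dt = d_r + b_r u - d_r R
##   dP/dt = (d_p + k_m) (R - P)
##   dG/dt = d_p (P - G)
## Raw coordinates (r, p, g):
##   dr/dt = b_r0 + b_r_gain u - d_r r
##   dp/dt = b_p r - (d_p + k_m) p
##   dg/dt = k_m p - d_p g
## Dividing raw trajectories by the un-induced steady state gives exactly
## the fold-change system with b_r = b_r_gain d_r / b_r0.

# normalize a piecewise-constant input specification to (times, values)
input_profile <- function(input, horizon) {
  if (is.function(input)) {
    tt <- seq(0, horizon, by = 1)
    vv <- vapply(tt, input, numeric(1))
    return(list(time = tt, value = vv))
  }
  if (is.data.frame(input)) {
    nm <- names(input)
    vcol <- setdiff(nm, "time")[1]
    o <- order(input$time)
    return(list(time = input$time[o], value = input[[vcol]][o]))
  }
  if (is.numeric(input) && length(input) == 1L) {
    return(list(time = 0, value = input))
  }
  stop("input must be a constant, a data.frame(time, u), or a function",
       call. = FALSE)
}

# integrate dx/dt = A x + b segment-wise over piecewise-constant input
integrate_segments <- function(deriv, x0, prof, horizon, dt_out, rtol = 1e-8) {
  breaks <- unique(c(0, prof$time[prof$time > 0 & prof$time < horizon],
                     horizon))
  breaks <- sort(breaks)
  out_t <- seq(0, horizon, by = dt_out)
  rows <- matrix(NA_real_, length(out_t), length(x0))
  uvals <- numeric(length(out_t))
  rows[1, ] <- x0
  uvals[1] <- prof$value[findInterval(0, prof$time)]
  x <- x0
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    u <- prof$value[findInterval(t0, prof$time)]
    tt <- out_t[out_t > t0 & out_t <= t1]
    times <- unique(c(t0, tt, t1))
    sol <- deSolve::lsoda(y = x, times = times, func = deriv, parms = u,
                          rtol = rtol, atol = 1e-10)
    x <- as.numeric(sol[nrow(sol), -1])
    if (length(tt)) {
      idx <- match(tt, out_t)
      rows[idx, ] <- sol[match(tt, sol[, 1]), -1, drop = FALSE]
      uvals[idx] <- u
    }
  }
  list(time = out_t, states = rows, u = uvals)
}

#' Simulate the fold-change expression model
#'
#' Integrates the three-state linear fold-change model under a
#' piecewise-constant input `u(t)` with a stiff-capable adaptive solver
#' (relative tolerance `1e-8`).  Inputs are zero-order-held between their
#' breakpoints, matching digital control operation.
#'
#' @param params a [model_params()] object.
#' @param input constant, `data.frame(time, u)` of breakpoints, or
#'   function of time; `u(t) >= 0`.
#' @param horizon simulation length (min), `> 0`.
#' @param initial initial `(R, P, G)` state (default the rest state).
#' @param dt_out output grid spacing (min).
#' @return `data.frame(time, R, P, G, u)`.
#' @examples
#' tr <- simulate_fold_change(nominal_model_params(), input = 1,
#'                            horizon = 3000)
#' tail(tr$G, 1)  # ~2: u = 1 doubles steady-state expression
#' @export
simulate_fold_change <- function(params, input, horizon,
                                 initial = c(R = 1, P = 1, G = 1),
                                 dt_out = 1) {
  stopifnot(inherits(params, "model_params"))
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0",
                                                call. = FALSE)
  if (any(!is.finite(initial)) || any(initial < 0)) {
    stop("initial state must be finite and non-negative", call. = FALSE)
  }
  prof <- input_profile(input, horizon)
  if (any(!is.finite(prof$value)) || any(prof$value < 0)) {
    stop("input u(t) must be finite and >= 0", call. = FALSE)
  }
  p <- params
  deriv <- function(t, x, u) {
    list(c(p$d_r + p$b_r * u - p$d_r * x[1],
           (p$d_p + p$k_m) * (x[1] - x[2]),
           p$d_p * (x[2] - x[3])))
  }
  res <- integrate_segments(deriv, as.numeric(initial), prof, horizon, dt_out)
  data.frame(time = res$time, R = res$states[, 1], P = res$states[, 2],
             G = res$states[, 3], u = res$u)
}

#' Simulate the raw (concentration) expression model
#'
#' Integrates the raw three-state model under a piecewise-constant green
#' intensity profile `U(t)` mapped through the dose-response curve.
#'
#' @param raw a [raw_model_params()] object.
#' @param light constant, `data.frame(time, U)`, or function of time;
#'   intensities in `[0, 100]` %.
#' @param dr a [dose_response()] map.
#' @param horizon simulation length (min).
#' @param initial initial `(r, p, g)`; default the un-induced steady state.
#' @param dt_out output grid spacing (min).
#' @return `data.frame(time, r, p, g, u, U_green_pct)`.
#' @export
simulate_raw <- function(raw, light, dr = dose_response(), horizon,
                         initial = raw_steady_state(raw), dt_out = 1) {
  stopifnot(inherits(raw, "raw_model_params"))
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0",
                                                call. = FALSE)
  prof <- input_profile(light, horizon)
  if (any(!is.finite(prof$value))) stop("light profile must be finite",
                                        call. = FALSE)
  uprof <- list(time = prof$time, value = dose_response_eval(dr, prof$value))
  rp <- raw
  deriv <- function(t, x, u) {
    list(c(rp$b_r0 + rp$b_r_gain * u - rp$d_r * x[1],
           rp$b_p * x[1] - (rp$d_p + rp$k_m) * x[2],
           rp$k_m * x[2] - rp$d_p * x[3]))
  }
  res <- integrate_segments(deriv, as.numeric(initial), uprof, horizon, dt_out)
  Uv <- prof$value[findInterval(res$time, prof$time)]
  data.frame(time = res$time, r = res$states[, 1], p = res$states[, 2],
             g = res$states[, 3], u = res$u, U_green_pct = Uv)
}

#' Define a culture disturbance event
#'
#' Global perturbations applied to a simulated culture at a stated onset
#' time: a growth-medium shift (new dilution rate from a new culture
#' doubling time), a temperature shift (global slow-down of kinetic rates
#' ramped over an interval, with a drop in production rates), a persistent
#' input offset (every subsequent commanded intensity `U` is reduced), or
#' an additive offset on the measured output.
#'
#' @param kind one of `"medium_shift"`, `"temperature_shift"`,
#'   `"input_offset"`, `"additive_output"`.
#' @param onset event time (min), `>= 0`.
#' @param new_doubling_time medium shift: post-shift culture doubling time
#'   (min); e.g. 25 for a switch from M9 (~38 min) to LB.
#' @param scale temperature shift: factor `< 1` multiplying the kinetic
#'   rates `d_r, d_p, k_m` and the input gain once the ramp completes.
#' @param production_scale temperature shift: additional factor on the
#'   production constants `b_r0, b_r_gain` (steady levels drop by this).
#' @param ramp temperature shift: linear ramp duration (min).
#' @param fraction input offset: fraction of the input applied at onset
#'   that is subtracted from all subsequent commands (`U -> max(0, U - c)`).
#' @param offset additive output offset, in measurement units.
#' @return An object of class `disturbance_event`.
#' @export
disturbance_event <- function(kind = c("medium_shift", "temperature_shift",
                                       "input_offset", "additive_output"),
                              onset,
                              new_doubling_time = 25,
                              scale = 0.5, production_scale = 0.8, ramp = 30,
                              fraction = 0.5, offset = 0) {
  kind <- match.arg(kind)
  if (!is.finite(onset) || onset < 0) stop("onset must be >= 0", call. = FALSE)
  ev <- list(kind = kind, onset = onset)
  ev <- switch(kind,
    medium_shift = c(ev, list(new_doubling_time = new_doubling_time)),
    temperature_shift = c(ev, list(scale = scale,
                                   production_scale = production_scale,
                                   ramp = ramp)),
    input_offset = c(ev, list(fraction = fraction)),
    additive_output = c(ev, list(offset = offset)))
  structure(ev, class = "disturbance_event")
}

#' A simulated culture: raw plant, dose-response and disturbances
#'
#' Bundles the true (hidden) plant of a closed-loop run: raw-model rates,
#' the dose-response input map, the input delay, and an ordered list of
#' disturbance events.
#'
#' @param raw a [raw_model_params()] object.
#' @param dr a [dose_response()] map.
#' @param disturbances list of [disturbance_event()]s.
#' @param input_delay_steps sampling periods of input delay (default 1).
#' @param T_s sampling period (min).
#' @return An object of class `gene_plant`.
#' @export
gene_plant <- function(raw = as_raw_params(), dr = dose_response(),
                       disturbances = list(), input_delay_steps = 1L,
                       T_s = 10) {
  stopifnot(inherits(raw, "raw_model_params"))
  for (ev in disturbances) {
    if (!inherits(ev, "disturbance_event")) {
      stop("disturbances must be disturbance_event objects", call. = FALSE)
    }
  }
  ons <- vapply(disturbances, `[[`, numeric(1), "onset")
  structure(list(raw = raw, dr = dr,
                 disturbances = disturbances[order(ons)],
                 input_delay_steps = as.integer(input_delay_steps),
                 T_s = T_s),
            class = "gene_plant")
}

#' Attach a disturbance event to a plant
#'
#' @param plant a [gene_plant()] object.
#' @param event a [disturbance_event()].
#' @return The plant with the event inserted in time order.
#' @export
apply_disturbance <- function(plant, event) {
  stopifnot(inherits(plant, "gene_plant"))
  if (!inherits(event, "disturbance_event")) {
    stop("unknown disturbance specification", call. = FALSE)
  }
  gene_plant(plant$raw, plant$dr,
             c(plant$disturbances, list(event)),
             plant$input_delay_steps, plant$T_s)
}

# effective raw rates at time t, after medium/temperature events
plant_rates_at <- function(plant, t) {
  r <- plant$raw
  for (ev in plant$disturbances) {
    if (t < ev$onset) next
    if (ev$kind == "medium_shift") {
      r$d_p <- log(2) / ev$new_doubling_time
    } else if (ev$kind == "temperature_shift") {
      frac <- if (ev$ramp > 0) min(1, (t - ev$onset) / ev$ramp) else 1
      s <- 1 + frac * (ev$scale - 1)
      ps <- 1 + frac * (ev$production_scale - 1)
      # uniform slow-down of every rate (steady states preserved), plus a
      # transcription penalty that lowers raw expression levels by ps
      r$d_r <- r$d_r * s; r$d_p <- r$d_p * s; r$k_m <- r$k_m * s
      r$b_p <- r$b_p * s
      r$b_r_gain <- r$b_r_gain * s * ps
      r$b_r0 <- r$b_r0 * s * ps
    }
  }
  r
}

# commanded intensity -> effective intensity after input_offset events;
# offsets are resolved against `U_at_onset` recorded by the harness
effective_intensity <- function(plant, t, U, U_at_onset = NULL) {
  for (i in seq_along(plant$disturbances)) {
    ev <- plant$disturbances[[i]]
    if (ev$kind == "input_offset" && t >= ev$onset) {
      base <- if (!is.null(U_at_onset)) U_at_onset[[as.character(i)]] else U
      U <- max(0, U - ev$fraction * base)
    }
  }
  U
}

# propagate the raw plant state over [t0, t1] under constant commanded u
plant_step <- function(plant, t0, t1, state, u) {
  deriv <- function(t, x, u) {
    rr <- plant_rates_at(plant, t)
    list(c(rr$b_r0 + rr$b_r_gain * u - rr$d_r * x[1],
           rr$b_p * x[1] - (rr$d_p + rr$k_m) * x[2],
           rr$k_m * x[2] - rr$d_p * x[3]))
  }
  sol <- deSolve::lsoda(y = state, times = c(t0, t1), func = deriv,
                        parms = u, rtol = 1e-8, atol = 1e-10)
  as.numeric(sol[nrow(sol), -1])
}

#' @export
print.gene_plant <- function(x, ...) {
  cat("Simulated culture (raw-coordinate plant)\n")
  cat(sprintf("  d_r=%.4g d_p=%.4g k_m=%.4g b_r0=%.3g b_r_gain=%.3g b_p=%.3g\n",
              x$raw$d_r, x$raw$d_p, x$raw$k_m, x$raw$b_r0,
              x$raw$b_r_gain, x$raw$b_p))
  cat(sprintf("  input delay %d step(s) of %g min, %d disturbance(s)\n",
              x$input_delay_steps, x$T_s, length(x$disturbances)))
  invisible(x)
}
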