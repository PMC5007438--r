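## Turbidostat inner loop, growth-rate estimation from the influx-pump
## signal, and the light-responsive growth plant (MetE under optogenetic
## control in methionine-dropout medium).

#' Turbidostat state and inner turbidity PI loop
#'
#' Biomass in a constant-volume vessel follows `dx/dt = mu x - (u/V) x`
#' where `u` is the fresh-medium inflow rate (outflow matches, so volume
#' is constant).  A fast PI loop on the optical-density error drives the
#' pumps; at regulation equilibrium the dilution rate equals the growth
#' rate, `u/V = mu`, which is what makes the pump signal a growth-rate
#' sensor.  Default gains settle the loop in about a minute.
#'
#' @param od_setpoint optical-density setpoint (default 0.1).
#' @param V culture volume (ml; default 17.5).
#' @param K_P,K_I inner PI gains (ml/min per OD unit, and per min).
#' @param x0 initial OD (defaults to the setpoint).
#' @return An object of class `turbidostat_state`.
#' @export
turbidostat <- function(od_setpoint = 0.1, V = 17.5,
                        K_P = 350, K_I = 175, x0 = od_setpoint) {
  stopifnot(od_setpoint > 0, V > 0, x0 > 0)
  structure(list(x = x0, V = V, setpoint = od_setpoint,
                 K_P = K_P, K_I = K_I, u_I = 0, u_flow = 0),
            class = "turbidostat_state")
}

#' Advance the turbidostat by one small time step
#'
#' @param state a [turbidostat()] state.
#' @param mu true instantaneous growth rate (1/min).
#' @param dt step (min); must be well below the inner-loop time constant
#'   (~1 min), e.g. 1 second.
#' @return The updated state (fields `x`, `u_flow` of interest).
#' @export
turbidostat_step <- function(state, mu, dt) {
  e <- state$x - state$setpoint  # positive error -> dilute harder
  u_I <- clip(state$u_I + state$K_I * e * dt, 0, 10)
  u <- max(0, state$K_P * e + u_I)
  state$x <- state$x + dt * (mu - u / state$V) * state$x
  state$u_I <- u_I
  state$u_flow <- u
  state
}

#' Raw influx-pump signal with its causal filter
#'
#' @param u_flow raw pump-rate samples (ml/min), typically at ~1 Hz.
#' @param dt sample spacing (min; default 1/60, i.e. 1 s).
#' @param tau exponential-moving-average time constant (min).
#' @return An object of class `growth_signal`.
#' @export
growth_signal <- function(u_flow, dt = 1 / 60, tau = 5) {
  stopifnot(length(u_flow) >= 1, dt > 0, tau > 0)
  structure(list(u_flow = u_flow, dt = dt, tau = tau),
            class = "growth_signal")
}

#' Estimate the growth rate from the pump signal
#'
#' When the turbidostat holds biomass constant the growth rate equals the
#' dilution rate `u / V`.  The raw pump samples are smoothed with a
#' causal exponential moving average (initialized at the first sample, so
#' a constant input is reproduced exactly) and divided by the culture
#' volume.  Negative raw samples are clipped to zero with a warning.
#'
#' @param signal a [growth_signal()].
#' @param V culture volume (ml).
#' @return Vector of filtered growth-rate estimates (1/min), one per raw
#'   sample.
#' @export
estimate_growth_rate <- function(signal, V) {
  stopifnot(inherits(signal, "growth_signal"), V > 0)
  u <- signal$u_flow
  if (any(u < 0)) {
    warning("negative pump samples clipped to 0")
    u <- pmax(u, 0)
  }
  alpha <- 1 - exp(-signal$dt / signal$tau)
  f <- numeric(length(u))
  f[1] <- u[1]
  if (length(u) > 1) {
    for (i in 2:length(u)) f[i] <- f[i - 1] + alpha * (u[i] - f[i - 1])
  }
  f / V
}

#' Doubling time of exponential growth
#'
#' @param mu growth rate (1/min), `> 0`.
#' @return `T_d = ln(2) / mu` (min); `NA` with a warning if `mu <= 0`.
#' @examples
#' doubling_time(0.0139)  # ~50 min, full green light
#' doubling_time(0.0035)  # ~200 min, full red light
#' @export
doubling_time <- function(mu) {
  out <- ifelse(mu > 0, log(2) / mu, NA_real_)
  if (any(mu <= 0)) warning("doubling time undefined for mu <= 0")
  out
}

#' Light-responsive growth plant
#'
#' Growth rate relaxes first-order (time constant `tau`) towards a
#' Hill-shaped steady-state map of the green-light fraction, spanning
#' ~0.0035 1/min under full red (doubling time ~200 min) to ~0.0139
#' 1/min under full green (~50 min).  An optional drift term slowly
#' raises the minimum achievable rate after prolonged growth under
#' predominantly red light, emulating the gradual loss of light
#' sensitivity through selection.
#'
#' @param mu_min,mu_max growth-rate range (1/min).
#' @param K half-saturation green intensity (%).
#' @param h Hill steepness.
#' @param tau response time constant (min).
#' @param drift enable the sensitivity-loss drift.
#' @param drift_rate increase of `mu_min` per minute of post-onset
#'   red-dominated growth (1/min^2).
#' @param drift_onset red-dominated exposure (min) before drift starts.
#' @param mu0 initial growth rate (defaults to the map at `u_green = 0`).
#' @return An object of class `growth_plant_state`.
#' @export
growth_plant <- function(mu_min = 0.0035, mu_max = 0.0139, K = 50, h = 2,
                         tau = 45, drift = FALSE, drift_rate = 5e-6,
                         drift_onset = 720, mu0 = NULL) {
  stopifnot(mu_min < mu_max, tau > 0, K > 0, h > 0)
  if (is.null(mu0)) mu0 <- mu_min
  stopifnot(mu0 >= 0, mu0 <= mu_max * 1.2)
  structure(list(mu = mu0, mu_min = mu_min, mu_max = mu_max, K = K, h = h,
                 tau = tau, drift = drift, drift_rate = drift_rate,
                 drift_onset = drift_onset, red_time = 0),
            class = "growth_plant_state")
}

#' Steady-state growth rate at a given green intensity
#'
#' @param state a [growth_plant()] state.
#' @param u_green green intensity (% of maximum), in `[0, 100]`.
#' @return Steady-state growth rate (1/min).
#' @export
growth_steady_state <- function(state, u_green) {
  mu_min <- state$mu_min
  if (state$drift && state$red_time > state$drift_onset) {
    mu_min <- min(mu_min + state$drift_rate *
                    (state$red_time - state$drift_onset),
                  0.9 * state$mu_max)
  }
  # Hill response normalized so full green reaches mu_max exactly
  hill <- function(u) u^state$h / (state$K^state$h + u^state$h)
  mu_min + (state$mu_max - mu_min) * hill(u_green) / hill(100)
}

#' Advance the growth plant by one time step
#'
#' Exact exponential relaxation towards the steady-state map, so
#' repeated small steps coincide with the continuous first-order
#' solution for piecewise-constant light.
#'
#' @param state a [growth_plant()] state.
#' @param u_green green intensity (%), in `[0, 100]`.
#' @param dt step (min).
#' @return The updated state (`mu` holds the current growth rate).
#' @export
growth_plant_step <- function(state, u_green, dt) {
  stopifnot(u_green >= 0, u_green <= 100)
  if (state$drift && u_green < 50) state$red_time <- state$red_time + dt
  mu_ss <- growth_steady_state(state, u_green)
  state$mu <- mu_ss + (state$mu - mu_ss) * exp(-dt / state$tau)
  state$mu <- clip(state$mu, 0, state$mu_max * 1.2)
  state
}
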