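#' Continuous-time fold-change model parameters
#'
#' Container for the four first-order rate constants of the CcaS/CcaR
#' sfGFP expression model in fold-change coordinates, plus the sampling
#' metadata used by the discrete-time controllers.  The model states are
#' mRNA (`R`), immature sfGFP (`P`) and fluorescent sfGFP (`G`), each
#' expressed relative to its un-induced steady state, so the rest state is
#' exactly `(1, 1, 1)`.
#'
#' @param d_r mRNA degradation rate (1/min).
#' @param d_p dilution rate of protein by growth (1/min).
#' @param b_r light-driven mRNA production gain in fold-change units
#'   (1/min per unit of fold-change input `u`).
#' @param k_m fluorophore maturation rate (1/min).
#' @param T_s sampling period of the digital control loop (min).
#' @param input_delay_steps integer number of sampling periods by which an
#'   applied light input is delayed before it affects transcription
#'   (unmodelled sensor-kinase dynamics); the characterized system uses 1.
#'
#' @return An object of class `model_params`.
#' @seealso [nominal_model_params()] for the maximum-likelihood values
#'   fitted to the characterization data set.
#' @export
model_params <- function(d_r, d_p, b_r, k_m, T_s = 10, input_delay_steps = 1L) {
  rates <- c(d_r = d_r, d_p = d_p, b_r = b_r, k_m = k_m)
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all rates must be finite and strictly positive", call. = FALSE)
  }
  if (!is.finite(T_s) || T_s <= 0) stop("T_s must be > 0", call. = FALSE)
  input_delay_steps <- as.integer(input_delay_steps)
  if (input_delay_steps < 0L) stop("input_delay_steps must be >= 0", call. = FALSE)
  td <- log(2) / d_p
  if (td < 10 || td > 300) {
    warning("d_p corresponds to a doubling time of ", signif(td, 3),
            " min, outside the plausible 10-300 min range")
  }
  g <- b_r / d_r
  if (g < 0.8 || g > 1.25) {
    warning("b_r/d_r = ", signif(g, 4),
            " is far from unity; fold-change input gain will not be ~1")
  }
  structure(list(d_r = d_r, d_p = d_p, b_r = b_r, k_m = k_m,
                 T_s = T_s, input_delay_steps = input_delay_steps),
            class = "model_params")
}

#' Nominal fitted model parameters
#'
#' Rate constants obtained by maximum-likelihood calibration of the
#' fold-change model against a characterization data set (a step response
#' plus several PI closed-loop responses): `d_r = 0.0956`, `d_p = 0.0214`,
#' `b_r = 0.0965`, `k_m = 0.0116` (all 1/min), with 10-min sampling and a
#' one-sample input delay.
#'
#' @return A `model_params` object.
#' @export
nominal_model_params <- function() {
  model_params(d_r = 0.0956, d_p = 0.0214, b_r = 0.0965, k_m = 0.0116,
               T_s = 10, input_delay_steps = 1L)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Fold-change expression model (rates in 1/min)\n")
  cat(sprintf("  d_r = %.4g  d_p = %.4g  b_r = %.4g  k_m = %.4g\n",
              x$d_r, x$d_p, x$b_r, x$k_m))
  cat(sprintf("  T_s = %g min, input delay = %d step(s)\n",
              x$T_s, x$input_delay_steps))
  cat(sprintf("  steady-state gain b_r/d_r = %.4f, doubling time %.1f min\n",
              x$b_r / x$d_r, log(2) / x$d_p))
  invisible(x)
}

#' Raw (concentration-coordinate) model parameters
#'
#' Parameters of the three-state linear model in absolute concentration
#' units: mRNA `r` is produced at basal rate `b_r0` plus `b_r_gain * u`
#' where `u = f(U)` is the dose-response-mapped green-light input, and
#' degraded at `d_r`; immature protein `p` is translated at `b_p * r`,
#' diluted at `d_p` and matures at `k_m`; fluorescent protein `g` is
#' produced at `k_m * p` and diluted at `d_p`.
#'
#' Dividing each species by its un-induced steady state recovers the
#' fold-change model, in which `b_p` and `b_r0` cancel and the effective
#' input gain is `b_r = b_r_gain * d_r / b_r0`.
#'
#' @param b_r0 basal mRNA production rate (conc/min).
#' @param b_r_gain light-driven mRNA production per unit fold-change input
#'   (conc/min).
#' @param d_r mRNA degradation rate (1/min).
#' @param b_p translation rate (1/min).
#' @param d_p dilution rate (1/min).
#' @param k_m maturation rate (1/min).
#'
#' @return An object of class `raw_model_params`.
#' @export
raw_model_params <- function(b_r0, b_r_gain, d_r, b_p, d_p, k_m) {
  v <- c(b_r0 = b_r0, b_r_gain = b_r_gain, d_r = d_r,
         b_p = b_p, d_p = d_p, k_m = k_m)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all raw-model rates must be finite and strictly positive",
         call. = FALSE)
  }
  td <- log(2) / d_p
  if (td < 10 || td > 300) {
    warning("d_p corresponds to a doubling time of ", signif(td, 3),
            " min, outside the plausible 10-300 min range")
  }
  structure(as.list(v), class = "raw_model_params")
}

#' Construct raw-model parameters consistent with a fold-change model
#'
#' Chooses absolute production constants (`b_r0`, `b_p`, arbitrary
#' concentration scale) such that normalizing the raw trajectories by
#' their un-induced steady states reproduces the given fold-change model
#' exactly.
#'
#' @param params a [model_params()] object.
#' @param b_r0 basal mRNA production rate (conc/min); sets the scale.
#' @param b_p translation rate (1/min).
#' @return A `raw_model_params` object.
#' @export
as_raw_params <- function(params = nominal_model_params(), b_r0 = 2, b_p = 1) {
  raw_model_params(b_r0 = b_r0,
                   b_r_gain = b_r0 * params$b_r / params$d_r,
                   d_r = params$d_r, b_p = b_p,
                   d_p = params$d_p, k_m = params$k_m)
}

#' Fold-change model implied by raw-model parameters
#'
#' @param raw a [raw_model_params()] object.
#' @inheritParams model_params
#' @return A `model_params` object.
#' @export
as_fold_params <- function(raw, T_s = 10, input_delay_steps = 1L) {
  model_params(d_r = raw$d_r, d_p = raw$d_p,
               b_r = raw$b_r_gain * raw$d_r / raw$b_r0, k_m = raw$k_m,
               T_s = T_s, input_delay_steps = input_delay_steps)
}

#' Un-induced steady state of the raw model
#'
#' At `u = 0` the raw model settles at `r0 = b_r0/d_r`,
#' `p0 = b_p r0 / (d_p + k_m)`, `g0 = k_m p0 / d_p`.  These are the
#' normalization constants of the fold-change coordinates.
#'
#' @param raw a [raw_model_params()] object.
#' @param u constant fold-change input (default 0, the un-induced state).
#' @return Named numeric vector `c(r, p, g)`.
#' @export
raw_steady_state <- function(raw, u = 0) {
  r <- (raw$b_r0 + raw$b_r_gain * u) / raw$d_r
  p <- raw$b_p * r / (raw$d_p + raw$k_m)
  g <- raw$k_m * p / raw$d_p
  c(r = r, p = p, g = g)
}

#' Fold-change steady state under constant input
#'
#' For constant fold-change input `u` the model settles at
#' `R = P = G = 1 + (b_r/d_r) u`; with the nominal fit `b_r/d_r = 1.0094`
#' so `u = 1` yields a steady-state fold change of ~2.
#'
#' @param params a [model_params()] object.
#' @param u constant fold-change input.
#' @return Named numeric vector `c(R, P, G)`.
#' @export
fold_change_steady_state <- function(params, u) {
  s <- 1 + (params$b_r / params$d_r) * u
  c(R = s, P = s, G = s)
}

#' Apply day-to-day variability to raw plant parameters
#'
#' Multiplies each rate constant independently by a log-normal factor
#' (median 1), emulating the day-to-day changes in the dynamic behaviour
#' of cultures started on different days.  Uses the current RNG stream.
#'
#' @param raw a [raw_model_params()] object.
#' @param sigma standard deviation of log-rates (default 0.15, i.e. ~15%
#'   day-to-day variation of each rate).
#' @return A perturbed `raw_model_params` object.
#' @export
perturb_day <- function(raw, sigma = 0.15) {
  f <- exp(stats::rnorm(6, 0, sigma))
  raw_model_params(b_r0 = raw$b_r0 * f[1], b_r_gain = raw$b_r_gain * f[2],
                   d_r = raw$d_r * f[3], b_p = raw$b_p * f[4],
                   d_p = raw$d_p * f[5], k_m = raw$k_m * f[6])
}
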