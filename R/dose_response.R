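#' Dose-response map from green-light intensity to fold-change input
#'
#' Static map `u = f(U)` converting an applied green LED intensity `U`
#' (percent of maximum) into the additional steady-state fold change `u`
#' that intensity can achieve.  A Hill curve with zero basal offset is
#' used, `f(U) = u_sat * U^n / (K^n + U^n)`, estimated in practice from
#' steady-state fluorescence measurements at a handful of intensities.
#' The defaults are chosen so that `f(0) = 0`, `f` saturates near 60%
#' intensity (`f(60) >= 0.95 f(100)`, the system's dose-response is almost
#' flat above that level) and `f(100) = 2` additional fold changes.
#'
#' @param u_sat asymptotic maximum additional fold change.
#' @param K half-saturation intensity (% of maximum green).
#' @param n Hill steepness.
#' @param basal basal offset; forced to 0 so that `f(0) = 0`.
#' @return An object of class `dose_response`.
#' @export
dose_response <- function(u_sat = 2.016, K = 20, n = 3, basal = 0) {
  if (!is.finite(u_sat) || u_sat <= 0) stop("u_sat must be > 0", call. = FALSE)
  if (!is.finite(K) || K <= 0) stop("K must be > 0", call. = FALSE)
  if (!is.finite(n) || n <= 0) stop("n must be > 0", call. = FALSE)
  if (basal != 0) stop("basal offset is fixed at 0 so that f(0) = 0",
                       call. = FALSE)
  dr <- structure(list(form = "hill", u_sat = u_sat, K = K, n = n, basal = 0),
                  class = "dose_response")
  if (dose_response_eval(dr, 100) - dose_response_eval(dr, 60) >
      0.05 * dose_response_eval(dr, 100)) {
    warning("dose-response is not nearly flat above 60% intensity")
  }
  dr
}

#' Evaluate the dose-response map
#'
#' @param dr a [dose_response()] object.
#' @param U green intensity, % of maximum, in `[0, 100]`.
#' @return Fold-change input `u = f(U)`.
#' @export
dose_response_eval <- function(dr, U) {
  if (any(!is.finite(U)) || any(U < 0) || any(U > 100)) {
    stop("U must lie in [0, 100]", call. = FALSE)
  }
  dr$u_sat * U^dr$n / (dr$K^dr$n + U^dr$n)
}

#' Invert the dose-response map
#'
#' Returns the intensity achieving a requested fold-change input.  Values
#' of `u` above `f(100)` are unreachable: the inversion saturates at 100%
#' and flags it via the `"saturated"` attribute.
#'
#' @param dr a [dose_response()] object.
#' @param u requested fold-change input, `u >= 0`.
#' @return Intensity `U` in `[0, 100]` with logical attribute `saturated`.
#' @export
dose_response_invert <- function(dr, u) {
  if (any(!is.finite(u)) || any(u < 0)) stop("u must be >= 0", call. = FALSE)
  umax <- dose_response_eval(dr, 100)
  sat <- u > umax
  u_c <- pmin(u, umax * (1 - 1e-15))
  # solve u = u_sat U^n/(K^n + U^n)  =>  U = K (u/(u_sat-u))^(1/n)
  U <- dr$K * (u_c / (dr$u_sat - u_c))^(1 / dr$n)
  U <- pmin(pmax(U, 0), 100)
  U[sat] <- 100
  structure(U, saturated = any(sat))
}

#' Fit a dose-response curve to steady-state measurements
#'
#' Estimates the Hill parameters from pairs of applied intensity and
#' measured steady-state fold change `G_ss` (the additional fold change is
#' `G_ss - 1`, up to the near-unity model gain).  Nonlinear least squares
#' with a coarse grid multistart on `(K, n)`.
#'
#' @param U intensities (% of maximum).
#' @param G_ss steady-state fold changes measured at each intensity.
#' @param gain fold-change steady-state gain `b_r/d_r` used to convert
#'   `G_ss` to input units (default 1).
#' @return A fitted `dose_response` object with attribute `"rss"`.
#' @export
fit_dose_response <- function(U, G_ss, gain = 1) {
  stopifnot(length(U) == length(G_ss), length(U) >= 4)
  u <- (G_ss - 1) / gain
  obj <- function(th) {
    pred <- th[1] * U^th[3] / (th[2]^th[3] + U^th[3])
    sum((pred - u)^2)
  }
  starts <- expand.grid(K = c(10, 20, 40), n = c(1, 2, 3, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(c(max(u), starts$K[i], starts$n[i]), obj,
                        method = "L-BFGS-B",
                        lower = c(1e-3, 1, 0.2), upper = c(50, 99, 10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  out <- dose_response(u_sat = best$par[1], K = best$par[2], n = best$par[3])
  attr(out, "rss") <- best$value
  out
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf(
    "Hill dose-response: f(U) = %.4g U^%.3g / (%.4g^%.3g + U^%.3g)\n",
    x$u_sat, x$n, x$K, x$n, x$n))
  cat(sprintf("  f(60) = %.4g, f(100) = %.4g\n",
              dose_response_eval(x, 60), dose_response_eval(x, 100)))
  invisible(x)
}
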