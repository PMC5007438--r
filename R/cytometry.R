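## Synthetic flow-cytometry event generation and reduction to the scalar
## "average of normalized sfGFP" the controllers consume.
##
## Event tables are plain data.frames with columns FSC_H, FSC_A, SSC_A,
## FL1_A (CSV headers FSC-H, FSC-A, SSC-A, FL1-A).  Channels are in
## arbitrary instrument units: typical cells sit around 30,000 a.u. of
## FSC-H and, at baseline induction, ~6,000 a.f.u. of FL1.

#' Gating configuration
#'
#' Events are kept when FSC-H and FL1 clear their noise thresholds and
#' the point falls inside an ellipse in FSC-A x SSC-A space (a very wide
#' gate enclosing the whole cellular cluster; its purpose is to remove
#' instrument-noise events, not to subset cells).  The default ellipse is
#' permissive, retaining roughly 75% of generated events (about 15,000 of
#' a 20,000-event sample).
#'
#' @param fsc_h_threshold FSC-H noise threshold (a.u.).
#' @param fl1_threshold FL1 noise threshold (a.f.u.).
#' @param ellipse list with `center` (length 2, FSC-A and SSC-A),
#'   `semi_axes` (length 2, `> 0`) and `angle` (radians, rotation of the
#'   first axis).
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(fsc_h_threshold = 11000, fl1_threshold = 800,
                        ellipse = list(center = c(33000, 16000),
                                       semi_axes = c(13000, 8500),
                                       angle = 0.35)) {
  stopifnot(fsc_h_threshold >= 0, fl1_threshold >= 0,
            length(ellipse$center) == 2, length(ellipse$semi_axes) == 2,
            all(ellipse$semi_axes > 0))
  structure(list(fsc_h_threshold = fsc_h_threshold,
                 fl1_threshold = fl1_threshold, ellipse = ellipse),
            class = "gate_config")
}

#' Gate a cytometry event table
#'
#' Discards events with fluorescence below the FL1 threshold, FSC-H
#' below the instrument-noise threshold, or falling outside the elliptical
#' gate on the FSC-A versus SSC-A scatter plot.  Event order is
#' preserved; gating is idempotent.
#'
#' @param events `data.frame` with columns `FSC_H`, `FSC_A`, `SSC_A`,
#'   `FL1_A`.
#' @param cfg a [gate_config()].
#' @return The retained events, with attribute `empty_input = TRUE` if
#'   the input had no rows (a warning is also raised).
#' @export
gate_events <- function(events, cfg = gate_config()) {
  stopifnot(all(c("FSC_H", "FSC_A", "SSC_A", "FL1_A") %in% names(events)))
  if (nrow(events) == 0) {
    warning("empty event table")
    return(structure(events, empty_input = TRUE))
  }
  el <- cfg$ellipse
  ca <- cos(el$angle); sa <- sin(el$angle)
  dx <- events$FSC_A - el$center[1]
  dy <- events$SSC_A - el$center[2]
  q <- ((ca * dx + sa * dy) / el$semi_axes[1])^2 +
    ((-sa * dx + ca * dy) / el$semi_axes[2])^2
  keep <- events$FSC_H >= cfg$fsc_h_threshold &
    events$FL1_A >= cfg$fl1_threshold & q <= 1
  events[keep, , drop = FALSE]
}

#' Mean FSC-H-normalized fluorescence of an event table
#'
#' Forward-scatter height is positively correlated with cell volume, so
#' FL1/FSC-H reflects intracellular fluorophore concentration.  The
#' sample mean of that per-event ratio is the scalar culture-fluorescence
#' measurement used by the controllers.
#'
#' @param events `data.frame` with at least `FL1_A` and `FSC_H`.
#' @return The mean of `FL1_A / FSC_H`, or `NA` with a warning if the
#'   table is empty (measurement failure: the controller should reuse the
#'   previous measurement).
#' @export
normalized_mean <- function(events) {
  if (nrow(events) == 0) {
    warning("no events: measurement failed")
    return(NA_real_)
  }
  mean(events$FL1_A / events$FSC_H)
}

#' Per-day cytometer calibration
#'
#' Maps the true population fold change to the expected normalized mean:
#' `E[FL1/FSC-H] = background + gain * G`.  The default gain of 0.2
#' matches ~6,000 a.f.u. fluorescence on ~30,000 a.u. forward scatter at
#' baseline; `cv` is the per-event coefficient of variation of the
#' fluorescence ratio.
#'
#' @param background fluorescence ratio not attributable to the reporter.
#' @param gain ratio units per fold change.
#' @param cv per-event coefficient of variation (`> 0`).
#' @return An object of class `cyto_calibration`.
#' @export
cyto_calibration <- function(background = 0, gain = 0.2, cv = 0.3) {
  stopifnot(background >= 0, gain > 0, cv > 0)
  structure(list(background = background, gain = gain, cv = cv),
            class = "cyto_calibration")
}

#' Synthesize a cytometry event cloud from a true fluorescence level
#'
#' Desk-scale stand-in for the autosampler + cytometer: draws correlated
#' log-normal scatter channels (a common latent size factor drives FSC-H,
#' FSC-A and SSC-A, reproducing the positive scatter-volume correlation)
#' and sets `FL1 = FSC_H * (background + gain * G) * noise` with
#' mean-one log-normal noise, so the expected normalized mean of the
#' gated table is `background + gain * G`.  Uses the current RNG stream.
#'
#' @param true_G population fold change (>= 0).
#' @param calib a [cyto_calibration()].
#' @param n_events events to draw (default 20,000, the acquisition cap).
#' @return An event `data.frame` (columns `FSC_H, FSC_A, SSC_A, FL1_A`).
#' @export
synthesize_sample <- function(true_G, calib = cyto_calibration(),
                              n_events = 20000) {
  stopifnot(n_events >= 1, true_G >= 0)
  z <- stats::rnorm(n_events)
  fsc_h <- 30000 * exp(0.22 * z + 0.10 * stats::rnorm(n_events))
  fsc_a <- 33000 * exp(0.25 * z + 0.10 * stats::rnorm(n_events))
  ssc_a <- 16000 * exp(0.30 * z + 0.20 * stats::rnorm(n_events))
  s <- sqrt(log(1 + calib$cv^2))
  noise <- exp(stats::rnorm(n_events, -s^2 / 2, s))
  level <- calib$background + calib$gain * true_G
  data.frame(FSC_H = fsc_h, FSC_A = fsc_a, SSC_A = ssc_a,
             FL1_A = fsc_h * level * noise)
}

#' Gate and summarize one cytometry sample
#'
#' @param events raw event table.
#' @param cfg a [gate_config()].
#' @param timestamp acquisition time (min).
#' @return List of class `cytometry_sample` with the gated `events`, the
#'   `normalized_mean` and the `timestamp`.
#' @export
cytometry_sample <- function(events, cfg = gate_config(), timestamp = NA) {
  gated <- gate_events(events, cfg)
  structure(list(events = gated,
                 normalized_mean = if (nrow(gated)) normalized_mean(gated)
                                   else NA_real_,
                 timestamp = timestamp),
            class = "cytometry_sample")
}

#' Read / write event tables as CSV
#'
#' CSV columns use the instrument naming `FSC-H, FSC-A, SSC-A, FL1-A`.
#'
#' @param path file path.
#' @param events event `data.frame` (for writing).
#' @return For reading, an event `data.frame` with syntactic names.
#' @export
read_events_csv <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE)
  need <- c("FSC-H", "FSC-A", "SSC-A", "FL1-A")
  stopifnot(all(need %in% names(x)))
  out <- x[, need]
  names(out) <- c("FSC_H", "FSC_A", "SSC_A", "FL1_A")
  out
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(events, path) {
  out <- events[, c("FSC_H", "FSC_A", "SSC_A", "FL1_A")]
  names(out) <- c("FSC-H", "FSC-A", "SSC-A", "FL1-A")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
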