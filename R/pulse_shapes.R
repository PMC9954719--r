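#' Describe one biphasic pulse-shape family
#'
#' A pulse-shape specification fixes everything about a stimulation pulse
#' except its charge: the family (rectangular, fixed-slope ramp, or
#' fixed-amplitude ramp), the polarity of the first phase, and the one
#' family parameter that stays constant while charge varies. Fixed-slope
#' ramps hold the ramp angle constant (85 or 80 degrees in the standard
#' protocol) and grow both duration and peak with charge; fixed-amplitude
#' ramps hold the peak current constant (750 or 500 uA) and grow duration;
#' rectangular pulses hold the phase duration constant and grow amplitude.
#'
#' The slope angle is a convention: `tan(slope_angle_deg)` is read in uA
#' per us, so 85 degrees is roughly 11.43 uA/us and 80 degrees roughly
#' 5.67 uA/us.
#'
#' @param family `"rectangular"`, `"fixed_slope"` or `"fixed_amplitude"`.
#' @param polarity_first `"cathodic"` (negative first phase) or `"anodic"`.
#' @param slope_angle_deg ramp angle in degrees, strictly between 0 and 90
#'   (fixed-slope family only).
#' @param peak_amplitude_uA constant peak current in uA, positive
#'   (fixed-amplitude family only).
#' @param rect_phase_duration_us constant phase duration in us
#'   (rectangular family only; default 21 us).
#'
#' @return An object of class `pulse_shape_spec` with a `label` such as
#'   `"FS80-C"` or `"FA750-A"`.
#' @examples
#' pulse_shape_spec("fixed_amplitude", "cathodic", peak_amplitude_uA = 750)
#' pulse_shape_spec("fixed_slope", "anodic", slope_angle_deg = 80)
#' @seealso [shape_presets()] for the five standard shapes, [solve_phase()]
#' @export
pulse_shape_spec <- function(family = c("rectangular", "fixed_slope", "fixed_amplitude"),
                             polarity_first = c("cathodic", "anodic"),
                             slope_angle_deg = NULL,
                             peak_amplitude_uA = NULL,
                             rect_phase_duration_us = 21) {
  family <- match.arg(family)
  polarity_first <- match.arg(polarity_first)
  if (family == "fixed_slope") {
    if (is.null(slope_angle_deg))
      stop_input("fixed_slope family requires slope_angle_deg")
    if (!is.null(peak_amplitude_uA))
      stop_input("peak_amplitude_uA is not a fixed_slope parameter")
    if (slope_angle_deg <= 0 || slope_angle_deg >= 90)
      stop_input("slope_angle_deg must lie strictly between 0 and 90 degrees")
  } else if (family == "fixed_amplitude") {
    if (is.null(peak_amplitude_uA))
      stop_input("fixed_amplitude family requires peak_amplitude_uA")
    if (!is.null(slope_angle_deg))
      stop_input("slope_angle_deg is not a fixed_amplitude parameter")
    if (peak_amplitude_uA <= 0)
      stop_input("peak_amplitude_uA must be positive")
  } else {
    if (!is.null(slope_angle_deg) || !is.null(peak_amplitude_uA))
      stop_input("rectangular family takes only rect_phase_duration_us")
    if (rect_phase_duration_us <= 0)
      stop_input("rect_phase_duration_us must be positive")
  }
  label <- switch(family,
    rectangular     = "Rec",
    fixed_slope     = sprintf("FS%g", slope_angle_deg),
    fixed_amplitude = sprintf("FA%g", peak_amplitude_uA))
  label <- paste0(label, if (polarity_first == "cathodic") "-C" else "-A")
  structure(
    list(family = family,
         polarity_first = polarity_first,
         slope_angle_deg = slope_angle_deg,
         peak_amplitude_uA = peak_amplitude_uA,
         rect_phase_duration_us = if (family == "rectangular") rect_phase_duration_us else NULL,
         label = label),
    class = "pulse_shape_spec")
}

#' @export
print.pulse_shape_spec <- function(x, ...) {
  cat("<pulse_shape_spec>", x$label, "\n")
  cat("  family:", x$family, "| first phase:", x$polarity_first, "\n")
  if (!is.null(x$slope_angle_deg))
    cat("  slope:", x$slope_angle_deg, "deg (",
        format(tan(x$slope_angle_deg * pi / 180), digits = 4), "uA/us )\n")
  if (!is.null(x$peak_amplitude_uA))
    cat("  peak amplitude:", x$peak_amplitude_uA, "uA\n")
  if (!is.null(x$rect_phase_duration_us))
    cat("  phase duration:", x$rect_phase_duration_us, "us\n")
  invisible(x)
}

#' The five standard pulse shapes of the stimulation protocol
#'
#' Returns the rectangular reference and the four ramped families
#' (fixed slope 85 and 80 degrees; fixed amplitude 750 and 500 uA)
#' with the requested first-phase polarity, as a named list keyed by
#' shape label (`"Rec-C"`, `"FS85-C"`, ...).
#'
#' @param polarity_first `"cathodic"` or `"anodic"`.
#' @return Named list of [pulse_shape_spec()] objects.
#' @examples
#' names(shape_presets())
#' @export
shape_presets <- function(polarity_first = c("cathodic", "anodic")) {
  polarity_first <- match.arg(polarity_first)
  shapes <- list(
    pulse_shape_spec("rectangular", polarity_first),
    pulse_shape_spec("fixed_slope", polarity_first, slope_angle_deg = 85),
    pulse_shape_spec("fixed_slope", polarity_first, slope_angle_deg = 80),
    pulse_shape_spec("fixed_amplitude", polarity_first, peak_amplitude_uA = 750),
    pulse_shape_spec("fixed_amplitude", polarity_first, peak_amplitude_uA = 500))
  names(shapes) <- vapply(shapes, `[[`, "", "label")
  shapes
}

#' Build a uniform charge schedule
#'
#' The stimulation protocol presents every pulse shape at a fixed set of
#' uniformly spaced total-charge levels, each repeated a fixed number of
#' times at a fixed pulse rate. The standard configuration is 20 levels
#' from 3 to 31.5 nC (step 1.5 nC), 32 repetitions per level, 4 Hz.
#'
#' @param min_nC,max_nC lowest and highest charge level in nC.
#' @param n_levels number of levels (at least 2).
#' @param n_repetitions trials per level.
#' @param rate_Hz pulse presentation rate; the inter-pulse interval in ms
#'   is `1000 / rate_Hz`.
#' @return A `charge_schedule` object with elements `levels_nC`,
#'   `n_levels`, `n_repetitions`, `stim_rate_Hz`, `ipi_ms`.
#' @examples
#' sched <- make_schedule()
#' sched$levels_nC[c(1, 20)]   # 3 and 31.5 nC
#' @export
make_schedule <- function(min_nC = 3, max_nC = 31.5, n_levels = 20,
                          n_repetitions = 32, rate_Hz = 4) {
  if (!(is.finite(min_nC) && is.finite(max_nC)) || min_nC >= max_nC)
    stop_input("schedule error: need min_nC < max_nC")
  if (n_levels < 2 || n_repetitions < 1 || rate_Hz <= 0)
    stop_input("schedule error: non-positive counts or fewer than 2 levels")
  structure(
    list(levels_nC = seq(min_nC, max_nC, length.out = n_levels),
         n_levels = as.integer(n_levels),
         n_repetitions = as.integer(n_repetitions),
         stim_rate_Hz = rate_Hz,
         ipi_ms = 1000 / rate_Hz),
    class = "charge_schedule")
}

#' @export
print.charge_schedule <- function(x, ...) {
  cat(sprintf("<charge_schedule> %d levels, %.3g to %.3g nC, %d repetitions at %g Hz\n",
              x$n_levels, min(x$levels_nC), max(x$levels_nC),
              x$n_repetitions, x$stim_rate_Hz))
  invisible(x)
}

#' Solve phase geometry for a target charge
#'
#' Given a pulse-shape specification and a total biphasic charge `Q`,
#' returns the peak amplitude, phase duration and slope of one phase.
#' Each ramped phase rises linearly from 0 to the peak `A` over the phase
#' duration `t`, so one phase carries charge `A * t / 2` and the biphasic
#' pulse carries `Q = A * t` in magnitude. Under this convention the
#' standard schedule end-points reproduce the published geometry: a
#' 750 uA fixed-amplitude pulse spans 4 us at 3 nC and 42 us at 31.5 nC,
#' a 500 uA pulse spans 6 to 63 us. For rectangular phases each phase
#' carries `A * t`, so `Q = 2 * A * t`.
#'
#' Closed forms: fixed amplitude `t = Q / A`; fixed slope (with
#' `s = tan(angle)` in uA/us) `t = sqrt(Q / s)`, `A = sqrt(Q * s)`;
#' rectangular `A = Q / (2 * t)` at the spec's fixed `t`.
#'
#' @param spec a [pulse_shape_spec()].
#' @param Q_nC target total biphasic charge in nC (positive).
#' @param charge_convention `"total"` (default, `Q` is the whole biphasic
#'   pulse) or `"per_phase"` (`Q` is the charge of one phase).
#' @param current_step_uA device current step used only to flag
#'   sub-quantum solutions (see Value).
#' @param min_phase_us device temporal resolution used only to flag
#'   sub-quantum solutions.
#' @return A `phase_solution` list: `peak_amplitude_uA`,
#'   `phase_duration_us`, `slope_uA_per_us`, and `below_quantum` (TRUE
#'   when the solved amplitude falls below one current step or the
#'   duration below the temporal resolution — a warning flag rather than
#'   an error).
#' @examples
#' fa750 <- pulse_shape_spec("fixed_amplitude", "cathodic", peak_amplitude_uA = 750)
#' solve_phase(fa750, 31.5)$phase_duration_us   # 42 us
#' solve_phase(fa750, 3)$phase_duration_us      # 4 us
#' @export
solve_phase <- function(spec, Q_nC, charge_convention = c("total", "per_phase"),
                        current_step_uA = 25, min_phase_us = 3) {
  stopifnot(inherits(spec, "pulse_shape_spec"))
  charge_convention <- match.arg(charge_convention)
  if (!is.numeric(Q_nC) || length(Q_nC) != 1 || !is.finite(Q_nC) || Q_nC <= 0)
    stop_input("charge domain error: Q_nC must be a single positive number")
  Q <- Q_nC * NC_TO_UAUS                      # uA*us over the whole pulse
  if (charge_convention == "per_phase") Q <- 2 * Q
  sol <- switch(spec$family,
    fixed_amplitude = {
      A <- spec$peak_amplitude_uA
      t <- Q / A                              # Q = A*t for mirrored triangles
      list(A = A, t = t, s = A / t)
    },
    fixed_slope = {
      s <- tan(spec$slope_angle_deg * pi / 180)
      t <- sqrt(Q / s)
      list(A = s * t, t = t, s = s)
    },
    rectangular = {
      t <- spec$rect_phase_duration_us
      list(A = Q / (2 * t), t = t, s = Inf)
    })
  structure(
    list(peak_amplitude_uA = sol$A,
         phase_duration_us = sol$t,
         slope_uA_per_us = sol$s,
         below_quantum = sol$A < current_step_uA || sol$t < min_phase_us),
    class = "phase_solution")
}

#' Synthesize a sampled charge-balanced biphasic waveform
#'
#' Samples the pulse solved by [solve_phase()] on a regular time grid.
#' The two phases mirror each other in sign, so the signed charge sums to
#' zero by construction. By default each ramped phase independently ramps
#' from 0 to the peak (the second phase is the sign-flipped copy of the
#' first); `mirrored_second_phase = TRUE` instead time-reverses the
#' second phase.
#'
#' Continuous waveforms are sampled at bin midpoints with the bin width
#' adjusted to divide the phase exactly, which makes the numerical charge
#' integral of linear and constant segments exact.
#'
#' With `quantize = TRUE` the ramp becomes a staircase of
#' `ceil(A / current_step_uA)` equal-dwell current levels, each level a
#' multiple of `current_step_uA` (the hardware current step, 25 uA on the
#' stimulation platform used for the standard protocol). The staircase
#' overshoots the triangle's charge slightly, so all dwell times are
#' scaled by a common factor to restore the target charge exactly while
#' preserving the peak amplitude. Whether the platform's 3-4 us timing
#' resolution constrains individual dwell times or only whole-phase
#' timing is not settled, so no dwell floor is enforced by default;
#' setting `min_dwell_us > 0` (e.g. 3) enforces one by coarsening the
#' staircase to a larger multiple of the current step and setting
#' `constraint_violated`, rather than erroring.
#'
#' @inheritParams solve_phase
#' @param sample_period_us requested sampling period in us; the realized
#'   period (returned) is the nearest value that tiles the phase or dwell
#'   exactly.
#' @param current_step_uA quantization step in uA.
#' @param quantize logical; apply the current-step staircase?
#' @param mirrored_second_phase logical; time-reverse the second phase.
#' @param min_dwell_us shortest realizable staircase dwell in us; 0
#'   (default) disables the constraint.
#' @return A `waveform` object: `sample_period_us`, `samples_uA` (signed;
#'   negative = cathodic), `realized_charge_nC` (integral of |i|),
#'   `charge_imbalance_nC` (signed integral), `current_step_uA`,
#'   `quantized`, `constraint_violated`, `spec`, `Q_nC`, and the phase
#'   solution used.
#' @examples
#' fa750 <- pulse_shape_spec("fixed_amplitude", "cathodic", peak_amplitude_uA = 750)
#' w <- synthesize(fa750, 31.5)
#' w$realized_charge_nC               # 31.5
#' wq <- synthesize(fa750, 31.5, quantize = TRUE)
#' length(unique(abs(wq$samples_uA))) # 30 staircase levels
#' @export
synthesize <- function(spec, Q_nC, sample_period_us = 1, current_step_uA = 25,
                       quantize = FALSE, mirrored_second_phase = FALSE,
                       charge_convention = c("total", "per_phase"),
                       min_dwell_us = 0) {
  stopifnot(inherits(spec, "pulse_shape_spec"))
  if (sample_period_us <= 0) stop_input("sample_period_us must be positive")
  charge_convention <- match.arg(charge_convention)
  sol <- solve_phase(spec, Q_nC, charge_convention, current_step_uA)
  A <- sol$peak_amplitude_uA
  t <- sol$phase_duration_us
  Q_phase <- Q_nC * NC_TO_UAUS / 2            # per-phase charge, uA*us
  if (charge_convention == "per_phase") Q_phase <- Q_nC * NC_TO_UAUS
  constraint <- FALSE

  if (t < sample_period_us)
    stop_input("degenerate waveform: phase shorter than one sample period")

  if (!quantize) {
    n <- max(1L, as.integer(round(t / sample_period_us)))
    dt <- t / n
    mid <- (seq_len(n) - 0.5) * dt
    phase1 <- if (spec$family == "rectangular") rep(A, n) else (A / t) * mid
  } else {
    if (spec$family == "rectangular") {
      # amplitude snapped to the current grid, dwell rescaled for charge
      Aq <- max(current_step_uA, round(A / current_step_uA) * current_step_uA)
      tq <- Q_phase / Aq
      n <- max(1L, as.integer(round(tq / sample_period_us)))
      dt <- tq / n
      phase1 <- rep(Aq, n)
      t <- tq
    } else {
      n_steps <- as.integer(ceiling(A / current_step_uA))
      max_steps <- if (min_dwell_us > 0)
        max(1L, as.integer(floor(t / min_dwell_us))) else n_steps
      step_eff <- current_step_uA
      if (n_steps > max_steps) {          # 30 steps cannot fit a 4 us phase:
        # coarsen the staircase to a multiple of the current step and flag it
        step_eff <- current_step_uA * ceiling(n_steps / max_steps)
        n_steps <- as.integer(ceiling(A / step_eff))
        constraint <- TRUE
      }
      levels <- seq_len(n_steps) * step_eff
      # equal dwells, uniformly rescaled so the staircase carries exactly the
      # per-phase charge (peak amplitude preserved, duration absorbs the fix)
      dwell <- Q_phase / sum(levels)
      k <- max(1L, as.integer(round(dwell / sample_period_us)))
      dt <- dwell / k
      phase1 <- rep(levels, each = k)
      t <- dwell * n_steps
      n <- length(phase1)
    }
  }

  phase2 <- if (mirrored_second_phase) rev(phase1) else phase1
  sgn <- if (spec$polarity_first == "cathodic") -1 else 1
  samples <- c(sgn * phase1, -sgn * phase2)
  realized <- sum(abs(samples)) * dt / NC_TO_UAUS
  imbalance <- sum(samples) * dt / NC_TO_UAUS

  structure(
    list(sample_period_us = dt,
         samples_uA = samples,
         realized_charge_nC = realized,
         charge_imbalance_nC = imbalance,
         current_step_uA = current_step_uA,
         quantized = quantize,
         constraint_violated = constraint,
         phase_duration_us = t,
         spec = spec,
         Q_nC = Q_nC,
         solution = sol),
    class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s, target %.4g nC, realized %.6g nC (imbalance %.3g nC)\n",
              x$spec$label, x$Q_nC, x$realized_charge_nC, x$charge_imbalance_nC))
  cat(sprintf("  %d samples at %.4g us%s%s\n", length(x$samples_uA),
              x$sample_period_us,
              if (x$quantized) sprintf(", quantized to %g uA", x$current_step_uA) else "",
              if (x$constraint_violated) " [dwell constraint violated]" else ""))
  invisible(x)
}

#' Total absolute charge of a sampled waveform
#'
#' Numerically integrates the absolute current over the waveform:
#' `sum(|i|) * sample_period`, converted to nC.
#'
#' @param w a [synthesize()] waveform.
#' @return Total charge magnitude in nC.
#' @examples
#' fa500 <- pulse_shape_spec("fixed_amplitude", "cathodic", peak_amplitude_uA = 500)
#' total_charge(synthesize(fa500, 31.5))   # 31.5
#' @export
total_charge <- function(w) {
  stopifnot(inherits(w, "waveform"))
  if (length(w$samples_uA) == 0) stop_input("empty waveform")
  sum(abs(w$samples_uA)) * w$sample_period_us / NC_TO_UAUS
}

#' Write / read a waveform as delimited text with a JSON sidecar
#'
#' The waveform samples go to a two-column tab-separated file
#' (`time_us`, `current_uA`; times are bin midpoints) and the metadata
#' (shape spec, target and realized charge, imbalance, quantization
#' settings) to `<path>.json`.
#'
#' @param w a waveform.
#' @param path output TSV path.
#' @return `write_waveform` returns `path` invisibly; `read_waveform`
#'   returns a `waveform` object.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  n <- length(w$samples_uA)
  df <- data.frame(time_us = (seq_len(n) - 0.5) * w$sample_period_us,
                   current_uA = w$samples_uA)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(
    spec = w$spec[c("family", "polarity_first", "slope_angle_deg",
                    "peak_amplitude_uA", "rect_phase_duration_us", "label")],
    Q_nC = w$Q_nC,
    realized_charge_nC = w$realized_charge_nC,
    charge_imbalance_nC = w$charge_imbalance_nC,
    sample_period_us = w$sample_period_us,
    current_step_uA = w$current_step_uA,
    quantized = w$quantized,
    constraint_violated = w$constraint_violated,
    phase_duration_us = w$phase_duration_us)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  df <- read.delim(path)
  assert_cols(df, c("time_us", "current_uA"), "waveform file")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sp <- meta$spec
  spec <- pulse_shape_spec(sp$family, sp$polarity_first,
                           slope_angle_deg = sp$slope_angle_deg,
                           peak_amplitude_uA = sp$peak_amplitude_uA,
                           rect_phase_duration_us = sp$rect_phase_duration_us %||% 21)
  structure(
    list(sample_period_us = meta$sample_period_us,
         samples_uA = df$current_uA,
         realized_charge_nC = meta$realized_charge_nC,
         charge_imbalance_nC = meta$charge_imbalance_nC,
         current_step_uA = meta$current_step_uA,
         quantized = meta$quantized,
         constraint_violated = meta$constraint_violated,
         phase_duration_us = meta$phase_duration_us,
         spec = spec,
         Q_nC = meta$Q_nC,
         solution = NULL),
    class = "waveform")
}
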