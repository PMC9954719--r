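#' Per-trial firing rates in the evoked and spontaneous windows
#'
#' Evoked discharges are quantified over a 45 ms window starting at pulse
#' onset, with activity in the first 9 ms excluded: responses earlier
#' than the shortest acoustic-response latency of the guinea pig primary
#' auditory cortex are discarded, which here means spikes in `[0, 9)` ms
#' do not enter the evoked count (the default evoked window is
#' `[9, 45)` ms). Spontaneous activity is counted over the last 100 ms of
#' the 250 ms inter-pulse interval (`[150, 250)` ms at the standard 4 Hz
#' rate). Counts are converted to rates (Hz) by their window duration.
#'
#' @param events spike-event data frame (columns `recording_id`,
#'   `shape_id`, `level_index`, `trial_index`, `spike_time_ms`).
#' @param schedule a [make_schedule()]; supplies the trial grid and the
#'   inter-pulse interval.
#' @param evoked_window,spont_window `[start, end)` windows in ms; must
#'   be disjoint and lie within the inter-pulse interval.
#' @return Data frame with one row per (recording, shape, level, trial):
#'   columns `recording_id`, `shape_id`, `level_index`, `trial_index`,
#'   `evoked_rate_Hz`, `spont_rate_Hz`. The grid is complete: trials
#'   without spikes appear with rate 0.
#' @examples
#' ev <- simulate_recording(ground_truth(), schedule = make_schedule(), seed = 1)
#' head(count_windows(ev, make_schedule()))
#' @export
count_windows <- function(events, schedule = make_schedule(),
                          evoked_window = c(9, 45),
                          spont_window = c(150, 250)) {
  stopifnot(inherits(schedule, "charge_schedule"))
  assert_cols(events, c("recording_id", "shape_id", "level_index",
                        "trial_index", "spike_time_ms"), "spike events")
  ipi <- schedule$ipi_ms
  if (evoked_window[1] >= evoked_window[2] || spont_window[1] >= spont_window[2])
    stop_input("windows must be non-empty [start, end) intervals")
  if (max(evoked_window[2], spont_window[2]) > ipi ||
      min(evoked_window[1], spont_window[1]) < 0)
    stop_input("windows must lie within [0, ", ipi, ") ms")
  if (evoked_window[2] > spont_window[1] && spont_window[2] > evoked_window[1])
    stop_input("evoked and spontaneous windows must be disjoint")
  bad <- events$spike_time_ms < 0 | events$spike_time_ms >= ipi |
    !is.finite(events$spike_time_ms)
  if (any(bad))
    stop_input("input-format error: ", sum(bad),
               " spike time(s) outside [0, ", ipi, ") ms")

  nl <- schedule$n_levels
  nr <- schedule$n_repetitions
  if (any(events$level_index < 1 | events$level_index > nl))
    stop_input("input-format error: level_index outside [1, ", nl, "]")
  if (any(events$trial_index < 1 | events$trial_index > nr))
    stop_input("input-format error: trial_index outside [1, ", nr, "]")

  # complete (recording, shape, level, trial) grid, zero-filled; counting is
  # done on a dense integer key so large cohorts stay cheap
  rs <- paste(events$recording_id, events$shape_id, sep = "\r")
  grid_lab <- sort(unique(rs))
  ng <- length(grid_lab)
  key <- (match(rs, grid_lab) - 1L) * (nl * nr) +
    (as.integer(events$level_index) - 1L) * nr +
    as.integer(events$trial_index)
  nslots <- ng * nl * nr
  in_win <- function(t, w) t >= w[1] & t < w[2]
  ev_counts <- tabulate(key[in_win(events$spike_time_ms, evoked_window)],
                        nbins = nslots)
  sp_counts <- tabulate(key[in_win(events$spike_time_ms, spont_window)],
                        nbins = nslots)
  ids <- do.call(rbind, strsplit(grid_lab, "\r", fixed = TRUE))
  full <- data.frame(
    recording_id = rep(ids[, 1], each = nl * nr),
    shape_id = rep(ids[, 2], each = nl * nr),
    level_index = rep(rep(seq_len(nl), each = nr), times = ng),
    trial_index = rep(seq_len(nr), times = ng * nl),
    evoked_rate_Hz = ev_counts / (diff(evoked_window) / 1000),
    spont_rate_Hz = sp_counts / (diff(spont_window) / 1000))
  attr(full, "evoked_window") <- evoked_window
  attr(full, "spont_window") <- spont_window
  full
}

#' Build the growth function of one recording under one shape
#'
#' Averages the per-trial evoked firing rates across the repetitions of
#' each charge level, and pools the spontaneous rates over all trials of
#' the recording-shape combination to obtain the baseline mean and
#' across-trial SD used by the threshold criterion.
#'
#' @param counts per-trial rates from [count_windows()], restricted to a
#'   single recording and shape (an error otherwise).
#' @param schedule the [make_schedule()] the counts were made under.
#' @return A `growth_function` object: `levels_nC`, `mean_rate_Hz` (raw
#'   evoked mean per level), `sd_rate_Hz` (across-trial SD per level),
#'   `subtracted_rate_Hz` (mean minus spontaneous mean), `spont_mean_Hz`,
#'   `spont_sd_Hz`, `n_trials`, plus the identifiers and windows.
#' @export
build_growth_function <- function(counts, schedule = make_schedule()) {
  stopifnot(inherits(schedule, "charge_schedule"))
  assert_cols(counts, c("recording_id", "shape_id", "level_index",
                        "trial_index", "evoked_rate_Hz", "spont_rate_Hz"),
              "count table")
  if (nrow(counts) == 0) stop_input("empty count table")
  if (length(unique(counts$recording_id)) != 1 ||
      length(unique(counts$shape_id)) != 1)
    stop_input("counts must cover exactly one recording x shape; see quantify_recordings()")
  lev <- sort(unique(counts$level_index))
  if (!identical(as.integer(lev), seq_len(schedule$n_levels)))
    stop_input("incomplete-protocol error: levels missing from the trial grid")
  mu <- tapply(counts$evoked_rate_Hz, counts$level_index, mean)
  sdv <- tapply(counts$evoked_rate_Hz, counts$level_index, sd)
  spont_mean <- mean(counts$spont_rate_Hz)
  spont_sd <- sd(counts$spont_rate_Hz)
  structure(
    list(recording_id = counts$recording_id[1],
         shape_id = counts$shape_id[1],
         levels_nC = schedule$levels_nC,
         mean_rate_Hz = as.vector(mu),
         sd_rate_Hz = as.vector(sdv),
         subtracted_rate_Hz = as.vector(mu) - spont_mean,
         spont_mean_Hz = spont_mean,
         spont_sd_Hz = if (is.na(spont_sd)) 0 else spont_sd,
         n_trials = as.vector(table(counts$level_index)),
         evoked_window = attr(counts, "evoked_window") %||% c(9, 45),
         spont_window = attr(counts, "spont_window") %||% c(150, 250)),
    class = "growth_function")
}

#' @export
print.growth_function <- function(x, ...) {
  cat(sprintf("<growth_function> %s / %s: %d levels, spont %.2f +/- %.2f Hz\n",
              x$recording_id, x$shape_id, length(x$levels_nC),
              x$spont_mean_Hz, x$spont_sd_Hz))
  invisible(x)
}

#' Plot a growth function
#'
#' Spontaneous-subtracted evoked rate against charge, with the
#' significance criterion line (baseline + `sd_multiplier` SD, drawn in
#' subtracted coordinates) and the detected threshold marked.
#'
#' @param x a `growth_function`.
#' @param sd_multiplier criterion multiplier, default 3.
#' @param ... passed to [graphics::plot()].
#' @export
plot.growth_function <- function(x, sd_multiplier = 3, ...) {
  graphics::plot(x$levels_nC, x$subtracted_rate_Hz, type = "b", pch = 16,
                 xlab = "charge (nC)", ylab = "evoked - spontaneous (AP/s)",
                 main = paste(x$recording_id, x$shape_id), ...)
  graphics::abline(h = sd_multiplier * x$spont_sd_Hz, lty = 2)
  thr <- detect_threshold(x, sd_multiplier)
  if (!is.na(thr)) graphics::abline(v = thr, col = 2, lty = 3)
  invisible(x)
}

# significance pattern of a growth function: raw evoked mean above
# spontaneous mean + m * SD, level by level
significant_levels <- function(gf, sd_multiplier = 3) {
  gf$mean_rate_Hz > gf$spont_mean_Hz + sd_multiplier * gf$spont_sd_Hz
}

#' Detect the response threshold of a growth function
#'
#' A charge level is significant when its mean raw evoked rate exceeds
#' the spontaneous mean plus `sd_multiplier` (default 3) spontaneous
#' SDs. The threshold is the lowest significant level whose two
#' immediate successors are also significant — the confirmation rule
#' that guards against isolated chance crossings. Returns `NA` when no
#' level qualifies (including patterns whose only significant runs sit
#' at the top two levels, where two successors do not exist).
#'
#' @param gf a [build_growth_function()] object.
#' @param sd_multiplier criterion multiplier (3 in the standard
#'   analysis).
#' @return Threshold charge in nC, or `NA_real_` if never significant.
#' @examples
#' ev <- simulate_recording(ground_truth(Q50_nC = 12), schedule = make_schedule(), seed = 2)
#' gf <- build_growth_function(count_windows(ev, make_schedule()), make_schedule())
#' detect_threshold(gf)
#' @export
detect_threshold <- function(gf, sd_multiplier = 3) {
  stopifnot(inherits(gf, "growth_function"))
  n <- length(gf$levels_nC)
  if (n < 3) stop_input("protocol error: need at least 3 charge levels")
  sig <- significant_levels(gf, sd_multiplier)
  ok <- sig[seq_len(n - 2)] & sig[seq_len(n - 2) + 1] & sig[seq_len(n - 2) + 2]
  if (!any(ok)) return(NA_real_)
  gf$levels_nC[which(ok)[1]]
}

#' Extract the growth-function parameters of one recording
#'
#' The four parameters of the standard quantification, plus the
#' 80-percent dynamic range:
#' \itemize{
#'   \item `max_fr_Hz`: maximal spontaneous-subtracted evoked rate over
#'     the levels.
#'   \item `charge_at_max_nC`: charge of the level attaining it (lowest
#'     charge on ties, which makes the dynamic range conservative).
#'   \item `threshold_nC`: [detect_threshold()]; `NA` when the recording
#'     never produces a confirmed significant response, in which case
#'     `significant` is `FALSE` and both ranges are `NA`.
#'   \item `dyn_range_nC`: `charge_at_max - threshold`.
#'   \item `dyn_range80_nC`: charge of the first level whose subtracted
#'     rate reaches 80 percent of `max_fr_Hz`, minus the threshold.
#' }
#'
#' @inheritParams detect_threshold
#' @return A one-row data frame (`quant_result`): `recording_id`,
#'   `shape_id`, `max_fr_Hz`, `charge_at_max_nC`, `threshold_nC`,
#'   `dyn_range_nC`, `dyn_range80_nC`, `significant`.
#' @export
extract_params <- function(gf, sd_multiplier = 3) {
  stopifnot(inherits(gf, "growth_function"))
  sub <- gf$subtracted_rate_Hz
  imax <- which.max(sub)                 # ties: first = lowest charge
  max_fr <- sub[imax]
  charge_at_max <- gf$levels_nC[imax]
  thr <- detect_threshold(gf, sd_multiplier)
  if (is.na(thr)) {
    dr <- dr80 <- NA_real_
  } else {
    dr <- charge_at_max - thr
    i80 <- which(sub >= 0.8 * max_fr)[1]
    dr80 <- gf$levels_nC[i80] - thr
  }
  data.frame(recording_id = gf$recording_id,
             shape_id = gf$shape_id,
             max_fr_Hz = max_fr,
             charge_at_max_nC = charge_at_max,
             threshold_nC = thr,
             dyn_range_nC = dr,
             dyn_range80_nC = dr80,
             significant = !is.na(thr))
}

#' Quantify every recording-shape combination of a spike-event table
#'
#' Convenience wrapper: window counts, growth function and parameter
#' extraction for each (recording, shape) present in `events`.
#'
#' @inheritParams count_windows
#' @param sd_multiplier threshold criterion multiplier.
#' @return Data frame of [extract_params()] rows, one per recording x
#'   shape.
#' @examples
#' co <- simulate_cohort(2, effects_by_shape = default_shape_effects()[c("Rec-C", "FS80-C")],
#'                       seed = 3)
#' quantify_recordings(co$events, make_schedule())
#' @export
quantify_recordings <- function(events, schedule = make_schedule(),
                                evoked_window = c(9, 45),
                                spont_window = c(150, 250),
                                sd_multiplier = 3) {
  counts <- count_windows(events, schedule, evoked_window, spont_window)
  nl <- schedule$n_levels
  nr <- schedule$n_repetitions
  ng <- nrow(counts) / (nl * nr)
  # counts come back ordered by (recording, shape, level, trial) on a dense
  # grid, so per-level and per-group statistics reduce to rowsum() sweeps
  grp <- rep(seq_len(ng), each = nl * nr)
  grp_lvl <- rep(seq_len(ng * nl), each = nr)
  mu <- rowsum(counts$evoked_rate_Hz, grp_lvl) / nr
  mu2 <- rowsum(counts$evoked_rate_Hz^2, grp_lvl) / nr
  sd_lvl <- sqrt(pmax(0, (mu2 - mu^2) * nr / (nr - 1)))
  sp_mu <- rowsum(counts$spont_rate_Hz, grp) / (nl * nr)
  sp_mu2 <- rowsum(counts$spont_rate_Hz^2, grp) / (nl * nr)
  sp_sd <- sqrt(pmax(0, (sp_mu2 - sp_mu^2) * (nl * nr) / (nl * nr - 1)))
  first <- (seq_len(ng) - 1L) * (nl * nr) + 1L
  res <- lapply(seq_len(ng), function(g) {
    idx <- (g - 1L) * nl + seq_len(nl)
    gf <- structure(
      list(recording_id = counts$recording_id[first[g]],
           shape_id = counts$shape_id[first[g]],
           levels_nC = schedule$levels_nC,
           mean_rate_Hz = mu[idx],
           sd_rate_Hz = sd_lvl[idx],
           subtracted_rate_Hz = mu[idx] - sp_mu[g],
           spont_mean_Hz = sp_mu[g],
           spont_sd_Hz = sp_sd[g],
           n_trials = rep(nr, nl),
           evoked_window = evoked_window,
           spont_window = spont_window),
      class = "growth_function")
    extract_params(gf, sd_multiplier)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$recording_id, out$shape_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag recordings whose evoked response onset precedes 9 ms
#'
#' Alternative reading of the early-latency exclusion: instead of
#' clipping spikes before 9 ms out of the evoked window (the default in
#' [count_windows()]), drop whole recordings whose response onset —
#' estimated as the median first-spike time after pulse onset in
#' `[0, 45)` ms over the top quartile of charge levels — falls below the
#' floor.
#'
#' @param events spike-event table.
#' @param schedule the schedule.
#' @param floor_ms latency floor, ms (default 9).
#' @return Character vector of `recording_id`s to exclude.
#' @export
early_onset_recordings <- function(events, schedule = make_schedule(),
                                   floor_ms = 9) {
  assert_cols(events, c("recording_id", "level_index", "spike_time_ms"),
              "spike events")
  top <- events$level_index > 0.75 * schedule$n_levels &
    events$spike_time_ms < 45
  if (!any(top)) return(character(0))
  e <- events[top, , drop = FALSE]
  first <- aggregate(spike_time_ms ~ recording_id + shape_id + level_index +
                       trial_index, data = e, FUN = min)
  onset <- tapply(first$spike_time_ms, first$recording_id, median)
  names(onset)[onset < floor_ms]
}
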