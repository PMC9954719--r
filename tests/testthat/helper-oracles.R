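# Independent oracles and small fixture builders used across the suite.

# Build a growth_function directly from per-level mean rates and a baseline;
# bypasses spike counting so the extraction rules can be tested in isolation.
make_gf <- function(mean_rate_Hz, levels_nC = seq_along(mean_rate_Hz),
                    spont_mean_Hz = 0, spont_sd_Hz = 1,
                    sd_rate_Hz = rep(0, length(mean_rate_Hz))) {
  structure(
    list(recording_id = "fix", shape_id = "fix",
         levels_nC = levels_nC,
         mean_rate_Hz = mean_rate_Hz,
         sd_rate_Hz = sd_rate_Hz,
         subtracted_rate_Hz = mean_rate_Hz - spont_mean_Hz,
         spont_mean_Hz = spont_mean_Hz,
         spont_sd_Hz = spont_sd_Hz,
         n_trials = rep(32, length(mean_rate_Hz)),
         evoked_window = c(9, 45), spont_window = c(150, 250)),
    class = "growth_function")
}

# Growth function whose significance pattern (3-SD criterion) equals `sig`:
# baseline 0 +/- 1, so the criterion line sits at 3 Hz.
gf_from_pattern <- function(sig) {
  make_gf(ifelse(sig, 10, 0), spont_mean_Hz = 0, spont_sd_Hz = 1)
}

# Exhaustive-scan threshold oracle: check every level explicitly against the
# rule "significant, with the next two levels also significant".
threshold_oracle <- function(sig, levels_nC = seq_along(sig)) {
  n <- length(sig)
  for (L in seq_len(n)) {
    if (L + 2 > n) next
    if (sig[L] && sig[L + 1] && sig[L + 2]) return(levels_nC[L])
  }
  NA_real_
}

# Brute-force two-tailed signed-rank p-value: enumerate all 2^n sign
# assignments of the ranked absolute differences.
signed_rank_brute <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  min(1, 2 * min(mean(W <= V), mean(W >= V)))
}

# A tiny quantification table with controllable significance, for the
# pairing logic.
quant_fixture <- function(ids, sig_ref, sig_shape,
                          shape = "FS80-C", ref = "Rec-C") {
  mk <- function(sid, sig) data.frame(
    recording_id = ids, shape_id = sid,
    max_fr_Hz = seq_along(ids) * 10,
    charge_at_max_nC = 21, threshold_nC = ifelse(sig, 9, NA),
    dyn_range_nC = ifelse(sig, 12, NA), dyn_range80_nC = ifelse(sig, 6, NA),
    significant = sig)
  rbind(mk(ref, sig_ref), mk(shape, sig_shape))
}
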