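# Shared fixtures: everything is generated in code at test time.

# small clean sinusoidal recording on the first n_ch montage channels
tiny_recording <- function(n_ch = 16, srate = 100, duration_s = 4,
                           freq = 10) {
  ts <- make_templates(n_ch, 4)
  t <- seq_len(srate * duration_s) / srate
  data <- t(ts$maps[1, ] %o% sin(2 * pi * freq * t)) * 10
  data <- t(data)
  eeg_recording(data, srate, labels = colnames(ts$maps),
                positions = ts$positions)
}

# synthetic subject with known ground truth
quick_sim <- function(seed = 1, srate = 250, duration_s = 20, snr = 4,
                      dwell = c(70, 70, 62, 110), n_ch = 64) {
  ts <- make_templates(n_ch, 4)
  truth <- make_ground_truth(ts, dwell, snr = snr, seed = seed)
  sim <- synthesize_recording(truth, srate = srate, duration_s = duration_s)
  sim$templates <- ts
  sim
}

# preprocessed version: epoched, average-referenced, microstate band
quick_clean <- function(sim, ms_band = TRUE) {
  rec <- average_reference(epoch_recording(sim$recording))
  if (ms_band) rec <- microstate_band(rec)
  rec
}

# build an ms_labels object directly from a state vector (one epoch)
labels_from_states <- function(states, srate, k = 4) {
  msdyn:::new_ms_labels(states, rep(1L, length(states)), srate, k,
                        corr = rep(1, length(states)),
                        gfp = rep(1, length(states)))
}
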