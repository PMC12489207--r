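# shared synthetic audio fixtures: ten digit waves + a 30 s stationary masker
# (a short stand-in for the 5-minute masker; generated fresh, never stored)
fx <- make_din_fixtures(seed = 101, noise_duration_s = 30)
calib100 <- calibration_map(100)

# a deterministic listener: correct iff SNR >= theta (steep logistic,
# no guesses, no lapses); theta off the step grid to avoid ties at theta
det_listener <- function(theta = -8.2) {
  listener_model(threshold_db = theta, slope_per_db = 1000,
                 lapse_rate = 0, guess_rate = 0)
}

# a listener that is correct on every trial regardless of SNR
always_correct_listener <- function() {
  listener_model(threshold_db = -1e6, slope_per_db = 1,
                 lapse_rate = 0, guess_rate = 0)
}
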