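# shared fixtures, built in code at test time

# band-passed labeled trials straight from the ERD generator
make_trials <- function(n_per_class = 10, erd_depth = 0.6, noise_sd = 10,
                        n_samples = 500, seed = 1) {
  set.seed(seed)
  p <- mi_gen_params(erd_depth = erd_depth, noise_sd = noise_sd)
  trials <- c(
    lapply(seq_len(n_per_class), function(i) gen_mi_trial("left", p, n_samples)),
    lapply(seq_len(n_per_class), function(i) gen_mi_trial("right", p, n_samples))
  )
  sample(trials)
}

# a full session piped through the standard preprocessing
make_session_trials <- function(n_trials = 40, erd_depth = 0.6, seed = 1,
                                noise_sd = 10) {
  sess <- gen_training_session(n_trials,
                               mi_gen_params(erd_depth = erd_depth,
                                             noise_sd = noise_sd),
                               seed = seed)
  filt <- bandpass(sess$recording)
  extract_trials(filt, sess$events, offset = 0, length = 5)
}

# 600-ms test epoch containing one template deflection
make_blink_epoch <- function(amp = 200, dur = 0.25, peak_t = 0.3, rate = 250,
                             noise_sd = 0) {
  n <- round(0.6 * rate)
  x <- if (noise_sd > 0) rnorm(n, sd = noise_sd) else rep(0, n)
  hbci:::add_at(x, hbci:::blink_template(amp, dur, rate), peak_t, rate)
}

steady_state_gain <- function(freq, rate = 250, dur = 8, ...) {
  t <- (seq_len(dur * rate) - 1) / rate
  rec <- recording(matrix(sin(2 * pi * freq * t), 1), rate = rate,
                   channel_labels = "x")
  out <- bandpass(rec, ...)
  mid <- seq(round(0.25 * length(t)), round(0.75 * length(t)))
  max(abs(out$samples[1, mid]))
}
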