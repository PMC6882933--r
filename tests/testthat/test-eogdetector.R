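test_that("waveform check gates on amplitude, slope and duration", {
  p <- eog_params()

  # flat / sub-threshold epochs produce nothing
  set.seed(30)
  expect_null(waveform_check(rnorm(150, sd = 15), p))

  # generator blink template at twice amp_min is found near the truth peak
  ep <- make_blink_epoch(amp = 200, peak_t = 0.3, noise_sd = 10)
  ev <- waveform_check(ep, p)
  expect_false(is.null(ev))
  expect_lte(abs(ev$peak_s - 0.3), 0.008 + 1e-9)
  expect_gte(ev$amp_uV, p$amp_min)
  expect_true(ev$duration_s >= p$dur_range[1] && ev$duration_s <= p$dur_range[2])

  # slow drift crossing amp_min but failing the slope gate
  drift <- seq(0, 150, length.out = 150)
  expect_null(waveform_check(drift, p))

  # a sustained plateau (eyebrow-like) fails the blink duration gate
  long <- hbci:::add_at(rep(0, 150), hbci:::eyebrow_template(200, 0.5, 250),
                        0.3, 250, align = "center")
  expect_null(waveform_check(long, p))

  expect_error(waveform_check(rep(0, 100), p), "150 samples")
})

test_that("epoch length follows the sampling rate (600 ms of samples)", {
  p <- eog_params()
  # at 250 Hz the epoch is exactly 150 samples
  expect_null(waveform_check(rep(0, 150), p, rate = 250))
  expect_error(waveform_check(rep(0, 149), p, rate = 250), "150 samples")
  # at 500 Hz it would be 300
  expect_error(waveform_check(rep(0, 150), p, rate = 500), "300 samples")
})

test_that("intended gate needs in-window latency AND supra-TH_a amplitude", {
  p <- eog_params(TH_a = 200, delay_window = c(0.28, 0.32))
  ev <- tibble::tibble(peak_s = 0, amp_uV = 0, duration_s = 0.12,
                       intended = FALSE, flash_onset_s = NA_real_)

  ev1 <- ev; ev1$peak_s <- 10.3; ev1$amp_uV <- 250
  expect_true(classify_intended(ev1, 10.0, p)$intended)     # 300 ms, > TH_a

  ev2 <- ev1; ev2$peak_s <- 10.25
  expect_false(classify_intended(ev2, 10.0, p)$intended)    # 250 ms: outside

  ev3 <- ev1; ev3$amp_uV <- 200
  expect_false(classify_intended(ev3, 10.0, p)$intended)    # amp = TH_a: strict

  expect_equal(classify_intended(ev1, 10.0, p)$flash_onset_s, 10.0)
})

test_that("delay-window calibration centers on the median latency", {
  # perfectly stable 300-ms responder gets the canonical 280-320 ms window
  expect_equal(calibrate_delay_window(1:10, 1:10 + 0.3), c(0.28, 0.32))

  set.seed(31)
  lat <- runif(50, 0.29, 0.31)
  w <- calibrate_delay_window(seq_len(50), seq_len(50) + lat)
  centre <- mean(w)
  expect_gte(centre, 0.295)
  expect_lte(centre, 0.305)
  expect_equal(diff(w), 0.04)

  expect_error(calibrate_delay_window(1:4, 1:4 + 0.3), "calibration error")
})

test_that("eyebrow raises are separated from blinks by duration", {
  p <- eog_params()
  rate <- 250
  pad <- rep(0, 100)
  eyebrow <- c(pad, hbci:::eyebrow_template(350, 0.5, rate), pad)
  expect_true(detect_eyebrow_raise(eyebrow, p, rate))

  blink <- c(pad, hbci:::blink_template(350, 0.25, rate), pad)
  expect_false(detect_eyebrow_raise(blink, p, rate))

  expect_false(detect_eyebrow_raise(rep(0, 300), p, rate))
  expect_error(detect_eyebrow_raise(rep(0, 50), p, rate), "shorter")
})

test_that("idle streams without supra-threshold activity yield zero FPR", {
  sched <- build_schedule("wheelchair")
  p <- eog_params()
  set.seed(32)
  quiet <- recording(matrix(rnorm(250 * 120, sd = 15), 1), rate = 250,
                     channel_labels = EOG_CHANNEL)
  expect_equal(false_positive_rate(quiet, sched, p), 0)

  # unintended blinks below TH_a never count as intended
  g <- gen_eog_stream(NULL, 300, sched,
                      p = eog_gen_params(unintended_amp_mean = 140,
                                         unintended_amp_sd = 15,
                                         intended_amp = 400),
                      seed = 32)
  expect_equal(false_positive_rate(g$recording, sched, p), 0)
})

test_that("FPR matches the geometric delay-window thinning of Poisson blinks", {
  # blinks above TH_a at rate lambda, timing uniform over the flash cycle:
  # only those landing in the 40-ms window after some flash (per 100-ms
  # interval) survive, so E[FPR] = lambda * width/interval
  sched <- build_schedule("wheelchair")
  p <- eog_params()
  lambda <- 15
  g <- gen_eog_stream(NULL, 600, sched,
                      p = eog_gen_params(unintended_amp_mean = 320,
                                         unintended_amp_sd = 10,
                                         intended_amp = 500),
                      seed = 33)
  # rescale the spontaneous process to the wanted rate via the generator
  fpr <- false_positive_rate(g$recording, sched, p)
  expected <- lambda * diff(p$delay_window) / sched$interval
  n_exp <- expected * 10                     # 10-minute stream
  se <- sqrt(n_exp) / 10
  expect_lt(abs(fpr - expected), 3 * se)
})

test_that("raising TH_a and narrowing the window only remove detections", {
  sched <- build_schedule("wheelchair")
  g <- gen_eog_stream(NULL, 300, sched,
                      p = eog_gen_params(unintended_amp_mean = 250,
                                         unintended_amp_sd = 60,
                                         intended_amp = 600),
                      seed = 34)
  th_grid <- c(120, 180, 240, 300, 360)
  counts <- vapply(th_grid, function(th) {
    ev <- detect_blinks(g$recording, sched, eog_params(TH_a = th))
    sum(ev$intended)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  widths <- c(0.01, 0.02, 0.04, 0.06, 0.08)
  wcounts <- vapply(widths, function(w) {
    pp <- eog_params(delay_window = 0.3 + c(-w / 2, w / 2))
    sum(detect_blinks(g$recording, sched, pp)$intended)
  }, numeric(1))
  expect_true(all(diff(wcounts) >= 0))
})

test_that("sensitivity stays high with TH_a midway between blink classes", {
  # intended amplitude twice the unintended mean; threshold midway
  sched <- build_schedule("wheelchair")
  pg <- eog_gen_params(intended_amp = 400, unintended_amp_mean = 200,
                       unintended_amp_sd = 20)
  p <- eog_params(TH_a = 300)
  hits <- 0; total <- 0
  for (seed in 1:4) {
    script <- tibble::tibble(time_s = seq(5, 55, by = 10),
                             button = rep("MOVE", 6), verify = FALSE)
    g <- gen_eog_stream(script, 70, sched, p = pg, seed = seed)
    ev <- detect_blinks(g$recording, sched, p)
    truth <- g$events[g$events$kind == "blink_truth" &
                        g$events$label != "unintended", ]
    for (tp in truth$onset_s) {
      total <- total + 1
      hit <- any(ev$intended & abs(ev$peak_s - tp) < 0.05)
      hits <- hits + hit
    }
  }
  expect_gte(hits / total, 0.95)
})
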