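test_that("trial covariance is trace-normalized, symmetric, PSD", {
  expect_equal(trial_covariance(rbind(c(1, 1), c(1, -1))),
               diag(0.5, 2))
  expect_equal(trial_covariance(rbind(c(2, 0), c(0, 0))),
               rbind(c(1, 0), c(0, 0)))

  set.seed(10)
  X <- matrix(rnorm(9 * 1250), 9)
  R <- trial_covariance(X)
  XXt <- X %*% t(X)
  expect_equal(R, XXt / sum(diag(XXt)))

  # property over random shapes
  for (i in 1:20) {
    nr <- sample(2:9, 1)
    Xi <- matrix(rnorm(nr * sample(10:50, 1)), nrow = nr)
    Ri <- trial_covariance(Xi)
    expect_equal(sum(diag(Ri)), 1, tolerance = 1e-12)
    expect_equal(Ri, t(Ri))
    expect_true(min(eigen(Ri, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-12)
  }
  expect_error(trial_covariance(matrix(0, 3, 10)), "degenerate")
})

test_that("CSP solves the two-class generalized eigenproblem", {
  # identical classes: every generalized eigenvalue is 1/2
  set.seed(11)
  trials <- lapply(1:4, function(i) matrix(rnorm(3 * 100), 3))
  f <- csp_fit(trials, trials, m = 2)
  expect_equal(f$eigenvalues, rep(0.5, 3), tolerance = 1e-9)

  # 2-channel toy with disjoint class variance: closed-form solution is
  # eigenvalue ~1 extracting ch1 and ~0 extracting ch2
  left <- lapply(1:5, function(i) rbind(rnorm(200, sd = 1), rnorm(200, sd = 1e-3)))
  right <- lapply(1:5, function(i) rbind(rnorm(200, sd = 1e-3), rnorm(200, sd = 1)))
  f2 <- csp_fit(left, right, m = 2)
  ev <- f2$eigenvalues[f2$selected]
  expect_gt(ev[1], 0.99)
  expect_lt(ev[2], 0.01)
  # first filter points at ch1, second at ch2
  expect_gt(abs(f2$W[1, 1]), 10 * abs(f2$W[1, 2]))
  expect_gt(abs(f2$W[2, 2]), 10 * abs(f2$W[2, 1]))

  # whitening constraint: W (SUM_l + SUM_r) W' has unit diagonal
  sum_l <- Reduce(`+`, lapply(left, trial_covariance))
  sum_r <- Reduce(`+`, lapply(right, trial_covariance))
  D <- f2$W %*% (sum_l + sum_r) %*% t(f2$W)
  expect_equal(diag(D), c(1, 1), tolerance = 1e-9)

  # eigenvalues bounded in [0,1], first maximal
  trials9 <- make_trials(8, seed = 12)
  labs <- vapply(trials9, function(tr) tr$label, character(1))
  f3 <- csp_fit(trials9[labs == "left"], trials9[labs == "right"], m = 4)
  expect_true(all(f3$eigenvalues >= -1e-9 & f3$eigenvalues <= 1 + 1e-9))
  expect_equal(which.max(f3$eigenvalues), 1)
})

test_that("CSP component 1 beats any raw channel at class separation", {
  trials <- make_trials(20, erd_depth = 0.8, seed = 13)
  labs <- vapply(trials, function(tr) tr$label, character(1))
  f <- csp_fit(trials[labs == "left"], trials[labs == "right"], m = 4)
  comp1_var <- vapply(trials, function(tr) stats::var(as.numeric(f$W[1, ] %*% tr$X)),
                      numeric(1))
  ratio_comp <- mean(comp1_var[labs == "left"]) / mean(comp1_var[labs == "right"])
  raw_ratio <- vapply(1:9, function(ch) {
    v <- vapply(trials, function(tr) stats::var(tr$X[ch, ]), numeric(1))
    mean(v[labs == "left"]) / mean(v[labs == "right"])
  }, numeric(1))
  expect_gt(max(ratio_comp, 1 / ratio_comp), max(raw_ratio, 1 / raw_ratio))
})

test_that("CSP features are log variance fractions that renormalize", {
  # diag(WRW') = (3,1) gives ln(3/4), ln(1/4); engineered via scaling
  W <- diag(c(sqrt(3), 1))
  f <- structure(list(W = W, eigenvalues = c(1, 0), selected = 1:2),
                 class = "csp_filter")
  X <- diag(2) %*% matrix(c(1, 0, 0, 1), 2)  # R = I/2; d = (3/2, 1/2)
  expect_equal(csp_features(f, X), c(log(0.75), log(0.25)))

  # equal component variances: every entry is -ln m
  fI <- structure(list(W = diag(3), eigenvalues = rep(0.5, 3), selected = 1:3),
                  class = "csp_filter")
  expect_equal(csp_features(fI, diag(3)), rep(-log(3), 3))

  # random trial against the explicit matrix oracle
  set.seed(14)
  trials <- make_trials(4, seed = 14)
  labs <- vapply(trials, function(tr) tr$label, character(1))
  filt <- csp_fit(trials[labs == "left"], trials[labs == "right"], m = 4)
  X <- trials[[1]]$X
  d <- diag(filt$W %*% trial_covariance(X) %*% t(filt$W))
  expect_equal(csp_features(filt, X), log(d / sum(d)))

  # normalization invariant over many trials
  for (tr in trials) {
    expect_equal(sum(exp(csp_features(filt, tr))), 1, tolerance = 1e-9)
    expect_true(all(csp_features(filt, tr) <= 0))
  }
})

test_that("training learns separable data and enforces score orientation", {
  trials <- make_trials(10, erd_depth = 0.8, seed = 15)
  model <- train_model(trials)
  labs <- vapply(trials, function(tr) tr$label, character(1))
  scores <- vapply(trials, function(tr) score_epoch(model, tr), numeric(1))
  pred <- ifelse(scores < 0, "left", "right")
  expect_equal(mean(pred == labs), 1)          # resubstitution on separable data
  expect_lt(mean(scores[labs == "left"]), mean(scores[labs == "right"]))

  expect_error(train_model(trials[labs == "left"]), "both classes")
})

test_that("label shuffling drops cross-validated accuracy to chance", {
  trials <- make_trials(20, erd_depth = 0.8, seed = 16)
  set.seed(16)
  # balanced relabeling of a random permutation severs signal from label
  perm <- sample(seq_along(trials))
  shuffled <- lapply(seq_along(perm), function(i) {
    tr <- trials[[perm[i]]]
    tr$label <- c("left", "right")[(i %% 2) + 1]
    tr
  })
  acc <- cross_validate(shuffled, k = 5, seed = 16)
  expect_gte(acc, 0.3)
  expect_lte(acc, 0.7)
})

test_that("cross-validation recovers strong ERD and stays honest on noise", {
  trials <- make_session_trials(40, erd_depth = 0.6, seed = 18)
  expect_gte(cross_validate(trials, k = 10, seed = 18), 0.9)

  noise_trials <- make_session_trials(40, erd_depth = 0, seed = 19)
  acc0 <- cross_validate(noise_trials, k = 10, seed = 19)
  expect_gte(acc0, 0.3)
  expect_lte(acc0, 0.7)

  # duplicated identical trials are perfectly classified
  dup <- c(rep(trials[1], 10), rep(trials[2], 10))
  expect_equal(cross_validate(dup, k = 5, seed = 20), 1.0)

  expect_error(cross_validate(trials, k = 100), "cannot exceed")
})

test_that("online scoring windows match the offline classifier", {
  model <- train_model(make_trials(10, seed = 21))
  set.seed(21)
  # periodic stream with period = step: every window sees identical samples
  tile <- matrix(rnorm(9 * 50), 9)
  stream <- recording(do.call(cbind, rep(list(tile), 20)),
                      channel_labels = EEG_CHANNELS)   # 4 s
  sc <- online_scores(model, stream)
  expect_equal(nrow(sc), 11)                            # floor((4-2)/.2)+1
  expect_equal(sc$t_s, seq(2, 4, by = 0.2))
  expect_true(all(abs(sc$score - sc$score[1]) < 1e-9))  # constant scores

  # offline/online equivalence on an aperiodic stream
  set.seed(22)
  stream2 <- recording(matrix(rnorm(9 * 1000), 9), channel_labels = EEG_CHANNELS)
  sc2 <- online_scores(model, stream2)
  for (i in c(1, 5, 11)) {
    end <- round(sc2$t_s[i] * 250)
    manual <- score_epoch(model, stream2$samples[, (end - 499):end])
    expect_equal(sc2$score[i], manual)
  }

  short <- recording(matrix(rnorm(9 * 100), 9), channel_labels = EEG_CHANNELS)
  expect_warning(out <- online_scores(model, short), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("steering uses strict idle-referenced dual thresholds", {
  model <- structure(list(C_idle = 0, TH_l = 1, TH_r = 1), class = "mi_model")
  expect_equal(steering_decision(0, model), "NEUTRAL")
  expect_equal(steering_decision(-1, model), "NEUTRAL")   # exact boundary
  expect_equal(steering_decision(-1.2, model), "LEFT")
  expect_equal(steering_decision(1.2, model), "RIGHT")

  # dyadic-rational thresholds keep the strict boundaries exact
  m2 <- structure(list(C_idle = 0.5, TH_l = 0.25, TH_r = 0.5),
                  class = "mi_model")
  expect_equal(steering_decision(c(0.5, 0.125, 0.25, 1.25, 1.0), m2),
               c("NEUTRAL", "LEFT", "NEUTRAL", "RIGHT", "NEUTRAL"))

  # reflecting scores about C_idle with thresholds swapped mirrors decisions
  set.seed(23)
  cs <- rnorm(200, 0.5, 1)
  swapped <- structure(list(C_idle = 0.5, TH_l = 0.5, TH_r = 0.25),
                       class = "mi_model")
  d1 <- steering_decision(cs, m2)
  d2 <- steering_decision(2 * 0.5 - cs, swapped)
  flip <- c(LEFT = "RIGHT", RIGHT = "LEFT", NEUTRAL = "NEUTRAL")
  expect_equal(unname(flip[d1]), d2)
})

test_that("idle-score renewal averages the renewal-window scores", {
  model <- train_model(make_trials(10, seed = 24))
  set.seed(24)
  idle <- recording(matrix(rnorm(9 * 250 * 6), 9), channel_labels = EEG_CHANNELS)
  renewed <- renew_idle_score(model, idle, duration = 3)
  sc <- online_scores(model, idle)
  expect_equal(renewed$C_idle, mean(sc$score[sc$t_s <= 3]))
  # everything else untouched
  expect_equal(renewed$TH_l, model$TH_l)
  expect_equal(renewed$filter$W, model$filter$W)

  short <- recording(matrix(rnorm(9 * 250), 9), channel_labels = EEG_CHANNELS)
  expect_error(renew_idle_score(model, short, duration = 3), "renewal error")
})

test_that("renewed idle score tracks the generator's idle mean", {
  model <- train_model(make_session_trials(40, seed = 25), TH_l = 0.5, TH_r = 0.5)
  # idle = rest-period signal: full-amplitude rhythms on both C3 and C4
  p <- mi_gen_params(erd_depth = 0)
  set.seed(26)
  idle_scores <- vapply(1:40, function(i)
    score_epoch(model, gen_mi_trial("left", p, 500)$X), numeric(1))
  gen_mean <- mean(idle_scores)
  se <- stats::sd(idle_scores) / sqrt(length(idle_scores))

  long_idle <- gen_training_session(2, p, seed = 27)$recording
  long_idle <- bandpass(long_idle)
  renewed <- renew_idle_score(model, long_idle, duration = 10)
  expect_lt(abs(renewed$C_idle - gen_mean), max(3 * se, 0.3))
})

test_that("threshold adjustment steps by 0.2 and clamps at zero", {
  model <- structure(list(TH_l = 1.0, TH_r = 0.1), class = "mi_model")
  expect_equal(adjust_threshold(model, "left", "+")$TH_l, 1.2)
  expect_warning(m2 <- adjust_threshold(model, "right", "-"), "clamped")
  expect_equal(m2$TH_r, 0)
  # "+" then "-" is the identity
  m3 <- adjust_threshold(adjust_threshold(model, "left", "+"), "left", "-")
  expect_equal(m3$TH_l, 1.0)
})

test_that("serialized models reload and score identically", {
  model <- train_model(make_trials(8, seed = 28), TH_l = 0.7, TH_r = 0.9)
  model$C_idle <- 0.123
  path <- withr::local_tempfile(fileext = ".json")
  write_mi_model(model, path)
  back <- read_mi_model(path)
  expect_equal(back$C_idle, 0.123)
  expect_equal(back$TH_l, 0.7)
  set.seed(28)
  for (i in 1:5) {
    X <- matrix(rnorm(9 * 500), 9)
    expect_equal(score_epoch(back, X), score_epoch(model, X), tolerance = 1e-12)
  }
})
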