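#' Trace-normalized trial covariance
#'
#' The spatial covariance of one band-passed trial, normalized by its trace
#' so trials contribute equally regardless of overall power:
#' \deqn{R_i = \frac{X_i X_i^T}{\mathrm{trace}(X_i X_i^T)}}
#'
#' @param X Numeric matrix, channels x samples, or a [labeled_trial()].
#' @return Symmetric positive-semidefinite matrix with unit trace.
#' @export
trial_covariance <- function(X) {
  if (inherits(X, "bci_trial")) X <- X$X
  X <- as.matrix(X)
  XXt <- tcrossprod(X)
  tr <- sum(diag(XXt))
  if (tr <= 0 || !is.finite(tr)) stop("degenerate trial: zero or non-finite power")
  XXt / tr
}

#' Fit common spatial pattern filters
#'
#' Sums the trace-normalized covariances per class into `SUM_l` and
#' `SUM_r`, then solves the generalized eigenproblem of
#' `(SUM_l, SUM_l + SUM_r)` by whitening. The returned rows are the `m/2`
#' eigenvectors with the largest and the `m/2` with the smallest
#' generalized eigenvalues (those maximize the left/right band-power
#' ratio in the two directions), ordered by decreasing eigenvalue, and
#' scaled so that `W (SUM_l + SUM_r) W^T` has unit diagonal.
#'
#' @param left_trials,right_trials Lists of [labeled_trial()] (or plain
#'   channels x samples matrices) for each class.
#' @param m Even number of spatial components to keep (default 4).
#' @return An object of class `csp_filter` with elements `W` (m x M
#'   matrix), `eigenvalues` (all M generalized eigenvalues, decreasing) and
#'   `selected` (indices of the kept components).
#' @export
csp_fit <- function(left_trials, right_trials, m = 4) {
  if (m %% 2 != 0 || m < 2) stop("`m` must be a positive even integer")
  if (length(left_trials) < 2 || length(right_trials) < 2) {
    stop("at least two trials per class are required")
  }
  sum_l <- Reduce(`+`, lapply(left_trials, trial_covariance))
  sum_r <- Reduce(`+`, lapply(right_trials, trial_covariance))
  M <- nrow(sum_l)
  if (m > M) stop("`m` cannot exceed the channel count")
  comp <- sum_l + sum_r

  ec <- eigen(comp, symmetric = TRUE)
  if (min(ec$values) < 1e-10 * max(ec$values)) {
    # ill-conditioned composite: Tikhonov ridge, then redecompose
    comp <- comp + diag(1e-8 * sum(diag(comp)), M)
    message("csp_fit: composite covariance ill-conditioned; applied ridge")
    ec <- eigen(comp, symmetric = TRUE)
  }
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)  # whitening: P comp P' = I
  S <- P %*% sum_l %*% t(P)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)                  # values in [0, 1], decreasing
  W_full <- t(es$vectors) %*% P                     # rows satisfy w comp w' = 1
  sel <- c(seq_len(m / 2), M - (m / 2):1 + 1)
  structure(
    list(W = W_full[sel, , drop = FALSE],
         eigenvalues = es$values,
         selected = sel),
    class = "csp_filter"
  )
}

#' @export
print.csp_filter <- function(x, ...) {
  cat(sprintf("<csp_filter> %d components over %d channels\n",
              nrow(x$W), ncol(x$W)))
  cat("kept eigenvalues:",
      paste(signif(x$eigenvalues[x$selected], 4), collapse = ", "), "\n")
  invisible(x)
}

#' Log-variance-fraction CSP features
#'
#' Projects a trial through the spatial filter and returns, per component,
#' the natural log of its share of the projected variance:
#' \deqn{F_k = \ln\left(\frac{d_k}{\sum_j d_j}\right), \quad
#'       d = \mathrm{diag}(W R W^T)}
#' with `R` the trace-normalized covariance. `exp(F)` always sums to 1.
#'
#' @param filter A `csp_filter` from [csp_fit()].
#' @param X Trial matrix (channels x samples) or [labeled_trial()].
#' @return Numeric vector of length `m`, all entries `<= 0`.
#' @export
csp_features <- function(filter, X) {
  if (inherits(X, "bci_trial")) X <- X$X
  W <- filter$W
  if (ncol(W) != nrow(X)) {
    stop("channel count of trial does not match the spatial filter")
  }
  R <- trial_covariance(X)
  d <- diag(W %*% R %*% t(W))
  if (any(d <= 0)) stop("degenerate component: zero projected variance")
  log(d / sum(d))
}

#' Train the motor-imagery decoder
#'
#' Fits CSP filters and a linear support vector machine on the
#' log-variance features of the labeled trials. The decision score `c` is
#' the signed distance to the separating hyperplane, oriented so that
#' left-class trials score negative and right-class trials positive (the
#' convention the steering rule assumes). The idle baseline `C_idle` and
#' the steering thresholds `TH_l`/`TH_r` are initialized to defaults and
#' updated later with [renew_idle_score()] and [adjust_threshold()].
#'
#' @param trials List of [labeled_trial()]; both classes must be present.
#' @param m Number of CSP components (even, default 4).
#' @param cost SVM regularization constant (default 1).
#' @param kernel SVM kernel (default `"linear"`; only linear models can be
#'   serialized with [write_mi_model()]).
#' @param C_idle,TH_l,TH_r Initial idle score and steering thresholds.
#' @return An object of class `mi_model`.
#' @export
train_model <- function(trials, m = 4, cost = 1, kernel = "linear",
                        C_idle = 0, TH_l = 1, TH_r = 1) {
  labels <- vapply(trials, function(tr) tr$label, character(1))
  if (length(unique(labels)) < 2) {
    stop("training requires trials from both classes")
  }
  filt <- csp_fit(trials[labels == "left"], trials[labels == "right"], m = m)
  feats <- t(vapply(trials, function(tr) csp_features(filt, tr), numeric(m)))
  y <- factor(labels, levels = c("left", "right"))
  fit <- e1071::svm(feats, y, kernel = kernel, cost = cost, scale = FALSE)
  dv <- attr(stats::predict(fit, feats, decision.values = TRUE),
             "decision.values")[, 1]
  # e1071's decision sign depends on which class it saw first; pin the
  # orientation to left-negative / right-positive
  orient <- if (mean(dv[y == "left"]) < mean(dv[y == "right"])) 1 else -1
  weights <- if (kernel == "linear") {
    list(w = as.numeric(t(fit$coefs) %*% fit$SV) * orient,
         b = -fit$rho * orient)
  } else NULL
  structure(
    list(filter = filt, svm = fit, orient = orient, weights = weights,
         kernel = kernel, cost = cost, m = m, n_train = length(trials),
         C_idle = C_idle, TH_l = TH_l, TH_r = TH_r),
    class = "mi_model"
  )
}

#' @export
print.mi_model <- function(x, ...) {
  cat(sprintf("<mi_model> %d CSP components, %s SVM, trained on %d trials\n",
              x$m, x$kernel, x$n_train))
  cat(sprintf("C_idle = %.4g, TH_l = %.3g, TH_r = %.3g\n",
              x$C_idle, x$TH_l, x$TH_r))
  invisible(x)
}

#' Decision score for one epoch
#'
#' @param model An `mi_model`.
#' @param X Epoch matrix (channels x samples) or [labeled_trial()].
#' @return Signed score `c`: negative leans left, positive leans right.
#' @export
score_epoch <- function(model, X) {
  f <- csp_features(model$filter, X)
  if (!is.null(model$weights)) {
    sum(model$weights$w * f) + model$weights$b
  } else {
    dv <- attr(stats::predict(model$svm, matrix(f, nrow = 1),
                              decision.values = TRUE), "decision.values")[, 1]
    model$orient * dv
  }
}

#' Stratified k-fold cross-validated decoding accuracy
#'
#' CSP and SVM are refitted inside each training fold; held-out trials are
#' classified by the sign of the decision score. Returns the mean held-out
#' accuracy over folds.
#'
#' @param trials List of [labeled_trial()].
#' @param m CSP components (default 4).
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed controlling the fold assignment.
#' @param ... Passed to [train_model()].
#' @return Accuracy fraction in \[0, 1\].
#' @export
cross_validate <- function(trials, m = 4, k = 10, seed = NULL, ...) {
  n <- length(trials)
  if (k > n) stop("`k` cannot exceed the number of trials")
  if (!is.null(seed)) set.seed(seed)
  labels <- vapply(trials, function(tr) tr$label, character(1))
  folds <- integer(n)
  for (cls in unique(labels)) {           # stratified assignment
    idx <- sample(which(labels == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  acc <- vapply(seq_len(k), function(fold) {
    test <- which(folds == fold)
    if (length(test) == 0) return(NA_real_)
    fit <- train_model(trials[-test], m = m, ...)
    pred <- vapply(trials[test],
                   function(tr) if (score_epoch(fit, tr) < 0) "left" else "right",
                   character(1))
    mean(pred == labels[test])
  }, numeric(1))
  mean(acc, na.rm = TRUE)
}

#' Sliding-window online scores
#'
#' Replays the continuous (already referenced and band-passed) stream
#' through the decoder the way the online system does: a `window`-second
#' epoch is scored every `step` seconds. The score timestamped `t` uses
#' the samples in the half-open interval `(t - window, t]`.
#'
#' @param model An `mi_model`.
#' @param stream A [recording()] whose channels match the model's montage.
#' @param window Epoch length in seconds (default 2).
#' @param step Hop in seconds (default 0.2).
#' @return A tibble with columns `t_s` and `score`; zero rows (with a
#'   warning) when the stream is shorter than one window.
#' @export
online_scores <- function(model, stream, window = 2, step = 0.2) {
  stopifnot(inherits(stream, "bci_recording"))
  T_total <- duration(stream)
  if (T_total < window) {
    warning("stream shorter than one scoring window; no scores produced")
    return(tibble::tibble(t_s = numeric(), score = numeric()))
  }
  n_scores <- floor((T_total - window) / step + 1e-9) + 1
  t_s <- window + (seq_len(n_scores) - 1) * step
  win_n <- round(window * stream$rate)
  scores <- vapply(t_s, function(t) {
    end <- round((t - stream$start_time) * stream$rate)
    X <- stream$samples[, (end - win_n + 1):end, drop = FALSE]
    score_epoch(model, X)
  }, numeric(1))
  tibble::tibble(t_s = t_s + stream$start_time, score = scores)
}

#' Idle-referenced dual-threshold steering rule
#'
#' Converts one decoder score into a turning decision by comparing it to
#' the idle baseline:
#' turn LEFT iff `c < C_idle` and `|c - C_idle| > TH_l`;
#' turn RIGHT iff `c > C_idle` and `|c - C_idle| > TH_r`;
#' otherwise NEUTRAL. All inequalities are strict, so boundary scores stay
#' neutral.
#'
#' @param c Decoder score (may be a vector).
#' @param model An `mi_model` carrying `C_idle`, `TH_l`, `TH_r`.
#' @return Character vector over `{"LEFT", "RIGHT", "NEUTRAL"}`.
#' @export
steering_decision <- function(c, model) {
  d <- c - model$C_idle
  out <- rep("NEUTRAL", length(c))
  out[d < 0 & abs(d) > model$TH_l] <- "LEFT"
  out[d > 0 & abs(d) > model$TH_r] <- "RIGHT"
  out
}

#' Renew the idle baseline from a rest stream
#'
#' Scores the first `duration` seconds of an idle-state stream with the
#' usual 2-s/0.2-s sliding window and sets `C_idle` to the mean score.
#' The default renewal window is 3 s; a 10-s window is the conservative
#' variant for long sessions.
#'
#' @param model An `mi_model`.
#' @param stream Idle-state [recording()] (referenced, band-passed).
#' @param duration Renewal window in seconds (default 3).
#' @param window,step Scoring epoch length and hop in seconds.
#' @return The model with `C_idle` replaced; all other fields unchanged.
#' @export
renew_idle_score <- function(model, stream, duration = 3, window = 2,
                             step = 0.2) {
  if (duration(stream) < duration) {
    stop("renewal error: stream shorter than the renewal window")
  }
  sc <- online_scores(model, stream, window = window, step = step)
  sc <- sc[sc$t_s <= stream$start_time + duration + 1e-9, , drop = FALSE]
  if (nrow(sc) == 0) stop("renewal error: no scores inside the renewal window")
  model$C_idle <- mean(sc$score)
  model
}

#' Adjust a steering threshold by one step
#'
#' The on-screen "+"/"-" buttons move the corresponding threshold by a
#' fixed step of 0.2; thresholds are clamped at zero.
#'
#' @param model An `mi_model`.
#' @param side `"left"` or `"right"`.
#' @param direction `"+"` or `"-"`.
#' @param step Step size (default 0.2).
#' @return The model with the threshold updated.
#' @export
adjust_threshold <- function(model, side = c("left", "right"),
                             direction = c("+", "-"), step = 0.2) {
  side <- match.arg(side)
  direction <- match.arg(direction)
  delta <- if (direction == "+") step else -step
  field <- if (side == "left") "TH_l" else "TH_r"
  new_val <- model[[field]] + delta
  if (new_val < 0) {
    warning(sprintf("%s clamped to 0", field))
    new_val <- 0
  }
  model[[field]] <- new_val
  model
}

#' Tidy method for fitted motor-imagery models
#'
#' One row per retained CSP component with its generalized eigenvalue
#' (the left-class share of projected band power) and the SVM weight it
#' receives in the linear decision function.
#'
#' @param x An `mi_model`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `eigenvalue`, `svm_weight`.
#' @method tidy mi_model
#' @export
tidy.mi_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$m),
    eigenvalue = x$filter$eigenvalues[x$filter$selected],
    svm_weight = if (!is.null(x$weights)) x$weights$w else rep(NA_real_, x$m)
  )
}

#' Glance method for fitted motor-imagery models
#'
#' @param x An `mi_model`.
#' @param ... Unused.
#' @return A one-row tibble summarizing the model configuration.
#' @method glance mi_model
#' @export
glance.mi_model <- function(x, ...) {
  tibble::tibble(
    m = x$m, kernel = x$kernel, cost = x$cost, n_train = x$n_train,
    C_idle = x$C_idle, TH_l = x$TH_l, TH_r = x$TH_r
  )
}

#' Plot an online score trace with the steering bands
#'
#' @param object A tibble from [online_scores()].
#' @param model The `mi_model` that produced it (for `C_idle` and the
#'   thresholds).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_scores <- function(object, model, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_s, .data$score)) +
    ggplot2::geom_hline(yintercept = model$C_idle, linetype = 2) +
    ggplot2::geom_hline(yintercept = model$C_idle + c(-model$TH_l, model$TH_r),
                        colour = "darkgreen") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "decoder score c")
}
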