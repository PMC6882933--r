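#' Binomial tail probability of a session result
#'
#' The significance of `a` correct predictions out of `num` two-class
#' trials against 50% guessing, using the strict upper tail
#' `p = P(X > a)` for `X ~ Binomial(num, 0.5)` — i.e.
#' `1 - BinomCDF(a, num, 0.5)`, the convention under which 28/40 correct
#' is the smallest significant session at the Bonferroni level 0.05/9.
#' Computed exactly; no normal approximation.
#'
#' @param a Correctly predicted trial count, `0 <= a <= num`.
#' @param num Trials in the session.
#' @return Tail probability in \[0, 1\].
#' @export
binomial_p <- function(a, num) {
  if (any(a < 0) || any(a > num)) stop("need 0 <= a <= num")
  if (num < 1) stop("num must be at least 1")
  stats::pbinom(a, num, 0.5, lower.tail = FALSE)
}

#' Minimum correct trials for a significant session
#'
#' Smallest `a` whose strict binomial tail falls below `alpha`. With 40
#' trials and the Bonferroni-corrected level 0.05/9 this is 28 correct
#' trials, i.e. a 70% session accuracy floor for statistical
#' significance (distinct from the 50% guessing chance).
#'
#' @param num Trials in a session.
#' @param alpha Significance level in (0, 1).
#' @return Smallest significant correct-trial count.
#' @export
min_correct_for_significance <- function(num, alpha) {
  stopifnot(num >= 1, alpha > 0, alpha <= 1)
  for (a in 0:num) {
    if (binomial_p(a, num) < alpha) return(a)
  }
  stop(sprintf("no attainable a <= %d reaches p < %g", num, alpha))
}

#' Selection performance report
#'
#' Scores a command log against the scripted ground truth: selection
#' accuracy (correct emissions over scripted targets), mean reaction time
#' (emission time minus attempt start), and optionally the
#' pre-verification false positive rate.
#'
#' Each scripted target (`command` rows of the truth table) is matched to
#' the first accepted emission at or after its start and before the next
#' target's start.
#'
#' @param commands Tibble with columns `t_s`, `command` (and optionally
#'   `accepted`, default all accepted).
#' @param truth A [event_table()] whose `command` rows carry the expected
#'   command label at the attempt start time.
#' @param fpr Optional pre-computed [false_positive_rate()] to carry into
#'   the report.
#' @return A one-row tibble `accuracy`, `mean_rt_s`, `fpr_per_min`,
#'   `n_targets`, `n_emitted`.
#' @export
selection_report <- function(commands, truth, fpr = NA_real_) {
  targets <- truth[truth$kind == "command", , drop = FALSE]
  if (nrow(targets) == 0) {
    warning("no scripted command targets in the truth table")
    return(tibble::tibble(accuracy = NA_real_, mean_rt_s = NA_real_,
                          fpr_per_min = fpr, n_targets = 0L,
                          n_emitted = nrow(commands)))
  }
  if (!"accepted" %in% names(commands)) commands$accepted <- TRUE
  emitted <- commands[commands$accepted, , drop = FALSE]
  ends <- c(targets$onset_s[-1], Inf)
  matched <- purrr::map2(targets$onset_s, ends, function(t0, t1) {
    hit <- emitted[emitted$t_s >= t0 & emitted$t_s < t1, , drop = FALSE]
    if (nrow(hit) == 0) NULL else hit[1, ]
  })
  correct <- vapply(seq_along(matched), function(i) {
    !is.null(matched[[i]]) && matched[[i]]$command == targets$label[i]
  }, logical(1))
  rts <- vapply(seq_along(matched), function(i) {
    if (correct[i]) matched[[i]]$t_s - targets$onset_s[i] else NA_real_
  }, numeric(1))
  tibble::tibble(
    accuracy = mean(correct),
    mean_rt_s = mean(rts, na.rm = TRUE),
    fpr_per_min = fpr,
    n_targets = nrow(targets),
    n_emitted = nrow(emitted)
  )
}

#' Misrecognition probability of a spontaneous blink
#'
#' The chance that any one spontaneous blink slips through the
#' intended-blink gate, as the ratio of the pre-verification false
#' positive rate to the user's spontaneous blink rate. At 1.5
#' false positives/min against the normal 10-20 blinks/min this is
#' 7.5-15%.
#'
#' @param fpr False positives per minute, `>= 0`.
#' @param blink_rate Spontaneous blinks per minute, `> 0`.
#' @return Fraction in \[0, 1\].
#' @export
misrecognition_probability <- function(fpr, blink_rate) {
  if (blink_rate <= 0) stop("blink_rate must be positive")
  stopifnot(fpr >= 0)
  fpr / blink_rate
}
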