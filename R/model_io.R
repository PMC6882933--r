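#' Serialize / restore a fitted motor-imagery model
#'
#' The on-disk container is versioned JSON holding the CSP filter matrix,
#' the linear SVM hyperplane (weights and intercept), the idle score, both
#' steering thresholds, and the montage/filter configuration. Only
#' linear-kernel models are serializable; restoring yields a model that
#' scores identically to the original through [score_epoch()].
#'
#' @param model An `mi_model` with `kernel = "linear"`.
#' @param path File path (conventionally `.json`).
#' @param montage Channel labels the model expects (stored for audit).
#' @param filter_band Band edges in Hz stored alongside the model.
#' @return `write_mi_model()` returns `path` invisibly; `read_mi_model()`
#'   returns an `mi_model`.
#' @export
write_mi_model <- function(model, path, montage = EEG_CHANNELS,
                           filter_band = c(8, 30)) {
  stopifnot(inherits(model, "mi_model"))
  if (is.null(model$weights)) {
    stop("only linear-kernel models can be serialized")
  }
  obj <- list(
    format = "hbci-mi-model",
    version = 1L,
    m = model$m,
    W = model$filter$W,
    eigenvalues = model$filter$eigenvalues,
    selected = model$filter$selected,
    svm_w = model$weights$w,
    svm_b = model$weights$b,
    C_idle = model$C_idle,
    TH_l = model$TH_l,
    TH_r = model$TH_r,
    montage = montage,
    filter_band = filter_band
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_mi_model
#' @export
read_mi_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "hbci-mi-model")) {
    stop(sprintf("parse error in %s: not an hbci model container", path))
  }
  if (obj$version != 1) {
    stop(sprintf("unsupported model container version %s", obj$version))
  }
  W <- as.matrix(obj$W)
  if (nrow(W) != obj$m) W <- t(W)
  filt <- structure(
    list(W = W, eigenvalues = obj$eigenvalues, selected = obj$selected),
    class = "csp_filter"
  )
  structure(
    list(filter = filt, svm = NULL, orient = 1,
         weights = list(w = obj$svm_w, b = obj$svm_b),
         kernel = "linear", cost = NA_real_, m = obj$m, n_train = NA_integer_,
         C_idle = obj$C_idle, TH_l = obj$TH_l, TH_r = obj$TH_r,
         montage = obj$montage, filter_band = obj$filter_band),
    class = "mi_model"
  )
}
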