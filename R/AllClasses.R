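#' CxrCase: one chest X-ray case
#'
#' A case holds one or two grayscale radiograph matrices (intensities in
#' \[0, 1\], rows = image height), the planted-abnormality truth table used
#' by the synthetic generator, and patient metadata. Truth boxes use
#' 0-based half-open pixel coordinates \[row0, row1) x \[col0, col1).
#'
#' @slot case_id Character scalar.
#' @slot images List of 1-2 numeric matrices.
#' @slot truths data.frame with columns `category`, `image_index` (1-based),
#'   `row0`, `col0`, `row1`, `col1`, `shape_kind`. Zero rows for a normal case.
#' @slot patient_meta List with elements `sex` ("F"/"M") and `age_group`
#'   (one of "22-44", "45-64", "65-74", "75+").
#'
#' @exportClass CxrCase
setClass("CxrCase",
  representation(case_id = "character", images = "list",
                 truths = "data.frame", patient_meta = "list"))

setValidity("CxrCase", function(object) {
  msg <- character()
  n <- length(object@images)
  if (n < 1L || n > 2L) msg <- c(msg, "a case must contain 1 or 2 images")
  for (im in object@images) {
    if (!is.matrix(im) || !is.numeric(im))
      msg <- c(msg, "images must be numeric matrices")
    else if (anyNA(im) || min(im) < 0 || max(im) > 1)
      msg <- c(msg, "image intensities must lie in [0, 1]")
  }
  tr <- object@truths
  if (nrow(tr) > 0) {
    if (!all(tr$category %in% cxrCategories()))
      msg <- c(msg, "truth categories must be one of the 8 categories")
    for (i in seq_len(nrow(tr))) {
      ii <- tr$image_index[i]
      if (ii < 1 || ii > n) { msg <- c(msg, "truth image_index out of range"); next }
      im <- object@images[[ii]]
      if (tr$row1[i] <= tr$row0[i] || tr$col1[i] <= tr$col0[i])
        msg <- c(msg, "truth box must have positive area")
      if (tr$row0[i] < 0 || tr$col0[i] < 0 ||
          tr$row1[i] > nrow(im) || tr$col1[i] > ncol(im))
        msg <- c(msg, "truth box must lie within its image bounds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' CxrCaseSet: a collection of cases with k-of-n labels
#'
#' Bundles generated (or loaded) cases with the per-category labels of a
#' simulated labeler panel: for each (case, category), `k` of `n` labelers
#' called the category abnormal, and `reference` is the majority-vote
#' reference standard. `labeler_boxes` carries the positive labelers'
#' (jittered) boxes.
#'
#' @slot cases List of [CxrCase-class] objects.
#' @slot labels data.frame with columns `case_id`, `category`, `k`, `n`,
#'   `reference`, `truth` (generator ground truth, when known).
#' @slot labeler_boxes data.frame with columns `case_id`, `category`,
#'   `labeler`, `image_index`, `row0`, `col0`, `row1`, `col1`.
#'
#' @exportClass CxrCaseSet
setClass("CxrCaseSet",
  representation(cases = "list", labels = "data.frame",
                 labeler_boxes = "data.frame"))

setValidity("CxrCaseSet", function(object) {
  msg <- character()
  if (!all(vapply(object@cases, is, logical(1), "CxrCase")))
    msg <- c(msg, "cases must all be CxrCase objects")
  lab <- object@labels
  if (nrow(lab) > 0) {
    if (any(lab$k < 0 | lab$k > lab$n)) msg <- c(msg, "labels must satisfy 0 <= k <= n")
    if (any(lab$n < 1)) msg <- c(msg, "labels must have n >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' CxrModel: the analysis-stage convolutional network
#'
#' Holds the weights and architecture configuration of the case-level
#' network: a convolutional image encoder, a shared projection to the case
#' feature dimension, max-pooling across the 1-2 radiographs of a case, a
#' classification head emitting per-category beta-binomial parameters
#' (alpha, beta), and a 1x1-convolution localization head emitting
#' per-category pixel-probability maps at the encoder's penultimate
#' resolution.
#'
#' @slot params Named list of weight arrays.
#' @slot config Named list; see [modelConfig()].
#' @slot version Character fingerprint of the architecture.
#'
#' @exportClass CxrModel
setClass("CxrModel",
  representation(params = "list", config = "list", version = "character"))

#' CasePrediction: raw model outputs for one case
#'
#' @slot case_id Character scalar.
#' @slot alpha,beta Named numeric vectors (one per category), strictly
#'   positive; parameters of the beta-binomial posterior over k-of-n labels.
#' @slot maps List (one per image) of h x w x 8 arrays of per-category
#'   localization probabilities in \[0, 1\] at the localization-branch
#'   resolution.
#' @slot model_version Character provenance stamp.
#'
#' @exportClass CasePrediction
setClass("CasePrediction",
  representation(case_id = "character", alpha = "numeric", beta = "numeric",
                 maps = "list", model_version = "character"))

setValidity("CasePrediction", function(object) {
  msg <- character()
  if (length(object@alpha) != 8L || length(object@beta) != 8L)
    msg <- c(msg, "alpha and beta must have one entry per category (8)")
  if (any(object@alpha <= 0) || any(object@beta <= 0))
    msg <- c(msg, "alpha and beta must be strictly positive")
  for (m in object@maps)
    if (min(m) < 0 || max(m) > 1)
      msg <- c(msg, "probability-map values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' OperatingPoints: frozen per-category decision and map thresholds
#'
#' Decision thresholds convert the beta-binomial posterior-mean score into
#' the binary abnormality-present determination (score on or above the
#' threshold is "present"); map thresholds binarize localization
#' probability maps for bounding-box extraction. Both are calibrated once
#' on a tuning set and then held fixed.
#'
#' @slot decision_thresholds Named numeric (8).
#' @slot map_thresholds Named numeric (8), values in (0, 1).
#' @slot achieved data.frame of per-category sensitivity/specificity
#'   achieved at calibration.
#' @slot fingerprint List: tuning-set identifier, date, procedure notes.
#'
#' @exportClass OperatingPoints
setClass("OperatingPoints",
  representation(decision_thresholds = "numeric", map_thresholds = "numeric",
                 achieved = "data.frame", fingerprint = "list"))

setValidity("OperatingPoints", function(object) {
  msg <- character()
  if (any(!is.finite(object@decision_thresholds)))
    msg <- c(msg, "decision thresholds must be finite")
  mt <- object@map_thresholds
  if (length(mt) && (any(mt <= 0) || any(mt >= 1)))
    msg <- c(msg, "map thresholds must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' DbmResult: Dorfman-Berbaum-Metz MRMC analysis result
#'
#' @slot ls_mean_auc_unaided,ls_mean_auc_aided Least-squares mean AUCs
#'   (means of jackknife pseudovalues) per condition.
#' @slot difference Aided minus unaided LS-mean AUC.
#' @slot ci_low,ci_high 95% confidence bounds on the difference.
#' @slot f_statistic,ddf,p_value Treatment F test (numerator df 1) with
#'   its denominator degrees of freedom.
#' @slot anova data.frame: the pseudovalue ANOVA mean squares, for audit.
#'
#' @exportClass DbmResult
setClass("DbmResult",
  representation(ls_mean_auc_unaided = "numeric", ls_mean_auc_aided = "numeric",
                 difference = "numeric", ci_low = "numeric", ci_high = "numeric",
                 f_statistic = "numeric", ddf = "numeric", p_value = "numeric",
                 anova = "data.frame"))
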