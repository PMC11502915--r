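#' Accessors for case collections
#'
#' @param x A [CxrCaseSet-class] (or, for `caseImages`, a [CxrCase-class]).
#' @param ... Unused.
#' @return `cxrCases` returns the list of cases; `caseLabels` the k-of-n
#'   label table; `nCases` the number of cases.
#' @export
setGeneric("cxrCases", function(x, ...) standardGeneric("cxrCases"))

#' @rdname cxrCases
#' @export
setGeneric("caseLabels", function(x, ...) standardGeneric("caseLabels"))

#' @rdname cxrCases
#' @export
setGeneric("nCases", function(x, ...) standardGeneric("nCases"))

#' @rdname cxrCases
#' @export
setGeneric("caseImages", function(x, ...) standardGeneric("caseImages"))

#' Predict model outputs for cases
#'
#' @param object A [CxrModel-class].
#' @param cases A [CxrCaseSet-class] or list of [CxrCase-class] objects
#'   (images must already be standardized to the model's input shape).
#' @param ... Passed to methods.
#' @return List of [CasePrediction-class] objects.
#' @export
setGeneric("predictCases", function(object, cases, ...)
  standardGeneric("predictCases"))

setMethod("cxrCases", "CxrCaseSet", function(x, ...) x@cases)
setMethod("caseLabels", "CxrCaseSet", function(x, ...) x@labels)
setMethod("nCases", "CxrCaseSet", function(x, ...) length(x@cases))
setMethod("caseImages", "CxrCase", function(x, ...) x@images)

setMethod("show", "CxrCase", function(object) {
  dims <- vapply(object@images, function(im) paste(dim(im), collapse = "x"), "")
  cat("CxrCase", object@case_id, "|", length(object@images), "image(s):",
      paste(dims, collapse = ", "), "|", nrow(object@truths),
      "planted abnormality(ies)\n")
})

setMethod("show", "CxrCaseSet", function(object) {
  cat("CxrCaseSet with", length(object@cases), "cases\n")
  if (nrow(object@labels)) {
    pos <- tapply(object@labels$reference, object@labels$category, mean)
    cat("  reference-positive fraction by category:\n")
    for (g in cxrCategories())
      cat(sprintf("    %-17s %.3f\n", g, pos[[g]]))
  }
})

setMethod("show", "CxrModel", function(object) {
  cfg <- object@config
  cat("CxrModel (", object@version, ")\n", sep = "")
  cat("  input ", cfg$input_height, "x", cfg$input_width,
      " | encoder channels ", paste(cfg$channels, collapse = "-"),
      " | image feature dim ", cfg$image_feature_dim,
      " | case feature dim ", cfg$case_feature_dim, "\n", sep = "")
})

setMethod("show", "CasePrediction", function(object) {
  cat("CasePrediction", object@case_id, "\n")
  s <- object@alpha / (object@alpha + object@beta)
  for (g in cxrCategories())
    cat(sprintf("  %-17s score %.3f (alpha %.2f, beta %.2f)\n",
                g, s[[g]], object@alpha[[g]], object@beta[[g]]))
})

setMethod("show", "OperatingPoints", function(object) {
  cat("OperatingPoints (frozen", object@fingerprint$date %||% "", ")\n")
  for (g in names(object@decision_thresholds))
    cat(sprintf("  %-17s decision %.4f  map %.3f\n", g,
                object@decision_thresholds[[g]],
                object@map_thresholds[[g]] %||% NA_real_))
})

setMethod("show", "DbmResult", function(object) {
  cat("DBM MRMC analysis (condition fixed; readers, cases random)\n")
  cat(sprintf("  LS mean AUC unaided: %.4f  aided: %.4f\n",
              object@ls_mean_auc_unaided, object@ls_mean_auc_aided))
  cat(sprintf("  difference (aided - unaided): %.4f  95%% CI [%.4f, %.4f]\n",
              object@difference, object@ci_low, object@ci_high))
  cat(sprintf("  F(1, %.1f) = %.3f, p = %.4g\n",
              object@ddf, object@f_statistic, object@p_value))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
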