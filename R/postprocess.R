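#' Posterior-mean point estimate
#'
#' The mean `alpha/(alpha+beta)` of the beta-binomial posterior is the
#' continuous score post-processing thresholds into the binary
#' determination.
#'
#' @param alpha,beta Strictly positive parameters (vectorized).
#' @return Scores in (0, 1).
#' @export
#' @examples
#' pointEstimate(9, 1)  # 0.9
pointEstimate <- function(alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0))
    stop("alpha and beta must be strictly positive", call. = FALSE)
  alpha / (alpha + beta)
}

# Exhaustive candidate scan: midpoints of adjacent sorted unique scores
# plus sentinels below/above all scores.
candidateThresholds <- function(scores) {
  u <- sort(unique(scores))
  c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
}

sensSpecAt <- function(scores, labels, thr) {
  pos <- labels == 1
  c(sens = mean(scores[pos] >= thr), spec = mean(scores[!pos] < thr))
}

#' Calibrate per-category decision thresholds on a tuning set
#'
#' For each category the threshold is chosen to equalize sensitivity and
#' specificity on the tuning set: among the candidate thresholds (midpoints
#' of adjacent sorted unique scores, with sentinels), the one minimizing
#' `|sensitivity - specificity|` is selected, ties broken toward higher
#' sensitivity (lower threshold). The thresholds are then frozen.
#'
#' @param tune_scores data.frame with `case_id`, `category`, `score`
#'   (e.g. from [scoreTable()]).
#' @param tune_reference data.frame with `case_id`, `category`,
#'   `reference`.
#' @param map_thresholds Optional named numeric of per-category map
#'   binarization thresholds (see [calibrateMapThresholds()]); defaults
#'   to 0.5.
#' @param tune_id Identifier stored in the calibration fingerprint.
#' @return An [OperatingPoints-class].
#' @export
calibrateThresholds <- function(tune_scores, tune_reference,
                                map_thresholds = NULL, tune_id = "tune") {
  merged <- merge(tune_scores, tune_reference,
                  by = c("case_id", "category"))
  cats <- cxrCategories()
  thr <- setNames(numeric(8L), cats)
  ach <- data.frame(category = cats, sensitivity = NA_real_,
                    specificity = NA_real_, stringsAsFactors = FALSE)
  for (gi in seq_along(cats)) {
    sub <- merged[merged$category == cats[gi], ]
    if (!any(sub$reference == 1) || !any(sub$reference == 0))
      stop("calibration error: category '", cats[gi],
           "' lacks a positive or a negative tuning case", call. = FALSE)
    cand <- candidateThresholds(sub$score)
    ss <- vapply(cand, sensSpecAt, numeric(2), scores = sub$score,
                 labels = sub$reference)
    gap <- abs(ss["sens", ] - ss["spec", ])
    # ties toward higher sensitivity = smallest threshold among minima
    best <- which(gap == min(gap))[1]
    thr[gi] <- cand[best]
    ach$sensitivity[gi] <- ss["sens", best]
    ach$specificity[gi] <- ss["spec", best]
  }
  mt <- map_thresholds %||% setNames(rep(0.5, 8L), cats)
  new("OperatingPoints", decision_thresholds = thr,
      map_thresholds = mt[cats], achieved = ach,
      fingerprint = list(tune_id = tune_id, date = format(Sys.Date()),
                         procedure = "equal sensitivity/specificity"))
}

#' Calibrate map-binarization thresholds on a tuning set
#'
#' For each category, scans a threshold grid and keeps the value
#' maximizing the mean set-union IoU between extracted boxes and truth
#' boxes over the reference-positive tuning cases.
#'
#' @param predictions List of [CasePrediction-class] for the tuning cases.
#' @param tune_set The tuning [CxrCaseSet-class] (standardized).
#' @param grid Candidate thresholds in (0, 1).
#' @param min_area_frac Passed to [extractBoxes()].
#' @return Named numeric vector of per-category thresholds.
#' @export
calibrateMapThresholds <- function(predictions, tune_set,
                                   grid = seq(0.2, 0.8, by = 0.1),
                                   min_area_frac = 5e-4) {
  cats <- cxrCategories()
  lab <- caseLabels(tune_set)
  ids <- vapply(predictions, function(p) p@case_id, "")
  out <- setNames(rep(0.5, 8L), cats)
  for (gi in seq_along(cats)) {
    pos_ids <- lab$case_id[lab$category == cats[gi] & lab$reference == 1]
    idx <- which(ids %in% pos_ids)
    if (!length(idx)) next
    mean_iou <- vapply(grid, function(th) {
      ious <- vapply(idx, function(i) {
        cs <- tune_set@cases[[which(vapply(tune_set@cases, function(x)
          x@case_id, "") == ids[i])]]
        tr <- cs@truths[cs@truths$category == cats[gi], , drop = FALSE]
        if (!nrow(tr)) return(NA_real_)
        pb <- list()
        for (ii in seq_along(cs@images)) {
          up <- upsampleMap(predictions[[i]]@maps[[ii]][, , gi],
                            nrow(cs@images[[ii]]), ncol(cs@images[[ii]]))
          bx <- extractBoxes(up, th, cats[gi], min_area_frac = min_area_frac)
          if (nrow(bx)) pb[[length(pb) + 1L]] <- bx
        }
        pb <- if (length(pb)) do.call(rbind, pb) else
          data.frame(row0 = numeric(), col0 = numeric(),
                     row1 = numeric(), col1 = numeric())
        summedIoU(pb, tr[, c("row0", "col0", "row1", "col1")])
      }, numeric(1))
      mean(ious, na.rm = TRUE)
    }, numeric(1))
    if (any(is.finite(mean_iou))) out[gi] <- grid[which.max(mean_iou)]
  }
  out
}

#' Binary abnormality determination
#'
#' Present exactly when the score lies on or above the frozen category
#' threshold (the boundary is inclusive).
#'
#' @param score Numeric scores.
#' @param operating_points An [OperatingPoints-class].
#' @param category Category name.
#' @return Character vector, `"present"` or `"absent"`.
#' @export
binaryDetermination <- function(score, operating_points, category) {
  thr <- operating_points@decision_thresholds[[category]]
  ifelse(score >= thr, "present", "absent")
}

#' Extract bounding boxes from a probability map
#'
#' Binarizes the (image-resolution) map at the category's threshold,
#' labels 4-connected components, drops components smaller than
#' `min_area_frac` of the image area, and returns the tight bounding box
#' of each surviving component with the maximum map value inside as its
#' score. Boxes use 0-based half-open coordinates.
#'
#' @param probability_map Numeric matrix in \[0, 1\] at image resolution.
#' @param map_threshold Binarization threshold in (0, 1).
#' @param category Category name attached to the boxes.
#' @param min_area_frac Minimum component area as a fraction of image area
#'   (default 0.05%).
#' @return data.frame with columns `category`, `row0`, `col0`, `row1`,
#'   `col1`, `score` (possibly zero rows).
#' @export
extractBoxes <- function(probability_map, map_threshold, category = "ROI",
                         min_area_frac = 5e-4) {
  stopifnot(map_threshold > 0, map_threshold < 1)
  mask <- probability_map >= map_threshold
  empty <- data.frame(category = character(), row0 = numeric(),
                      col0 = numeric(), row1 = numeric(), col1 = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask * 1)
  min_area <- min_area_frac * length(probability_map)
  out <- list()
  for (id in seq_len(max(lab))) {
    sel <- lab == id
    if (sum(sel) < min_area) next
    pos <- which(sel, arr.ind = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      category = category,
      row0 = min(pos[, 1]) - 1, col0 = min(pos[, 2]) - 1,
      row1 = max(pos[, 1]), col1 = max(pos[, 2]),
      score = max(probability_map[sel]), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Apply post-processing to model predictions
#'
#' Converts raw [CasePrediction-class] outputs into the device's two
#' per-category outputs: the binary determination at the frozen decision
#' threshold, and bounding boxes extracted from the upsampled localization
#' maps at the frozen map thresholds. A "present" determination with no
#' boxes raises a warning (coupling of boxes to presence is heuristic).
#'
#' @param predictions List of [CasePrediction-class].
#' @param cases Matching [CxrCaseSet-class] or list of cases (for image
#'   geometry).
#' @param operating_points An [OperatingPoints-class].
#' @param min_area_frac Passed to [extractBoxes()].
#' @param warn_empty_present Warn on present-with-no-boxes.
#' @return data.frame: one row per (case, category) with `score`,
#'   `determination`, `n_boxes`; attribute `"boxes"` holds the box table.
#' @export
applyOperatingPoints <- function(predictions, cases, operating_points,
                                 min_area_frac = 5e-4,
                                 warn_empty_present = TRUE) {
  case_list <- if (is(cases, "CxrCaseSet")) cases@cases else cases
  ids <- vapply(case_list, function(x) x@case_id, "")
  rows <- list(); boxes <- list()
  for (pr in predictions) {
    cs <- case_list[[match(pr@case_id, ids)]]
    s <- pointEstimate(pr@alpha, pr@beta)
    for (g in cxrCategories()) {
      det <- binaryDetermination(s[[g]], operating_points, g)
      bx <- list()
      for (ii in seq_along(cs@images)) {
        up <- upsampleMap(pr@maps[[ii]][, , g],
                          nrow(cs@images[[ii]]), ncol(cs@images[[ii]]))
        b <- extractBoxes(up, operating_points@map_thresholds[[g]], g,
                          min_area_frac = min_area_frac)
        if (nrow(b)) { b$image_index <- ii; bx[[length(bx) + 1L]] <- b }
      }
      nb <- if (length(bx)) sum(vapply(bx, nrow, 0L)) else 0L
      if (det == "present" && nb == 0L && warn_empty_present)
        warning("case ", pr@case_id, " category '", g,
                "': present determination with no boxes", call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = pr@case_id, category = g, score = s[[g]],
        determination = det, n_boxes = nb, stringsAsFactors = FALSE)
      if (length(bx)) {
        bt <- do.call(rbind, bx); bt$case_id <- pr@case_id
        boxes[[length(boxes) + 1L]] <- bt
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "boxes") <- if (length(boxes)) do.call(rbind, boxes) else NULL
  out
}
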