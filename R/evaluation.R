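#' ROC area under the curve
#'
#' Trapezoidal AUC, computed as the normalized Mann-Whitney U statistic
#' with ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1) with both classes present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 1, 0, 1))  # 0.75
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0L || N == 0L)
    stop("undefined metric: labels must contain both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Micro-averaged overall metrics
#'
#' Pools every (case, category) score/label pair from all categories into
#' one vector before computing the overall AUC; pooled binary
#' determinations at the per-category frozen thresholds give the overall
#' sensitivity and specificity.
#'
#' @param per_category_scores Named list (over categories) of score
#'   vectors, cases aligned within each category.
#' @param per_category_labels Named list of matching binary label vectors.
#' @param thresholds Optional named per-category decision thresholds; when
#'   supplied, pooled sensitivity/specificity are computed from the
#'   per-category determinations (score on/above threshold is positive).
#' @return List: `auc`, `sensitivity`, `specificity` (the last two `NA`
#'   without thresholds).
#' @export
microAverage <- function(per_category_scores, per_category_labels,
                         thresholds = NULL) {
  cats <- names(per_category_scores)
  stopifnot(identical(cats, names(per_category_labels)))
  scores <- unlist(per_category_scores, use.names = FALSE)
  labels <- unlist(per_category_labels, use.names = FALSE)
  auc <- rocAuc(scores, labels)
  sens <- spec <- NA_real_
  if (!is.null(thresholds)) {
    det <- unlist(lapply(cats, function(g)
      per_category_scores[[g]] >= thresholds[[g]]), use.names = FALSE)
    sens <- mean(det[labels == 1])
    spec <- mean(!det[labels == 0])
  }
  list(auc = auc, sensitivity = sens, specificity = spec)
}

#' Case-resampled bootstrap percentile confidence interval
#'
#' Resamples whole cases with replacement (all of a case's category
#' observations move together), recomputes the metric on each of `m`
#' replicates, and returns the percentile interval. Deterministic for a
#' fixed seed. Replicates on which the metric is undefined (e.g. a
#' one-class resample) are skipped, up to `max_skip_frac` of `m`.
#'
#' @param metric_fn Function taking a vector of case indices (with
#'   repetition) and returning a scalar; or, if `cases` is supplied, a
#'   function of the resampled case subset.
#' @param n_cases Number of cases to resample.
#' @param m Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @param max_skip_frac Maximum tolerated fraction of skipped replicates.
#' @return Named numeric: `low`, `high`.
#' @export
bootstrapCI <- function(metric_fn, n_cases, m = 1000L, seed = 1L,
                        conf = 0.95, max_skip_frac = 0.2) {
  stopifnot(m >= 1)
  set.seed(childSeed(seed, 71L))
  vals <- numeric(m); skipped <- 0L
  for (b in seq_len(m)) {
    idx <- sample.int(n_cases, n_cases, replace = TRUE)
    v <- tryCatch(metric_fn(idx), error = function(e) NA_real_)
    if (is.na(v)) { skipped <- skipped + 1L; vals[b] <- NA } else vals[b] <- v
  }
  if (skipped > max_skip_frac * m)
    stop("more than ", round(100 * max_skip_frac),
         "% of bootstrap replicates were degenerate", call. = FALSE)
  q <- stats::quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       na.rm = TRUE, names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

rectUnionCells <- function(boxes, xs, ys) {
  inP <- matrix(FALSE, length(xs) - 1, length(ys) - 1)
  for (i in seq_len(NROW(boxes))) {
    xr <- which(xs[-length(xs)] >= boxes$row0[i] & xs[-1] <= boxes$row1[i])
    yr <- which(ys[-length(ys)] >= boxes$col0[i] & ys[-1] <= boxes$col1[i])
    inP[xr, yr] <- TRUE
  }
  inP
}

#' Intersection-over-union of predicted and reference box sets
#'
#' The headline value uses set semantics: the pixel regions covered by the
#' union of the predicted boxes (P) and of the reference boxes (R) give
#' `|P intersect R| / |P union R|`, so overlapping boxes within one side
#' are not double-counted. The raw summed-area variant (total predicted
#' area and total reference area found by summing individual box areas)
#' is available via `semantics = "summed"` for reporting transparency.
#'
#' @param pred_boxes,ref_boxes data.frames with columns `row0`, `col0`,
#'   `row1`, `col1` (same coordinate frame, 0-based half-open); zero rows
#'   allowed.
#' @param semantics `"set"` (default) or `"summed"`.
#' @return IoU in \[0, 1\]; `NA` when both sets are empty (undefined,
#'   excluded from aggregation).
#' @export
#' @examples
#' a <- data.frame(row0 = 0, col0 = 0, row1 = 10, col1 = 10)
#' b <- data.frame(row0 = 5, col0 = 0, row1 = 15, col1 = 10)
#' summedIoU(a, b)  # 50 / 150
summedIoU <- function(pred_boxes, ref_boxes,
                      semantics = c("set", "summed")) {
  semantics <- match.arg(semantics)
  np <- NROW(pred_boxes); nr <- NROW(ref_boxes)
  if (np == 0L && nr == 0L) return(NA_real_)
  if (np == 0L || nr == 0L) return(0)
  pred_boxes <- as.data.frame(pred_boxes); ref_boxes <- as.data.frame(ref_boxes)
  xs <- sort(unique(c(pred_boxes$row0, pred_boxes$row1,
                      ref_boxes$row0, ref_boxes$row1)))
  ys <- sort(unique(c(pred_boxes$col0, pred_boxes$col1,
                      ref_boxes$col0, ref_boxes$col1)))
  area <- outer(diff(xs), diff(ys))
  inP <- rectUnionCells(pred_boxes, xs, ys)
  inR <- rectUnionCells(ref_boxes, xs, ys)
  inter <- sum(area[inP & inR])
  if (semantics == "set") {
    inter / sum(area[inP | inR])
  } else {
    boxArea <- function(b) sum((b$row1 - b$row0) * (b$col1 - b$col0))
    sp <- boxArea(pred_boxes); sr <- boxArea(ref_boxes)
    inter / (sp + sr - inter)
  }
}

#' Stratified sensitivity or AUC with bootstrap confidence intervals
#'
#' Computes the metric within each stratum of a case-level partition
#' (e.g. planted shape kind, patient sex, age group, image count) with a
#' case-resampled bootstrap CI. Strata observed on `min_count` cases or
#' fewer are suppressed (reported with `NA`), mirroring the rule that only
#' abnormalities found on over 20 cases are analyzed.
#'
#' @param table data.frame with one row per (case, category) carrying
#'   `case_id`, `reference` (0/1), and either `score` (for
#'   `metric = "auc"`) or `positive_call` (0/1, for sensitivity), plus a
#'   stratum column.
#' @param stratum_col Name of the stratum column (constant within case).
#' @param metric `"sensitivity"` or `"auc"`.
#' @param min_count Suppression threshold (default 20: strata need more
#'   than 20 cases).
#' @param m,seed Bootstrap replicates and seed.
#' @return data.frame: stratum, n_cases, value, ci_low, ci_high.
#' @export
subsetSensitivity <- function(table, stratum_col, metric = c("sensitivity", "auc"),
                              min_count = 20L, m = 200L, seed = 1L) {
  metric <- match.arg(metric)
  strata <- unique(table[[stratum_col]])
  out <- lapply(strata, function(s) {
    sub <- table[table[[stratum_col]] == s, ]
    ids <- unique(sub$case_id)
    n <- length(ids)
    if (n <= min_count)
      return(data.frame(stratum = s, n_cases = n, value = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    by_case <- split(seq_len(nrow(sub)), match(sub$case_id, ids))
    calc <- function(case_idx) {
      rows <- unlist(by_case[case_idx], use.names = FALSE)
      d <- sub[rows, ]
      if (metric == "sensitivity") {
        pos <- d$reference == 1
        if (!any(pos)) return(NA_real_)
        mean(d$positive_call[pos])
      } else {
        if (length(unique(d$reference)) < 2L) return(NA_real_)
        rocAuc(d$score, d$reference)
      }
    }
    v <- calc(seq_len(n))
    ci <- bootstrapCI(calc, n, m = m, seed = seed)
    data.frame(stratum = s, n_cases = n, value = v,
               ci_low = ci[["low"]], ci_high = ci[["high"]])
  })
  do.call(rbind, out)
}

#' Standalone performance report
#'
#' Per-category and micro-averaged overall AUC, sensitivity and
#' specificity (at the frozen operating points) with case-resampled
#' bootstrap confidence intervals, plus the per-category mean IoU between
#' predicted and reference boxes over true-positive cases.
#'
#' @param determinations Output of [applyOperatingPoints()] (with its
#'   `"boxes"` attribute) for the test cases.
#' @param case_set The test [CxrCaseSet-class].
#' @param m,seed Bootstrap replicates (default 1000) and seed.
#' @return List with `metrics` (data.frame, one row per category plus
#'   `"Overall"`: n_pos, auc, sensitivity, specificity and their CIs) and
#'   `iou` (per-category mean true-positive IoU, set semantics, with the
#'   raw summed-area variant alongside).
#' @export
evaluateStandalone <- function(determinations, case_set, m = 1000L, seed = 1L) {
  lab <- caseLabels(case_set)
  d <- merge(determinations, lab[, c("case_id", "category", "reference")],
             by = c("case_id", "category"))
  d$positive_call <- as.integer(d$determination == "present")
  ids <- unique(d$case_id)
  by_case <- split(seq_len(nrow(d)), match(d$case_id, ids))
  cats <- cxrCategories()

  metricRow <- function(sub_fn, name) {
    calc <- function(what) function(case_idx) {
      rows <- unlist(by_case[case_idx], use.names = FALSE)
      s <- sub_fn(d[rows, ])
      if (length(unique(s$reference)) < 2L && what == "auc") return(NA_real_)
      switch(what,
        auc = rocAuc(s$score, s$reference),
        sens = if (!any(s$reference == 1)) NA_real_ else
          mean(s$positive_call[s$reference == 1]),
        spec = if (!any(s$reference == 0)) NA_real_ else
          mean(1 - s$positive_call[s$reference == 0]))
    }
    full <- sub_fn(d)
    n <- length(ids)
    row <- data.frame(category = name, n_pos = sum(full$reference == 1),
                      auc = calc("auc")(seq_len(n)),
                      sensitivity = calc("sens")(seq_len(n)),
                      specificity = calc("spec")(seq_len(n)))
    for (w in c("auc", "sens", "spec")) {
      ci <- bootstrapCI(calc(w), n, m = m, seed = childSeed(seed, match(w, c("auc", "sens", "spec"))))
      row[[paste0(w, "_ci_low")]] <- ci[["low"]]
      row[[paste0(w, "_ci_high")]] <- ci[["high"]]
    }
    row
  }

  metrics <- do.call(rbind, c(
    lapply(cats, function(g) metricRow(function(x) x[x$category == g, ], g)),
    list(metricRow(identity, "Overall"))))

  # localization: mean set-IoU over true positives per category
  boxes <- attr(determinations, "boxes")
  iou <- do.call(rbind, lapply(cats, function(g) {
    tp <- d$case_id[d$category == g & d$reference == 1 & d$positive_call == 1]
    vals <- vapply(tp, function(id) {
      cs <- case_set@cases[[match(id, vapply(case_set@cases, function(x)
        x@case_id, ""))]]
      tr <- cs@truths[cs@truths$category == g, , drop = FALSE]
      pb <- if (is.null(boxes)) NULL else
        boxes[boxes$case_id == id & boxes$category == g, , drop = FALSE]
      if (!nrow(tr) && (is.null(pb) || !nrow(pb))) return(NA_real_)
      summedIoU(pb %||% data.frame(), tr[, c("row0", "col0", "row1", "col1")])
    }, numeric(1))
    data.frame(category = g, n_tp = length(tp),
               mean_iou = mean(vals, na.rm = TRUE),
               mean_iou_summed = mean(vapply(tp, function(id) {
                 cs <- case_set@cases[[match(id, vapply(case_set@cases,
                   function(x) x@case_id, ""))]]
                 tr <- cs@truths[cs@truths$category == g, , drop = FALSE]
                 pb <- if (is.null(boxes)) NULL else
                   boxes[boxes$case_id == id & boxes$category == g, , drop = FALSE]
                 if (!nrow(tr) && (is.null(pb) || !nrow(pb))) return(NA_real_)
                 summedIoU(pb %||% data.frame(),
                           tr[, c("row0", "col0", "row1", "col1")],
                           semantics = "summed")
               }, numeric(1)), na.rm = TRUE))
  }))
  list(metrics = metrics, iou = iou)
}
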