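#' Reader-study design configuration
#'
#' Defaults reproduce the reference crossover design: 24 physicians (6
#' radiologists, 6 internal, 6 family, 6 emergency medicine), 238 cases
#' (190 with at least one abnormality, 48 normal), two sessions with the
#' aided/unaided condition crossed over, overall micro-averaged AUC
#' targets 0.773 unaided and 0.874 aided, and median read times of
#' 107/98.5 s (non-radiologists) and 69.5/67.5 s (radiologists) for
#' unaided/aided reads.
#'
#' @param n_readers_per_specialty Named integer vector over
#'   radiology/internal/family/emergency.
#' @param n_abnormal,n_normal Case counts.
#' @param auc_unaided,auc_aided Target overall AUCs; setting them equal
#'   gives a null (no aided effect) design.
#' @param reader_sd Reader skill spread (separation scale).
#' @param case_sd Case difficulty spread (induces within-case correlation).
#' @param time_median_unaided,time_median_aided Named (`radiology`,
#'   `other`) median read times in seconds.
#' @param prevalence Per-category positive prevalence among cases.
#' @return A list of class `StudyDesignConfig`.
#' @export
studyDesignConfig <- function(n_readers_per_specialty = c(radiology = 6L,
                                                          internal = 6L,
                                                          family = 6L,
                                                          emergency = 6L),
                              n_abnormal = 190L, n_normal = 48L,
                              auc_unaided = 0.773, auc_aided = 0.874,
                              reader_sd = 0.15, case_sd = 0.5,
                              time_median_unaided = c(radiology = 69.5, other = 107),
                              time_median_aided = c(radiology = 67.5, other = 98.5),
                              prevalence = c(Cardiac = 0.3193,
                                             `Mediastinum/Hila` = 0.2269,
                                             Lungs = 0.6331, Pleura = 0.3221,
                                             Bones = 0.1443,
                                             `Soft Tissues` = 0.0476,
                                             Hardware = 0.5042,
                                             Other = 0.1092)) {
  if (sum(n_readers_per_specialty) < 1L)
    stop("configuration error: at least one reader is required", call. = FALSE)
  if (n_abnormal + n_normal < 2L)
    stop("configuration error: at least two cases are required", call. = FALSE)
  structure(list(n_readers = n_readers_per_specialty,
                 n_abnormal = as.integer(n_abnormal),
                 n_normal = as.integer(n_normal),
                 auc_unaided = auc_unaided, auc_aided = auc_aided,
                 reader_sd = reader_sd, case_sd = case_sd,
                 time_median_unaided = time_median_unaided,
                 time_median_aided = time_median_aided,
                 prevalence = prevalence[cxrCategories()]),
            class = "StudyDesignConfig")
}

#' Assign crossover conditions to reader-case pairs
#'
#' For every reader, session 1 reads a randomly stratified half of the
#' cases aided and the other half unaided (odd strata split within one);
#' session 2 reads every case in the opposite condition. Deterministic
#' for a fixed seed.
#'
#' @param case_ids Character vector (>= 2 cases).
#' @param reader_ids Character vector.
#' @param strata Stratification key per case (default: one stratum);
#'   typically reference positivity.
#' @param seed Integer seed.
#' @return data.frame: `reader_id`, `case_id`, `session1_condition`.
#' @export
assignConditions <- function(case_ids, reader_ids, strata = NULL, seed = 1L) {
  if (length(case_ids) < 2L)
    stop("configuration error: need at least two cases", call. = FALSE)
  if (length(reader_ids) < 1L)
    stop("configuration error: need at least one reader", call. = FALSE)
  strata <- strata %||% rep(1L, length(case_ids))
  set.seed(childSeed(seed, 41L))
  out <- lapply(reader_ids, function(rd) {
    cond <- character(length(case_ids))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      n_aid <- length(idx) %/% 2L + sample(0:1, 1L) * (length(idx) %% 2L)
      aided <- idx[sample.int(length(idx), n_aid)]
      cond[idx] <- "unaided"; cond[aided] <- "aided"
    }
    data.frame(reader_id = rd, case_id = case_ids,
               session1_condition = cond, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a synthetic MRMC reader-study table
#'
#' Simulates the crossover study: per-case per-category reference labels,
#' a latent-signal confidence model with reader skill and case difficulty
#' random effects (binormal separation calibrated to the configured
#' unaided/aided AUC targets), confidence scores on the 0-100 scale, and
#' log-normal read times with the configured condition effect. Each
#' (reader, case, category) appears exactly once per condition, sessions
#' condition-complementary.
#'
#' @param design A [studyDesignConfig()].
#' @param seed Integer seed.
#' @return data.frame with columns `reader_id`, `specialty`, `case_id`,
#'   `session`, `condition`, `category`, `confidence`, `read_time_s`,
#'   `reference`.
#' @export
generateReaderStudy <- function(design = studyDesignConfig(), seed = 1L) {
  stopifnot(inherits(design, "StudyDesignConfig"))
  set.seed(childSeed(seed, 53L))
  cats <- cxrCategories()
  n_case <- design$n_abnormal + design$n_normal
  case_ids <- sprintf("case%04d", seq_len(n_case))

  # reference labels: abnormal cases have >= 1 positive category
  ref <- matrix(0L, n_case, 8L, dimnames = list(case_ids, cats))
  for (i in seq_len(design$n_abnormal)) {
    repeat {
      v <- stats::rbinom(8L, 1L, design$prevalence)
      if (any(v == 1L)) break
    }
    ref[i, ] <- v
  }

  specs <- rep(names(design$n_readers), design$n_readers)
  reader_ids <- sprintf("reader%02d", seq_along(specs))
  delta <- c(unaided = sqrt(2) * stats::qnorm(design$auc_unaided),
             aided = sqrt(2) * stats::qnorm(design$auc_aided))
  r_eff <- stats::rnorm(length(reader_ids), 0, design$reader_sd)
  v_case <- matrix(stats::rnorm(n_case * 8L, 0, design$case_sd), n_case, 8L)
  sd_e <- sqrt(max(1 - design$case_sd^2, 0.05))
  t_reader <- stats::rnorm(length(reader_ids), 0, 0.15)

  asg <- assignConditions(case_ids, reader_ids,
                          strata = as.integer(rowSums(ref) > 0),
                          seed = childSeed(seed, 59L))
  key <- paste(asg$reader_id, asg$case_id)
  s1cond <- setNames(asg$session1_condition, key)

  rows <- vector("list", 2L * length(reader_ids))
  ri <- 0L
  for (j in seq_along(reader_ids)) {
    for (session in 1:2) {
      cond1 <- s1cond[paste(reader_ids[j], case_ids)]
      cond <- if (session == 1L) cond1 else
        ifelse(cond1 == "aided", "unaided", "aided")
      d <- delta[cond] + r_eff[j]
      lat <- sweep(v_case + matrix(stats::rnorm(n_case * 8L, 0, sd_e),
                                   n_case, 8L),
                   1L, 0, "+") + d * ref
      conf <- round(100 * stats::pnorm(lat / 1.5 - 0.35))
      med <- ifelse(specs[j] == "radiology",
                    ifelse(cond == "aided", design$time_median_aided[["radiology"]],
                           design$time_median_unaided[["radiology"]]),
                    ifelse(cond == "aided", design$time_median_aided[["other"]],
                           design$time_median_unaided[["other"]]))
      rt <- exp(log(med) + t_reader[j] + stats::rnorm(n_case, 0, 0.35))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        reader_id = reader_ids[j], specialty = specs[j],
        case_id = rep(case_ids, each = 8L), session = session,
        condition = rep(cond, each = 8L), category = rep(cats, n_case),
        confidence = as.numeric(t(conf)),
        read_time_s = rep(rt, each = 8L),
        reference = as.integer(t(ref)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Validate a reader-study table
#'
#' Checks the long-format schema, the crossover invariant (each (reader,
#' case, category) exactly once per condition with complementary
#' sessions), confidence in \[0, 100\] and positive read times.
#'
#' @param table data.frame.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
validateReaderStudyTable <- function(table) {
  need <- c("reader_id", "case_id", "session", "condition", "category",
            "confidence", "read_time_s", "reference")
  if (!all(need %in% names(table)))
    stop("missing columns: ", paste(setdiff(need, names(table)),
                                    collapse = ", "), call. = FALSE)
  if (any(table$confidence < 0 | table$confidence > 100))
    stop("confidence scores must lie in [0, 100]", call. = FALSE)
  if (any(table$read_time_s <= 0))
    stop("read times must be positive", call. = FALSE)
  cnt <- table(paste(table$reader_id, table$case_id, table$category),
               table$condition)
  if (!all(cnt == 1L))
    stop("each (reader, case, category) must appear exactly once per condition",
         call. = FALSE)
  invisible(TRUE)
}

# Fast case-deletion jackknife of the Mann-Whitney AUC: pseudovalues
# Y_c = nC * AUC - (nC - 1) * AUC_{-c}, computed from placement counts so
# the whole jackknife costs O(n log n + n).
jackknifeAucPseudovalues <- function(scores, labels, case_of, case_levels) {
  pos <- labels == 1
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L)
    stop("undefined metric: labels must contain both classes", call. = FALSE)
  sp <- sort(scores[!pos])  # negatives
  sq <- sort(scores[pos])   # positives
  # per-observation placement weights
  negLE <- findInterval(scores, sp)
  negL <- findInterval(scores, sp, left.open = TRUE)
  Wn <- negL + 0.5 * (negLE - negL)          # for positive obs
  posLE <- findInterval(scores, sq)
  posL <- findInterval(scores, sq, left.open = TRUE)
  Wp <- (P - posLE) + 0.5 * (posLE - posL)   # for negative obs
  U <- sum(Wn[pos])
  auc <- U / (P * N)

  ci <- match(case_of, case_levels)
  nC <- length(case_levels)
  P_c <- tabulate(ci[pos], nC)
  N_c <- tabulate(ci[!pos], nC)
  sumWn <- numeric(nC)
  tmp <- rowsum(Wn[pos], ci[pos])
  sumWn[as.integer(rownames(tmp))] <- tmp[, 1]
  sumWp <- numeric(nC)
  tmp <- rowsum(Wp[!pos], ci[!pos])
  sumWp[as.integer(rownames(tmp))] <- tmp[, 1]
  # within-case pos-neg cross pairs (subtracted twice above)
  within <- numeric(nC)
  both <- which(P_c > 0 & N_c > 0)
  for (cc in both) {
    ip <- scores[pos & ci == cc]; iq <- scores[!pos & ci == cc]
    within[cc] <- sum(outer(ip, iq, ">")) + 0.5 * sum(outer(ip, iq, "=="))
  }
  U_del <- U - (sumWn + sumWp - within)
  Pd <- P - P_c; Nd <- N - N_c
  auc_del <- ifelse(Pd > 0 & Nd > 0, U_del / (Pd * Nd), auc)
  if (any(Pd == 0 | Nd == 0))
    warning("jackknife replicate with a single class; pseudovalue from the ",
            "reduced set", call. = FALSE)
  nC * auc - (nC - 1) * auc_del
}

#' Per-reader micro-averaged AUCs from a study table
#'
#' Confidence scores of all 8 categories are pooled per reader and
#' condition (micro-averaging) and scored against the reference standard.
#'
#' @param table Validated reader-study table.
#' @return data.frame: `reader_id`, `specialty`, `condition`, `auc`.
#' @export
readerAucTable <- function(table) {
  sp <- split(table, list(table$reader_id, table$condition), drop = TRUE)
  out <- lapply(sp, function(d)
    data.frame(reader_id = d$reader_id[1],
               specialty = if ("specialty" %in% names(d)) d$specialty[1] else NA,
               condition = d$condition[1],
               auc = rocAuc(d$confidence, d$reference),
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  do.call(rbind, out)
}

#' Dorfman-Berbaum-Metz MRMC analysis
#'
#' Computes case-jackknife pseudovalues of each reader's micro-averaged
#' AUC under each condition, then the three-factor pseudovalue ANOVA
#' (condition fixed; readers and cases random, all interactions). The
#' treatment F statistic uses the Hillis denominator
#' `MS(TR) + max(MS(TC) - MS(TRC), 0)` with its matching degrees of
#' freedom by default; `df = "dbm"` gives the original
#' `MS(TR) + MS(TC) - MS(TRC)` denominator with Satterthwaite df.
#'
#' @param table Reader-study table (see [generateReaderStudy()]).
#' @param df `"hillis"` (default) or `"dbm"`.
#' @return A [DbmResult-class].
#' @export
dbmAnalysis <- function(table, df = c("hillis", "dbm")) {
  df <- match.arg(df)
  validateReaderStudyTable(table)
  readers <- sort(unique(table$reader_id))
  case_levels <- sort(unique(table$case_id))
  conds <- c("unaided", "aided")
  r <- length(readers); nC <- length(case_levels); t <- 2L
  if (r < 2L || nC < 2L)
    stop("DBM analysis requires at least 2 readers and 2 cases", call. = FALSE)
  Y <- array(NA_real_, c(t, r, nC), dimnames = list(conds, readers, NULL))
  for (ic in seq_len(t)) for (jr in seq_len(r)) {
    d <- table[table$reader_id == readers[jr] & table$condition == conds[ic], ]
    Y[ic, jr, ] <- jackknifeAucPseudovalues(d$confidence, d$reference,
                                            d$case_id, case_levels)
  }
  g <- mean(Y)
  A <- apply(Y, 1, mean); B <- apply(Y, 2, mean); C <- apply(Y, 3, mean)
  AB <- apply(Y, c(1, 2), mean); AC <- apply(Y, c(1, 3), mean)
  BC <- apply(Y, c(2, 3), mean)
  MS_T <- r * nC * sum((A - g)^2) / (t - 1)
  MS_R <- t * nC * sum((B - g)^2) / (r - 1)
  MS_C <- t * r * sum((C - g)^2) / (nC - 1)
  MS_TR <- nC * sum((AB - outer(A, rep(1, r)) - outer(rep(1, t), B) + g)^2) /
    ((t - 1) * (r - 1))
  MS_TC <- r * sum((AC - outer(A, rep(1, nC)) - outer(rep(1, t), C) + g)^2) /
    ((t - 1) * (nC - 1))
  MS_RC <- t * sum((BC - outer(B, rep(1, nC)) - outer(rep(1, r), C) + g)^2) /
    ((r - 1) * (nC - 1))
  resid <- Y
  for (ic in seq_len(t)) for (jr in seq_len(r))
    resid[ic, jr, ] <- Y[ic, jr, ] - AB[ic, jr] - AC[ic, ] - BC[jr, ] +
      A[ic] + B[jr] + C - g
  MS_TRC <- sum(resid^2) / ((t - 1) * (r - 1) * (nC - 1))

  if (df == "hillis") {
    den <- MS_TR + max(MS_TC - MS_TRC, 0)
    ddf <- if (MS_TR > 0) den^2 / (MS_TR^2 / ((t - 1) * (r - 1))) else NA_real_
  } else {
    den <- MS_TR + MS_TC - MS_TRC
    ddf <- if (den > 0) den^2 / (MS_TR^2 / ((t - 1) * (r - 1)) +
                                   MS_TC^2 / ((t - 1) * (nC - 1)) +
                                   MS_TRC^2 / ((t - 1) * (r - 1) * (nC - 1)))
      else NA_real_
  }
  diffv <- A[["aided"]] - A[["unaided"]]
  if (den <= 0 || !is.finite(ddf)) {
    Fstat <- if (MS_T == 0) 0 else Inf
    p <- if (MS_T == 0) 1 else 0
    se <- 0; ddf <- max(ddf, 1, na.rm = TRUE)
  } else {
    Fstat <- MS_T / den
    p <- stats::pf(Fstat, 1, ddf, lower.tail = FALSE)
    se <- sqrt(2 * den / (r * nC))
  }
  ci <- diffv + c(-1, 1) * stats::qt(0.975, ddf) * se
  anova_tab <- data.frame(
    term = c("T", "R", "C", "TR", "TC", "RC", "TRC"),
    ms = c(MS_T, MS_R, MS_C, MS_TR, MS_TC, MS_RC, MS_TRC),
    df = c(t - 1, r - 1, nC - 1, (t - 1) * (r - 1), (t - 1) * (nC - 1),
           (r - 1) * (nC - 1), (t - 1) * (r - 1) * (nC - 1)))
  new("DbmResult",
      ls_mean_auc_unaided = unname(A[["unaided"]]),
      ls_mean_auc_aided = unname(A[["aided"]]),
      difference = unname(diffv), ci_low = ci[1], ci_high = ci[2],
      f_statistic = Fstat, ddf = ddf, p_value = p, anova = anova_tab)
}

#' DeLong test for two correlated AUCs
#'
#' Placement-value (structural component) estimate of the covariance of
#' two AUCs computed from paired score vectors on the same cases, with a
#' two-sided normal test of their difference. Any multiplicity adjustment
#' (e.g. Bonferroni) is the caller's responsibility.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared binary labels with both classes present.
#' @return List: `auc_a`, `auc_b`, `z`, `p`.
#' @export
delongTest <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0L || N == 0L)
    stop("undefined metric: labels must contain both classes", call. = FALSE)
  placements <- function(s) {
    sp <- s[labels == 1]; sn <- s[labels == 0]
    so <- sort(sn)
    le <- findInterval(sp, so); l <- findInterval(sp, so, left.open = TRUE)
    V10 <- (l + 0.5 * (le - l)) / N
    so <- sort(sp)
    le <- findInterval(sn, so); l <- findInterval(sn, so, left.open = TRUE)
    V01 <- ((P - le) + 0.5 * (le - l)) / P
    list(V10 = V10, V01 = V01, auc = mean(V10))
  }
  pa <- placements(scores_a); pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$V10, pb$V10))
  s01 <- stats::cov(cbind(pa$V01, pb$V01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / P +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / N
  d <- pa$auc - pb$auc
  z <- if (d == 0) 0 else d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Relative reduction in missed abnormalities
#'
#' `100 * [(1 - s_unaided) - (1 - s_aided)] / (1 - s_unaided)`: the
#' percentage of unaided misses eliminated when aided.
#'
#' @param sens_unaided,sens_aided Sensitivities in \[0, 1\],
#'   `sens_unaided < 1`.
#' @return Percentage.
#' @export
#' @examples
#' missRateReduction(0.757, 0.856)  # 40.74
missRateReduction <- function(sens_unaided, sens_aided) {
  if (any(sens_unaided < 0 | sens_unaided >= 1) ||
      any(sens_aided < 0 | sens_aided > 1))
    stop("sensitivities must lie in [0, 1] with sens_unaided < 1", call. = FALSE)
  100 * ((1 - sens_unaided) - (1 - sens_aided)) / (1 - sens_unaided)
}

#' Paired read-time comparison on log times
#'
#' Read times are log-transformed, averaged per reader within each
#' condition, and compared with a paired t-test across readers (df =
#' number of readers - 1). Raw-time medians and the relative median
#' change are reported alongside.
#'
#' @param times_unaided,times_aided Positive read times.
#' @param readers_unaided,readers_aided Reader id per time (pairing unit).
#' @return List: `t`, `df`, `p`, `median_unaided`, `median_aided`,
#'   `relative_median_change_pct`.
#' @export
readTimeTest <- function(times_unaided, times_aided,
                         readers_unaided, readers_aided) {
  if (any(times_unaided <= 0) || any(times_aided <= 0))
    stop("read times must be positive", call. = FALSE)
  mu <- tapply(log(times_unaided), readers_unaided, mean)
  ma <- tapply(log(times_aided), readers_aided, mean)
  readers <- intersect(names(mu), names(ma))
  diffs <- mu[readers] - ma[readers]
  n <- length(diffs)
  if (n < 2L) stop("need at least two paired readers", call. = FALSE)
  if (stats::sd(diffs) == 0) {
    tt <- list(statistic = 0, parameter = n - 1, p.value = 1)
  } else {
    ht <- stats::t.test(mu[readers], ma[readers], paired = TRUE)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  med_u <- stats::median(times_unaided); med_a <- stats::median(times_aided)
  list(t = tt$statistic, df = tt$parameter, p = tt$p.value,
       median_unaided = med_u, median_aided = med_a,
       relative_median_change_pct = 100 * (med_u - med_a) / med_u)
}

#' Full MRMC report
#'
#' DBM analysis of aided vs unaided AUC, per-specialty mean reader AUCs,
#' the DeLong comparison of radiologists vs non-radiologists in each
#' condition (group scores = mean confidence across the group's readers),
#' miss-rate reductions at the given confidence call threshold, and
#' read-time tests per group. p-values are reported unadjusted; compare
#' the DeLong p-values against a Bonferroni-adjusted level (0.05/2) when
#' reading both conditions.
#'
#' @param table Reader-study table.
#' @param call_threshold Confidence at or above which a reader call counts
#'   as positive (default 50).
#' @return List: `dbm`, `reader_aucs`, `specialty_aucs`, `delong`,
#'   `miss_rate`, `read_time`.
#' @export
mrmcReport <- function(table, call_threshold = 50) {
  validateReaderStudyTable(table)
  dbm <- dbmAnalysis(table)
  raucs <- readerAucTable(table)
  spec_auc <- aggregate(auc ~ specialty + condition, raucs, mean)

  groupScores <- function(cond, radiol) {
    sel <- table$condition == cond &
      ((table$specialty == "radiology") == radiol)
    d <- table[sel, ]
    agg <- aggregate(confidence ~ case_id + category + reference, d, mean)
    agg
  }
  delong <- lapply(c(unaided = "unaided", aided = "aided"), function(cond) {
    ra <- groupScores(cond, TRUE); nr <- groupScores(cond, FALSE)
    key <- paste(ra$case_id, ra$category)
    nr <- nr[match(key, paste(nr$case_id, nr$category)), ]
    delongTest(ra$confidence, nr$confidence, ra$reference)
  })

  sens <- function(cond, radiol = NULL) {
    sel <- table$condition == cond & table$reference == 1
    if (!is.null(radiol))
      sel <- sel & ((table$specialty == "radiology") == radiol)
    mean(table$confidence[sel] >= call_threshold)
  }
  miss <- list(
    overall = missRateReduction(sens("unaided"), sens("aided")),
    radiologists = missRateReduction(sens("unaided", TRUE), sens("aided", TRUE)),
    non_radiologists = missRateReduction(sens("unaided", FALSE),
                                         sens("aided", FALSE)))

  rt <- lapply(c(radiologists = TRUE, non_radiologists = FALSE), function(radiol) {
    sub <- table[(table$specialty == "radiology") == radiol, ]
    one <- sub[!duplicated(paste(sub$reader_id, sub$case_id, sub$condition)), ]
    u <- one[one$condition == "unaided", ]; a <- one[one$condition == "aided", ]
    readTimeTest(u$read_time_s, a$read_time_s, u$reader_id, a$reader_id)
  })

  list(dbm = dbm, reader_aucs = raucs, specialty_aucs = spec_auc,
       delong = delong, miss_rate = miss, read_time = rt)
}
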