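test_that("ROC AUC equals brute-force pair counting", {
  # 3 of 4 positive-negative pairs correctly ordered
  expect_equal(rocAuc(c(0.1, 0.3, 0.35, 0.8), c(0, 1, 0, 1)), 0.75)
  expect_equal(rocAuc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")

  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    scores <- round(runif(n), sample(1:3, 1))  # induce ties
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(rocAuc(scores, labels), bruteAuc(scores, labels),
                 tolerance = 1e-12)
  }

  # chance level for independent scores
  set.seed(5)
  expect_lt(abs(rocAuc(runif(20000), rbinom(20000, 1, 0.5)) - 0.5), 0.02)
})

test_that("ROC AUC agrees with an independent implementation", {
  set.seed(7)
  scores <- runif(300); labels <- rbinom(300, 1, 0.4)
  expect_equal(rocAuc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("micro-averaging pools observations across categories", {
  cats <- cxrCategories()
  # identical data in every category: pooled equals per-category
  s <- c(0.9, 0.7, 0.3, 0.2); l <- c(1, 1, 0, 0)
  ps <- setNames(rep(list(s), 8), cats)
  pl <- setNames(rep(list(l), 8), cats)
  out <- microAverage(ps, pl)
  expect_equal(out$auc, rocAuc(s, l))

  # AUC 1 and AUC 0 categories pool strictly between them
  ps2 <- setNames(c(list(c(0.9, 0.8, 0.2, 0.1)), list(c(0.2, 0.1, 0.9, 0.8)),
                    rep(list(s), 6)), cats)
  pl2 <- setNames(rep(list(c(1, 1, 0, 0)), 8), cats)
  a_hi <- rocAuc(ps2[[1]], pl2[[1]]); a_lo <- rocAuc(ps2[[2]], pl2[[2]])
  pooled <- microAverage(ps2[c(1, 2)], pl2[c(1, 2)])$auc
  expect_gt(pooled, a_lo); expect_lt(pooled, a_hi)

  # pooled length is cases x categories
  expect_length(unlist(ps), 8 * 4)

  # invariance to category order
  perm <- sample(8)
  expect_equal(microAverage(ps2[perm], pl2[perm])$auc,
               microAverage(ps2, pl2)$auc)

  # thresholds give pooled sensitivity/specificity of the determinations
  thr <- setNames(rep(0.5, 8), cats)
  ms <- microAverage(ps, pl, thresholds = thr)
  expect_equal(ms$sensitivity, 1)
  expect_equal(ms$specificity, 1)
})

test_that("bootstrap CIs are deterministic, degenerate-safe and calibrated", {
  # constant metric: zero-width interval
  ci <- bootstrapCI(function(idx) 0.7, n_cases = 50, m = 100, seed = 3)
  expect_identical(unname(ci), c(0.7, 0.7))

  # same seed, same interval
  set.seed(99); x <- rnorm(80)
  f <- function(idx) mean(x[idx])
  expect_identical(bootstrapCI(f, 80, m = 200, seed = 11),
                   bootstrapCI(f, 80, m = 200, seed = 11))

  # percentile interval contains the point estimate on non-degenerate data
  ci <- bootstrapCI(f, 80, m = 500, seed = 2)
  expect_gte(mean(x), ci[["low"]]); expect_lte(mean(x), ci[["high"]])

  # coverage for the mean of N(0,1), n = 100, near the nominal 95%
  set.seed(17)
  hits <- vapply(1:400, function(s) {
    y <- rnorm(100)
    ci <- bootstrapCI(function(idx) mean(y[idx]), 100, m = 200, seed = s)
    ci[["low"]] <= 0 && 0 <= ci[["high"]]
  }, logical(1))
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)

  # replicates where the metric is undefined are capped
  expect_error(bootstrapCI(function(idx) NA_real_, 10, m = 50, seed = 1),
               "degenerate")
})

test_that("box-set IoU matches closed forms and the pixel-mask oracle", {
  b <- function(r0, c0, r1, c1) data.frame(row0 = r0, col0 = c0,
                                           row1 = r1, col1 = c1)
  expect_equal(summedIoU(b(0, 0, 10, 10), b(0, 0, 10, 10)), 1)
  expect_equal(summedIoU(b(0, 0, 10, 10), b(20, 20, 30, 30)), 0)
  expect_equal(summedIoU(b(0, 0, 10, 10), b(5, 0, 15, 10)), 1 / 3)
  expect_true(is.na(summedIoU(b(0, 0, 10, 10)[0, ], b(0, 0, 1, 1)[0, ])))

  set.seed(41)
  for (i in 1:100) {
    np <- sample(0:4, 1); nr <- sample(1:4, 1)
    mk <- function(n) {
      if (n == 0) return(b(0, 0, 1, 1)[0, ])
      r0 <- sample(0:150, n, TRUE); c0 <- sample(0:150, n, TRUE)
      b(r0, c0, r0 + sample(5:40, n, TRUE), c0 + sample(5:40, n, TRUE))
    }
    P <- mk(np); R <- mk(nr)
    expect_equal(summedIoU(P, R), if (np == 0) 0 else maskIoU(P, R),
                 tolerance = 1e-12)
    # symmetry
    expect_equal(summedIoU(P, R), summedIoU(R, P), tolerance = 1e-12)
  }

  # equality of covered pixel sets is the only way to reach 1
  P <- rbind(b(0, 0, 10, 10), b(5, 5, 10, 10))   # overlapping within one side
  expect_equal(summedIoU(P, b(0, 0, 10, 10)), 1)
  # the raw summed-area variant double-counts that overlap
  expect_lt(summedIoU(P, b(0, 0, 10, 10), semantics = "summed"), 1)
})

test_that("stratified metrics suppress small strata and recover difficulty order", {
  set.seed(3)
  n <- 150
  tab <- data.frame(
    case_id = sprintf("c%03d", 1:n),
    stratum = c(rep("easy", 70), rep("hard", 61), rep("tiny", 19)),
    reference = 1L)
  tab$positive_call <- rbinom(n, 1, ifelse(tab$stratum == "easy", 0.95,
                                           ifelse(tab$stratum == "hard", 0.6, 0.5)))
  out <- subsetSensitivity(tab, "stratum", metric = "sensitivity",
                           m = 100, seed = 1)
  expect_true(is.na(out$value[out$stratum == "tiny"]))   # 19 <= 20 suppressed
  expect_gt(out$value[out$stratum == "easy"],
            out$value[out$stratum == "hard"])
  expect_identical(out$n_cases[out$stratum == "tiny"], 19L)

  # a single stratum reproduces the global metric
  tab$one <- "all"
  out1 <- subsetSensitivity(tab, "one", metric = "sensitivity", m = 50, seed = 1)
  expect_equal(out1$value, mean(tab$positive_call))
})

test_that("standalone evaluation produces a coherent report", {
  set.seed(55)
  set <- stdCaseSet(n = 24, seed = 91, prev = 0.5)
  m <- initModel(modelConfig("test"), seed = 1)
  preds <- predictCases(m, set)
  sc <- scoreTable(preds)
  lab <- caseLabels(set)
  ref <- lab[, c("case_id", "category", "reference")]
  for (g in cxrCategories()) {
    idx <- which(ref$category == g)
    if (length(unique(ref$reference[idx])) < 2)
      ref$reference[idx[1:2]] <- c(0L, 1L)
  }
  lab2 <- merge(lab[, c("case_id", "category", "k", "n", "truth")], ref,
                by = c("case_id", "category"))
  set@labels <- lab2
  op <- calibrateThresholds(sc, ref)
  det <- suppressWarnings(applyOperatingPoints(preds, set, op))
  rep <- evaluateStandalone(det, set, m = 60, seed = 5)
  expect_identical(nrow(rep$metrics), 9L)  # 8 categories + overall
  num <- rep$metrics[, c("auc", "sensitivity", "specificity")]
  expect_true(all(num >= 0 & num <= 1, na.rm = TRUE))
  expect_true(all(rep$metrics$auc_ci_low <= rep$metrics$auc +1e-12, na.rm = TRUE))
  expect_true(all(rep$metrics$auc_ci_high >= rep$metrics$auc - 1e-12, na.rm = TRUE))
  ov <- rep$metrics[rep$metrics$category == "Overall", ]
  pooled <- merge(det, ref, by = c("case_id", "category"))
  expect_equal(ov$auc, rocAuc(pooled$score, pooled$reference))
})
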