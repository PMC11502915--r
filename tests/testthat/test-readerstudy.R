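nullDesign <- function(n_readers = 4, n_abnormal = 30, n_normal = 10,
                       auc = 0.78) {
  studyDesignConfig(
    n_readers_per_specialty = c(radiology = n_readers / 2,
                                internal = n_readers / 2,
                                family = 0, emergency = 0),
    n_abnormal = n_abnormal, n_normal = n_normal,
    auc_unaided = auc, auc_aided = auc)
}

test_that("condition assignment satisfies the crossover constraints", {
  ids <- sprintf("c%03d", 1:238)
  strata <- rep(c(1, 0), c(190, 48))
  asg <- assignConditions(ids, sprintf("r%02d", 1:5), strata = strata, seed = 2)
  for (rd in unique(asg$reader_id)) {
    sub <- asg[asg$reader_id == rd, ]
    # half the cases aided in session 1 (within-stratum balance, even strata)
    expect_identical(sum(sub$session1_condition == "aided"), 119L)
    expect_identical(sum(sub$session1_condition == "aided" &
                           strata == 1), 95L)
  }
  expect_identical(assignConditions(ids, "r1", strata = strata, seed = 7),
                   assignConditions(ids, "r1", strata = strata, seed = 7))
  expect_error(assignConditions("one", "r1"), "two cases")
})

test_that("generated study tables satisfy the design invariants", {
  tab <- generateReaderStudy(nullDesign(), seed = 3)
  expect_true(validateReaderStudyTable(tab))
  # every (reader, case) pair appears once per condition with complementary
  # sessions
  pair <- tab[!duplicated(paste(tab$reader_id, tab$case_id, tab$condition)), ]
  cross <- table(paste(pair$reader_id, pair$case_id))
  expect_true(all(cross == 2L))
  sess <- tapply(pair$session, paste(pair$reader_id, pair$case_id),
                 function(s) sort(s))
  expect_true(all(vapply(sess, function(s) identical(as.integer(s), 1:2),
                         logical(1))))
  expect_true(all(tab$confidence >= 0 & tab$confidence <= 100))
  expect_true(all(tab$read_time_s > 0))
  # determinism
  expect_identical(generateReaderStudy(nullDesign(), seed = 3), tab)
  # full-size design has 24 x 238 x 2 rows per category
  big <- generateReaderStudy(studyDesignConfig(), seed = 1)
  expect_identical(nrow(big), 24L * 238L * 2L * 8L)
})

test_that("aided separation raises confidence-based sensitivity at a fixed threshold", {
  des <- studyDesignConfig(n_readers_per_specialty = c(radiology = 2,
                                                       internal = 2,
                                                       family = 0, emergency = 0),
                           n_abnormal = 150, n_normal = 50)
  tab <- generateReaderStudy(des, seed = 5)
  sens <- function(cond) {
    d <- tab[tab$condition == cond & tab$reference == 1, ]
    mean(d$confidence >= 50)
  }
  expect_gt(sens("aided"), sens("unaided"))
})

test_that("jackknife pseudovalues match naive recomputation", {
  set.seed(13)
  n_case <- 25
  case_of <- rep(sprintf("c%02d", 1:n_case), each = 4)
  labels <- rbinom(length(case_of), 1, 0.4)
  labels[1:2] <- c(0, 1)
  scores <- round(runif(length(case_of)), 2)
  lev <- sort(unique(case_of))
  ps <- cxrcad:::jackknifeAucPseudovalues(scores, labels, case_of, lev)
  full <- rocAuc(scores, labels)
  for (cc in seq_along(lev)) {
    keep <- case_of != lev[cc]
    naive <- n_case * full - (n_case - 1) * rocAuc(scores[keep], labels[keep])
    expect_equal(ps[cc], naive, tolerance = 1e-10)
  }
})

test_that("DBM analysis behaves on identity and antisymmetric swaps", {
  tab <- generateReaderStudy(nullDesign(), seed = 11)
  # make aided an exact copy of unaided: difference 0, p = 1
  base <- tab[tab$condition == "unaided", ]
  clone <- base; clone$condition <- "aided"; clone$session <- 3 - base$session
  ident <- rbind(base, clone)
  res <- dbmAnalysis(ident)
  expect_equal(res@difference, 0, tolerance = 1e-12)
  expect_equal(res@p_value, 1)

  # swapping condition labels flips the sign of the difference
  res1 <- dbmAnalysis(tab)
  swapped <- tab
  swapped$condition <- ifelse(tab$condition == "aided", "unaided", "aided")
  res2 <- dbmAnalysis(swapped)
  expect_equal(res1@difference, -res2@difference, tolerance = 1e-10)
  expect_equal(res1@p_value, res2@p_value, tolerance = 1e-10)
  # LS-mean identity
  expect_equal(res1@difference,
               res1@ls_mean_auc_aided - res1@ls_mean_auc_unaided,
               tolerance = 1e-12)
  expect_true(res1@ci_low <= res1@difference &&
                res1@difference <= res1@ci_high)
})

test_that("DBM detects a planted separation on a modest design", {
  des <- studyDesignConfig(n_readers_per_specialty = c(radiology = 3,
                                                       internal = 3,
                                                       family = 0,
                                                       emergency = 0),
                           n_abnormal = 80, n_normal = 30,
                           auc_unaided = 0.70, auc_aided = 0.90)
  tab <- generateReaderStudy(des, seed = 21)
  res <- dbmAnalysis(tab)
  expect_gt(res@difference, 0.05)
  expect_lt(res@p_value, 0.05)
})

test_that("the DeLong test matches pROC and degenerates to z = 0", {
  set.seed(31)
  labels <- rbinom(400, 1, 0.4); labels[1:2] <- c(0, 1)
  base <- rnorm(400) + labels
  sa <- base + rnorm(400, sd = 0.6)
  sb <- base + rnorm(400, sd = 0.6)
  res <- delongTest(sa, sb, labels)
  expect_equal(res$auc_a, rocAuc(sa, labels), tolerance = 1e-12)
  expect_equal(res$auc_b, rocAuc(sb, labels), tolerance = 1e-12)
  ref <- pROC::roc.test(pROC::roc(labels, sa, quiet = TRUE, direction = "<"),
                        pROC::roc(labels, sb, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-8)
  expect_equal(abs(res$z), abs(unname(ref$statistic)), tolerance = 1e-8)

  ident <- delongTest(sa, sa, labels)
  expect_identical(ident$z, 0)
  expect_identical(ident$p, 1)
  expect_error(delongTest(sa, sb, rep(1, 400)), "both classes")
})

test_that("the DeLong variance approximates the case-bootstrap variance", {
  set.seed(43)
  n <- 500
  labels <- rbinom(n, 1, 0.4); labels[1:2] <- c(0, 1)
  base <- rnorm(n) + 1.1 * labels
  sa <- base + rnorm(n, sd = 0.8)
  sb <- 0.8 * base + rnorm(n, sd = 0.8)
  # implied DeLong variance of the difference
  res <- delongTest(sa, sb, labels)
  d <- res$auc_a - res$auc_b
  v_delong <- (d / res$z)^2
  boots <- vapply(1:400, function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[idx])) < 2) return(NA_real_)
    rocAuc(sa[idx], labels[idx]) - rocAuc(sb[idx], labels[idx])
  }, numeric(1))
  v_boot <- var(boots, na.rm = TRUE)
  expect_lt(abs(v_delong - v_boot) / v_boot, 0.25)
})

test_that("miss-rate reduction reproduces its definition", {
  expect_equal(missRateReduction(0.757, 0.856), 40.74, tolerance = 0.01)
  expect_equal(missRateReduction(0.6, 0.6), 0)
  expect_equal(missRateReduction(0.5, 1.0), 100)
  # invariant to rescaling both miss rates by a common factor
  s1 <- 0.8; s2 <- 0.9; f <- 0.5
  expect_equal(missRateReduction(s1, s2),
               missRateReduction(1 - f * (1 - s1), 1 - f * (1 - s2)),
               tolerance = 1e-10)
  expect_error(missRateReduction(1, 0.9), "sens_unaided < 1")
})

test_that("read-time analysis pairs readers on log times", {
  set.seed(51)
  readers <- rep(sprintf("r%02d", 1:18), each = 30)
  tu <- rlnorm(length(readers), log(107), 0.3)
  ta <- rlnorm(length(readers), log(98.5), 0.3)
  res <- readTimeTest(tu, ta, readers, readers)
  expect_identical(res$df, 17)  # 18 paired readers
  expect_equal(res$relative_median_change_pct,
               100 * (median(tu) - median(ta)) / median(tu))
  # identical conditions: t = 0, p = 1
  same <- readTimeTest(tu, tu, readers, readers)
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_error(readTimeTest(c(-1, 2), c(1, 2), c("a", "b"), c("a", "b")),
               "positive")
})

test_that("the full MRMC report assembles all analyses", {
  des <- studyDesignConfig(n_readers_per_specialty = c(radiology = 2,
                                                       internal = 2,
                                                       family = 2,
                                                       emergency = 0),
                           n_abnormal = 60, n_normal = 20)
  tab <- generateReaderStudy(des, seed = 9)
  rep <- mrmcReport(tab)
  expect_s4_class(rep$dbm, "DbmResult")
  expect_gt(rep$dbm@difference, 0)
  expect_identical(sort(unique(rep$specialty_aucs$condition)),
                   c("aided", "unaided"))
  expect_true(all(c("unaided", "aided") %in% names(rep$delong)))
  expect_true(rep$miss_rate$overall > 0)
  expect_identical(rep$read_time$non_radiologists$df, 4 - 1)
  # CSV round trip preserves the table
  p <- withr::local_tempfile(fileext = ".csv")
  writeReaderStudyCSV(tab, p)
  back <- readReaderStudyCSV(p)
  expect_equal(back$confidence, tab$confidence)
  expect_identical(nrow(back), nrow(tab))
})
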