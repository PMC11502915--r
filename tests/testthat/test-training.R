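test_that("beta-binomial NLL reproduces closed-form values", {
  expect_equal(betaBinomialNLL(1, 1, 1, 1), log(2), tolerance = 1e-12)
  # Beta(1,1) makes k uniform on 0..n
  for (k in 0:3)
    expect_equal(betaBinomialNLL(1, 1, k, 3), log(4), tolerance = 1e-12)
  # mean of Beta(5,1) is 5/6
  expect_equal(betaBinomialNLL(5, 1, 1, 1), -log(5 / 6), tolerance = 1e-12)
  expect_error(betaBinomialNLL(0, 1, 1, 3), "strictly positive")
  expect_error(betaBinomialNLL(1, 1, 4, 3), "invalid label")
})

test_that("beta-binomial NLL agrees with the numerical-integration oracle", {
  # substitute p = qbeta(u): the integrand becomes bounded and smooth,
  # avoiding the endpoint singularities of dbeta when alpha, beta < 1
  oracle <- function(alpha, beta, k, n) {
    f <- function(u) stats::dbinom(k, n, stats::qbeta(u, alpha, beta))
    -log(stats::integrate(f, 0, 1, rel.tol = 1e-12)$value)
  }
  grid <- expand.grid(alpha = c(0.5, 1, 2, 7.3), beta = c(0.4, 1, 3.1, 9),
                      n = c(1, 3, 6), k_frac = c(0, 0.5, 1))
  grid$k <- round(grid$k_frac * grid$n)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(betaBinomialNLL(g$alpha, g$beta, g$k, g$n),
                 oracle(g$alpha, g$beta, g$k, g$n), tolerance = 1e-8)
  }
})

test_that("NLL gradients match numerical differentiation", {
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 0.2, 8); b <- runif(1, 0.2, 8)
    n <- sample(1:6, 1); k <- sample(0:n, 1)
    g <- cxrcad:::betaBinomialNLLGrad(a, b, k, n)
    eps <- 1e-6
    num_a <- (betaBinomialNLL(a + eps, b, k, n) -
                betaBinomialNLL(a - eps, b, k, n)) / (2 * eps)
    num_b <- (betaBinomialNLL(a, b + eps, k, n) -
                betaBinomialNLL(a, b - eps, k, n)) / (2 * eps)
    expect_equal(g$alpha, num_a, tolerance = 1e-5)
    expect_equal(g$beta, num_b, tolerance = 1e-5)
  }
})

test_that("pixel BCE reproduces closed forms and validates shapes", {
  y <- matrix(rbinom(60, 1, 0.5), 6, 10)
  expect_lt(pixelBCE(y, y), 1e-6)                       # perfect prediction
  expect_equal(pixelBCE(matrix(0.5, 6, 10), y), log(2), tolerance = 1e-12)
  expect_equal(pixelBCE(matrix(0.9, 6, 10), matrix(1, 6, 10)), -log(0.9),
               tolerance = 1e-12)
  expect_error(pixelBCE(matrix(0.5, 3, 3), matrix(1, 2, 2)), "shape")
})

test_that("joint loss decomposes and degenerates correctly", {
  set <- stdCaseSet(n = 3, seed = 31)
  m <- initModel(modelConfig("test"), seed = 1)
  cs <- cxrCases(set)[[1]]
  fw <- cxrcad:::forwardCase(m, cs@images)
  tm <- groundTruthMaps(cs, 8, 10)
  lab <- caseLabels(set)
  lab <- lab[lab$case_id == cs@case_id, ]
  ll <- jointLoss(fw, lab, tm)
  expect_equal(ll$total, sum(ll$bce) + sum(ll$nll), tolerance = 1e-12)
  # zero localization weight leaves only the NLL sum
  ll0 <- jointLoss(fw, lab, tm, w_loc = 0)
  expect_equal(ll0$total, sum(ll0$nll), tolerance = 1e-12)
  expect_error(jointLoss(fw, lab[-1, ], tm), "8 categories")

  # perfect predictions reach the grid-searched NLL minimum per label
  for (i in seq_len(nrow(lab))) {
    grid <- expand.grid(a = exp(seq(log(0.01), log(200), length = 120)),
                        b = exp(seq(log(0.01), log(200), length = 120)))
    best <- min(betaBinomialNLL(grid$a, grid$b, lab$k[i], lab$n[i]))
    fit <- fitBetaBinomial(lab$k[i], lab$n[i])
    expect_lte(fit$nll, best + 1e-3)
  }
})

test_that("ground-truth maps rasterize reference boxes at map resolution", {
  cfg <- generatorConfig(prevalence = c(1, 0, 0, 0, 0, 0, 0, 0))
  cs <- preprocessCases(generateCase(cfg, seed = 2), preprocessConfig("test"))
  tm <- groundTruthMaps(cs, 8, 10)
  ii <- cs@truths$image_index[1]
  arr <- tm[[ii]]
  expect_identical(dim(arr), c(8L, 10L, 8L))
  expect_true(all(arr %in% 0:1))
  expect_gt(sum(arr[, , "Cardiac"]), 0)
  expect_identical(sum(arr[, , -1]), 0)
  # positive cells sit inside the scaled truth box (within one cell)
  pos <- which(arr[, , 1] == 1, arr.ind = TRUE)
  b <- cxrcad:::scaleBox(cs@truths[1, c("row0", "col0", "row1", "col1")],
                         64, 80, 8, 10)
  expect_true(all(pos[, 1] - 1 >= floor(b[["row0"]]) - 1))
  expect_true(all(pos[, 1] <= ceiling(b[["row1"]]) + 1))
})

test_that("augmentation respects identity parameters and flip consistency", {
  img <- matrix(runif(64 * 80), 64, 80)
  mask <- matrix(0, 64, 80); mask[10:20, 30:40] <- 1
  off <- list(p_rot = 0, p_hflip = 0, p_vflip = 0, p_gamma = 0,
              p_contrast = 0, p_crop = 0)
  out <- augmentImage(img, list(mask), seed = 1, params = off)
  expect_identical(out$image, img)
  expect_identical(out$truth_masks[[1]], mask)

  # forced horizontal flip mirrors image and mask identically
  hf <- augmentImage(img, list(mask), seed = 1,
                     params = modifyList(off, list(p_hflip = 1)))
  expect_identical(hf$image, img[, 80:1])
  expect_identical(hf$truth_masks[[1]], mask[, 80:1])

  # gamma = 1 and contrast = 1 leave intensities unchanged
  id <- augmentImage(img, list(mask), seed = 1,
                     params = modifyList(off, list(p_gamma = 1,
                                                   gamma_range = c(1, 1),
                                                   p_contrast = 1,
                                                   contrast_range = c(1, 1))))
  expect_equal(id$image, img, tolerance = 1e-12)

  # augmentation is label-preserving: masks stay binary, same shape
  full <- augmentImage(img, list(mask), seed = 7)
  expect_identical(dim(full$image), c(64L, 80L))
  expect_true(all(full$truth_masks[[1]] %in% 0:1))
  # determinism
  full2 <- augmentImage(img, list(mask), seed = 7)
  expect_identical(full, full2)
})

test_that("whole-case backward gradients match finite differences", {
  set.seed(5)
  m <- initModel(modelConfig("test"), seed = 3)
  imgs <- list(matrix(runif(64 * 80), 64, 80), matrix(runif(64 * 80), 64, 80))
  tm <- lapply(1:2, function(i) array(rbinom(640, 1, 0.2), c(8, 10, 8)))
  k <- c(1, 0, 2, 0, 0, 0, 3, 0); n <- rep(3L, 8)
  fw <- cxrcad:::forwardCase(m, imgs, keep_cache = TRUE)
  g <- cxrcad:::backwardCase(m, fw, tm, k, n, rep(1, 8), rep(1, 8))
  lossAt <- function(model) {
    f <- cxrcad:::forwardCase(model, imgs)
    jointLoss(f, data.frame(category = cxrCategories(), k = k, n = n), tm)$total
  }
  base <- lossAt(m); eps <- 1e-6
  check <- function(getter, setter, ana) {
    m2 <- setter(m, eps)
    num <- (lossAt(m2) - base) / eps
    expect_equal(num, ana, tolerance = 1e-3)
  }
  for (nm in c("cls_w", "proj_w", "loc_w", "conv_w")) {
    if (nm == "conv_w") {
      for (i in 1:4) {
        idx <- which(abs(g$conv_w[[i]]) > 1e-3)[1]
        if (is.na(idx)) next
        check(NULL, function(mm, e) {
          mm@params$conv_w[[i]][idx] <- mm@params$conv_w[[i]][idx] + e; mm
        }, g$conv_w[[i]][idx])
      }
    } else {
      idx <- which(abs(g[[nm]]) > 1e-3)[1]
      if (is.na(idx)) next
      check(NULL, function(mm, e) {
        mm@params[[nm]][idx] <- mm@params[[nm]][idx] + e; mm
      }, g[[nm]][idx])
    }
  }
})

test_that("early stopping fires after the patience window and returns the best epoch", {
  set <- stdCaseSet(n = 14, seed = 71, prev = 0.5)
  train <- set; tune <- stdCaseSet(n = 10, seed = 72, prev = 0.5)
  # zero learning rate: tuning AUC never improves after epoch 1
  cfg <- trainingConfig(batch_size_cases = 7, lr = 0, max_epochs = 30,
                        early_stop_patience_epochs = 4, augment = FALSE,
                        seed = 2)
  res <- trainModel(train, tune, cfg, modelConfig("test"))
  expect_identical(res$stopped_epoch, 5L)  # best at 1, stop after 1 + patience
  expect_identical(res$best_epoch, 1L)
  # returned checkpoint carries the best tuning AUC seen
  expect_equal(max(res$history$tune_mean_auc),
               res$history$tune_mean_auc[res$best_epoch], tolerance = 1e-12)
})

test_that("short training is deterministic and reduces the loss", {
  train <- stdCaseSet(n = 16, seed = 81, prev = 0.4)
  tune <- stdCaseSet(n = 10, seed = 82, prev = 0.4)
  cfg <- trainingConfig(batch_size_cases = 8, lr = 3e-3, max_epochs = 4,
                        early_stop_patience_epochs = 10, augment = TRUE,
                        seed = 4)
  r1 <- trainModel(train, tune, cfg, modelConfig("test"))
  r2 <- trainModel(train, tune, cfg, modelConfig("test"))
  expect_identical(r1$history, r2$history)
  expect_lt(tail(r1$history$loss, 1), r1$history$loss[1])
})

test_that("fitting the likelihood head recovers the labeling rate", {
  set.seed(9)
  k <- rbinom(1500, 3, 0.9)
  fit <- fitBetaBinomial(k, rep(3, 1500))
  expect_lt(abs(fit$mean - 0.9), 0.03)
})
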