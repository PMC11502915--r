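#' Training configuration
#'
#' @param batch_size_cases Cases per optimization batch (default 64; the
#'   final short batch of an epoch is kept).
#' @param lr,weight_decay AdamW learning rate and decoupled weight decay.
#' @param loss_weight_classification,loss_weight_localization Per-category
#'   (or scalar, recycled) weights of the beta-binomial negative
#'   log-likelihood and of the per-pixel binary cross-entropy in the joint
#'   loss; both default to 1.
#' @param early_stop_patience_epochs Stop when the across-category mean
#'   tuning-set AUC has not improved in this many epochs (default 10).
#' @param max_epochs Hard cap on epochs.
#' @param augment Logical: apply random augmentation during training.
#' @param augment_params See [augmentImage()].
#' @param seed Single seed fanned out to weight initialization, batch
#'   shuffling and augmentation via the package's seed-splitting scheme.
#' @return A list of class `TrainingConfig`.
#' @export
trainingConfig <- function(batch_size_cases = 64L, lr = 5e-3,
                           weight_decay = 1e-4,
                           loss_weight_classification = 1,
                           loss_weight_localization = 1,
                           early_stop_patience_epochs = 10L,
                           max_epochs = 30L,
                           augment = TRUE, augment_params = list(),
                           seed = 1L) {
  if (batch_size_cases < 1) stop("batch_size_cases must be >= 1", call. = FALSE)
  if (early_stop_patience_epochs < 1) stop("patience must be >= 1", call. = FALSE)
  structure(list(batch_size_cases = as.integer(batch_size_cases), lr = lr,
                 weight_decay = weight_decay,
                 w_cls = rep_len(loss_weight_classification, 8L),
                 w_loc = rep_len(loss_weight_localization, 8L),
                 patience = as.integer(early_stop_patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 augment = augment, augment_params = augment_params,
                 seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Beta-binomial negative log-likelihood
#'
#' `-log P(k | n, alpha, beta)` for the beta-binomial distribution
#' (a Binomial whose success probability is Beta(alpha, beta) distributed),
#' computed in log-space through log-gamma:
#' `-log[ C(n,k) B(k+alpha, n-k+beta) / B(alpha, beta) ]`.
#' This is the classification loss term: (alpha, beta) are the model's
#' outputs and (k, n) the k-of-n expert labels of the case.
#'
#' @param alpha,beta Strictly positive parameters (vectorized).
#' @param k,n Integer counts with `0 <= k <= n`, `n >= 1`.
#' @return Non-negative numeric vector of the same length.
#' @export
#' @examples
#' betaBinomialNLL(1, 1, 1, 1)  # log(2)
betaBinomialNLL <- function(alpha, beta, k, n) {
  if (any(alpha <= 0) || any(beta <= 0))
    stop("alpha and beta must be strictly positive", call. = FALSE)
  if (any(n < 1) || any(k < 0) || any(k > n))
    stop("invalid label: require 0 <= k <= n, n >= 1", call. = FALSE)
  -(lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta))
}

# Gradient of betaBinomialNLL w.r.t. (alpha, beta).
betaBinomialNLLGrad <- function(alpha, beta, k, n) {
  common <- digamma(n + alpha + beta) - digamma(alpha + beta)
  list(alpha = -(digamma(k + alpha) - digamma(alpha)) + common,
       beta = -(digamma(n - k + beta) - digamma(beta)) + common)
}

#' Per-pixel binary cross-entropy between a probability map and its truth
#'
#' Mean over pixels of `-[y log p + (1-y) log(1-p)]` with predictions
#' clipped to `[eps, 1-eps]`. Pass single maps (matrix/array) of equal
#' shape; averaging across a case's radiographs is done by [jointLoss()].
#'
#' @param predicted_map,truth_map Equal-shaped numeric arrays; truth in
#'   \{0, 1\}.
#' @param eps Clipping epsilon (default 1e-7).
#' @return Non-negative scalar.
#' @export
pixelBCE <- function(predicted_map, truth_map, eps = 1e-7) {
  if (!identical(dim(predicted_map), dim(truth_map)) ||
      length(predicted_map) != length(truth_map))
    stop("predicted and truth maps must have identical shape", call. = FALSE)
  p <- clamp(predicted_map, eps, 1 - eps)
  -mean(truth_map * log(p) + (1 - truth_map) * log(1 - p))
}

#' Rasterize reference boxes into ground-truth maps
#'
#' One binary mask per image per category at the localization-branch
#' resolution: a map pixel is 1 exactly when it falls inside some
#' reference box of that category (boxes are scaled from image to map
#' coordinates; a cell is positive when at least a quarter of it is
#' covered).
#'
#' @param case A [CxrCase-class] with standardized images.
#' @param map_h,map_w Localization-branch resolution.
#' @return List (per image) of `map_h x map_w x 8` arrays in \{0, 1\}.
#' @export
groundTruthMaps <- function(case, map_h, map_w) {
  cats <- cxrCategories()
  lapply(seq_along(case@images), function(ii) {
    im <- case@images[[ii]]
    arr <- array(0, c(map_h, map_w, 8L), dimnames = list(NULL, NULL, cats))
    tr <- case@truths[case@truths$image_index == ii, , drop = FALSE]
    for (j in seq_len(nrow(tr))) {
      b <- scaleBox(tr[j, c("row0", "col0", "row1", "col1")],
                    nrow(im), ncol(im), map_h, map_w)
      cover <- rasterizeCoverage(b, map_h, map_w)
      g <- tr$category[j]
      arr[, , g] <- pmax(arr[, , g], as.numeric(cover >= 0.25))
    }
    arr
  })
}

# Fractional coverage of each map cell by one (possibly fractional) box.
rasterizeCoverage <- function(box, h, w) {
  rows <- pmin(pmax(pmin(box[["row1"]], seq_len(h)) -
                      pmax(box[["row0"]], seq_len(h) - 1), 0), 1)
  cols <- pmin(pmax(pmin(box[["col1"]], seq_len(w)) -
                      pmax(box[["col0"]], seq_len(w) - 1), 0), 1)
  outer(rows, cols)
}

#' Joint training loss for one case
#'
#' The across-radiograph average per-pixel BCE of each category's
#' localization map plus the weighted beta-binomial NLL of its (alpha,
#' beta) output against the k-of-n label, summed across the 8 categories.
#'
#' @param prediction A [CasePrediction-class] or the list returned by the
#'   internal forward pass (fields `alpha`, `beta`, `maps`).
#' @param labels data.frame with columns `category`, `k`, `n` covering all
#'   8 categories.
#' @param maps List (per image) of truth arrays from [groundTruthMaps()].
#' @param w_cls,w_loc Per-category term weights (recycled).
#' @return List: `total`, and per-category `bce` and `nll` vectors.
#' @export
jointLoss <- function(prediction, labels, maps, w_cls = 1, w_loc = 1) {
  if (is(prediction, "CasePrediction"))
    prediction <- list(alpha = prediction@alpha, beta = prediction@beta,
                       maps = prediction@maps)
  cats <- cxrCategories()
  if (!all(cats %in% labels$category))
    stop("labels must cover all 8 categories", call. = FALSE)
  w_cls <- rep_len(w_cls, 8L); w_loc <- rep_len(w_loc, 8L)
  lab <- labels[match(cats, labels$category), ]
  nll <- betaBinomialNLL(prediction$alpha, prediction$beta, lab$k, lab$n)
  bce <- vapply(seq_along(cats), function(gi) {
    mean(vapply(seq_along(prediction$maps), function(ii)
      pixelBCE(prediction$maps[[ii]][, , gi], maps[[ii]][, , gi]),
      numeric(1)))
  }, numeric(1))
  names(bce) <- cats
  list(total = sum(w_loc * bce + w_cls * nll), bce = bce, nll = nll)
}

#' Random training augmentation
#'
#' Applies, each with its configured probability: rotation (uniform within
#' `rot_deg` degrees), horizontal and vertical flips, gamma correction,
#' contrast adjustment, and random cropping (at least `crop_min_area` of
#' the area, resized back to the original shape). Geometric transforms are
#' applied identically to the truth masks (nearest-neighbour); intensity
#' transforms touch only the image.
#'
#' @param image Standardized numeric matrix.
#' @param truth_masks List of binary matrices (image resolution) to carry
#'   through the geometric transforms; may be empty.
#' @param seed Integer seed (deterministic augmentation).
#' @param params List overriding defaults: `p_rot`, `rot_deg`, `p_hflip`,
#'   `p_vflip`, `p_gamma`, `gamma_range`, `p_contrast`, `contrast_range`,
#'   `p_crop`, `crop_min_area`.
#' @return List with `image` and `truth_masks`.
#' @export
augmentImage <- function(image, truth_masks = list(), seed = 1L,
                         params = list()) {
  d <- list(p_rot = 0.3, rot_deg = 10, p_hflip = 0.5, p_vflip = 0.1,
            p_gamma = 0.3, gamma_range = c(0.8, 1.25),
            p_contrast = 0.3, contrast_range = c(0.9, 1.1),
            p_crop = 0.2, crop_min_area = 0.9)
  d[names(params)] <- params
  set.seed(childSeed(seed, 31L))
  h <- nrow(image); w <- ncol(image)
  if (stats::runif(1) < d$p_rot) {
    ang <- stats::runif(1, -d$rot_deg, d$rot_deg)
    image <- rotateImage(image, ang)
    truth_masks <- lapply(truth_masks, function(m)
      rotateImage(m, ang, interp = "nearest"))
  }
  if (stats::runif(1) < d$p_hflip) {
    image <- image[, w:1, drop = FALSE]
    truth_masks <- lapply(truth_masks, function(m) m[, w:1, drop = FALSE])
  }
  if (stats::runif(1) < d$p_vflip) {
    image <- image[h:1, , drop = FALSE]
    truth_masks <- lapply(truth_masks, function(m) m[h:1, , drop = FALSE])
  }
  if (stats::runif(1) < d$p_crop) {
    frac <- sqrt(stats::runif(1, d$crop_min_area, 1))
    ch <- max(2L, round(h * frac)); cw <- max(2L, round(w * frac))
    r0 <- sample.int(h - ch + 1L, 1L); c0 <- sample.int(w - cw + 1L, 1L)
    image <- resampleImage(image[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L)],
                           h, w, antialias = FALSE)
    truth_masks <- lapply(truth_masks, function(m) {
      mm <- resampleImage(m[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L)],
                          h, w, antialias = FALSE)
      as.numeric(mm >= 0.5) * 1
    })
    truth_masks <- lapply(truth_masks, matrix, nrow = h)
  }
  if (stats::runif(1) < d$p_gamma) {
    g <- stats::runif(1, d$gamma_range[1], d$gamma_range[2])
    image <- image^g
  }
  if (stats::runif(1) < d$p_contrast) {
    s <- stats::runif(1, d$contrast_range[1], d$contrast_range[2])
    image <- clamp(0.5 + s * (image - 0.5), 0, 1)
  }
  list(image = clamp(image, 0, 1), truth_masks = truth_masks)
}

# ---- backward pass ---------------------------------------------------------

zeroGrads <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

addGrads <- function(a, b) {
  for (i in seq_along(a$conv_w)) {
    a$conv_w[[i]] <- a$conv_w[[i]] + b$conv_w[[i]]
    a$conv_b[[i]] <- a$conv_b[[i]] + b$conv_b[[i]]
  }
  for (nm in c("proj_w", "proj_b", "cls_w", "cls_b", "loc_w", "loc_b"))
    a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

# Gradient of the joint loss of one case w.r.t. every model parameter.
backwardCase <- function(model, fw, truth_maps, k, n, w_cls, w_loc) {
  cfg <- model@config; p <- model@params
  g <- zeroGrads(p)
  nimg <- length(fw$maps)
  npix <- cfg$map_height * cfg$map_width

  # classification branch
  gr <- betaBinomialNLLGrad(fw$alpha, fw$beta, k, n)
  g_ab <- c(w_cls * gr$alpha, w_cls * gr$beta)          # d loss / d (alpha,beta)
  g_z <- g_ab * (1 / (1 + exp(-fw$cls_z)))              # softplus'
  g$cls_w <- outer(fw$case_vec, g_z)
  g$cls_b <- g_z
  g_case <- drop(p$cls_w %*% g_z)

  # max over images -> winning image per coordinate (ties: first image)
  projm <- do.call(rbind, fw$proj)
  win <- max.col(t(projm), ties.method = "first")
  g_feat <- vector("list", nimg)
  for (ii in seq_len(nimg)) {
    g_proj <- ifelse(win == ii, g_case, 0)
    g_pre <- g_proj * (fw$proj_pre[[ii]] > 0)
    g$proj_w <- g$proj_w + outer(fw$encs[[ii]]$feature_vector, g_pre)
    g$proj_b <- g$proj_b + g_pre
    g_feat[[ii]] <- drop(p$proj_w %*% g_pre)
  }

  # localization branch + encoder, per image
  for (ii in seq_len(nimg)) {
    enc <- fw$encs[[ii]]
    Fm <- enc$feature_maps
    dmap <- dim(Fm)
    Fmat <- matrix(Fm, dmap[1] * dmap[2], dmap[3])
    pmap <- fw$maps[[ii]]
    # d(mean over images of per-pixel BCE)/d logit = (p - y)/(npix*nimg)
    gz <- sweep(matrix(pmap - truth_maps[[ii]], npix, 8L), 2L,
                w_loc / (npix * nimg), "*")
    g$loc_w <- g$loc_w + crossprod(Fmat, gz)
    g$loc_b <- g$loc_b + colSums(gz)
    g_F <- array(gz %*% t(p$loc_w), dmap)
    # global-pool path
    if ((cfg$global_pool %||% "max") == "avg") {
      g_x <- g_F + array(rep(g_feat[[ii]] / (dmap[1] * dmap[2]),
                             each = dmap[1] * dmap[2]), dmap)
    } else {
      g_x <- g_F
      amax <- fw$encs[[ii]]$cache$gpool_arg
      gm <- matrix(g_x, dmap[1] * dmap[2], dmap[3])
      gm[cbind(amax, seq_len(dmap[3]))] <-
        gm[cbind(amax, seq_len(dmap[3]))] + g_feat[[ii]]
      g_x <- array(gm, dmap)
    }
    cache <- enc$cache
    for (i in rev(seq_along(cfg$channels))) {
      for (kk in rev(seq_len(cfg$pools[i]))) {
        dd <- cache$pool_in_dim[[i]][[kk]]
        g_x <- .maxpool2_backward(cache$pool_arg[[i]][[kk]], g_x, dd[1], dd[2])
      }
      g_a <- g_x * cache$relu_mask[[i]]
      bw <- .conv3x3_backward(cache$stage_in[[i]], p$conv_w[[i]], g_a)
      g$conv_w[[i]] <- g$conv_w[[i]] + bw$grad_weight
      g$conv_b[[i]] <- g$conv_b[[i]] + as.numeric(bw$grad_bias)
      g_x <- bw$grad_input
    }
  }
  g
}

adamwInit <- function(params) {
  list(m = zeroGrads(params), v = zeroGrads(params), t = 0L)
}

adamwStep <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    p <- p - lr * (mh / (sqrt(vh) + eps) + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(params$conv_w)) {
    u <- upd(params$conv_w[[i]], grads$conv_w[[i]],
             state$m$conv_w[[i]], state$v$conv_w[[i]])
    params$conv_w[[i]] <- u$p; state$m$conv_w[[i]] <- u$m; state$v$conv_w[[i]] <- u$v
    u <- upd(params$conv_b[[i]], grads$conv_b[[i]],
             state$m$conv_b[[i]], state$v$conv_b[[i]])
    params$conv_b[[i]] <- u$p; state$m$conv_b[[i]] <- u$m; state$v$conv_b[[i]] <- u$v
  }
  for (nm in c("proj_w", "proj_b", "cls_w", "cls_b", "loc_w", "loc_b")) {
    u <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- u$p; state$m[[nm]] <- u$m; state$v[[nm]] <- u$v
  }
  list(params = params, state = state)
}

# Across-category mean AUC of posterior-mean scores on a case set.
tuneMeanAUC <- function(model, tune_set, warn_empty = FALSE) {
  preds <- predictCases(model, tune_set)
  scr <- scoreTable(preds)
  lab <- caseLabels(tune_set)
  merged <- merge(scr, lab[, c("case_id", "category", "reference")],
                  by = c("case_id", "category"))
  aucs <- vapply(cxrCategories(), function(g) {
    sub <- merged[merged$category == g, ]
    if (length(unique(sub$reference)) < 2L) {
      if (warn_empty)
        warning("category '", g, "' has a single class in the tuning set; ",
                "excluded from the mean AUC", call. = FALSE)
      return(NA_real_)
    }
    rocAuc(sub$score, sub$reference)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Score table from predictions
#'
#' Long-format posterior-mean scores, one row per (case, category).
#'
#' @param predictions List of [CasePrediction-class].
#' @return data.frame with `case_id`, `category`, `score`.
#' @export
scoreTable <- function(predictions) {
  do.call(rbind, lapply(predictions, function(pr)
    data.frame(case_id = pr@case_id, category = cxrCategories(),
               score = unname(pr@alpha / (pr@alpha + pr@beta)),
               stringsAsFactors = FALSE)))
}

#' Train the analysis-stage network
#'
#' Iterates over the training cases in randomized batches, minimizing the
#' joint loss with AdamW. After each epoch the across-category mean AUC of
#' the posterior-mean scores on the tuning set is computed; training stops
#' once no improvement has occurred within the patience window (or at
#' `max_epochs`), and the best-epoch weights are returned. Deterministic
#' for a fixed configuration seed.
#'
#' @param train_set,tune_set Disjoint [CxrCaseSet-class] objects with
#'   standardized images.
#' @param config A [trainingConfig()].
#' @param model_config A [modelConfig()].
#' @param verbose Emit one log line per epoch.
#' @return List: `model` (best-epoch [CxrModel-class]), `history`
#'   (data.frame: epoch, loss, bce, nll, tune_mean_auc), `best_epoch`,
#'   `stopped_epoch`.
#' @export
trainModel <- function(train_set, tune_set, config = trainingConfig(),
                       model_config = modelConfig("test"), verbose = FALSE) {
  stopifnot(is(train_set, "CxrCaseSet"), is(tune_set, "CxrCaseSet"))
  model <- initModel(model_config, seed = config$seed)
  state <- adamwInit(model@params)
  ncase <- nCases(train_set)
  lab <- caseLabels(train_set)
  cats <- cxrCategories()
  mh <- model@config$map_height; mw <- model@config$map_width

  # Per-case (k, n) matrices and ground-truth masks at image resolution
  # (masks are re-derived per epoch only when augmenting).
  kmat <- nmat <- matrix(0L, ncase, 8L)
  for (i in seq_len(ncase)) {
    li <- lab[lab$case_id == train_set@cases[[i]]@case_id, ]
    li <- li[match(cats, li$category), ]
    kmat[i, ] <- li$k; nmat[i, ] <- li$n
  }
  base_maps <- lapply(train_set@cases, groundTruthMaps, map_h = mh, map_w = mw)

  history <- data.frame(epoch = integer(), loss = numeric(), bce = numeric(),
                        nll = numeric(), tune_mean_auc = numeric())
  best_auc <- -Inf; best_epoch <- 0L; best_params <- model@params
  warned <- FALSE

  for (epoch in seq_len(config$max_epochs)) {
    set.seed(childSeed(config$seed, 300L + epoch))
    order_idx <- sample.int(ncase)
    ep_loss <- ep_bce <- ep_nll <- 0
    batches <- split(order_idx, ceiling(seq_along(order_idx) /
                                          config$batch_size_cases))
    for (b in batches) {
      grads <- zeroGrads(model@params)
      for (ci in b) {
        cs <- train_set@cases[[ci]]
        images <- cs@images
        tmaps <- base_maps[[ci]]
        if (config$augment) {
          for (ii in seq_along(images)) {
            masks <- lapply(seq_len(8L), function(gi) {
              tr <- cs@truths[cs@truths$image_index == ii &
                                cs@truths$category == cats[gi], , drop = FALSE]
              rasterizeBoxes(tr, nrow(images[[ii]]), ncol(images[[ii]]))
            })
            aug <- augmentImage(images[[ii]], masks,
                                seed = childSeed(config$seed,
                                                 epoch * 100000L + ci * 10L + ii),
                                params = config$augment_params)
            images[[ii]] <- aug$image
            arr <- array(0, c(mh, mw, 8L), dimnames = list(NULL, NULL, cats))
            for (gi in seq_len(8L)) {
              small <- resampleImage(aug$truth_masks[[gi]], mh, mw)
              arr[, , gi] <- as.numeric(small >= 0.25)
            }
            tmaps[[ii]] <- arr
          }
        }
        fw <- forwardCase(model, images, keep_cache = TRUE)
        ll <- jointLoss(fw, data.frame(category = cats, k = kmat[ci, ],
                                       n = nmat[ci, ]),
                        tmaps, w_cls = config$w_cls, w_loc = config$w_loc)
        ep_loss <- ep_loss + ll$total
        ep_bce <- ep_bce + sum(ll$bce); ep_nll <- ep_nll + sum(ll$nll)
        g <- backwardCase(model, fw, tmaps, kmat[ci, ], nmat[ci, ],
                          config$w_cls, config$w_loc)
        grads <- addGrads(grads, g)
      }
      grads <- rapply(grads, function(x) x / length(b), how = "replace")
      st <- adamwStep(model@params, grads, state, config$lr,
                      config$weight_decay)
      model@params <- st$params; state <- st$state
    }
    auc <- withCallingHandlers(
      tuneMeanAUC(model, tune_set, warn_empty = !warned),
      warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
    history <- rbind(history, data.frame(
      epoch = epoch, loss = ep_loss / ncase, bce = ep_bce / ncase,
      nll = ep_nll / ncase, tune_mean_auc = auc))
    if (verbose)
      message(sprintf("epoch %3d | loss %.4f (bce %.4f, nll %.4f) | tune mean AUC %.4f",
                      epoch, ep_loss / ncase, ep_bce / ncase, ep_nll / ncase, auc))
    if (is.finite(auc) && auc > best_auc) {
      best_auc <- auc; best_epoch <- epoch; best_params <- model@params
    }
    if (epoch - best_epoch >= config$patience) break
  }
  model@params <- best_params
  list(model = model, history = history, best_epoch = best_epoch,
       stopped_epoch = nrow(history))
}

#' Fit the beta-binomial likelihood alone to k-of-n labels
#'
#' Maximum-likelihood estimation of (alpha, beta) over a sample of k-of-n
#' counts by minimizing the summed [betaBinomialNLL()] (L-BFGS-B on
#' log-parameters). The fitted posterior mean `alpha/(alpha+beta)` is the
#' recovered positive rate.
#'
#' @param k,n Integer vectors of labels.
#' @param init Starting (alpha, beta).
#' @return List: `alpha`, `beta`, `mean`, `nll`.
#' @export
fitBetaBinomial <- function(k, n, init = c(1, 1)) {
  obj <- function(lp) sum(betaBinomialNLL(exp(lp[1]), exp(lp[2]), k, n))
  fit <- stats::optim(log(init), obj, method = "L-BFGS-B",
                      lower = log(1e-4), upper = log(1e6))
  a <- exp(fit$par[1]); b <- exp(fit$par[2])
  list(alpha = a, beta = b, mean = a / (a + b), nll = fit$value)
}
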