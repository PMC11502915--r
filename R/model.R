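#' Model architecture configuration
#'
#' The analysis-stage network is a convolutional image encoder (a chain of
#' 3x3 convolution + ReLU stages with 2x max-pooling between them), a
#' shared fully connected projection to the case feature dimension,
#' max-pooling across the case's 1-2 radiographs, a classification head
#' emitting per-category (alpha, beta) beta-binomial parameters, and a 1x1
#' convolutional localization head applied to the encoder's penultimate
#' feature maps.
#'
#' The `"test"` profile is a 4-stage encoder on 64 x 80 inputs (32-dim
#' image features, 64-dim case features) that trains on a CPU in minutes.
#' The `"deployed"` profile mirrors the deployed geometry: 800 x 1024 inputs
#' and a deep encoder ending in a 512-dimensional per-radiograph feature
#' vector projected to a 1024-dimensional case embedding. The encoder is
#' a plain convolutional chain; the profile reproduces the deployed
#' network's interface (feature dimensions and map resolution), not its
#' residual wiring.
#'
#' @param profile `"test"` or `"deployed"`.
#' @param input_height,input_width Standardized input geometry.
#' @param channels Integer vector: output channels of each encoder stage.
#' @param pools Integer vector, same length: number of 2x max-pools after
#'   each stage. The last stage is the penultimate feature-map source.
#' @param case_feature_dim Dimension of the case embedding.
#' @param upsample `"bilinear"` or `"nearest"`: how localization maps are
#'   lifted back to image resolution for box extraction.
#' @param global_pool `"max"` (default) or `"avg"`: spatial pooling that
#'   turns the final feature maps into the per-image feature vector. Max
#'   pooling keeps small high-contrast abnormalities from being diluted
#'   over the map.
#' @return A list of class `ModelConfig`.
#' @export
modelConfig <- function(profile = c("test", "deployed"),
                        input_height = NULL, input_width = NULL,
                        channels = NULL, pools = NULL,
                        case_feature_dim = NULL,
                        upsample = c("bilinear", "nearest"),
                        global_pool = c("max", "avg")) {
  profile <- match.arg(profile)
  upsample <- match.arg(upsample)
  global_pool <- match.arg(global_pool)
  d <- switch(profile,
    test  = list(h = 64L, w = 80L, ch = c(8L, 16L, 32L, 32L),
                 po = c(1L, 1L, 1L, 0L), cd = 64L),
    deployed = list(h = 800L, w = 1024L, ch = c(64L, 128L, 256L, 512L, 512L),
                 po = c(2L, 1L, 1L, 1L, 0L), cd = 1024L))
  cfg <- list(profile = profile,
              input_height = input_height %||% d$h,
              input_width = input_width %||% d$w,
              channels = channels %||% d$ch,
              pools = pools %||% d$po,
              case_feature_dim = case_feature_dim %||% d$cd,
              n_categories = 8L,
              upsample = upsample,
              global_pool = global_pool)
  if (length(cfg$channels) != length(cfg$pools))
    stop("channels and pools must have the same length", call. = FALSE)
  stride <- 2^sum(cfg$pools)
  if (cfg$input_height %% stride != 0 || cfg$input_width %% stride != 0)
    stop("input dimensions must be divisible by the total pooling stride ",
         stride, call. = FALSE)
  cfg$image_feature_dim <- cfg$channels[length(cfg$channels)]
  cfg$map_height <- cfg$input_height %/% stride
  cfg$map_width <- cfg$input_width %/% stride
  structure(cfg, class = "ModelConfig")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

heInit <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

#' Initialize a model with random weights
#'
#' He-normal initialization; deterministic for a fixed seed.
#'
#' @param config A [modelConfig()].
#' @param seed Integer seed.
#' @return A [CxrModel-class].
#' @export
initModel <- function(config = modelConfig("test"), seed = 1L) {
  set.seed(childSeed(seed, 101L))
  nstage <- length(config$channels)
  cin <- c(1L, config$channels[-nstage])
  params <- list(conv_w = vector("list", nstage),
                 conv_b = vector("list", nstage))
  for (i in seq_len(nstage)) {
    params$conv_w[[i]] <- heInit(9L * cin[i], config$channels[i])
    params$conv_b[[i]] <- numeric(config$channels[i])
  }
  fd <- config$image_feature_dim; cd <- config$case_feature_dim
  params$proj_w <- heInit(fd, cd); params$proj_b <- numeric(cd)
  params$cls_w <- heInit(cd, 2L * config$n_categories)
  params$cls_b <- numeric(2L * config$n_categories)
  params$loc_w <- heInit(config$image_feature_dim, config$n_categories)
  params$loc_b <- numeric(config$n_categories)
  new("CxrModel", params = params, config = unclass(config),
      version = sprintf("cxrcad-cnn/%s-%s", config$profile,
                        paste(config$channels, collapse = ".")))
}

# Full encoder forward for one image; cache holds everything the backward
# pass needs (stage inputs, ReLU masks, pool argmaxes).
encoderForward <- function(model, image, keep_cache = FALSE) {
  cfg <- model@config; p <- model@params
  if (nrow(image) != cfg$input_height || ncol(image) != cfg$input_width)
    stop("image shape ", nrow(image), "x", ncol(image),
         " does not match the model input ", cfg$input_height, "x",
         cfg$input_width, call. = FALSE)
  # center intensities so first-layer features see signed inputs
  x <- array(image - 0.5, c(nrow(image), ncol(image), 1L))
  cache <- list(stage_in = list(), relu_mask = list(), pool_arg = list(),
                pool_in_dim = list())
  for (i in seq_along(cfg$channels)) {
    if (keep_cache) cache$stage_in[[i]] <- x
    a <- .conv3x3_forward(x, p$conv_w[[i]], p$conv_b[[i]])
    mask <- a > 0
    x <- a * mask
    if (keep_cache) cache$relu_mask[[i]] <- mask
    args <- vector("list", cfg$pools[i])
    dims <- vector("list", cfg$pools[i])
    for (k in seq_len(cfg$pools[i])) {
      dims[[k]] <- dim(x)[1:2]
      pl <- .maxpool2_forward(x)
      x <- pl$output
      args[[k]] <- pl$argmax
    }
    if (keep_cache) { cache$pool_arg[[i]] <- args; cache$pool_in_dim[[i]] <- dims }
  }
  if ((cfg$global_pool %||% "max") == "avg") {
    feat <- apply(x, 3, mean)
  } else {
    d <- dim(x)
    xm <- matrix(x, d[1] * d[2], d[3])
    amax <- max.col(t(xm), ties.method = "first")
    feat <- xm[cbind(amax, seq_len(d[3]))]
    if (keep_cache) cache$gpool_arg <- amax
  }
  list(feature_vector = feat, feature_maps = x,
       cache = if (keep_cache) cache else NULL)
}

#' Encode one radiograph
#'
#' Runs the image through the convolutional encoder, returning the pooled
#' per-image feature vector and the penultimate-stage spatial feature maps
#' consumed by the localization branch.
#'
#' @param model A [CxrModel-class].
#' @param image Standardized numeric matrix matching the model input shape.
#' @return List with `feature_vector` (length `image_feature_dim`) and
#'   `feature_maps` (map_height x map_width x image_feature_dim array).
#' @export
encodeImage <- function(model, image) {
  out <- encoderForward(model, image, keep_cache = FALSE)
  out[c("feature_vector", "feature_maps")]
}

#' Pool per-image features into a case embedding
#'
#' Each per-image feature vector is passed through the shared fully
#' connected projection (ReLU) to the case feature dimension, then the
#' 1-2 projected vectors are collapsed by elementwise maximum. The result
#' is therefore invariant to image order and coordinate-wise monotone in
#' the evidence of either image.
#'
#' @param model A [CxrModel-class].
#' @param feature_vectors List of 1-2 vectors of length `image_feature_dim`.
#' @return Numeric vector of length `case_feature_dim`.
#' @export
caseEmbedding <- function(model, feature_vectors) {
  if (length(feature_vectors) < 1L)
    stop("a case must provide at least one feature vector", call. = FALSE)
  p <- model@params
  proj <- lapply(feature_vectors, function(v) {
    pmax(drop(v %*% p$proj_w) + p$proj_b, 0)
  })
  Reduce(pmax, proj)
}

#' Classification head: beta-binomial parameters per category
#'
#' A fully connected layer maps the case embedding to 2 logits per
#' category; softplus plus a small floor guarantees strictly positive
#' (alpha, beta).
#'
#' @param model A [CxrModel-class].
#' @param case_vector Case embedding of length `case_feature_dim`.
#' @return Matrix 8 x 2 with columns `alpha`, `beta`, rows named by
#'   category.
#' @export
classificationHead <- function(model, case_vector) {
  p <- model@params
  z <- drop(case_vector %*% p$cls_w) + p$cls_b
  if (any(!is.finite(z)))
    stop("non-finite activations in the classification head", call. = FALSE)
  ab <- softplus(z) + 1e-4
  out <- matrix(ab, ncol = 2L, dimnames = list(cxrCategories(), c("alpha", "beta")))
  out
}

#' Localization head: per-category probability maps
#'
#' A 1x1 convolution (shared across pixels) over the encoder's penultimate
#' feature maps, followed by a sigmoid, gives one probability map per
#' category at the penultimate resolution. Use [upsampleMap()] to lift a
#' map to image coordinates for box extraction.
#'
#' @param model A [CxrModel-class].
#' @param feature_maps Array from [encodeImage()].
#' @return Array map_height x map_width x 8 with values in \[0, 1\].
#' @export
localizationHead <- function(model, feature_maps) {
  p <- model@params
  d <- dim(feature_maps)
  F <- matrix(feature_maps, d[1] * d[2], d[3])
  z <- sweep(F %*% p$loc_w, 2L, p$loc_b, "+")
  array(1 / (1 + exp(-z)), c(d[1], d[2], ncol(p$loc_w)),
        dimnames = list(NULL, NULL, cxrCategories()))
}

#' Upsample a localization map to image resolution
#'
#' @param map Matrix (one category's map).
#' @param out_h,out_w Target size.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return Matrix out_h x out_w.
#' @export
upsampleMap <- function(map, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (method == "bilinear") return(clamp(resampleImage(map, out_h, out_w, antialias = FALSE), 0, 1))
  ri <- clamp(floor((seq_len(out_h) - 0.5) * nrow(map) / out_h) + 1, 1, nrow(map))
  ci <- clamp(floor((seq_len(out_w) - 0.5) * ncol(map) / out_w) + 1, 1, ncol(map))
  map[ri, ci, drop = FALSE]
}

# Full forward pass over one case; returns prediction pieces (+ caches).
forwardCase <- function(model, images, keep_cache = FALSE) {
  encs <- lapply(images, encoderForward, model = model, keep_cache = keep_cache)
  p <- model@params
  feats <- lapply(encs, `[[`, "feature_vector")
  proj_pre <- lapply(feats, function(v) drop(v %*% p$proj_w) + p$proj_b)
  proj <- lapply(proj_pre, pmax, 0)
  case_vec <- Reduce(pmax, proj)
  z <- drop(case_vec %*% p$cls_w) + p$cls_b
  ab <- softplus(z) + 1e-4
  nms <- cxrCategories()
  alpha <- setNames(ab[seq_len(8L)], nms)
  beta <- setNames(ab[9:16], nms)
  maps <- lapply(encs, function(e) localizationHead(model, e$feature_maps))
  list(alpha = alpha, beta = beta, maps = maps, case_vec = case_vec,
       cls_z = z, proj_pre = proj_pre, proj = proj, encs = encs)
}

#' @describeIn predictCases Forward every case of a set through the model.
#' @param seed Unused (prediction is deterministic); present for interface
#'   symmetry.
#' @export
setMethod("predictCases", "CxrModel", function(object, cases, seed = NULL, ...) {
  case_list <- if (is(cases, "CxrCaseSet")) cases@cases else cases
  lapply(case_list, function(cs) {
    fw <- forwardCase(object, cs@images)
    new("CasePrediction", case_id = cs@case_id, alpha = fw$alpha,
        beta = fw$beta, maps = fw$maps, model_version = object@version)
  })
})
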