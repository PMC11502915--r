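#' Configuration for the phantom-case generator
#'
#' Phantom radiographs are a smoothed random field plus a coarse thorax-like
#' intensity gradient; abnormalities are high-contrast parametric shapes,
#' one characteristic shape family (kind, contrast sign, scale) per
#' category, so that a small convolutional network can learn them.
#'
#' Default prevalences follow the per-category reference-positive rates of
#' a large multi-site chest X-ray testing population; the default
#' two-image probability reproduces an average of about 1.45 radiographs
#' per case.
#'
#' @param image_height,image_width Phantom size in pixels.
#' @param prevalence Named numeric vector over [cxrCategories()], each in
#'   \[0, 1\]: probability that a case truly contains that category.
#' @param two_image_prob Probability that a case has 2 radiographs.
#' @param noise_amplitude Background texture amplitude.
#' @return A validated list of class `GeneratorConfig`.
#' @export
#' @examples
#' cfg <- generatorConfig(prevalence = rep(0.25, 8))
#' cs <- generateCase(cfg, seed = 1)
#' cs
generatorConfig <- function(image_height = 100, image_width = 125,
                            prevalence = c(Cardiac = 0.3157,
                                           `Mediastinum/Hila` = 0.2023,
                                           Lungs = 0.6107, Pleura = 0.3254,
                                           Bones = 0.1234,
                                           `Soft Tissues` = 0.0357,
                                           Hardware = 0.4957, Other = 0.0833),
                            two_image_prob = 0.45,
                            noise_amplitude = 0.04) {
  if (image_height < 48 || image_width < 48)
    stop("image size too small to host the smallest abnormality shape ",
         "(minimum 48x48)", call. = FALSE)
  if (is.null(names(prevalence))) names(prevalence) <- cxrCategories()
  prevalence <- prevalence[cxrCategories()]
  if (anyNA(prevalence) || any(prevalence < 0) || any(prevalence > 1))
    stop("prevalence must be named over the 8 categories with values in [0,1]",
         call. = FALSE)
  if (two_image_prob < 0 || two_image_prob > 1)
    stop("two_image_prob must lie in [0,1]", call. = FALSE)
  structure(list(image_height = image_height, image_width = image_width,
                 prevalence = prevalence, two_image_prob = two_image_prob,
                 noise_amplitude = noise_amplitude),
            class = "GeneratorConfig")
}

# One characteristic shape family per category. Contrast signs and scales
# are chosen pairwise-distinct so the 8 classes remain separable under
# mild augmentation.
shapeCatalog <- function() {
  list(
    "Cardiac"          = list(kind = "blob", contrast = +0.50, size = c(0.20, 0.28)),
    "Lungs"            = list(kind = "blob", contrast = -0.45, size = c(0.11, 0.17)),
    "Mediastinum/Hila" = list(kind = "ring", contrast = +0.50, size = c(0.15, 0.21)),
    "Hardware"         = list(kind = "ring", contrast = -0.50, size = c(0.08, 0.12)),
    "Pleura"           = list(kind = "line", contrast = +0.50, size = c(0.35, 0.50), angle = 45),
    "Bones"            = list(kind = "line", contrast = -0.45, size = c(0.35, 0.50), angle = 0),
    "Soft Tissues"     = list(kind = "grid-texture", contrast = +0.45, size = c(0.22, 0.32), period = 8),
    "Other"            = list(kind = "grid-texture", contrast = -0.45, size = c(0.22, 0.32), period = 16)
  )
}

# Draw one shape onto `image`; returns list(image, box) with the tight
# 0-based half-open bounding box of the painted pixels.
drawShape <- function(image, spec) {
  h <- nrow(image); w <- ncol(image)
  m <- min(h, w)
  sz <- stats::runif(1, spec$size[1], spec$size[2]) * m
  rg <- outer(seq_len(h) - 1, rep(1, w))
  cg <- outer(rep(1, h), seq_len(w) - 1)
  # half-extent of the shape: blob/ring sizes are radii, line/grid extents
  half <- switch(spec$kind, blob = sz, ring = sz, sz / 2)
  margin <- min(half + 2, (min(h, w) - 4) / 2)
  cr <- stats::runif(1, margin, h - 1 - margin)
  cc <- stats::runif(1, margin, w - 1 - margin)
  mask <- switch(spec$kind,
    blob = {
      a <- sz * stats::runif(1, 0.8, 1.0); b <- sz * stats::runif(1, 0.6, 0.9)
      ((rg - cr) / a)^2 + ((cg - cc) / b)^2 <= 1
    },
    ring = {
      r_out <- sz; r_in <- sz * stats::runif(1, 0.5, 0.65)
      d2 <- (rg - cr)^2 + (cg - cc)^2
      d2 <= r_out^2 & d2 >= r_in^2
    },
    line = {
      th <- (spec$angle + stats::runif(1, -8, 8)) * pi / 180
      len <- sz; wid <- max(2, 0.04 * m)
      u <- (rg - cr) * sin(th) + (cg - cc) * cos(th)   # along
      v <- (rg - cr) * cos(th) - (cg - cc) * sin(th)   # across
      abs(u) <= len / 2 & abs(v) <= wid / 2
    },
    `grid-texture` = {
      ext <- sz
      inside <- abs(rg - cr) <= ext / 2 & abs(cg - cc) <= ext / 2
      checker <- ((rg %/% spec$period) + (cg %/% spec$period)) %% 2 == 0
      inside & checker
    },
    stop("unknown shape kind: ", spec$kind))
  if (!any(mask)) return(NULL)
  image[mask] <- clamp(image[mask] + spec$contrast, 0, 1)
  rr <- range(rg[mask]); cc2 <- range(cg[mask])
  list(image = image,
       box = c(row0 = rr[1], col0 = cc2[1], row1 = rr[2] + 1, col1 = cc2[2] + 1))
}

phantomBackground <- function(h, w, noise_amplitude) {
  cc <- (w - 1) / 2
  cols <- outer(rep(1, h), seq_len(w) - 1)
  rows <- outer(seq_len(h) - 1, rep(1, w))
  base <- 0.30 + 0.28 * exp(-((cols - cc) / (0.40 * w))^2) *
    (1 - 0.25 * rows / h)
  noise <- gaussBlur(matrix(stats::rnorm(h * w), h, w), sigma = 2.5)
  noise <- noise / max(1e-8, stats::sd(noise)) * noise_amplitude
  clamp(base + noise, 0.02, 0.92)
}

#' Generate one phantom chest X-ray case
#'
#' Deterministic for a fixed `(gen_config, seed)` pair. Each category is
#' independently present with its configured prevalence; a present
#' category plants one characteristic shape in one of the case's 1-2
#' radiographs and records its tight bounding box as truth. A case may
#' carry zero abnormalities (a normal case).
#'
#' @param gen_config A [generatorConfig()].
#' @param seed Integer seed.
#' @param case_id Optional id; defaults to `"case<seed>"`.
#' @return A [CxrCase-class].
#' @export
generateCase <- function(gen_config, seed, case_id = NULL) {
  stopifnot(inherits(gen_config, "GeneratorConfig"))
  set.seed(childSeed(seed, 11L))
  h <- gen_config$image_height; w <- gen_config$image_width
  n_img <- 1L + stats::rbinom(1L, 1L, gen_config$two_image_prob)
  images <- lapply(seq_len(n_img), function(i)
    phantomBackground(h, w, gen_config$noise_amplitude))
  catalog <- shapeCatalog()
  present <- stats::runif(8) < gen_config$prevalence
  truths <- data.frame(category = character(), image_index = integer(),
                       row0 = numeric(), col0 = numeric(),
                       row1 = numeric(), col1 = numeric(),
                       shape_kind = character(), stringsAsFactors = FALSE)
  for (gi in seq_along(cxrCategories())) {
    if (!present[gi]) next
    g <- cxrCategories()[gi]
    ii <- sample.int(n_img, 1L)
    drawn <- drawShape(images[[ii]], catalog[[g]])
    if (is.null(drawn)) next
    images[[ii]] <- drawn$image
    truths <- rbind(truths, data.frame(
      category = g, image_index = ii,
      row0 = drawn$box[["row0"]], col0 = drawn$box[["col0"]],
      row1 = drawn$box[["row1"]], col1 = drawn$box[["col1"]],
      shape_kind = catalog[[g]]$kind, stringsAsFactors = FALSE))
  }
  meta <- list(
    sex = sample(c("F", "M"), 1L, prob = c(0.52, 0.48)),
    age_group = sample(c("22-44", "45-64", "65-74", "75+"), 1L,
                       prob = c(0.174, 0.372, 0.218, 0.236)))
  new("CxrCase", case_id = case_id %||% paste0("case", seed),
      images = images, truths = truths, patient_meta = meta)
}

#' Configuration of a simulated labeler panel
#'
#' Each of `n_labelers` simulated experts independently calls a category
#' positive with probability `sensitivity` when the case truly contains it
#' and with probability `1 - specificity` when it does not, yielding the
#' k-of-n counts the beta-binomial head models. Positive labelers on a
#' truly positive category emit a jittered copy of the truth box (uniform
#' shift/scale up to `box_jitter` of the box side).
#'
#' @param n_labelers Number of panel members (>= 1); 3 reproduces the
#'   majority-of-three reference standard.
#' @param sensitivity,specificity Per-category probabilities in (0, 1\];
#'   scalars are recycled across the 8 categories.
#' @param box_jitter Maximum relative shift/scale of labeler boxes.
#' @return A validated list of class `LabelerPanelConfig`.
#' @export
labelerPanelConfig <- function(n_labelers = 3L, sensitivity = 0.90,
                               specificity = 0.97, box_jitter = 0.10) {
  if (n_labelers < 1) stop("n_labelers must be >= 1", call. = FALSE)
  sens <- rep_len(sensitivity, 8L); spec <- rep_len(specificity, 8L)
  if (any(sens <= 0) || any(sens > 1) || any(spec <= 0) || any(spec > 1))
    stop("sensitivity and specificity must lie in (0, 1]", call. = FALSE)
  names(sens) <- names(spec) <- cxrCategories()
  structure(list(n_labelers = as.integer(n_labelers), sensitivity = sens,
                 specificity = spec, box_jitter = box_jitter),
            class = "LabelerPanelConfig")
}

jitterBox <- function(box, jitter) {
  side_r <- box[["row1"]] - box[["row0"]]; side_c <- box[["col1"]] - box[["col0"]]
  dr <- stats::runif(1, -jitter, jitter) * side_r
  dc <- stats::runif(1, -jitter, jitter) * side_c
  sr <- 1 + stats::runif(1, -jitter, jitter)
  sc <- 1 + stats::runif(1, -jitter, jitter)
  cr <- (box[["row0"]] + box[["row1"]]) / 2 + dr
  cc <- (box[["col0"]] + box[["col1"]]) / 2 + dc
  c(row0 = cr - sr * side_r / 2, col0 = cc - sc * side_c / 2,
    row1 = cr + sr * side_r / 2, col1 = cc + sc * side_c / 2)
}

#' Simulate a labeler panel reading one case
#'
#' @param case A [CxrCase-class].
#' @param panel A [labelerPanelConfig()].
#' @param seed Integer seed.
#' @return List with `labels` (data.frame: category, k, n, truth) and
#'   `labeler_boxes` (data.frame of positive labelers' jittered boxes).
#' @export
simulateLabels <- function(case, panel, seed = 1L) {
  stopifnot(is(case, "CxrCase"), inherits(panel, "LabelerPanelConfig"))
  set.seed(childSeed(seed, 23L))
  n <- panel$n_labelers
  cats <- cxrCategories()
  truth <- cats %in% case@truths$category
  labels <- data.frame(category = cats, k = 0L, n = n, truth = as.integer(truth),
                       stringsAsFactors = FALSE)
  boxes <- list()
  for (gi in seq_along(cats)) {
    p <- if (truth[gi]) panel$sensitivity[gi] else 1 - panel$specificity[gi]
    calls <- stats::runif(n) < p
    labels$k[gi] <- sum(calls)
    if (truth[gi] && any(calls)) {
      tr <- case@truths[case@truths$category == cats[gi], ][1, ]
      im <- case@images[[tr$image_index]]
      for (l in which(calls)) {
        jb <- jitterBox(c(row0 = tr$row0, col0 = tr$col0,
                          row1 = tr$row1, col1 = tr$col1), panel$box_jitter)
        jb <- c(row0 = max(0, jb[["row0"]]), col0 = max(0, jb[["col0"]]),
                row1 = min(nrow(im), jb[["row1"]]),
                col1 = min(ncol(im), jb[["col1"]]))
        boxes[[length(boxes) + 1L]] <- data.frame(
          case_id = case@case_id, category = cats[gi], labeler = l,
          image_index = tr$image_index, row0 = jb[["row0"]],
          col0 = jb[["col0"]], row1 = jb[["row1"]], col1 = jb[["col1"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  list(labels = labels,
       labeler_boxes = if (length(boxes)) do.call(rbind, boxes) else
         data.frame(case_id = character(), category = character(),
                    labeler = integer(), image_index = integer(),
                    row0 = numeric(), col0 = numeric(), row1 = numeric(),
                    col1 = numeric(), stringsAsFactors = FALSE))
}

#' Majority-vote reference standard from a k-of-n label
#'
#' Positive when a strict majority of the panel called the category
#' abnormal: for n = 3 that is at least two of three; for n = 1, the single
#' call; for even n a tie is negative.
#'
#' @param k,n Integer vectors (recycled), 0 <= k <= n, n >= 1.
#' @return Integer vector of 0/1 reference calls.
#' @export
#' @examples
#' referenceStandard(2, 3)  # 1
#' referenceStandard(1, 3)  # 0
referenceStandard <- function(k, n) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("invalid label: require 0 <= k <= n", call. = FALSE)
  as.integer(k > n / 2)
}

#' Generate a labeled collection of phantom cases
#'
#' Convenience wrapper: generates `n_cases` cases, runs the simulated
#' labeler panel over each, and attaches the majority-vote reference
#' standard. Deterministic for fixed `(gen_config, panel, seed)`.
#'
#' @param n_cases Number of cases.
#' @param gen_config A [generatorConfig()].
#' @param panel A [labelerPanelConfig()].
#' @param seed Integer seed.
#' @param id_prefix Prefix for case ids.
#' @return A [CxrCaseSet-class].
#' @export
buildCaseSet <- function(n_cases, gen_config = generatorConfig(),
                         panel = labelerPanelConfig(), seed = 1L,
                         id_prefix = "case") {
  cases <- vector("list", n_cases)
  labels <- vector("list", n_cases)
  lboxes <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    s <- childSeed(seed, 1000L + i)
    cs <- generateCase(gen_config, s, case_id = sprintf("%s%04d", id_prefix, i))
    sl <- simulateLabels(cs, panel, seed = childSeed(seed, 2000L + i))
    lab <- sl$labels
    lab$case_id <- cs@case_id
    lab$reference <- referenceStandard(lab$k, lab$n)
    cases[[i]] <- cs
    labels[[i]] <- lab[, c("case_id", "category", "k", "n", "reference", "truth")]
    lboxes[[i]] <- sl$labeler_boxes
  }
  new("CxrCaseSet", cases = cases, labels = do.call(rbind, labels),
      labeler_boxes = do.call(rbind, lboxes))
}
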