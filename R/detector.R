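#' Detector backend configuration
#'
#' Configuration of the reference hotspot-detector backend: a classical
#' pipeline of multi-scale difference-of-Gaussians blob proposal followed
#' by a regularized (ridge) multinomial logistic classifier over
#' hand-crafted features. The classifier's calibrated class probability is
#' the detection confidence. Hyperparameters recorded under `external` are
#' the published defaults for a GPU-trained one-stage detector plugged in
#' through the same `fit`/`predict` contract; they are metadata only and
#' never used by the reference backend.
#'
#' @param backend backend name (registry key), default `"reference"`.
#' @param confidence_floor default detection threshold (strictly greater
#'   than), default 0.1.
#' @param scales proposal blob scales (Gaussian sigma, px), default
#'   2, 3, 4.5.
#' @param dog_sigma_ratio ratio of the two smoothing scales in the
#'   difference-of-Gaussians, default 1.6.
#' @param dog_threshold minimum DoG response at a candidate peak.
#' @param min_contrast minimum peak-over-ring-background contrast for a
#'   candidate (8-bit intensity units).
#' @param nms_iou non-maximum-suppression overlap; two same-category
#'   detections never overlap more than this.
#' @param match_iou IoU at which training candidates are matched to ground
#'   truth, default 0.3.
#' @param class_balance exponent of the class-balancing observation
#'   weights (0 = none, 1 = fully balanced classes), default 0.5.
#' @param lambda ridge penalty of the classifier.
#' @param lambda_finetune ridge penalty of the fine-tuning increment
#'   (stronger, shrinking the update toward the pre-trained model).
#' @param max_candidates cap on proposals per image.
#' @param seed training seed (background sampling, reproducibility).
#' @param external recorded hyperparameter defaults for an external
#'   neural backend adapter (iterations, batch size, learning rate).
#' @return object of class `backend_config`.
#' @export
backend_config <- function(backend = "reference", confidence_floor = 0.1,
                           scales = c(2, 3, 4.5), dog_sigma_ratio = 1.6,
                           dog_threshold = 3, min_contrast = 10,
                           nms_iou = 0.5, match_iou = 0.3,
                           class_balance = 0.5,
                           lambda = 0.01, lambda_finetune = 0.05,
                           max_candidates = 120L, seed = 1L,
                           external = list(iterations = 150000L,
                                           batch_size = 64L,
                                           learning_rate = 0.00261)) {
  stopifnot(confidence_floor >= 0, confidence_floor <= 1)
  structure(list(backend = backend, confidence_floor = confidence_floor,
                 scales = scales, dog_sigma_ratio = dog_sigma_ratio,
                 dog_threshold = dog_threshold, min_contrast = min_contrast,
                 nms_iou = nms_iou, match_iou = match_iou,
                 class_balance = class_balance,
                 lambda = lambda, lambda_finetune = lambda_finetune,
                 max_candidates = as.integer(max_candidates),
                 seed = as.integer(seed), external = external),
            class = "backend_config")
}

gauss_blur <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k <- dnorm(-r:r, sd = sigma)
  sep_convolve(m, k / sum(k))
}

max_channel <- function(fused) {
  ch <- fused$channels
  m <- pmax(ch[, , 1], ch[, , 2], ch[, , 3])
  storage.mode(m) <- "double"
  m
}

# summed-area table with a zero top row/left column for O(1) box sums
integral_image <- function(m) {
  II <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  II[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  II
}

# vectorized sum over half-open boxes [y0,y1) x [x0,x1) (0-based coords)
rect_sum <- function(II, y0, x0, y1, x1) {
  r0 <- y0 + 1L; r1 <- y1 + 1L; c0 <- x0 + 1L; c1 <- x1 + 1L
  II[cbind(r1, c1)] - II[cbind(r0, c1)] - II[cbind(r1, c0)] + II[cbind(r0, c0)]
}

# mean intensity in a 2-px ring just outside the box (0 if none in frame)
ring_mean <- function(m, x_min, y_min, x_max, y_max, ring = 2L) {
  h <- nrow(m); w <- ncol(m)
  oc0 <- max(1L, floor(x_min) + 1L - ring); oc1 <- min(w, ceiling(x_max) + ring)
  or0 <- max(1L, floor(y_min) + 1L - ring); or1 <- min(h, ceiling(y_max) + ring)
  ic0 <- floor(x_min) + 1L; ic1 <- ceiling(x_max)
  ir0 <- floor(y_min) + 1L; ir1 <- ceiling(y_max)
  outer_sum <- sum(m[or0:or1, oc0:oc1])
  inner_sum <- sum(m[max(1L, ir0):min(h, ir1), max(1L, ic0):min(w, ic1)])
  n_outer <- (or1 - or0 + 1L) * (oc1 - oc0 + 1L)
  n_inner <- (min(h, ir1) - max(1L, ir0) + 1L) * (min(w, ic1) - max(1L, ic0) + 1L)
  if (n_outer <= n_inner) return(0)
  (outer_sum - inner_sum) / (n_outer - n_inner)
}

# greedy non-maximum suppression; keeps the highest-`by` box of each
# overlapping cluster. Ties break on ascending x_min then y_min.
nms_boxes <- function(df, iou_threshold = 0.5, by = "confidence",
                      within_category = TRUE, center_suppress = FALSE) {
  if (nrow(df) <= 1) return(df)
  ord <- order(-df[[by]], df$x_min, df$y_min)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  x0 <- df$x_min; y0 <- df$y_min; x1 <- df$x_max; y1 <- df$y_max
  area <- (x1 - x0) * (y1 - y0)
  cx <- (x0 + x1) / 2; cy <- (y0 + y1) / 2
  cat_ <- if (within_category) df$category else rep("", n)
  keep <- integer(0)
  for (i in seq_len(n)) {
    k <- keep[cat_[keep] == cat_[i]]
    if (length(k)) {
      iw <- pmax(0, pmin(x1[k], x1[i]) - pmax(x0[k], x0[i]))
      ih <- pmax(0, pmin(y1[k], y1[i]) - pmax(y0[k], y0[i]))
      inter <- iw * ih
      if (any(inter / (area[k] + area[i] - inter) > iou_threshold)) next
      if (center_suppress &&
          any(cx[i] >= x0[k] & cx[i] < x1[k] & cy[i] >= y0[k] & cy[i] < y1[k]))
        next
    }
    keep <- c(keep, i)
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Propose candidate hotspot boxes
#'
#' Multi-scale difference-of-Gaussians blob detection on the pixelwise
#' maximum of the three channels. Local maxima of the DoG response above
#' `dog_threshold` become candidate boxes (half-width 2 sigma); candidates
#' whose peak intensity is less than `min_contrast` above the surrounding
#' 2-px ring background are discarded, and overlapping candidates across
#' scales are deduplicated by response-ordered suppression. Deterministic
#' for fixed input; an empty result is allowed.
#'
#' @param image a [fused_image()].
#' @param config a [backend_config()].
#' @return data frame of candidate boxes with a `score` column (DoG
#'   response), sorted by descending score.
#' @export
propose_candidates <- function(image, config = backend_config()) {
  stopifnot(inherits(image, "fused_image"))
  m <- max_channel(image)
  h <- nrow(m); w <- ncol(m)
  empty <- cbind(empty_boxes(), data.frame(score = numeric()))
  if (max(m) <= 0) return(empty)
  # DoG response at every scale; peaks are sized by classic scale
  # selection on the sigma-normalized response
  dogs <- lapply(config$scales, function(s)
    gauss_blur(m, s) - gauss_blur(m, config$dog_sigma_ratio * s))
  II <- integral_image(m)
  cands <- list()
  for (si in seq_along(config$scales)) {
    d <- dogs[[si]]
    pk <- which(local_maxima8(d, config$dog_threshold), arr.ind = TRUE)
    if (nrow(pk) == 0) next
    if (nrow(pk) > 300) {  # keep the strongest responses per scale
      pk <- pk[order(-d[pk])[1:300], , drop = FALSE]
    }
    # best-responding scale at each peak determines the blob size (for
    # this DoG ratio the blob sigma is about 0.85 of the scale)
    nr <- vapply(seq_along(config$scales),
                 function(k) dogs[[k]][pk] * config$scales[k],
                 numeric(nrow(pk)))
    if (nrow(pk) == 1) nr <- matrix(nr, nrow = 1)
    s_star <- config$scales[max.col(nr, ties.method = "first")]
    rad <- pmax(3, 2.2 * 0.85 * s_star)
    x0 <- pmax(0, round(pk[, 2] - 0.5 - rad)); x1 <- pmin(w, round(pk[, 2] - 0.5 + rad))
    y0 <- pmax(0, round(pk[, 1] - 0.5 - rad)); y1 <- pmin(h, round(pk[, 1] - 0.5 + rad))
    ring <- 2L
    ox0 <- pmax(0, x0 - ring); ox1 <- pmin(w, x1 + ring)
    oy0 <- pmax(0, y0 - ring); oy1 <- pmin(h, y1 + ring)
    inner <- rect_sum(II, y0, x0, y1, x1)
    outer_ <- rect_sum(II, oy0, ox0, oy1, ox1)
    n_in <- (x1 - x0) * (y1 - y0)
    n_out <- (ox1 - ox0) * (oy1 - oy0)
    ringm <- ifelse(n_out > n_in, (outer_ - inner) / (n_out - n_in), 0)
    ok <- (x1 - x0 >= 2) & (y1 - y0 >= 2) & (m[pk] >= ringm + config$min_contrast)
    if (!any(ok)) next
    cands[[length(cands) + 1L]] <- data.frame(
      category = NA_character_, confidence = NA_real_,
      x_min = x0[ok], y_min = y0[ok], x_max = x1[ok], y_max = y1[ok],
      score = d[pk[ok, , drop = FALSE]], stringsAsFactors = FALSE)
  }
  if (length(cands) == 0) return(empty)
  df <- do.call(rbind, cands)
  df <- nms_boxes(df, config$nms_iou, by = "score",
                  within_category = FALSE, center_suppress = TRUE)
  head(df, config$max_candidates)
}

FEATURE_NAMES <- c("r_mean", "r_max", "r_var", "g_mean", "g_max", "g_var",
                   "b_mean", "b_max", "b_var", "contrast", "aspect",
                   "log_area", "mirror_cor", "mirror_balance",
                   "colinear", "near_count")

#' Compute the feature vector of a candidate box
#'
#' Fixed-length descriptor encoding the clinical cues experts use to
#' separate benign from metastatic hotspots: per-channel interior
#' statistics, contrast over the surrounding ring, box shape, a left-right
#' mirror-symmetry score (correlation and intensity balance with the
#' mirrored location; degenerative joint uptake is symmetric), and a
#' collinearity count over the other candidates (rib-injury chains line up).
#'
#' @param image a [fused_image()].
#' @param box single box (1-row data frame or named vector).
#' @param others optional data frame of the other candidate boxes in the
#'   image, used for the collinearity and crowding features.
#' @param max_dist neighbourhood radius (px) for the collinearity count.
#' @param .m precomputed channel-maximum matrix (internal fast path).
#' @return named numeric vector of length `length(FEATURE_NAMES)`.
#' @export
featurize_box <- function(image, box, others = NULL, max_dist = 150,
                          .m = NULL) {
  stopifnot(inherits(image, "fused_image"))
  b <- as.list(box)
  w <- dim(image$channels)[2]; h <- dim(image$channels)[1]
  x0 <- as.numeric(b$x_min); y0 <- as.numeric(b$y_min)
  x1 <- as.numeric(b$x_max); y1 <- as.numeric(b$y_max)
  if ((x1 - x0) * (y1 - y0) <= 1)
    stopf("feature error: degenerate box (area <= 1 px)")
  c0 <- max(1L, floor(x0) + 1L); c1 <- min(w, ceiling(x1))
  r0 <- max(1L, floor(y0) + 1L); r1 <- min(h, ceiling(y1))
  if (c1 < c0 || r1 < r0) stopf("feature error: box outside image")
  f <- numeric(0)
  for (k in 1:3) {
    patch <- image$channels[r0:r1, c0:c1, k]
    f <- c(f, mean(patch), max(patch),
           if (length(patch) > 1) var(as.numeric(patch)) else 0)
  }
  m <- .m %||% max_channel(image)
  interior <- m[r0:r1, c0:c1]
  f <- c(f, mean(interior) - ring_mean(m, x0, y0, x1, y1))
  f <- c(f, (x1 - x0) / (y1 - y0), log((x1 - x0) * (y1 - y0)))

  # mirror symmetry: compare with the left-right mirrored location
  mc0 <- max(1L, floor(w - x1) + 1L); mc1 <- min(w, ceiling(w - x0))
  mpatch <- m[r0:r1, mc0:mc1, drop = FALSE]
  mpatch <- mpatch[, rev(seq_len(ncol(mpatch))), drop = FALSE]
  nc <- min(ncol(interior), ncol(mpatch))
  a <- as.numeric(interior[, seq_len(nc)]); bb <- as.numeric(mpatch[, seq_len(nc)])
  mirror_cor <- if (length(a) > 2 && stats::sd(a) > 0 && stats::sd(bb) > 0)
    stats::cor(a, bb) else 0
  mirror_balance <- 1 - abs(mean(a) - mean(bb)) / (mean(a) + mean(bb) + 1e-6)
  f <- c(f, mirror_cor, mirror_balance)

  # collinearity and crowding over the other candidates
  colin <- 0; near <- 0
  if (!is.null(others) && nrow(others) > 0) {
    cx <- (x0 + x1) / 2; cy <- (y0 + y1) / 2
    ox <- (others$x_min + others$x_max) / 2 - cx
    oy <- (others$y_min + others$y_max) / 2 - cy
    d <- sqrt(ox^2 + oy^2)
    sel <- d > 1e-6 & d <= max_dist
    near <- sum(d > 1e-6 & d <= 60)
    if (any(sel)) {
      ang <- atan2(oy[sel], ox[sel]) %% pi
      tol <- 10 * pi / 180
      angdiff <- abs(outer(ang, ang, "-"))
      angdiff <- pmin(angdiff, pi - angdiff)
      colin <- max(rowSums(angdiff <= tol))
    }
  }
  f <- c(f, colin, near)
  stats::setNames(f, FEATURE_NAMES)
}

featurize_table <- function(image, boxes, others) {
  m <- max_channel(image)
  b <- as.matrix(boxes[, c("x_min", "y_min", "x_max", "y_max")])
  t(vapply(seq_len(nrow(boxes)),
           function(i) featurize_box(image, b[i, ], others = others, .m = m),
           numeric(length(FEATURE_NAMES))))
}

softmax_rows <- function(lp) {
  e <- exp(lp - apply(lp, 1, max))
  e / rowSums(e)
}

model_classes <- function(n_categories) {
  c("background", c("metastasis", "normal_hotspot")[seq_len(n_categories)])
}

# sum of linear predictors over the coefficient stack (base + fine-tune
# increments); each element carries its own standardization
model_linear_predictor <- function(model, X) {
  K <- length(model$classes)
  lp <- matrix(0, nrow(X), K)
  for (st in model$coef_stack) {
    Xs <- sweep(sweep(X, 2, st$center, "-"), 2, st$scale, "/")
    lp <- lp + cbind(1, Xs) %*% st$B
  }
  lp
}

standardize_stats <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-8] <- 1
  list(center = ctr, scale = scl)
}

fit_multinomial <- function(X, y, lambda, offset = NULL, balance = 0.5) {
  ss <- standardize_stats(X)
  Xs <- sweep(sweep(X, 2, ss$center, "-"), 2, ss$scale, "/")
  # class-balanced observation weights: proposal candidates are mostly
  # background, which would otherwise suppress hotspot probabilities
  tab <- table(y)
  wts <- as.numeric((length(y) / (length(tab) * tab[y]))^balance)
  fit <- glmnet::glmnet(Xs, y, family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = FALSE,
                        weights = wts, offset = offset, maxit = 200000)
  cf <- glmnet::coef.glmnet(fit)
  B <- vapply(levels(y), function(cl) as.numeric(cf[[cl]]),
              numeric(ncol(X) + 1))
  list(B = B, center = ss$center, scale = ss$scale, classes = levels(y))
}

# build (features, labels) training rows from one labeled fused image
training_rows <- function(image, config, cats, equivocal = "as-normal") {
  gt <- image$boxes
  if (nrow(gt) > 0) {
    if (equivocal == "as-normal" && "normal_hotspot" %in% cats)
      gt$category[gt$category == "equivocal"] <- "normal_hotspot"
    gt <- gt[gt$category %in% cats, , drop = FALSE]
    gt <- merge_duplicate_boxes(gt)
  }
  cand <- propose_candidates(image, config)
  ylab <- character(0); X <- NULL
  if (nrow(cand) > 0) {
    ious <- iou_matrix(cand, gt)
    ylab <- vapply(seq_len(nrow(cand)), function(i) {
      if (nrow(gt) == 0) return("background")
      j <- which.max(ious[i, ])
      if (ious[i, j] >= config$match_iou) gt$category[j] else "background"
    }, character(1))
    X <- featurize_table(image, cand, others = cand)
  }
  if (nrow(gt) > 0) {  # ground-truth boxes as additional positive examples
    X <- rbind(X, featurize_table(image, gt, others = cand))
    ylab <- c(ylab, gt$category)
  }
  list(X = X, y = ylab, n_background = sum(ylab == "background"))
}

# deterministic low-signal background boxes when proposals yield too few
sample_background_boxes <- function(image, n, rad = 8) {
  h <- dim(image$channels)[1]; w <- dim(image$channels)[2]
  out <- empty_boxes()
  tries <- 0L
  while (nrow(out) < n && tries < 20L * n) {
    tries <- tries + 1L
    xc <- runif(1, rad + 1, w - rad - 1); yc <- runif(1, rad + 1, h - rad - 1)
    out <- rbind(out, data.frame(category = NA_character_, confidence = NA_real_,
                                 x_min = xc - rad, y_min = yc - rad,
                                 x_max = xc + rad, y_max = yc + rad,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Train the reference hotspot detector
#'
#' Proposal candidates on every training image are matched to ground truth
#' at IoU >= `match_iou`; matched candidates (and the ground-truth boxes
#' themselves) become positive feature examples of their category, the
#' rest become background. A ridge-regularized multinomial logistic
#' classifier over background plus the `n_categories` hotspot categories
#' is then fit to convergence. Training is bit-reproducible for a fixed
#' seed.
#'
#' @param train list of [fused_image()] with ground-truth boxes.
#' @param config a [backend_config()].
#' @param n_categories 1 (metastasis only) or 2 (metastasis and
#'   normal_hotspot).
#' @param equivocal `"as-normal"` folds equivocal ground truth into
#'   normal_hotspot for training; `"ignore"` drops it.
#' @return object of class `hotspot_detector`.
#' @export
fit_detector <- function(train, config = backend_config(), n_categories = 2L,
                         equivocal = c("as-normal", "ignore")) {
  equivocal <- match.arg(equivocal)
  stopifnot(n_categories %in% 1:2, length(train) > 0)
  cats <- c("metastasis", "normal_hotspot")[seq_len(n_categories)]
  withr::with_seed(config$seed, {
    Xs <- list(); ys <- list()
    for (im in train) {
      tr <- training_rows(im, config, cats, equivocal)
      extra <- 5L - tr$n_background
      if (extra > 0) {
        bg <- sample_background_boxes(im, extra)
        if (nrow(bg) > 0) {
          tr$X <- rbind(tr$X, featurize_table(im, bg, others = NULL))
          tr$y <- c(tr$y, rep("background", nrow(bg)))
        }
      }
      Xs[[length(Xs) + 1L]] <- tr$X
      ys[[length(ys) + 1L]] <- tr$y
    }
    X <- do.call(rbind, Xs)
    y <- unlist(ys)
    if (sum(y == "metastasis") == 0 && "metastasis" %in% cats)
      stopf("training error: no positive (metastasis) examples")
    lv <- model_classes(n_categories)
    present <- lv[lv %in% y]
    # duplicate singleton classes so the solver has >= 2 obs per class
    for (cl in present) if (sum(y == cl) == 1) {
      i <- which(y == cl)
      X <- rbind(X, X[i, , drop = FALSE]); y <- c(y, cl)
    }
    yf <- factor(y, levels = present)
    fm <- fit_multinomial(X, yf, config$lambda,
                          balance = config$class_balance %||% 0.5)
    # embed into the full class set (absent classes get zero columns)
    B <- matrix(0, ncol(X) + 1, length(lv), dimnames = list(NULL, lv))
    B[, fm$classes] <- fm$B
    structure(list(classes = lv, n_categories = as.integer(n_categories),
                   coef_stack = list(list(B = B, center = fm$center, scale = fm$scale)),
                   config = config, seed = config$seed,
                   config_digest = text_digest(config),
                   n_train = length(train), trained = TRUE),
              class = "hotspot_detector")
  })
}

#' @export
#' @method print hotspot_detector
print.hotspot_detector <- function(x, ...) {
  cat(sprintf("<hotspot_detector: %d categor%s, %d training image(s), %d stage(s), seed %d>\n",
              x$n_categories, ifelse(x$n_categories == 1, "y", "ies"),
              x$n_train, length(x$coef_stack), x$seed))
  invisible(x)
}

#' Detect hotspots in a fused chest image
#'
#' Generic over detector backends: proposes candidates, featurizes them,
#' classifies, keeps detections whose confidence is strictly greater than
#' `confidence_floor`, applies within-category greedy non-maximum
#' suppression, and returns the survivors sorted by descending confidence.
#' The result is monotone in the floor: raising it can only shrink the
#' detection set.
#'
#' @param model a trained detector (for the reference backend, a
#'   `hotspot_detector` from [fit_detector()]).
#' @param image a [fused_image()].
#' @param confidence_floor keep detections with confidence strictly
#'   greater than this, default 0.1.
#' @param ... backend-specific arguments.
#' @return box data frame with `category` and `confidence` filled in.
#' @export
detect_hotspots <- function(model, image, confidence_floor = 0.1, ...) {
  UseMethod("detect_hotspots")
}

#' @rdname detect_hotspots
#' @export
detect_hotspots.hotspot_detector <- function(model, image, confidence_floor = 0.1, ...) {
  if (!isTRUE(model$trained)) stopf("state error: detector is not trained")
  stopifnot(confidence_floor >= 0, confidence_floor <= 1)
  cand <- propose_candidates(image, model$config)
  if (nrow(cand) == 0) return(empty_boxes())
  X <- featurize_table(image, cand, others = cand)
  P <- softmax_rows(model_linear_predictor(model, X))
  colnames(P) <- model$classes
  cats <- setdiff(model$classes, "background")
  Pc <- P[, cats, drop = FALSE]
  best <- max.col(Pc, ties.method = "first")
  det <- cand[, c("category", "confidence", "x_min", "y_min", "x_max", "y_max")]
  det$category <- cats[best]
  det$confidence <- Pc[cbind(seq_len(nrow(Pc)), best)]
  det <- det[det$confidence > confidence_floor, , drop = FALSE]
  det <- nms_boxes(det, model$config$nms_iou, by = "confidence",
                   within_category = TRUE)
  det <- det[order(-det$confidence, det$x_min, det$y_min), , drop = FALSE]
  rownames(det) <- NULL
  det
}
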