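#' Mining configuration
#'
#' @param harvest_confidence detections with confidence strictly greater
#'   than this are harvested as negatives, default 0.1.
#' @param seed seed recorded in mined-negative provenance.
#' @return object of class `mining_config`.
#' @export
mining_config <- function(harvest_confidence = 0.1, seed = 1L) {
  stopifnot(harvest_confidence >= 0, harvest_confidence <= 1)
  structure(list(harvest_confidence = harvest_confidence, seed = as.integer(seed)),
            class = "mining_config")
}

#' Pre-train a one-class (metastasis-only) detector
#'
#' First stage of the negative-mining workflow: a detector with the single
#' category metastasis is trained on a positives-only corpus. Every image
#' must contain at least one metastasis box; other annotations are ignored
#' at this stage, mimicking a corpus where only metastases were labeled.
#'
#' @param positives list of [fused_image()], each with >= 1 metastasis box.
#' @param config a [backend_config()].
#' @return 1-category `hotspot_detector`.
#' @export
pretrain_positive_only <- function(positives, config = backend_config()) {
  for (i in seq_along(positives)) {
    b <- positives[[i]]$boxes
    if (sum(b$category == "metastasis") == 0)
      stopf("validation error: image %d (%s) has no metastasis box",
            i, positives[[i]]$source_id %||% "?")
  }
  fit_detector(positives, config, n_categories = 1L)
}

#' Harvest false positives from known-normal images
#'
#' The one-class pre-model is run on images known to contain no metastasis;
#' since every resulting box is by construction a false positive, each
#' detection with confidence strictly greater than the harvest threshold is
#' collected and relabeled `normal_hotspot`. Ground-truth label files are
#' never mutated: the mined boxes live in a provenance-tracked store and
#' are merged with the originals only at training time.
#'
#' @param model 1-category `hotspot_detector` (mining is defined on the
#'   pre-model; a 2-category model is a state error).
#' @param normals list of [fused_image()] with zero metastasis ground truth.
#' @param config a [mining_config()].
#' @return object of class `mined_negatives`: `boxes` (data frame with
#'   `image_id`, box columns and `originating_confidence`), `images` (the
#'   normal images with mined boxes attached as their training ground
#'   truth), and provenance (`model_digest`, `config`).
#' @export
harvest_negatives <- function(model, normals, config = mining_config()) {
  if (!identical(model$n_categories, 1L))
    stopf("state error: negative mining requires the 1-category pre-model")
  rows <- list(); images <- vector("list", length(normals))
  for (i in seq_along(normals)) {
    im <- normals[[i]]
    if (any(im$boxes$category == "metastasis"))
      stopf("validation error: image %d (%s) contains metastasis ground truth",
            i, im$source_id %||% "?")
    det <- detect_hotspots(model, im, confidence_floor = config$harvest_confidence)
    mined <- empty_boxes()
    if (nrow(det) > 0) {
      mined <- det
      mined$category <- "normal_hotspot"
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(image_id = im$source_id %||% as.character(i),
                   stringsAsFactors = FALSE),
        mined[, c("category", "x_min", "y_min", "x_max", "y_max")],
        data.frame(originating_confidence = det$confidence))
      mined$confidence <- 1   # becomes training ground truth
    }
    im$boxes <- mined
    images[[i]] <- im
  }
  boxes <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(image_id = character()),
          empty_boxes()[, c("category", "x_min", "y_min", "x_max", "y_max")],
          data.frame(originating_confidence = numeric()))
  rownames(boxes) <- NULL
  structure(list(boxes = boxes, images = images,
                 model_digest = model$config_digest, config = config),
            class = "mined_negatives")
}

#' @export
#' @method print mined_negatives
print.mined_negatives <- function(x, ...) {
  cat(sprintf("<mined_negatives: %d boxes from %d normal image(s), floor %g>\n",
              nrow(x$boxes), length(x$images), x$config$harvest_confidence))
  invisible(x)
}

#' Retrain with mined negatives to obtain the two-class pre-trained model
#'
#' The original metastasis annotations and the mined `normal_hotspot`
#' boxes are pooled and a 2-category detector is trained on the union.
#'
#' @param positives the positive corpus used for pre-training.
#' @param mined a [harvest_negatives()] result; must be non-empty.
#' @param config a [backend_config()].
#' @return 2-category `hotspot_detector`.
#' @export
retrain_two_class <- function(positives, mined, config = backend_config()) {
  stopifnot(inherits(mined, "mined_negatives"))
  if (nrow(mined$boxes) == 0)
    stopf("training error: no mined negatives; lower the harvest confidence threshold")
  pos <- lapply(positives, function(im) {
    im$boxes <- im$boxes[im$boxes$category == "metastasis", , drop = FALSE]
    im
  })
  fit_detector(c(pos, mined$images), config, n_categories = 2L)
}

#' Fine-tune the pre-trained model on a target cohort
#'
#' Transfer step: the 2-category pre-trained model is further fit on the
#' target images. For the reference backend the update is a ridge-penalized
#' increment on top of the pre-trained linear predictor (the pre-trained
#' coefficients act as the initialization and prior), so the fine-tuned
#' model deviates from the pre-model only as far as the target data
#' warrants. Equivocal target annotations are folded into the normal
#' group for training by default (they are too few to form a class), or
#' dropped with `equivocal = "ignore"`.
#'
#' @param pretrained 2-category `hotspot_detector`.
#' @param target list of [fused_image()] with target-cohort labels.
#' @param config a [backend_config()] (`lambda_finetune` controls the
#'   shrinkage toward the pre-trained model).
#' @param equivocal `"as-normal"` (default) or `"ignore"`.
#' @return 2-category `hotspot_detector`; if `target` is empty the
#'   pre-trained model is returned unchanged with a warning.
#' @export
transfer_finetune <- function(pretrained, target, config = backend_config(),
                              equivocal = c("as-normal", "ignore")) {
  equivocal <- match.arg(equivocal)
  if (!identical(pretrained$n_categories, 2L))
    stopf("state error: fine-tuning requires a 2-category pre-trained model")
  if (length(target) == 0) {
    warning("empty target set: returning the pre-trained model unchanged")
    return(pretrained)
  }
  cats <- c("metastasis", "normal_hotspot")
  withr::with_seed(config$seed, {
    Xs <- list(); ys <- list()
    for (im in target) {
      tr <- training_rows(im, config, cats, equivocal)
      extra <- 3L - tr$n_background
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
    present <- pretrained$classes[pretrained$classes %in% y]
    for (cl in present) if (sum(y == cl) == 1) {
      i <- which(y == cl)
      X <- rbind(X, X[i, , drop = FALSE]); y <- c(y, cl)
    }
    if (length(present) < 2) {
      warning("target data covers fewer than two classes: returning the pre-trained model unchanged")
      return(pretrained)
    }
    keep <- y %in% present
    X <- X[keep, , drop = FALSE]; y <- y[keep]
    yf <- factor(y, levels = present)
    base_lp <- model_linear_predictor(pretrained, X)
    colnames(base_lp) <- pretrained$classes
    fm <- fit_multinomial(X, yf, config$lambda_finetune,
                          offset = base_lp[, present, drop = FALSE],
                          balance = config$class_balance %||% 0.5)
    B <- matrix(0, ncol(X) + 1, length(pretrained$classes),
                dimnames = list(NULL, pretrained$classes))
    B[, fm$classes] <- fm$B
    out <- pretrained
    out$coef_stack <- c(pretrained$coef_stack,
                        list(list(B = B, center = fm$center, scale = fm$scale)))
    out$n_train <- length(target)
    out
  })
}
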