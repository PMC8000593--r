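#' Match detections against ground truth at an IoU threshold
#'
#' Greedy confidence-ordered matching (ties break on ascending `x_min`,
#' then `y_min`): each detection claims the unmatched same-category
#' ground-truth box of highest IoU at or above the threshold (a true
#' positive); failing that, if its best above-threshold overlap is with an
#' unmatched equivocal box, the detection is ignored and the equivocal box
#' consumed (neither TP nor FP); otherwise it is a false positive.
#' Unmatched non-equivocal ground truth counts as false negatives;
#' equivocal boxes are never false negatives. Duplicate fused-view ground
#' truth is pre-merged with [merge_duplicate_boxes()] unless disabled.
#'
#' @param dets detection box data frame (category, confidence filled).
#' @param gts ground-truth box data frame; may include equivocal boxes.
#' @param iou_threshold matching threshold in `(0, 1]`, default 0.3.
#' @param merge_duplicates pre-merge duplicate ground truth (IoU >= 0.5
#'   within category), default TRUE.
#' @return object of class `match_result`: `pairs` (detection index,
#'   ground-truth index, IoU), per-category `tp`, `fp`, `fn` counts, and
#'   the number of `ignored` detections.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.3,
                             merge_duplicates = TRUE) {
  if (!(iou_threshold > 0 && iou_threshold <= 1))
    stopf("parameter error: iou_threshold must be in (0, 1]")
  validate_boxes(dets); validate_boxes(gts)
  if (merge_duplicates && nrow(gts) > 1) gts <- merge_duplicate_boxes(gts)
  cats <- setdiff(BOX_CATEGORIES, "equivocal")
  tp <- setNames(integer(length(cats)), cats)
  fp <- setNames(integer(length(cats)), cats)
  matched <- rep(FALSE, nrow(gts))
  ignored <- 0L
  pairs <- data.frame(det = integer(), gt = integer(), iou = numeric())
  if (nrow(dets) > 0) {
    ord <- order(-dets$confidence, dets$x_min, dets$y_min)
    M <- iou_matrix(dets, gts)
    for (i in ord) {
      cat_i <- dets$category[i]
      same <- which(!matched & gts$category == cat_i)
      hit <- FALSE
      if (length(same) > 0) {
        j <- same[which.max(M[i, same])]
        if (M[i, j] >= iou_threshold) {
          matched[j] <- TRUE
          tp[cat_i] <- tp[cat_i] + 1L
          pairs <- rbind(pairs, data.frame(det = i, gt = j, iou = M[i, j]))
          hit <- TRUE
        }
      }
      if (!hit) {
        eq <- which(!matched & gts$category == "equivocal")
        if (length(eq) > 0) {
          j <- eq[which.max(M[i, eq])]
          if (M[i, j] >= iou_threshold) {
            matched[j] <- TRUE
            ignored <- ignored + 1L
            hit <- TRUE
          }
        }
      }
      if (!hit) fp[cat_i] <- fp[cat_i] + 1L
    }
  }
  fn <- setNames(vapply(cats, function(cl)
    sum(!matched & gts$category == cl), integer(1)), cats)
  structure(list(pairs = pairs, tp = tp, fp = fp, fn = fn,
                 ignored = ignored, n_gt = nrow(gts), n_det = nrow(dets)),
            class = "match_result")
}

#' Lesion-level metrics from match results
#'
#' Sensitivity `TP / (TP + FN)` and precision `TP / (TP + FP)` for one
#' category, pooled over a list of per-image match results. True negatives
#' are undefined at the lesion level, so specificity does not exist here.
#' Undefined ratios (zero denominators) are reported as `NA`, never as 0.
#'
#' @param matches a `match_result` or list of them.
#' @param category category to score, default `"metastasis"`.
#' @return object of class `lesion_metrics` with `tp`, `fp`, `fn`,
#'   `sensitivity`, `precision`.
#' @export
lesion_metrics <- function(matches, category = "metastasis") {
  if (inherits(matches, "match_result")) matches <- list(matches)
  tp <- sum(vapply(matches, function(m) m$tp[[category]], numeric(1)))
  fp <- sum(vapply(matches, function(m) m$fp[[category]], numeric(1)))
  fn <- sum(vapply(matches, function(m) m$fn[[category]], numeric(1)))
  structure(list(tp = tp, fp = fp, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_),
            class = "lesion_metrics")
}

#' Patient-level metastasis call
#'
#' An image is called positive iff it has at least one metastasis
#' detection with confidence strictly greater than `decision_conf`.
#'
#' @param dets detection box data frame for one image.
#' @param decision_conf decision threshold in `[0, 1]`, default 0.5.
#' @return logical flag.
#' @export
patient_call <- function(dets, decision_conf = 0.5) {
  stopifnot(decision_conf >= 0, decision_conf <= 1)
  nrow(dets) > 0 && any(dets$category == "metastasis" &
                          dets$confidence > decision_conf)
}

#' Patient-level metrics
#'
#' Image-level confusion of metastasis calls against truth; with negatives
#' defined, both sensitivity `TP / (TP + FN)` and specificity
#' `TN / (TN + FP)` exist.
#'
#' @param calls logical vector of per-image calls.
#' @param truths logical vector of per-image ground truth (metastasis
#'   present in the image).
#' @return object of class `patient_metrics` with the four counts and the
#'   two ratios (`NA` when undefined).
#' @export
patient_metrics <- function(calls, truths) {
  stopifnot(length(calls) == length(truths))
  tp <- sum(calls & truths); fn <- sum(!calls & truths)
  tn <- sum(!calls & !truths); fp <- sum(calls & !truths)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "patient_metrics")
}

#' Stratified k-fold assignment
#'
#' Positives and negatives (by `patient_positive`) are shuffled
#' independently with the given seed and dealt round-robin into `k` folds,
#' so fold sizes within each stratum differ by at most one. The assignment
#' is reproducible from the seed.
#'
#' @param manifest data frame with a logical `patient_positive` column.
#' @param k number of folds, `>= 2`, default 10.
#' @param seed shuffle seed.
#' @return integer vector of fold labels (1..k), one per manifest row,
#'   with the seed stored as an attribute.
#' @export
make_folds <- function(manifest, k = 10L, seed = 1L) {
  stopifnot(k >= 2)
  fold <- integer(nrow(manifest))
  withr::with_seed(seed, {
    for (s in c(TRUE, FALSE)) {
      idx <- which(manifest$patient_positive == s)
      if (length(idx) == 0) next
      if (length(idx) < k)
        stopf("split error: stratum patient_positive=%s has %d < k = %d members",
              s, length(idx), k)
      perm <- sample(idx)
      fold[perm] <- ((seq_along(perm) - 1L) %% k) + 1L
    }
  })
  attr(fold, "seed") <- seed
  fold
}

#' Mean and sample standard deviation with two-decimal rendering
#'
#' Aggregation used for the shuffle-table "Average" row: arithmetic mean
#' and sample (n-1) standard deviation, both also rendered at two decimals
#' with half-away-from-zero rounding.
#'
#' @param values numeric vector with at least one non-missing value;
#'   missing values are dropped with a warning.
#' @return list with `mean`, `sd`, `n`, and a `rendered` "m ± s" string.
#' @export
aggregate_metrics <- function(values) {
  if (length(values) == 0) stopf("aggregation error: no values")
  if (anyNA(values)) {
    warning(sprintf("dropping %d undefined value(s) from aggregation", sum(is.na(values))))
    values <- values[!is.na(values)]
    if (length(values) == 0)
      return(list(mean = NA_real_, sd = NA_real_, n = 0L, rendered = "n/a"))
  }
  m <- mean(values)
  s <- if (length(values) > 1) stats::sd(values) else 0
  list(mean = m, sd = s, n = length(values),
       rendered = paste0(render2(m), " ± ", render2(s)))
}

#' Assemble a fused cohort held in memory
#'
#' @param images list of [fused_image()].
#' @param patient_id character vector of ids.
#' @param patient_positive logical vector; defaults to presence of a
#'   metastasis ground-truth box in the fused image.
#' @return object of class `fused_cohort`.
#' @export
fused_cohort <- function(images, patient_id = NULL, patient_positive = NULL) {
  patient_id <- patient_id %||%
    vapply(images, function(im) im$source_id, character(1))
  patient_positive <- patient_positive %||%
    vapply(images, function(im) any(im$boxes$category == "metastasis"), logical(1))
  stopifnot(length(images) == length(patient_id),
            length(images) == length(patient_positive))
  structure(list(images = images,
                 manifest = data.frame(patient_id = patient_id,
                                       patient_positive = patient_positive,
                                       stringsAsFactors = FALSE)),
            class = "fused_cohort")
}

#' Load a cohort from a manifest and run the preprocessing chain
#'
#' Reads every scan and label file of a manifest, runs
#' [prepare_fused()] on each, and returns the in-memory cohort.
#'
#' @param manifest manifest data frame from [read_manifest()] or
#'   [generate_cohort()] (paths resolved against its `dir` attribute), or
#'   a path to a manifest CSV.
#' @param t1,t2,band preprocessing parameters, see [prepare_fused()].
#' @return a [fused_cohort()].
#' @export
load_fused_cohort <- function(manifest, t1 = 7, t2 = 14, band = c(0.10, 0.45)) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir <- attr(manifest, "dir") %||% "."
  images <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    scan <- read_scan(file.path(dir, manifest$image[i]),
                      scan_id = manifest$patient_id[i])
    boxes <- read_labels(file.path(dir, manifest$label[i]),
                         width = ncol(scan$pixels), height = nrow(scan$pixels))
    images[[i]] <- prepare_fused(scan, boxes, t1 = t1, t2 = t2, band = band,
                                 source_id = manifest$patient_id[i])
  }
  fused_cohort(images, manifest$patient_id, manifest$patient_positive)
}

#' Generate a fused phantom cohort directly in memory
#'
#' Same per-scan plan as [generate_cohort()] but without touching disk:
#' each phantom is generated, preprocessed and fused.
#'
#' @param n_positive,n_negative cohort sizes.
#' @param seed cohort seed.
#' @param t1,t2,band preprocessing parameters.
#' @param ... overrides passed to [phantom_config()].
#' @return a [fused_cohort()].
#' @export
simulate_fused_cohort <- function(n_positive, n_negative, seed,
                                  t1 = 7, t2 = 14, band = c(0.10, 0.45), ...) {
  plan <- cohort_plan(n_positive, n_negative, seed)
  images <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    cfg <- phantom_config(seed = plan$scan_seed[i],
                          n_metastases = plan$n_metastases[i],
                          n_benign = plan$n_benign[i], ...)
    g <- generate_scan(cfg)
    native <- rbind(g$ap_boxes, shift_boxes(g$pa_boxes, VIEW_W, 0))
    id <- sprintf("synthetic_%03d", i)
    images[[i]] <- prepare_fused(g$scan, native, t1 = t1, t2 = t2, band = band,
                                 source_id = id)
  }
  fused_cohort(images,
               patient_id = sprintf("synthetic_%03d", plan$index),
               patient_positive = plan$positive)
}

evaluate_on_images <- function(model, images, truths, confidence_floor = 0.1,
                               iou_threshold = 0.3, decision_conf = 0.5) {
  matches <- vector("list", length(images))
  calls <- logical(length(images))
  for (i in seq_along(images)) {
    det <- detect_hotspots(model, images[[i]], confidence_floor = confidence_floor)
    matches[[i]] <- match_detections(det, images[[i]]$boxes, iou_threshold)
    calls[i] <- patient_call(det, decision_conf)
  }
  list(lesion = lesion_metrics(matches),
       patient = patient_metrics(calls, truths))
}

#' Shuffled cross-validation of the fine-tuned detector
#'
#' For each shuffle `s = 1..n_shuffles` (seed `base_seed + s`) the cohort
#' is split into `k` stratified folds, fold 1 is held out, the pre-trained
#' model is fine-tuned on the augmented remainder, and lesion- and
#' patient-level metrics are computed on the held-out fold. One shuffle is
#' one re-randomized split with a single held-out tenth; `full_cv = TRUE`
#' instead rotates through all `k` folds per shuffle and pools the test
#' results.
#'
#' @param cohort a [fused_cohort()].
#' @param pretrained 2-category `hotspot_detector`.
#' @param n_shuffles number of shuffles, default 10.
#' @param k folds per shuffle, default 10.
#' @param base_seed base of the per-shuffle seeds.
#' @param config a [backend_config()].
#' @param plan an [augment_plan()] applied to the training images.
#' @param iou_threshold lesion-matching IoU, default 0.3.
#' @param decision_conf patient-call threshold, default 0.5.
#' @param confidence_floor detection threshold, default 0.1.
#' @param full_cv rotate through every fold per shuffle, default FALSE.
#' @return object of class `cv_report`: per-shuffle `rows`, `aggregate`
#'   (mean, sample sd and rendering per metric), and the fold assignments
#'   and seeds needed for replay.
#' @export
run_shuffles <- function(cohort, pretrained, n_shuffles = 10L, k = 10L,
                         base_seed = 1L, config = backend_config(),
                         plan = augment_plan(), iou_threshold = 0.3,
                         decision_conf = 0.5, confidence_floor = 0.1,
                         full_cv = FALSE) {
  stopifnot(inherits(cohort, "fused_cohort"), n_shuffles >= 1)
  truths_all <- cohort$manifest$patient_positive
  rows <- vector("list", n_shuffles)
  folds_list <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    seed_s <- base_seed + s
    fold <- make_folds(cohort$manifest, k = k, seed = seed_s)
    folds_list[[s]] <- fold
    test_folds <- if (full_cv) seq_len(k) else 1L
    lm_list <- list(); calls <- logical(0); truths <- logical(0)
    for (tf in test_folds) {
      test_i <- which(fold == tf)
      train_i <- which(fold != tf)
      train_imgs <- unlist(lapply(cohort$images[train_i], augment_fused, plan = plan),
                           recursive = FALSE)
      model_s <- transfer_finetune(pretrained, train_imgs, config)
      for (i in test_i) {
        det <- detect_hotspots(model_s, cohort$images[[i]],
                               confidence_floor = confidence_floor)
        lm_list[[length(lm_list) + 1L]] <-
          match_detections(det, cohort$images[[i]]$boxes, iou_threshold)
        calls <- c(calls, patient_call(det, decision_conf))
        truths <- c(truths, truths_all[i])
      }
    }
    lm <- lesion_metrics(lm_list)
    pm <- patient_metrics(calls, truths)
    rows[[s]] <- data.frame(
      shuffle = s, seed = seed_s,
      lesion_tp = lm$tp, lesion_fp = lm$fp, lesion_fn = lm$fn,
      lesion_sensitivity = lm$sensitivity, lesion_precision = lm$precision,
      patient_tp = pm$tp, patient_fn = pm$fn, patient_tn = pm$tn,
      patient_fp = pm$fp,
      patient_sensitivity = pm$sensitivity, patient_specificity = pm$specificity)
  }
  rows <- do.call(rbind, rows)
  metric_cols <- c("lesion_sensitivity", "lesion_precision",
                   "patient_sensitivity", "patient_specificity")
  agg <- lapply(rows[metric_cols], aggregate_metrics)
  structure(list(rows = rows, aggregate = agg, base_seed = base_seed,
                 k = k, n_shuffles = n_shuffles, folds = folds_list,
                 full_cv = full_cv),
            class = "cv_report")
}

#' @export
#' @method print cv_report
print.cv_report <- function(x, ...) {
  cat("Shuffled cross-validation report\n")
  cat("Shuffle  Lesion sens  Lesion prec  Patient sens  Patient spec\n")
  for (i in seq_len(nrow(x$rows))) {
    r <- x$rows[i, ]
    cat(sprintf("%7d  %11s  %11s  %12s  %12s\n", r$shuffle,
                render2(r$lesion_sensitivity), render2(r$lesion_precision),
                render2(r$patient_sensitivity), render2(r$patient_specificity)))
  }
  cat(sprintf("Average  %11s  %11s  %12s  %12s\n",
              x$aggregate$lesion_sensitivity$rendered,
              x$aggregate$lesion_precision$rendered,
              x$aggregate$patient_sensitivity$rendered,
              x$aggregate$patient_specificity$rendered))
  invisible(x)
}
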