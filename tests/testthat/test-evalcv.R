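box <- function(x0, y0, x1, y1, cat = "metastasis", conf = 1) {
  boxes_df(cat, conf, x0, y0, x1, y1)
}

test_that("iou follows the half-open geometry", {
  a <- box(0, 0, 10, 10)
  expect_equal(iou(a[1, ], a[1, ]), 1)
  expect_equal(iou(a[1, ], box(20, 20, 30, 30)[1, ]), 0)
  expect_equal(iou(a[1, ], box(5, 5, 15, 15)[1, ]), 1 / 7)
  expect_error(iou(c(x_min = 5, y_min = 0, x_max = 5, y_max = 3), a[1, ]),
               "degenerate")
})

test_that("formula iou matches pixel rasterization on random integer boxes", {
  withr::with_seed(99, {
    for (i in 1:200) {
      a <- rand_box(); b <- rand_box()
      av <- unlist(a[1, c("x_min", "y_min", "x_max", "y_max")])
      bv <- unlist(b[1, c("x_min", "y_min", "x_max", "y_max")])
      expect_lt(abs(iou(a[1, ], b[1, ]) - raster_iou(av, bv)), 1e-9)
    }
  })
})

test_that("matching applies the IoU threshold as a hard boundary", {
  gt <- box(0, 0, 10, 10)
  near <- box(5.5, 0, 15.5, 10)            # IoU 45/155 = 0.29...
  m <- match_detections(near, gt, 0.3)
  expect_equal(unname(m$tp["metastasis"]), 0)
  expect_equal(unname(m$fp["metastasis"]), 1)
  expect_equal(unname(m$fn["metastasis"]), 1)

  exact <- match_detections(gt, gt, 0.3)
  expect_equal(unname(exact$tp["metastasis"]), 1)
  expect_equal(unname(exact$fp["metastasis"]), 0)
  expect_equal(unname(exact$fn["metastasis"]), 0)

  expect_error(match_detections(gt, gt, 0), "parameter error")
  expect_error(match_detections(gt, gt, 1.2), "parameter error")
})

test_that("confidence order decides contested ground truth", {
  gt <- box(0, 0, 10, 10)
  dets <- rbind(box(0, 0, 10, 10, conf = 0.6),
                box(1, 0, 11, 10, conf = 0.9))
  m <- match_detections(dets, gt, 0.3)
  expect_equal(unname(m$tp["metastasis"]), 1)
  expect_equal(unname(m$fp["metastasis"]), 1)
  expect_equal(m$pairs$det, 2)            # the 0.9 detection wins
})

test_that("equivocal ground truth absorbs detections and is never a miss", {
  gt <- rbind(box(0, 0, 10, 10, cat = "equivocal"),
              box(30, 30, 40, 40))
  dets <- box(0, 0, 10, 10, conf = 0.8)
  m <- match_detections(dets, gt, 0.3)
  expect_equal(m$ignored, 1)
  expect_equal(unname(m$fp["metastasis"]), 0)
  expect_equal(sum(m$fn), 1)              # only the true metastasis is missed
  # a second detection on the same equivocal box is a plain FP
  dets2 <- rbind(dets, box(1, 0, 11, 10, conf = 0.5))
  m2 <- match_detections(dets2, gt, 0.3)
  expect_equal(m2$ignored, 1)
  expect_equal(unname(m2$fp["metastasis"]), 1)
})

test_that("matching counts are conserved on random instances", {
  withr::with_seed(123, {
    for (i in 1:150) {
      nd <- sample(0:4, 1); ng <- sample(0:4, 1)
      dets <- do.call(rbind, c(list(empty_boxes()), lapply(seq_len(nd), function(j)
        rand_box(cat = sample(c("metastasis", "normal_hotspot"), 1),
                 conf = runif(1)))))
      gts <- do.call(rbind, c(list(empty_boxes()), lapply(seq_len(ng), function(j)
        rand_box(cat = sample(BOX_CATEGORIES, 1)))))
      m <- match_detections(dets, gts, 0.3, merge_duplicates = FALSE)
      expect_equal(sum(m$tp) + sum(m$fn),
                   sum(gts$category != "equivocal"))
      expect_equal(sum(m$tp) + sum(m$fp) + m$ignored, nrow(dets))
    }
  })
})

test_that("greedy matching equals exhaustive assignment for <= 2 detections", {
  withr::with_seed(321, {
    for (i in 1:200) {
      nd <- sample(0:2, 1); ng <- sample(0:3, 1)
      dets <- do.call(rbind, c(list(empty_boxes()), lapply(seq_len(nd), function(j)
        rand_box(cat = sample(c("metastasis", "normal_hotspot"), 1),
                 conf = runif(1)))))
      gts <- do.call(rbind, c(list(empty_boxes()), lapply(seq_len(ng), function(j)
        rand_box(cat = sample(c("metastasis", "normal_hotspot"), 1)))))
      m <- match_detections(dets, gts, 0.3, merge_duplicates = FALSE)
      expect_equal(sum(m$tp), brute_match_tp(dets, gts, 0.3))
    }
  })
})

test_that("lesion sensitivity is monotone non-increasing in the IoU threshold", {
  withr::with_seed(55, {
    dets <- do.call(rbind, lapply(1:6, function(j) rand_box(conf = runif(1))))
    gts <- do.call(rbind, lapply(1:5, function(j) rand_box()))
    sens <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(thr) {
      lesion_metrics(match_detections(dets, gts, thr, merge_duplicates = FALSE))$sensitivity
    }, numeric(1))
    expect_true(all(diff(sens) <= 0))
  })
})

test_that("patient calls require a confident metastasis detection", {
  expect_false(patient_call(empty_boxes()))
  expect_true(patient_call(box(0, 0, 5, 5, conf = 0.9), 0.5))
  expect_false(patient_call(box(0, 0, 5, 5, cat = "normal_hotspot", conf = 0.9), 0.5))
  expect_false(patient_call(box(0, 0, 5, 5, conf = 0.5), 0.5))  # strictly greater
})

test_that("stratified folds deal both strata evenly and reproducibly", {
  manifest <- data.frame(patient_id = sprintf("p%03d", 1:194),
                         patient_positive = rep(c(TRUE, FALSE), c(100, 94)))
  f <- make_folds(manifest, k = 10, seed = 3)
  sizes <- table(f)
  expect_true(all(sizes %in% c(19, 20)))
  pos_per_fold <- table(f[manifest$patient_positive])
  neg_per_fold <- table(f[!manifest$patient_positive])
  expect_true(all(pos_per_fold == 10))
  expect_true(all(neg_per_fold %in% c(9, 10)))
  expect_identical(f, make_folds(manifest, k = 10, seed = 3))
  expect_false(identical(f, make_folds(manifest, k = 10, seed = 4)))
  tiny <- manifest[c(1:12, 101:106), ]    # only six negatives
  expect_error(make_folds(tiny, k = 10, seed = 1), "split error")
})

test_that("aggregation reproduces the published shuffle-table averages", {
  tab <- read.delim(system.file("extdata", "cv_shuffles_yolov4.tsv",
                                package = "scintihot"))
  expect_equal(nrow(tab), 10)
  rendered <- vapply(tab[, -1], function(v) render2(aggregate_metrics(v)$mean),
                     character(1))
  expect_equal(unname(rendered), c("0.72", "0.90", "0.94", "0.92"))

  tab2 <- read.delim(system.file("extdata", "cv_shuffles_faster_rcnn.tsv",
                                 package = "scintihot"))
  rendered2 <- vapply(tab2[, -1], function(v) render2(aggregate_metrics(v)$mean),
                      character(1))
  expect_equal(unname(rendered2), c("0.67", "0.65", "0.91", "0.73"))
})

test_that("aggregation computes mean and sample standard deviation", {
  a <- aggregate_metrics(rep(0.5, 10))
  expect_equal(a$mean, 0.5)
  expect_equal(a$sd, 0)
  expect_equal(a$rendered, "0.50 ± 0.00")
  expect_error(aggregate_metrics(numeric(0)), "no values")
  expect_warning(b <- aggregate_metrics(c(0.5, NA)), "undefined")
  expect_equal(b$n, 1L)
})
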