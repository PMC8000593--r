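# stub backend used to test the harvesting contract in isolation
stub_detector <- function(per_image, n_categories = 1L) {
  structure(list(per_image = per_image, n_categories = n_categories,
                 config_digest = "stub", trained = TRUE),
            class = c("stub_detector"))
}

detect_hotspots.stub_detector <- function(model, image, confidence_floor = 0.1, ...) {
  det <- model$per_image[[image$source_id]]
  if (is.null(det)) det <- empty_boxes()
  det[det$confidence > confidence_floor, , drop = FALSE]
}
registerS3method("detect_hotspots", "stub_detector", detect_hotspots.stub_detector,
                 envir = asNamespace("scintihot"))

stub_box <- function(conf, x = 20) {
  boxes_df("metastasis", conf, x, 30, x + 10, 40)
}

normals_fixture <- function(n = 3) {
  lapply(seq_len(n), function(i) {
    ch <- array(5L, c(60, 80, 3))
    fused_image(ch, source_id = paste0("n", i))
  })
}

test_that("positives-only pre-training enforces its corpus contract", {
  cohort <- small_cohort()
  pos <- cohort$images[cohort$manifest$patient_positive][1:4]
  neg <- cohort$images[!cohort$manifest$patient_positive][1]
  pre <- pretrain_positive_only(pos, backend_config(seed = 2))
  expect_equal(pre$n_categories, 1L)
  expect_error(pretrain_positive_only(c(pos, neg)), "no metastasis box")
  pre2 <- pretrain_positive_only(pos, backend_config(seed = 2))
  expect_identical(pre$coef_stack, pre2$coef_stack)
})

test_that("harvesting collects every firing as a relabeled negative", {
  normals <- normals_fixture(3)
  fires <- list(n1 = rbind(stub_box(0.9, 10), stub_box(0.9, 40)),
                n2 = stub_box(0.9, 10),
                n3 = rbind(stub_box(0.9, 10), stub_box(0.9, 30), stub_box(0.9, 55)))
  mined <- harvest_negatives(stub_detector(fires), normals)
  expect_equal(nrow(mined$boxes), 6)
  expect_true(all(mined$boxes$category == "normal_hotspot"))
  expect_true(all(mined$boxes$originating_confidence > 0.1))
  # mined boxes become the training ground truth of their image
  expect_equal(sum(vapply(mined$images, function(im) nrow(im$boxes), integer(1))), 6)
  expect_true(all(unlist(lapply(mined$images, function(im) im$boxes$category))
                  == "normal_hotspot"))
})

test_that("a detection at exactly the harvest threshold is never collected", {
  normals <- normals_fixture(1)
  at_floor <- list(n1 = rbind(stub_box(0.1, 10), stub_box(0.1 + 1e-9, 40)))
  mined <- harvest_negatives(stub_detector(at_floor), normals)
  expect_equal(nrow(mined$boxes), 1)         # strictly greater only
  expect_true(all(mined$boxes$originating_confidence > 0.1))
})

test_that("harvesting guards its preconditions", {
  normals <- normals_fixture(2)
  two_class <- stub_detector(list(), n_categories = 2L)
  expect_error(harvest_negatives(two_class, normals), "1-category")

  bad <- normals
  bad[[1]]$boxes <- stub_box(1, 10)          # metastasis ground truth
  expect_error(harvest_negatives(stub_detector(list()), bad),
               "metastasis ground truth")

  silent <- harvest_negatives(stub_detector(list()), normals)
  expect_equal(nrow(silent$boxes), 0)
  expect_error(retrain_two_class(list(), silent), "no mined negatives")
})

test_that("retraining with mined negatives yields a working two-class model", {
  cohort <- small_cohort()
  pos <- cohort$images[cohort$manifest$patient_positive]
  neg <- cohort$images[!cohort$manifest$patient_positive]
  pre <- pretrain_positive_only(pos, backend_config(seed = 5))
  mined <- harvest_negatives(pre, neg, mining_config(0.1))
  expect_true(all(mined$boxes$originating_confidence > 0.1))
  skip_if(nrow(mined$boxes) == 0, "pre-model did not fire on the normals")
  two <- retrain_two_class(pos, mined, backend_config(seed = 5))
  expect_equal(two$n_categories, 2L)
  # mined boxes are predominantly recognized as normal hotspots afterwards
  hits <- 0; tot <- 0
  for (im in mined$images) {
    if (nrow(im$boxes) == 0) next
    det <- detect_hotspots(two, im, 0.1)
    for (j in seq_len(nrow(im$boxes))) {
      if (nrow(det) == 0) next
      ious <- scintihot:::iou_matrix(det, im$boxes[j, , drop = FALSE])
      k <- which.max(ious)
      if (ious[k] >= 0.3) {
        tot <- tot + 1
        if (det$category[k] == "normal_hotspot") hits <- hits + 1
      }
    }
  }
  expect_gte(hits / tot, 0.7)
})

test_that("fine-tuning extends the pre-trained model and handles empty targets", {
  cohort <- small_cohort()
  pos <- cohort$images[cohort$manifest$patient_positive]
  neg <- cohort$images[!cohort$manifest$patient_positive]
  pre <- pretrain_positive_only(pos[1:4], backend_config(seed = 5))
  mined <- harvest_negatives(pre, neg, mining_config(0.1))
  skip_if(nrow(mined$boxes) == 0, "pre-model did not fire on the normals")
  two <- retrain_two_class(pos[1:4], mined, backend_config(seed = 5))

  ft <- transfer_finetune(two, cohort$images[5:8], backend_config(seed = 5))
  expect_gt(length(ft$coef_stack), length(two$coef_stack))

  expect_warning(same <- transfer_finetune(two, list()), "empty target")
  expect_identical(same$coef_stack, two$coef_stack)

  expect_error(transfer_finetune(pre, cohort$images[5:6]), "2-category")
})
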