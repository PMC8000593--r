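test_that("projection profiles find the body range", {
  img <- matrix(0, 300, 200)
  img[101:110, 51:60] <- 50
  expect_equal(detect_body_range(img),
               c(row_min = 100, row_max = 110, col_min = 50, col_max = 60))

  const <- matrix(3, 40, 30)
  expect_equal(detect_body_range(const),
               c(row_min = 0, row_max = 40, col_min = 0, col_max = 30))

  expect_error(detect_body_range(matrix(0, 5, 5)), "no positive counts")

  # phantom: detected range contains the brute-force nonzero bounding box
  g <- generate_scan(phantom_config(seed = 3, noise = "none", global_gain = 1))
  ap <- g$scan$pixels[, 1:256]
  rng <- detect_body_range(ap)
  nz <- which(ap > 0, arr.ind = TRUE)
  expect_lte(rng["row_min"], min(nz[, 1]) - 1)
  expect_gte(rng["row_max"], max(nz[, 1]))
  expect_lte(rng["col_min"], min(nz[, 2]) - 1)
  expect_gte(rng["col_max"], max(nz[, 2]))
})

test_that("centering places crops with the expected offsets and guards size", {
  cc <- scintihot:::center_on_canvas(matrix(1, 900, 400))
  expect_equal(cc$row_off, 25)
  expect_equal(cc$col_off, 56)
  expect_equal(dim(cc$canvas), c(950, 512))
  expect_error(scintihot:::center_on_canvas(matrix(1, 951, 400)), "centering error")
  expect_error(scintihot:::center_on_canvas(matrix(1, 900, 513)), "centering error")
})

test_that("split_and_center shifts boxes rigidly (IoU invariant)", {
  g <- generate_scan(phantom_config(seed = 13, n_metastases = 3, n_benign = 1,
                                    noise = "none", global_gain = 1))
  native <- rbind(g$ap_boxes, scintihot:::shift_boxes(g$pa_boxes, 256, 0))
  pair <- split_and_center(g$scan, native)
  before <- g$ap_boxes; after <- pair$boxes$ap
  expect_equal(nrow(after), nrow(before))
  # translation: coordinates differ by one constant offset per axis
  expect_equal(length(unique(round(after$x_min - before$x_min, 9))), 1)
  expect_equal(length(unique(round(after$y_min - before$y_min, 9))), 1)
  if (nrow(before) >= 2) {
    for (i in 1:(nrow(before) - 1)) {
      expect_equal(iou(after[i, ], after[i + 1, ]),
                   iou(before[i, ], before[i + 1, ]))
    }
  }
})

test_that("mean-controlled normalization hits its range and is idempotent", {
  const10 <- matrix(10, 50, 40)
  out <- normalize_intensity(const10, 7, 14)
  expect_equal(as.vector(out), rep(10L, 2000))
  expect_equal(attr(out, "iterations"), 0L)

  const210 <- matrix(210, 50, 40)
  out2 <- normalize_intensity(const210, 7, 14)
  expect_true(all(out2 == 11L))   # 210 * 10.5/210 = 10.5 rounds away to 11

  expect_error(normalize_intensity(matrix(0, 4, 4)), "not positive")

  withr::with_seed(31, {
    for (i in 1:25) {
      g <- generate_scan(phantom_config(seed = sample.int(1e6, 1)))
      pair <- split_and_center(g$scan)
      for (v in list(pair$ap, pair$pa)) {
        n1 <- normalize_intensity(v, 7, 14)
        m <- mean(n1)
        expect_gt(m, 7); expect_lt(m, 14)
        n2 <- normalize_intensity(n1, 7, 14)
        expect_identical(as.vector(n2), as.vector(n1))
      }
    }
  })
})

test_that("one normalization iteration suffices when no clipping occurs", {
  withr::with_seed(5, {
    img <- matrix(runif(5000, 0, 40), 100, 50)  # mean ~20, max < 255 * 2m/(t1+t2)
    out <- normalize_intensity(img, 7, 14)
    expect_equal(attr(out, "iterations"), 1L)
    expect_gt(mean(out), 7); expect_lt(mean(out), 14)
  })
})

test_that("chest extraction crops the fractional body band and maps boxes", {
  ap <- matrix(0L, 950, 512); ap[51:950, 100:400] <- 5L
  boxes_ap <- boxes_df(c("metastasis", "metastasis", "normal_hotspot"),
                       1, x_min = c(200, 210, 220),
                       y_min = c(200, 600, 450), x_max = c(210, 222, 232),
                       y_max = c(210, 612, 460))
  pair <- structure(list(ap = ap, pa = ap,
                         boxes = list(ap = boxes_ap, pa = empty_boxes()),
                         offsets = list(), body = list(), normalized = TRUE),
                    class = "view_pair")
  roi <- extract_chest(pair)
  expect_equal(unname(roi$crop[c("row_min", "row_max")]), c(140, 455))
  expect_equal(dim(roi$ap_chest), c(315, 512))
  kept <- roi$boxes$ap
  # box at y 600..612 lies wholly below the band and is dropped
  expect_equal(nrow(kept), 2)
  # fully inside: un-translating recovers the original
  inside <- kept[kept$x_min == 200, ]
  expect_equal(inside$y_min + 140, 200)
  expect_equal(inside$y_max + 140, 210)
  # straddling the lower edge: clipped there (rectangle-intersection oracle)
  clipped <- kept[kept$x_min == 220, ]
  expect_equal(clipped$y_min + 140, 450)
  expect_equal(clipped$y_max + 140, 455)   # min(460, 455)
})

test_that("chest extraction refuses degenerate bodies", {
  ap <- matrix(0L, 950, 512); ap[100:150, 200:300] <- 9L
  pair <- structure(list(ap = ap, pa = ap,
                         boxes = list(ap = empty_boxes(), pa = empty_boxes()),
                         offsets = list(), body = list(), normalized = TRUE),
                    class = "view_pair")
  expect_error(extract_chest(pair), "body height")
})
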