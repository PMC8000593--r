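test_that("label lines convert to absolute half-open pixel boxes", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 1.0 1.0", f)
  b <- read_labels(f, width = 100, height = 200)
  expect_equal(b$category, "metastasis")
  expect_equal(unlist(b[, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 0, y_min = 0, x_max = 100, y_max = 200))

  writeLines("1 0.25 0.5 0.1 0.2", f)
  b <- read_labels(f, width = 512, height = 950)
  expect_equal(b$category, "normal_hotspot")
  expect_equal(b$x_min, 102.4); expect_equal(b$x_max, 153.6)
  expect_equal(b$y_min, 380);   expect_equal(b$y_max, 570)
})

test_that("label write-read round trip is the identity to 1e-6 px", {
  withr::with_seed(42, {
    f <- withr::local_tempfile(fileext = ".txt")
    for (i in 1:20) {
      n <- sample(0:6, 1)
      boxes <- do.call(rbind, c(list(empty_boxes()),
                                lapply(seq_len(n), function(j)
                                  rand_box(lim = 200, cat = sample(BOX_CATEGORIES, 1)))))
      write_labels(boxes, f, width = 256, height = 256)
      back <- read_labels(f, width = 256, height = 256)
      expect_equal(nrow(back), n)
      if (n > 0) {
        for (col in c("x_min", "y_min", "x_max", "y_max"))
          expect_lt(max(abs(back[[col]] - boxes[[col]])), 1e-6)
        expect_identical(back$category, boxes$category)
      }
    }
  })
})

test_that("malformed or out-of-bounds labels raise informative errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.2 0.2", "0 0.5 banana 0.2"), f)
  expect_error(read_labels(f, 100, 100), "line 2")
  writeLines("0 0.95 0.5 0.2 0.2", f)   # escapes the right edge
  expect_error(read_labels(f, 100, 100), "escapes")
  writeLines("7 0.5 0.5 0.2 0.2", f)
  expect_error(read_labels(f, 100, 100), "category index")
})

test_that("flip_box mirrors, is an involution, and fixes centered boxes", {
  b <- boxes_df("metastasis", 1, 0, 0, 10, 10)
  fb <- flip_box(b, 100)
  expect_equal(unlist(fb[, c("x_min", "x_max")]), c(x_min = 90, x_max = 100))
  expect_equal(fb$y_min, 0); expect_equal(fb$y_max, 10)

  centered <- boxes_df("equivocal", 1, 45, 5, 55, 15)
  expect_equal(flip_box(centered, 100), centered)

  withr::with_seed(7, {
    for (i in 1:50) {
      bb <- rand_box(lim = 80, cat = sample(BOX_CATEGORIES, 1))
      expect_equal(flip_box(flip_box(bb, 80), 80), bb)
    }
  })
})

test_that("scan I/O preserves counts bit-exactly across dialects", {
  d <- withr::local_tempdir()
  zero <- raw_scan(matrix(0L, 1024, 512), "z")
  write_scan(zero, file.path(d, "z.tif"))
  expect_equal(sum(read_scan(file.path(d, "z.tif"))$pixels), 0)

  px <- matrix(0L, 1024, 512)
  px[1, 1] <- 65535L                       # extreme single count
  px[5, 7] <- 12345L
  s <- raw_scan(px, "x")
  write_scan(s, file.path(d, "x.tif"))
  write_scan(s, file.path(d, "x.raw"))
  t1 <- read_scan(file.path(d, "x.tif"))    # two independent decoders
  t2 <- read_scan(file.path(d, "x.raw"))
  expect_identical(t1$pixels[1, 1], 65535L)
  expect_identical(t1$pixels, t2$pixels)
  expect_equal(sum(t1$pixels), sum(px))

  g <- generate_scan(phantom_config(seed = 2, n_metastases = 1))
  write_scan(g$scan, file.path(d, "p.tif"))
  expect_identical(read_scan(file.path(d, "p.tif"))$pixels,
                   {m <- g$scan$pixels; storage.mode(m) <- "integer"; m})
})

test_that("scan reader rejects unreadable input and wrong raw sizes", {
  d <- withr::local_tempdir()
  expect_error(read_scan(file.path(d, "missing.tif")), "not found")
  writeBin(raw(10), file.path(d, "short.raw"))
  expect_error(read_scan(file.path(d, "short.raw")), "expected")
  expect_error(read_scan(file.path(d, "x.dcm"), dialect = "dicom"), "not found")
  writeBin(raw(8), file.path(d, "x.dcm"))
  expect_error(read_scan(file.path(d, "x.dcm")), "dicom")
})

test_that("manifest round trips and validates its columns", {
  d <- withr::local_tempdir()
  m <- data.frame(image = c("a.tif", "b.tif"), label = c("a.txt", "b.txt"),
                  patient_id = c("a", "b"), cohort = "synthetic",
                  patient_positive = c(TRUE, FALSE))
  write_manifest(m, file.path(d, "m.csv"))
  back <- read_manifest(file.path(d, "m.csv"))
  expect_equal(back$patient_positive, c(TRUE, FALSE))
  expect_equal(back$image, m$image)
  m2 <- m; m2$image <- "a.tif"
  write.csv(m2, file.path(d, "dup.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(d, "dup.csv")), "duplicate")
})
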