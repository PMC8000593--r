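#' Hotspot categories
#'
#' Category coding shared by annotations and detections. In label files the
#' integer indices are 0 = metastasis, 1 = normal_hotspot, 2 = equivocal.
#'
#' @export
BOX_CATEGORIES <- c("metastasis", "normal_hotspot", "equivocal")

CATEGORY_INDEX <- c(metastasis = 0L, normal_hotspot = 1L, equivocal = 2L)

#' Construct a bounding-box table
#'
#' Boxes are stored as a data frame with one row per box and columns
#' `category`, `confidence`, `x_min`, `y_min`, `x_max`, `y_max`. Coordinates
#' are 0-based and half-open: a box covers pixels with x in
#' `[x_min, x_max)` and y in `[y_min, y_max)`, so its area is
#' `(x_max - x_min) * (y_max - y_min)`. Ground-truth boxes carry
#' confidence 1.
#'
#' @param category character vector drawn from [BOX_CATEGORIES].
#' @param confidence numeric in `[0, 1]`.
#' @param x_min,y_min,x_max,y_max pixel coordinates.
#' @return validated data frame of class `data.frame`.
#' @export
boxes_df <- function(category = character(), confidence = numeric(),
                     x_min = numeric(), y_min = numeric(),
                     x_max = numeric(), y_max = numeric()) {
  df <- data.frame(category = as.character(category),
                   confidence = as.numeric(confidence),
                   x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                   x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                   stringsAsFactors = FALSE)
  validate_boxes(df)
}

empty_boxes <- function() {
  data.frame(category = character(), confidence = numeric(),
             x_min = numeric(), y_min = numeric(),
             x_max = numeric(), y_max = numeric(),
             stringsAsFactors = FALSE)
}

#' Validate a box table
#'
#' Checks category labels, confidence range, box orientation
#' (`x_min < x_max`, `y_min < y_max`) and, when image dimensions are
#' supplied, containment within `[0, width) x [0, height)` bounds.
#'
#' @param boxes box data frame (see [boxes_df()]).
#' @param width,height optional host-image dimensions in pixels.
#' @return `boxes`, invisibly unchanged, or an error.
#' @export
validate_boxes <- function(boxes, width = NULL, height = NULL) {
  need <- c("category", "confidence", "x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(boxes)))
    stopf("box table must have columns: %s", paste(need, collapse = ", "))
  if (nrow(boxes) == 0) return(boxes)
  bad <- !boxes$category %in% BOX_CATEGORIES
  if (any(bad))
    stopf("unknown box category: %s", paste(unique(boxes$category[bad]), collapse = ", "))
  if (any(boxes$confidence < 0 | boxes$confidence > 1))
    stopf("box confidence outside [0, 1]")
  if (any(boxes$x_min >= boxes$x_max) || any(boxes$y_min >= boxes$y_max))
    stopf("degenerate box: x_min < x_max and y_min < y_max required")
  tol <- 1e-6
  if (!is.null(width) && any(boxes$x_min < -tol | boxes$x_max > width + tol))
    stopf("box escapes image bounds in x (width %s)", width)
  if (!is.null(height) && any(boxes$y_min < -tol | boxes$y_max > height + tol))
    stopf("box escapes image bounds in y (height %s)", height)
  boxes
}

#' Mirror boxes left-right
#'
#' Reflects boxes about the vertical axis of an image of the given width,
#' the coordinate transform used when the posterior view is flipped.
#' The operation is an involution: applying it twice is the identity.
#'
#' @param boxes box data frame.
#' @param width image width in pixels.
#' @return box data frame with `x_min' = width - x_max`,
#'   `x_max' = width - x_min`; y, category and confidence unchanged.
#' @export
flip_box <- function(boxes, width) {
  if (nrow(boxes) == 0) return(boxes)
  validate_boxes(boxes, width = width)
  new_x_min <- width - boxes$x_max
  boxes$x_max <- width - boxes$x_min
  boxes$x_min <- new_x_min
  boxes
}

shift_boxes <- function(boxes, dx, dy) {
  if (nrow(boxes) == 0) return(boxes)
  boxes$x_min <- boxes$x_min + dx
  boxes$x_max <- boxes$x_max + dx
  boxes$y_min <- boxes$y_min + dy
  boxes$y_max <- boxes$y_max + dy
  boxes
}

# intersect boxes with the rectangle [x0,x1) x [y0,y1); boxes left with
# no interior are dropped
clip_boxes <- function(boxes, x0, y0, x1, y1) {
  if (nrow(boxes) == 0) return(boxes)
  boxes$x_min <- pmax(boxes$x_min, x0)
  boxes$y_min <- pmax(boxes$y_min, y0)
  boxes$x_max <- pmin(boxes$x_max, x1)
  boxes$y_max <- pmin(boxes$y_max, y1)
  keep <- boxes$x_min < boxes$x_max & boxes$y_min < boxes$y_max
  boxes[keep, , drop = FALSE]
}

#' Intersection over union of two boxes
#'
#' Areas follow the half-open convention, so there is no +/-1 ambiguity:
#' identical boxes give 1, disjoint boxes give 0.
#'
#' @param a,b single boxes: 1-row data frames or named vectors with
#'   `x_min`, `y_min`, `x_max`, `y_max`.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  ax0 <- as.numeric(a$x_min); ay0 <- as.numeric(a$y_min)
  ax1 <- as.numeric(a$x_max); ay1 <- as.numeric(a$y_max)
  bx0 <- as.numeric(b$x_min); by0 <- as.numeric(b$y_min)
  bx1 <- as.numeric(b$x_max); by1 <- as.numeric(b$y_max)
  if (ax0 >= ax1 || ay0 >= ay1 || bx0 >= bx1 || by0 >= by1)
    stopf("degenerate box passed to iou()")
  iw <- max(0, min(ax1, bx1) - max(ax0, bx0))
  ih <- max(0, min(ay1, by1) - max(ay0, by0))
  inter <- iw * ih
  union <- (ax1 - ax0) * (ay1 - ay0) + (bx1 - bx0) * (by1 - by0) - inter
  inter / union
}

# pairwise IoU matrix between two box tables (rows of a x rows of b)
iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(0, na, nb))
  ix0 <- outer(a$x_min, b$x_min, pmax)
  iy0 <- outer(a$y_min, b$y_min, pmax)
  ix1 <- outer(a$x_max, b$x_max, pmin)
  iy1 <- outer(a$y_max, b$y_max, pmin)
  inter <- pmax(ix1 - ix0, 0) * pmax(iy1 - iy0, 0)
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (outer(area_a, area_b, "+") - inter)
}

#' Merge duplicate ground-truth boxes
#'
#' Fused chest images carry the union of anterior and mirrored-posterior
#' annotations, so the same physical lesion can appear twice. Same-category
#' boxes overlapping at IoU >= `iou_threshold` are merged into their
#' bounding union (confidence = max of the pair), repeatedly until stable.
#'
#' @param boxes box data frame.
#' @param iou_threshold merge threshold, default 0.5.
#' @return deduplicated box data frame.
#' @export
merge_duplicate_boxes <- function(boxes, iou_threshold = 0.5) {
  if (nrow(boxes) <= 1) return(boxes)
  repeat {
    n <- nrow(boxes)
    m <- iou_matrix(boxes, boxes)
    same <- outer(boxes$category, boxes$category, "==")
    m[!same] <- 0
    diag(m) <- 0
    hit <- which(m >= iou_threshold, arr.ind = TRUE)
    if (nrow(hit) == 0) break
    i <- hit[1, 1]; j <- hit[1, 2]
    merged <- boxes[i, , drop = FALSE]
    merged$x_min <- min(boxes$x_min[c(i, j)])
    merged$y_min <- min(boxes$y_min[c(i, j)])
    merged$x_max <- max(boxes$x_max[c(i, j)])
    merged$y_max <- max(boxes$y_max[c(i, j)])
    merged$confidence <- max(boxes$confidence[c(i, j)])
    boxes <- rbind(merged, boxes[-c(i, j), , drop = FALSE])
    rownames(boxes) <- NULL
    if (nrow(boxes) >= n) break  # safety; cannot normally happen
  }
  boxes
}

#' Read box annotations in normalized one-line-per-box format
#'
#' Parses the plain-text annotation dialect of one-stage detectors: one box
#' per line, `<category> <x_center> <y_center> <w> <h>`, with the last four
#' fields normalized to `[0, 1]`. Category indices are 0 = metastasis,
#' 1 = normal_hotspot, 2 = equivocal.
#'
#' @param path label file path.
#' @param width,height dimensions of the host image in pixels.
#' @return box data frame in absolute half-open pixel coordinates with
#'   confidence 1 (ground truth).
#' @export
read_labels <- function(path, width, height) {
  if (!file.exists(path)) stopf("label file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  out <- empty_boxes()
  for (ln in which(keep)) {
    fields <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) != 5 || anyNA(vals))
      stopf("parse error in %s at line %d: expected 5 numeric fields", path, ln)
    ci <- as.integer(vals[1])
    if (!ci %in% CATEGORY_INDEX || vals[1] != ci)
      stopf("parse error in %s at line %d: unknown category index %s", path, ln, fields[1])
    xc <- vals[2] * width; yc <- vals[3] * height
    w <- vals[4] * width;  h <- vals[5] * height
    out <- rbind(out, data.frame(
      category = names(CATEGORY_INDEX)[match(ci, CATEGORY_INDEX)],
      confidence = 1,
      x_min = xc - w / 2, y_min = yc - h / 2,
      x_max = xc - w / 2 + w, y_max = yc - h / 2 + h,
      stringsAsFactors = FALSE))
  }
  validate_boxes(out, width = width, height = height)
}

#' Write box annotations in normalized one-line-per-box format
#'
#' Inverse of [read_labels()]; a read-write-read round trip reproduces box
#' coordinates to within 1e-6 pixel.
#'
#' @param boxes box data frame in absolute pixel coordinates.
#' @param path output file path.
#' @param width,height host-image dimensions used for normalization.
#' @return `path`, invisibly.
#' @export
write_labels <- function(boxes, path, width, height) {
  validate_boxes(boxes, width = width, height = height)
  lines <- character(nrow(boxes))
  if (nrow(boxes) > 0) {
    ci <- CATEGORY_INDEX[boxes$category]
    xc <- (boxes$x_min + boxes$x_max) / 2 / width
    yc <- (boxes$y_min + boxes$y_max) / 2 / height
    w <- (boxes$x_max - boxes$x_min) / width
    h <- (boxes$y_max - boxes$y_min) / height
    lines <- sprintf("%d %.10f %.10f %.10f %.10f", ci, xc, yc, w, h)
  }
  writeLines(lines, path)
  invisible(path)
}
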