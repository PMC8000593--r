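CANVAS_H <- 950L
CANVAS_W <- 512L

#' Detect the body range from projection profiles
#'
#' Row and column sum profiles are thresholded at `tau` times their
#' maximum; the smallest half-open row/column interval containing every
#' above-threshold profile entry is returned (0-based, half-open).
#'
#' @param image non-empty 2-D count grid with some positive counts.
#' @param tau profile threshold as a fraction of the profile maximum;
#'   default 0.01, robust to isolated noise counts.
#' @return named integer vector `(row_min, row_max, col_min, col_max)`.
#' @export
detect_body_range <- function(image, tau = 0.01) {
  if (length(image) == 0 || all(image <= 0))
    stopf("body-range detection error: image has no positive counts")
  rp <- rowSums(image); cp <- colSums(image)
  ri <- which(rp >= tau * max(rp))
  ci <- which(cp >= tau * max(cp))
  c(row_min = min(ri) - 1L, row_max = max(ri),
    col_min = min(ci) - 1L, col_max = max(ci))
}

# place a crop centered on a zero canvas; returns canvas + 0-based offsets
center_on_canvas <- function(crop, canvas_height = CANVAS_H, canvas_width = CANVAS_W) {
  ch <- nrow(crop); cw <- ncol(crop)
  if (ch > canvas_height || cw > canvas_width)
    stopf("centering error: body crop %d x %d exceeds canvas %d x %d",
          ch, cw, canvas_height, canvas_width)
  row_off <- (canvas_height - ch) %/% 2L
  col_off <- (canvas_width - cw) %/% 2L
  canvas <- matrix(0, canvas_height, canvas_width)
  canvas[row_off + seq_len(ch), col_off + seq_len(cw)] <- crop
  list(canvas = canvas, row_off = row_off, col_off = col_off)
}

split_views <- function(scan) {
  px <- scan$pixels
  if (scan$layout == "side_by_side") {
    w <- ncol(px) %/% 2L
    list(ap = px[, seq_len(w), drop = FALSE],
         pa = px[, w + seq_len(w), drop = FALSE])
  } else {
    h <- nrow(px) %/% 2L
    list(ap = px[seq_len(h), , drop = FALSE],
         pa = px[h + seq_len(h), , drop = FALSE])
  }
}

#' Split a scan into views and center each on a 512 x 950 canvas
#'
#' Each view's body range is detected with projection profiles, cut out and
#' placed centered on a zero canvas of 512 columns by 950 rows, without any
#' scaling or resampling. Ground-truth boxes (in native-frame coordinates)
#' are split by view and rigidly translated by the same offsets, so all
#' pairwise box relations (including IoU) are preserved.
#'
#' @param scan a [raw_scan()].
#' @param boxes optional box data frame in native-frame coordinates.
#' @param tau projection-profile threshold, see [detect_body_range()].
#' @return object of class `view_pair`: 16-bit staging canvases `ap` and
#'   `pa`, per-view `offsets` (0-based `(row, col)` placement) and detected
#'   `body` ranges, per-view `boxes`, and a `normalized` flag (FALSE until
#'   [normalize_views()] is applied).
#' @export
split_and_center <- function(scan, boxes = NULL, tau = 0.01) {
  stopifnot(inherits(scan, "raw_scan"))
  views <- split_views(scan)
  vw <- ncol(views$ap)
  box_split <- list(ap = empty_boxes(), pa = empty_boxes())
  if (!is.null(boxes) && nrow(boxes) > 0) {
    in_ap <- boxes$x_max <= vw
    box_split$ap <- boxes[in_ap, , drop = FALSE]
    box_split$pa <- shift_boxes(boxes[!in_ap, , drop = FALSE], -vw, 0)
  }
  out <- list(boxes = list(), offsets = list(), body = list())
  for (v in c("ap", "pa")) {
    rng <- detect_body_range(views[[v]], tau = tau)
    crop <- views[[v]][(rng["row_min"] + 1):rng["row_max"],
                       (rng["col_min"] + 1):rng["col_max"], drop = FALSE]
    cc <- center_on_canvas(crop)
    out[[v]] <- cc$canvas
    out$offsets[[v]] <- c(row = cc$row_off, col = cc$col_off)
    out$body[[v]] <- rng
    b <- shift_boxes(box_split[[v]],
                     cc$col_off - rng["col_min"], cc$row_off - rng["row_min"])
    out$boxes[[v]] <- clip_boxes(b, 0, 0, CANVAS_W, CANVAS_H)
  }
  out$normalized <- FALSE
  structure(out, class = "view_pair")
}

#' Mean-controlled intensity normalization to 8 bits
#'
#' Iteratively rescales an image so its average intensity falls in the open
#' interval `(t1, t2)`: the mean `m` is computed in double precision over
#' the full grid; if it is outside the interval every pixel is multiplied
#' by `((t1 + t2)/2) / m` (scaling to the interval midpoint), clipped to
#' `[0, 255]`, rounded half away from zero, and the mean re-checked.
#' Clipping can drag the mean back down for heavy-tailed images, which is
#' why the loop iterates. The operation is idempotent: a second application
#' sees the mean already in range and returns the input unchanged.
#'
#' @param image count grid with positive mean (16-bit or 8-bit).
#' @param t1,t2 target interval, `0 < t1 < t2 <= 255`; the defaults (7, 14)
#'   are the whole-body operating range.
#' @param max_iterations iteration cap; if exhausted the image is returned
#'   with a warning (pathological inputs).
#' @return 8-bit integer matrix with attributes `iterations` and
#'   `achieved_mean`.
#' @export
normalize_intensity <- function(image, t1 = 7, t2 = 14, max_iterations = 10L) {
  if (!(t1 > 0 && t1 < t2 && t2 <= 255))
    stopf("invalid normalization range: need 0 < t1 < t2 <= 255")
  img <- image
  storage.mode(img) <- "double"
  if (mean(img) <= 0) stopf("normalization error: image mean is not positive")
  it <- 0L
  repeat {
    m <- mean(img)
    if (m > t1 && m < t2 && max(img) <= 255) break
    if (it >= max_iterations) {
      warning(sprintf("normalization did not reach (%g, %g) after %d iterations (mean %.3f)",
                      t1, t2, max_iterations, m))
      img <- round_half_away(clip8(img))
      break
    }
    img <- if (m > t1 && m < t2) round_half_away(clip8(img))
           else round_half_away(clip8(img * ((t1 + t2) / 2) / m))
    it <- it + 1L
  }
  out <- img
  storage.mode(out) <- "integer"
  attr(out, "iterations") <- it
  attr(out, "achieved_mean") <- mean(img)
  out
}

#' Normalize both views of a centered pair
#'
#' Applies [normalize_intensity()] to each 512 x 950 canvas. The mean is
#' taken over the full canvas including the zero background.
#'
#' @param pair a `view_pair` from [split_and_center()].
#' @param t1,t2,max_iterations see [normalize_intensity()].
#' @return the pair with 8-bit views and `normalized = TRUE`.
#' @export
normalize_views <- function(pair, t1 = 7, t2 = 14, max_iterations = 10L) {
  stopifnot(inherits(pair, "view_pair"))
  pair$ap <- normalize_intensity(pair$ap, t1, t2, max_iterations)
  pair$pa <- normalize_intensity(pair$pa, t1, t2, max_iterations)
  pair$normalized <- TRUE
  pair
}

#' Extract the chest region from a normalized view pair
#'
#' A single crop rectangle is applied to both views: the full canvas width,
#' and the rows spanning `[body_top + band[1] * H, body_top + band[2] * H)`
#' where `H` is the body height detected on the summed views. The fixed
#' fractional band replaces a learned chest detector; it is deterministic
#' and testable, and the fractions are exposed for tuning. Boxes are
#' translated into crop coordinates; boxes fully outside are dropped and
#' boxes straddling an edge are clipped.
#'
#' @param pair a normalized `view_pair`.
#' @param band lower/upper chest band as fractions of body height,
#'   default `c(0.10, 0.45)`.
#' @return object of class `chest_roi` with `ap_chest`, `pa_chest`, the
#'   `crop` rectangle in canvas coordinates, and per-view `boxes`.
#' @export
extract_chest <- function(pair, band = c(0.10, 0.45)) {
  stopifnot(inherits(pair, "view_pair"), length(band) == 2, band[1] < band[2])
  comb <- pair$ap + pair$pa
  rng <- detect_body_range(comb)
  top <- rng[["row_min"]]; hb <- rng[["row_max"]] - top
  if (hb < 100) stopf("chest extraction error: body height %d px < 100", hb)
  r_lo <- as.integer(round_half_away(top + band[1] * hb))
  r_hi <- as.integer(round_half_away(top + band[2] * hb))
  crop_rows <- (r_lo + 1):r_hi
  out <- list(
    ap_chest = pair$ap[crop_rows, , drop = FALSE],
    pa_chest = pair$pa[crop_rows, , drop = FALSE],
    crop = c(row_min = r_lo, row_max = r_hi, col_min = 0L, col_max = CANVAS_W),
    boxes = lapply(pair$boxes, function(b)
      clip_boxes(shift_boxes(b, 0, -r_lo), 0, 0, CANVAS_W, r_hi - r_lo))
  )
  structure(out, class = "chest_roi")
}

#' Full preprocessing chain: scan to fused chest image
#'
#' Convenience wrapper running [split_and_center()], [normalize_views()],
#' [extract_chest()] and [fuse_views()] with one set of parameters.
#'
#' @param scan a [raw_scan()].
#' @param boxes native-frame ground-truth boxes (optional).
#' @param t1,t2 normalization range, default (7, 14).
#' @param band chest band fractions, default `c(0.10, 0.45)`.
#' @param source_id identifier attached to the fused image.
#' @return a [fused_image()].
#' @export
prepare_fused <- function(scan, boxes = NULL, t1 = 7, t2 = 14,
                          band = c(0.10, 0.45), source_id = scan$scan_id) {
  pair <- split_and_center(scan, boxes)
  pair <- normalize_views(pair, t1, t2)
  chest <- extract_chest(pair, band)
  fuse_views(chest, source_id = source_id)
}
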