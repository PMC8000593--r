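#' Construct a fused three-channel chest image
#'
#' @param channels 8-bit integer array `height x width x 3`
#'   (red = AP chest, green = mirrored PA chest, third = scaled product).
#' @param boxes box data frame in fused coordinates.
#' @param source_id provenance: originating scan id.
#' @param intensity_level augmentation level (1-based ordinal) or `NA`.
#' @param is_flipped whether this is a horizontally mirrored variant.
#' @return object of class `fused_image`.
#' @export
fused_image <- function(channels, boxes = empty_boxes(), source_id = "fused",
                        intensity_level = NA_integer_, is_flipped = FALSE) {
  stopifnot(length(dim(channels)) == 3, dim(channels)[3] == 3)
  validate_boxes(boxes, width = dim(channels)[2], height = dim(channels)[1])
  structure(list(channels = channels, boxes = boxes,
                 source_id = source_id,
                 intensity_level = intensity_level,
                 is_flipped = isTRUE(is_flipped)),
            class = "fused_image")
}

#' @export
#' @method print fused_image
print.fused_image <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<fused_image %s: %d x %d, %d boxes, level %s%s>\n",
              x$source_id, d[1], d[2], nrow(x$boxes),
              ifelse(is.na(x$intensity_level), "-", x$intensity_level),
              if (x$is_flipped) ", flipped" else ""))
  invisible(x)
}

fused_dims <- function(fused) dim(fused$channels)[1:2]

#' Fuse AP and mirrored PA chest views into a three-channel image
#'
#' The anterior chest becomes the red channel; the posterior chest is
#' flipped left-right (restoring anatomical correspondence) and becomes the
#' green channel. The third channel is the pixelwise product of the two,
#' rescaled so that its average intensity equals the mean of the two view
#' means; because the product image is heavy-tailed, the scale factor is
#' re-adjusted after clipping to 255 until the post-clip mean is within
#' 0.2 of the target (the first iteration uses the analytic pre-clip
#' factor). Boxes are the union of AP boxes and mirrored PA boxes, kept as
#' separate entries; deduplication happens at evaluation time
#' (see [merge_duplicate_boxes()]).
#'
#' @param chest a `chest_roi` from [extract_chest()].
#' @param source_id provenance id.
#' @return a [fused_image()].
#' @export
fuse_views <- function(chest, source_id = "fused") {
  stopifnot(inherits(chest, "chest_roi"))
  ap <- chest$ap_chest; storage.mode(ap) <- "double"
  pa <- chest$pa_chest; storage.mode(pa) <- "double"
  if (!identical(dim(ap), dim(pa)))
    stopf("fusion error: view crops differ in size (%s vs %s)",
          paste(dim(ap), collapse = "x"), paste(dim(pa), collapse = "x"))
  w <- ncol(ap)
  green <- pa[, w:1, drop = FALSE]
  target <- (mean(ap) + mean(green)) / 2
  pr <- ap * green
  if (mean(pr) > 0 && target > 0) {
    s <- target / mean(pr)
    third <- clip8(s * pr)
    for (i in 1:25) {
      m <- mean(third)
      if (abs(m - target) <= 0.2 || m == 0) break
      s <- s * target / m
      third <- clip8(s * pr)
    }
  } else {
    third <- pr * 0
  }
  ch <- array(0L, dim = c(nrow(ap), ncol(ap), 3))
  ch[, , 1] <- quantize8(ap)
  ch[, , 2] <- quantize8(green)
  ch[, , 3] <- quantize8(third)
  boxes <- rbind(chest$boxes$ap, flip_box(chest$boxes$pa, w))
  rownames(boxes) <- NULL
  fused_image(ch, boxes = boxes, source_id = source_id)
}

#' Augmentation plan
#'
#' Offline augmentation: `n_levels` intensity variants whose red-channel
#' means are evenly spaced midpoints of the target range, each optionally
#' emitted with a horizontal mirror. With the defaults (6 levels in
#' (25, 48), flips on) the dataset grows by a factor of exactly 12; the
#' original image is not additionally emitted.
#'
#' @param low,high open target range for the chest average intensity,
#'   default (25, 48).
#' @param n_levels number of intensity levels, default 6.
#' @param include_flips also emit mirrored variants, default TRUE.
#' @return object of class `augment_plan`.
#' @export
augment_plan <- function(low = 25, high = 48, n_levels = 6L, include_flips = TRUE) {
  stopifnot(low < high, n_levels >= 1)
  structure(list(low = low, high = high, n_levels = as.integer(n_levels),
                 include_flips = isTRUE(include_flips)),
            class = "augment_plan")
}

flip_fused <- function(fused) {
  w <- dim(fused$channels)[2]
  ch <- fused$channels[, w:1, , drop = FALSE]
  fused_image(ch, boxes = flip_box(fused$boxes, w),
              source_id = fused$source_id,
              intensity_level = fused$intensity_level, is_flipped = !fused$is_flipped)
}

#' Produce the offline augmentation set of a fused image
#'
#' For level `k = 1..n_levels` the target mean is the midpoint
#' `low + (high - low) * (2k - 1) / (2 n_levels)` (for the defaults:
#' 26.917, 30.75, 34.583, 38.417, 42.25, 46.083); midpoint spacing keeps
#' every achieved mean strictly inside the open range despite clipping.
#' All three channels are rescaled jointly by one factor (preserving the
#' channel ratios) until the red-channel mean is within 0.3 of the target,
#' re-clipping and re-checking as in [normalize_intensity()]. Box geometry
#' is untouched by re-leveling; flip variants carry mirrored boxes.
#'
#' @param fused a [fused_image()].
#' @param plan an [augment_plan()].
#' @return list of [fused_image()] of length
#'   `n_levels * (2 if flips else 1)`, provenance fields set.
#' @export
augment_fused <- function(fused, plan = augment_plan()) {
  stopifnot(inherits(fused, "fused_image"), inherits(plan, "augment_plan"))
  base <- fused$channels
  storage.mode(base) <- "double"
  m0 <- mean(base[, , 1])
  if (m0 <= 0) stopf("augmentation error: red channel has zero mean")
  out <- vector("list", plan$n_levels * (1L + plan$include_flips))
  j <- 0L
  red <- base[, , 1]
  for (k in seq_len(plan$n_levels)) {
    tk <- plan$low + (plan$high - plan$low) * (2 * k - 1) / (2 * plan$n_levels)
    s <- tk / m0
    for (i in 1:12) {
      m <- mean(clip8(s * red))
      if (abs(m - tk) <= 0.3 || m == 0) break
      s <- s * tk / m
    }
    v <- fused_image(quantize8(s * base), boxes = fused$boxes,
                     source_id = fused$source_id,
                     intensity_level = k, is_flipped = fused$is_flipped)
    j <- j + 1L; out[[j]] <- v
    if (plan$include_flips) { j <- j + 1L; out[[j]] <- flip_fused(v) }
  }
  out
}
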