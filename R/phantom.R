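VIEW_H <- 1024L
VIEW_W <- 256L

#' Phantom configuration
#'
#' Parameters of the synthetic whole-body scintigraphy phantom. The phantom
#' is schematic (ellipse torso, parametric rib arcs), not anatomical: it
#' reproduces the statistical structure downstream stages depend on --
#' a body silhouette with skeletal baseline uptake, focal metastatic
#' hotspots, benign patterns (collinear rib-injury chains and left/right
#' symmetric joint pairs), optional bladder and injection-leak artifacts,
#' Poisson counting noise, and wide global-intensity variation.
#'
#' @param seed integer; fixing it makes the output bit-reproducible.
#' @param n_metastases number of metastatic hotspots (0 for a negative
#'   patient), each a bright focal Gaussian blob with peak 3-8x the local
#'   background and a tight ground-truth box in each view.
#' @param n_benign number of benign patterns, split randomly between
#'   rib-line injury chains (>= 3 collinear blobs) and intensity-matched
#'   symmetric joint pairs.
#' @param global_gain positive multiplier emulating uptake variability;
#'   `NULL` (default) samples log-uniformly from `[0.25, 4]` so the
#'   normalization stage has real work to do.
#' @param add_bladder render a bright unboxed bladder hotspot.
#' @param add_injection_leak render an unboxed injection-leak hotspot on
#'   the forearm.
#' @param noise `"poisson"` (counting statistics, applied last) or
#'   `"none"` (returns expected counts, useful for oracles).
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(seed = 1L, n_metastases = 3L, n_benign = 2L,
                           global_gain = NULL, add_bladder = TRUE,
                           add_injection_leak = FALSE,
                           noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  stopifnot(n_metastases >= 0, n_benign >= 0,
            is.null(global_gain) || global_gain > 0)
  structure(list(seed = as.integer(seed), n_metastases = as.integer(n_metastases),
                 n_benign = as.integer(n_benign), global_gain = global_gain,
                 add_bladder = isTRUE(add_bladder),
                 add_injection_leak = isTRUE(add_injection_leak),
                 noise = noise),
            class = "phantom_config")
}

# additive Gaussian blob, evaluated only on a local window
add_blob <- function(img, x, y, sigma, peak) {
  r <- ceiling(4 * sigma)
  c0 <- max(1, floor(x - r)); c1 <- min(ncol(img), ceiling(x + r))
  r0 <- max(1, floor(y - r)); r1 <- min(nrow(img), ceiling(y + r))
  cs <- (c0:c1) - 0.5; rs <- (r0:r1) - 0.5
  blob <- peak * exp(-outer((rs - y)^2, (cs - x)^2, "+") / (2 * sigma^2))
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + blob
  img
}

# tight ground-truth box around a Gaussian hotspot (2.2 sigma half-width)
hot_box <- function(x, y, sigma, width = VIEW_W, height = VIEW_H) {
  e <- 2.2 * sigma
  c(x_min = max(0, floor(x - e)), y_min = max(0, floor(y - e)),
    x_max = min(width, ceiling(x + e)), y_max = min(height, ceiling(y + e)))
}

# static anatomy: returns list(common, ap_extra, pa_extra) intensity layers
# in anatomical (anterior) orientation, each VIEW_H x VIEW_W
phantom_anatomy <- function() {
  H <- VIEW_H; W <- VIEW_W
  yy <- matrix(seq_len(H) - 0.5, H, W)
  xx <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  ell <- function(cx, cy, rx, ry) ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
  rect <- function(x0, x1, y0, y1) xx >= x0 & xx < x1 & yy >= y0 & yy < y1

  head <- ell(128, 85, 38, 46)
  neck <- rect(114, 142, 120, 170)
  torso <- ell(128, 400, 95, 265)
  pelvis <- ell(128, 715, 82, 72)
  legs <- rect(92, 116, 760, 970) | rect(140, 164, 760, 970)
  arms <- rect(10, 30, 200, 560) | rect(226, 246, 200, 560)
  silhouette <- head | neck | torso | pelvis | legs | arms

  common <- 3 * silhouette                       # soft tissue baseline
  common <- common + 4 * (head & !ell(128, 85, 30, 38))     # skull rim
  spine <- rect(123, 133, 170, 680)
  # rib arcs: parabolic curves sloping down laterally from the spine
  ribs <- matrix(FALSE, H, W)
  for (k in 1:6) {
    r0 <- 218 + 36 * k
    curve <- r0 + ((xx - 128) / 60)^2 * 18
    ribs <- ribs | (abs(yy - curve) <= 2 & abs(xx - 128) >= 8 & abs(xx - 128) <= 80 & torso)
  }
  common <- common + 7 * ribs
  clav <- abs(yy - 196) <= 3 & abs(xx - 128) >= 18 & abs(xx - 128) <= 72
  common <- common + 6 * clav
  pring <- pelvis & !ell(128, 715, 58, 50)
  common <- common + 8 * pring + 4 * (pelvis & !pring)
  common <- common + 4 * legs + 2 * arms
  # shoulder joints: mild symmetric uptake (baseline, unboxed)
  common <- add_blob(common, 50, 200, 5, 10)
  common <- add_blob(common, 206, 200, 5, 10)

  ap_extra <- 5 * rect(120, 136, 235, 430)       # sternum, anterior only
  ap_extra <- ap_extra + 9 * spine
  pa_extra <- 16 * spine                          # spine brighter posteriorly
  list(common = common, ap_extra = ap_extra, pa_extra = pa_extra,
       silhouette = silhouette)
}

# cached anatomy (deterministic, no RNG involved)
the <- new.env(parent = emptyenv())
get_anatomy <- function() {
  if (is.null(the$anatomy)) the$anatomy <- phantom_anatomy()
  the$anatomy
}

#' Generate one synthetic whole-body scan
#'
#' Renders anterior and posterior views of a schematic body with skeletal
#' baseline uptake, places the configured hotspots, applies the global gain
#' and (optionally) Poisson noise, and returns the assembled native frame
#' together with per-view ground-truth boxes. A hotspot at AP column `c`
#' appears in the PA view mirrored about the view's vertical axis.
#'
#' With `noise = "none"` the pixel grid holds the (fractional) expected
#' counts, so renders at different gains are exact scalar multiples of one
#' another; with `"poisson"` the counts are integer Poisson draws.
#'
#' @param config a [phantom_config()].
#' @return list with elements `scan` (a [raw_scan()]), `ap_boxes` and
#'   `pa_boxes` (box data frames in per-view pixel coordinates, view width
#'   256, height 1024, confidence 1).
#' @export
generate_scan <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, generate_scan_impl(config))
}

generate_scan_impl <- function(config) {
  H <- VIEW_H; W <- VIEW_W
  anat <- get_anatomy()
  ap <- anat$common + anat$ap_extra
  pa <- anat$common + anat$pa_extra   # anatomical orientation; flipped later

  gain <- config$global_gain %||% exp(runif(1, log(0.25), log(4)))

  # --- hotspot placement ------------------------------------------------
  # chest zone (rib cage) for metastases and benign patterns
  zone <- list(x = c(58, 198), y = c(238, 442))
  centers <- matrix(numeric(0), 0, 2)
  min_sep <- 24
  place <- function(x, y) {
    if (nrow(centers) > 0 &&
        any(sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2) < min_sep))
      return(FALSE)
    centers <<- rbind(centers, c(x, y))
    TRUE
  }
  sample_point <- function(xr, yr) {
    for (i in 1:300) {
      x <- runif(1, xr[1], xr[2]); y <- runif(1, yr[1], yr[2])
      if (place(x, y)) return(c(x, y))
    }
    stopf("phantom generation error: could not place hotspot after 300 retries")
  }
  local_bg <- function(x, y) max(ap[ceiling(y), ceiling(x)], 3)

  boxes <- empty_boxes()
  add_hotspot <- function(x, y, sigma, factor, category, boxed = TRUE) {
    peak <- factor * local_bg(x, y)
    ap <<- add_blob(ap, x, y, sigma, peak)
    pa <<- add_blob(pa, x, y, sigma, 0.9 * peak)
    if (boxed) {
      b <- hot_box(x, y, sigma)
      boxes <<- rbind(boxes, data.frame(
        category = category, confidence = 1,
        x_min = b["x_min"], y_min = b["y_min"],
        x_max = b["x_max"], y_max = b["y_max"],
        stringsAsFactors = FALSE))
    }
  }

  if (config$n_metastases > 0) {
    for (i in seq_len(config$n_metastases)) {
      p <- sample_point(zone$x, zone$y)
      add_hotspot(p[1], p[2], runif(1, 1.4, 4.2), runif(1, 3, 8), "metastasis")
    }
  }
  if (config$n_benign > 0) {
    for (i in seq_len(config$n_benign)) {
      if (runif(1) < 0.5) {
        # rib injury chain: >= 3 collinear blobs along a rib arc
        k <- sample(2:5, 1)
        r0 <- 218 + 36 * k
        m <- sample(3:5, 1)
        sp <- runif(1, 15, 19)
        m <- min(m, 1L + floor(56 / sp))   # chain must fit on the rib
        side <- sample(c(-1, 1), 1)
        x0 <- 128 + side * runif(1, 14, 70 - (m - 1) * sp)
        sg <- runif(1, 1.2, 1.8)
        fc <- runif(1, 3, 5)
        for (j in seq_len(m)) {
          x <- x0 + side * (j - 1) * sp
          y <- r0 + ((x - 128) / 60)^2 * 18
          if (place(x, y)) add_hotspot(x, y, sg, fc * runif(1, 0.9, 1.1), "normal_hotspot")
        }
      } else {
        # symmetric joint pair near the shoulders, intensity matched
        d <- runif(1, 55, 86)
        y <- runif(1, 236, 268)
        sg <- runif(1, 1.5, 2.5)
        fc <- runif(1, 3, 6)
        if (place(128 - d, y)) add_hotspot(128 - d, y, sg, fc, "normal_hotspot")
        if (place(128 + d, y)) add_hotspot(128 + d, y, sg, fc, "normal_hotspot")
      }
    }
  }
  if (config$add_bladder) add_hotspot(128, 735, 7, 12, "normal_hotspot", boxed = FALSE)
  if (config$add_injection_leak) add_hotspot(20, 300, 4, 15, "normal_hotspot", boxed = FALSE)

  # --- assemble native frame -------------------------------------------
  ap_view <- gain * ap
  pa_view <- gain * pa[, W:1]          # posterior acquisition is mirrored
  frame <- cbind(ap_view, pa_view)
  if (config$noise == "poisson") {
    frame <- matrix(rpois(length(frame), lambda = frame), nrow = H)
  }
  rownames(boxes) <- NULL
  pa_boxes <- flip_box(boxes, W)
  list(scan = raw_scan(frame, scan_id = sprintf("phantom_%d", config$seed)),
       ap_boxes = boxes, pa_boxes = pa_boxes)
}

# per-scan generation plan shared by on-disk and in-memory cohorts
cohort_plan <- function(n_positive, n_negative, seed) {
  n <- n_positive + n_negative
  withr::with_seed(seed, {
    data.frame(
      index = seq_len(n),
      positive = seq_len(n) <= n_positive,
      scan_seed = (seed + seq_len(n) * 7919L) %% 2147483647L,
      n_metastases = ifelse(seq_len(n) <= n_positive, sample(1:4, n, replace = TRUE), 0L),
      n_benign = sample(0:3, n, replace = TRUE) + ifelse(seq_len(n) <= n_positive, 0L, 1L)
    )
  })
}

#' Generate a synthetic cohort on disk
#'
#' Writes scans (16-bit TIFF), labels (normalized one-line-per-box text in
#' native-frame coordinates, width 512, height 1024, with PA boxes offset
#' by the view width) and a manifest CSV. Exactly `n_positive` entries are
#' flagged `patient_positive`; the rest contain no metastasis boxes.
#' Re-running with the same arguments reproduces the files byte for byte.
#'
#' @param n_positive,n_negative number of positive / negative patients.
#' @param seed cohort seed (controls per-scan seeds and lesion counts).
#' @param out_dir output directory, created if needed.
#' @param cohort cohort tag recorded in the manifest.
#' @param ... overrides passed to [phantom_config()] (e.g. `noise`).
#' @return the manifest data frame (invisibly also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_cohort <- function(n_positive, n_negative, seed, out_dir,
                            cohort = "synthetic", ...) {
  stopifnot(n_positive >= 0, n_negative >= 0)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  plan <- cohort_plan(n_positive, n_negative, seed)
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    cfg <- phantom_config(seed = plan$scan_seed[i],
                          n_metastases = plan$n_metastases[i],
                          n_benign = plan$n_benign[i], ...)
    g <- generate_scan(cfg)
    id <- sprintf("%s_%03d", cohort, i)
    img_file <- paste0(id, ".tif"); lab_file <- paste0(id, ".txt")
    write_scan(g$scan, file.path(out_dir, img_file))
    native <- rbind(g$ap_boxes, shift_boxes(g$pa_boxes, VIEW_W, 0))
    write_labels(native, file.path(out_dir, lab_file),
                 width = 2L * VIEW_W, height = VIEW_H)
    rows[[i]] <- data.frame(image = img_file, label = lab_file,
                            patient_id = id, cohort = cohort,
                            patient_positive = plan$positive[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "dir") <- out_dir
  manifest
}
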