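# Shared fixtures are generated once per session and cached; everything is
# built in code from fixed seeds.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- force(expr)
  fixture_env[[name]]
}

# small mixed cohort for detector/mining unit tests
small_cohort <- function() cached("small", simulate_fused_cohort(8, 4, seed = 11))

# 40-phantom noise-free unit-gain corpus: the "easy" training benchmark
easy_corpus <- function() {
  cached("easy", simulate_fused_cohort(28, 12, seed = 77,
                                       noise = "none", global_gain = 1))
}

# single fused image with one synthetic Gaussian blob on a flat background
blob_image <- function(peak = 200, bg = 20, sigma = 4, h = 120, w = 160,
                       cx = 80, cy = 60, extra = NULL) {
  m <- matrix(bg, h, w)
  add <- function(m, cx, cy, peak, sigma) {
    ys <- seq_len(h) - 0.5; xs <- seq_len(w) - 0.5
    m + peak * exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / (2 * sigma^2))
  }
  m <- add(m, cx, cy, peak, sigma)
  if (!is.null(extra)) for (e in extra) m <- add(m, e[1], e[2], e[3], e[4])
  ch <- array(0L, c(h, w, 3))
  for (k in 1:3) ch[, , k] <- quantize8(m)
  fused_image(ch, source_id = "blob")
}

# pixel-rasterized IoU oracle for integer-coordinate boxes
raster_iou <- function(a, b) {
  xs <- seq(min(a["x_min"], b["x_min"]), max(a["x_max"], b["x_max"]) - 1)
  ys <- seq(min(a["y_min"], b["y_min"]), max(a["y_max"], b["y_max"]) - 1)
  ina <- outer(ys >= a["y_min"] & ys < a["y_max"], xs >= a["x_min"] & xs < a["x_max"], "&")
  inb <- outer(ys >= b["y_min"] & ys < b["y_max"], xs >= b["x_min"] & xs < b["x_max"], "&")
  sum(ina & inb) / sum(ina | inb)
}

rand_box <- function(lim = 60, cat = "metastasis", conf = 1) {
  x0 <- sample(0:(lim - 2), 1); y0 <- sample(0:(lim - 2), 1)
  data.frame(category = cat, confidence = conf,
             x_min = x0, y_min = y0,
             x_max = min(x0 + sample(1:15, 1), lim),
             y_max = min(y0 + sample(1:15, 1), lim),
             stringsAsFactors = FALSE)
}

# exhaustive-assignment oracle: maximum number of category-consistent
# det/gt pairs with IoU >= thr, each box used at most once
brute_match_tp <- function(dets, gts, thr = 0.3) {
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd == 0 || ng == 0) return(0L)
  M <- matrix(0, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng)) {
    if (dets$category[i] == gts$category[j]) {
      v <- iou(dets[i, ], gts[j, ])
      if (v >= thr) M[i, j] <- 1
    }
  }
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (nd - i + 1) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    for (j in which(M[i, ] == 1 & !used)) {
      used[j] <- TRUE
      recurse(i + 1, used, count + 1L)
      used[j] <- FALSE
    }
    recurse(i + 1, used, count)
  }
  recurse(1L, rep(FALSE, ng), 0L)
  best
}
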