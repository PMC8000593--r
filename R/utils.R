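#' Round half away from zero
#'
#' Quantization convention used everywhere intensities are discretized:
#' ties round away from zero (so 10.5 becomes 11, -10.5 becomes -11),
#' unlike base R's banker's rounding.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape with integral values (still numeric).
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)

# clip to [0,255], round half away from zero, store as integer (dims kept)
quantize8 <- function(x) {
  q <- round_half_away(clip8(x))
  storage.mode(q) <- "integer"
  q
}

#' Render a value at two decimals, rounding half away from zero
#'
#' Formatting rule used for report tables (e.g. 0.715 renders as "0.72").
#' `NA` renders as "n/a".
#'
#' @param x numeric vector.
#' @return character vector.
#' @export
render2 <- function(x) {
  ifelse(is.na(x), "n/a",
         sprintf("%.2f", sign(x) * floor(abs(x) * 100 + 0.5) / 100))
}

# cheap deterministic digest of an R object (provenance only, not crypto)
text_digest <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  v <- utf8ToInt(txt)
  h <- 0
  for (b in v) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
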