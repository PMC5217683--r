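# Internal helpers shared across stages.

# Evaluate `code` under a fixed RNG state without touching the caller's seed.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Fan a single pipeline seed out to per-stage sub-seeds by fixed offsets, so
# each stage is individually reproducible.  Offsets stay small so that the
# derived seeds remain valid 32-bit integers for small user seeds.
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, shading = 211L, correct = 307L, segment = 401L,
    gate = 503L, report = 601L, qpcr = 701L
  )
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown pipeline stage '", stage, "'"), class = "platetalk_config_error")
  }
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    abort(
      sprintf("`%s` must be a finite scalar in %s%s, %s%s", name,
              if (strict_lower) "(" else "[", format(lower),
              format(upper), if (strict_upper) ")" else "]"),
      class = "platetalk_invalid_parameter"
    )
  }
  invisible(x)
}

# Separable Gaussian smoothing with replicate-boundary handling, used for
# shading-surface estimation.  Delegates to EBImage's 2-D convolution.
smooth_gaussian <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  size <- min(size, 2L * (min(dim(mat)) %/% 2L) - 1L)
  if (size < 3L) return(mat)
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  out <- EBImage::filter2(EBImage::Image(mat), brush, boundary = "replicate")
  matrix(EBImage::imageData(out), nrow = nrow(mat))
}

population_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Unscaled median absolute deviation: median(|x - median(x)|), no 1.4826
# consistency factor (the windows are stated in raw MAD units).
mad_raw <- function(x) {
  median(abs(x - median(x)))
}
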