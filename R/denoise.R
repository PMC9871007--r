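# Orthogonal periodized discrete wavelet transform and BayesShrink
# soft-threshold denoising. Filters are the standard symlet-8
# coefficients; periodization keeps subband lengths at n/2 (odd lengths
# are extended by repeating the final sample).

WAVELET_FILTERS <- list(
  sym8 = list(
    rec_lo = c(0.0018899503327594609, -0.0003029205147213668,
               -0.014952258337048231, 0.0038087520138906151,
               0.049137179673607506, -0.027219029917056003,
               -0.051945838107709037, 0.3644418948353314,
               0.77718575170052351, 0.48135965125837221,
               -0.061273359067658524, -0.14329423835080971,
               0.0076074873249176054, 0.031695087811492981,
               -0.00054213233179114812, -0.0033824159510061256)),
  db4 = list(
    rec_lo = c(0.23037781330889651, 0.71484657055291567,
               0.63088076792985892, -0.027983769416859854,
               -0.18703481171909309, 0.030841381835560764,
               0.032883011666885197, -0.010597401785069032)))

waveletFilterPair <- function(name) {
  stopIf(!name %in% names(WAVELET_FILTERS),
         "unsupported wavelet '%s' (available: %s)", name,
         paste(names(WAVELET_FILTERS), collapse = ", "))
  g <- WAVELET_FILTERS[[name]]$rec_lo
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * rev(g)
  list(g = g, h = h, L = L)
}

# One analysis step under circular extension; n must be even.
dwtStep <- function(x, flt) {
  n <- length(x)
  n2 <- n %/% 2L
  a <- numeric(n2); d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in 0:(flt$L - 1L)) {
    idx <- (base + m) %% n + 1L
    a <- a + flt$g[m + 1L] * x[idx]
    d <- d + flt$h[m + 1L] * x[idx]
  }
  list(a = a, d = d)
}

idwtStep <- function(a, d, flt) {
  n2 <- length(a)
  n <- 2L * n2
  x <- numeric(n)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in 0:(flt$L - 1L)) {
    idx <- (base + m) %% n + 1L
    x[idx] <- x[idx] + flt$g[m + 1L] * a + flt$h[m + 1L] * d
  }
  x
}

# Multilevel periodized DWT. Returns approximation, detail subbands
# (finest first) and the per-level original lengths for reconstruction.
dwtDecompose <- function(x, wavelet = "sym8", levels) {
  flt <- waveletFilterPair(wavelet)
  stopIf(levels < 1, "levels must be >= 1")
  stopIf(length(x) < 2^levels,
         "signal of length %d too short for %d levels", length(x), levels)
  details <- vector("list", levels)
  lens <- integer(levels)
  a <- x
  for (l in seq_len(levels)) {
    lens[l] <- length(a)
    if (length(a) %% 2L == 1L) a <- c(a, a[length(a)])
    st <- dwtStep(a, flt)
    details[[l]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, lens = lens, wavelet = wavelet)
}

dwtReconstruct <- function(dec) {
  flt <- waveletFilterPair(dec$wavelet)
  a <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    a <- idwtStep(a, dec$details[[l]], flt)
    a <- a[seq_len(dec$lens[l])]
  }
  a
}

#' Denoising configuration
#'
#' @param wavelet wavelet family; "sym8" (default) or "db4".
#' @param levels decomposition depth, or "auto" for
#'   \code{floor(log2(n)) - 6} capped to [1, 6].
#' @param thresholdMode only "soft" is supported.
#' @return a list of class \code{"DenoiseConfig"}.
#' @export
denoiseConfig <- function(wavelet = "sym8", levels = "auto",
                          thresholdMode = "soft") {
  waveletFilterPair(wavelet)
  stopIf(!identical(thresholdMode, "soft"),
         "only soft thresholding is supported")
  if (!identical(levels, "auto"))
    stopIf(!is.numeric(levels) || levels < 1, "levels must be >= 1 or 'auto'")
  structure(list(wavelet = wavelet, levels = levels,
                 thresholdMode = thresholdMode),
            class = "DenoiseConfig")
}

autoLevels <- function(n) max(1L, min(6L, floor(log2(n)) - 6L))

#' BayesShrink wavelet denoising
#'
#' Multilevel wavelet shrinkage with the BayesShrink data-driven
#' threshold: the noise scale is estimated from the finest detail
#' subband as \code{median(|d1|)/0.6745}; each detail subband is
#' soft-thresholded at \eqn{\sigma_n^2 / \sigma_x} where
#' \eqn{\sigma_x = \sqrt{\max(\sigma_y^2 - \sigma_n^2, 0)}} is the
#' estimated noise-free signal scale in that subband (the whole subband
#' is zeroed when \eqn{\sigma_x = 0}). Approximation coefficients are
#' left untouched; output length equals input length.
#'
#' @param signal numeric vector.
#' @param config a [denoiseConfig()].
#' @return denoised numeric vector of the same length.
#' @examples
#' t <- seq(0, 1, length.out = 8192)
#' clean <- sin(2 * pi * 300 * t)
#' noisy <- clean + rnorm(length(t), sd = 0.5)
#' out <- denoise(noisy)
#' @export
denoise <- function(signal, config = denoiseConfig()) {
  stopIf(length(signal) < 2, "signal too short to denoise")
  levels <- if (identical(config$levels, "auto"))
    autoLevels(length(signal)) else as.integer(config$levels)
  stopIf(length(signal) < 2^levels,
         "signal of length %d too short for %d decomposition levels",
         length(signal), levels)
  dec <- dwtDecompose(signal, config$wavelet, levels)
  sigmaN <- stats::median(abs(dec$details[[1]])) / 0.6745
  for (l in seq_along(dec$details)) {
    d <- dec$details[[l]]
    sigmaY2 <- mean(d^2)
    sigmaX <- sqrt(max(sigmaY2 - sigmaN^2, 0))
    thr <- if (sigmaX > 0) sigmaN^2 / sigmaX else
      if (length(d)) max(abs(d)) else 0
    dec$details[[l]] <- sign(d) * pmax(abs(d) - thr, 0)
  }
  dwtReconstruct(dec)
}
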