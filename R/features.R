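#' Feature-extraction configuration
#'
#' Defaults follow the study pipeline: 40 MFCCs from an FFT window of
#' 660 samples, hop length 512 samples and Hann windowing, over a
#' 128-band mel filterbank.
#'
#' @param nMfcc number of cepstral coefficients (default 40).
#' @param fftLength FFT window length in samples (default 660).
#' @param hopLength hop between frames in samples (default 512).
#' @param nMels mel filterbank size (default 128); must be >= nMfcc.
#' @param centerPadding center frames by reflect-padding
#'   \code{fftLength/2} samples at each end (default TRUE); the frame
#'   count is then \code{floor(n / hopLength) + 1}.
#' @param amin floor applied to mel power before taking dB (default
#'   1e-10), making silent-input behavior deterministic.
#' @return a list of class \code{"FeatureConfig"}.
#' @export
featureConfig <- function(nMfcc = 40, fftLength = 660, hopLength = 512,
                          nMels = 128, centerPadding = TRUE,
                          amin = 1e-10) {
  stopIf(fftLength <= 0 || hopLength <= 0,
         "fftLength and hopLength must be positive")
  stopIf(nMfcc > nMels, "nMfcc must not exceed nMels")
  stopIf(amin <= 0, "amin must be positive")
  structure(list(nMfcc = as.integer(nMfcc),
                 fftLength = as.integer(fftLength),
                 hopLength = as.integer(hopLength),
                 nMels = as.integer(nMels),
                 centerPadding = isTRUE(centerPadding), amin = amin),
            class = "FeatureConfig")
}

# Slaney-style mel scale (linear below 1 kHz, logarithmic above).
hzToMel <- function(f) {
  ifelse(f < 1000, 3 * f / 200,
         15 + 27 * log(pmax(f, 1000) / 1000) / log(6.4))
}
melToHz <- function(m) {
  ifelse(m < 15, 200 * m / 3, 1000 * exp(log(6.4) * (m - 15) / 27))
}

# Triangular mel filterbank (nMels x nBins) with Slaney area
# normalization; bin frequencies for an fftLength-point FFT at sr Hz.
melFilterbank <- function(sr, fftLength, nMels, fmin = 0, fmax = sr / 2) {
  nBins <- fftLength %/% 2L + 1L
  binHz <- (seq_len(nBins) - 1) * sr / fftLength
  pts <- melToHz(seq(hzToMel(fmin), hzToMel(fmax), length.out = nMels + 2))
  fb <- matrix(0, nMels, nBins)
  for (m in seq_len(nMels)) {
    lo <- pts[m]; ctr <- pts[m + 1]; hi <- pts[m + 2]
    up <- (binHz - lo) / (ctr - lo)
    down <- (hi - binHz) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)
  }
  attr(fb, "centerHz") <- pts[2:(nMels + 1)]
  fb
}

# Short-time power spectrum: (fftLength/2 + 1) x nFrames matrix.
stftPower <- function(x, config) {
  nfft <- config$fftLength
  hop <- config$hopLength
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / nfft)  # periodic Hann
  n <- length(x)
  if (config$centerPadding) {
    pad <- nfft %/% 2L
    x <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
    nFrames <- floor(n / hop) + 1L
    starts <- (seq_len(nFrames) - 1L) * hop
  } else {
    stopIf(n < nfft, "signal shorter than fftLength without padding")
    nFrames <- 1L + (n - nfft) %/% hop
    starts <- (seq_len(nFrames) - 1L) * hop
  }
  idx <- outer(seq_len(nfft), starts, `+`)
  frames <- matrix(x[idx], nrow = nfft) * win
  S <- stats::mvfft(frames)[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  Mod(S)^2
}

#' Mel spectrogram of a fixed window
#'
#' Power spectrogram (Hann window, configured FFT/hop lengths) mapped
#' through a Slaney-normalized triangular mel filterbank.
#'
#' @param window a [FixedWindow-class] (or numeric vector with
#'   \code{sampleRate} given).
#' @param config a [featureConfig()].
#' @param sampleRate required when \code{window} is a bare vector.
#' @return non-negative nMels x nFrames matrix; mel-band center
#'   frequencies in Hz are attached as attribute \code{"centerHz"},
#'   frame times in seconds as \code{"time"}.
#' @export
melSpectrogram <- function(window, config = featureConfig(),
                           sampleRate = NULL) {
  if (is(window, "FixedWindow")) {
    sampleRate <- sampleRate(window)
    x <- samples(window)
  } else {
    stopIf(is.null(sampleRate), "sampleRate required for numeric input")
    x <- as.numeric(window)
  }
  P <- stftPower(x, config)
  fb <- melFilterbank(sampleRate, config$fftLength, config$nMels)
  M <- fb %*% P
  attr(M, "centerHz") <- attr(fb, "centerHz")
  attr(M, "time") <- (seq_len(ncol(M)) - 1) * config$hopLength / sampleRate
  M
}

# Orthonormal DCT-II matrix (nOut x nIn).
dctMatrix <- function(nOut, nIn) {
  k <- seq_len(nOut) - 1
  m <- seq_len(nIn) - 1
  D <- cos(pi * outer(k, m + 0.5) / nIn) * sqrt(2 / nIn)
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' MFCC matrix of a fixed window
#'
#' Log (dB) mel power spectrogram followed by an orthonormal DCT-II
#' along the mel axis, keeping the first \code{nMfcc} coefficients.
#'
#' @inheritParams melSpectrogram
#' @return nMfcc x nFrames matrix of class \code{"MFCCMatrix"} (plain
#'   matrix with the config attached as attribute \code{"config"}).
#' @examples
#' w <- preprocessClip(synthClip("normal", synthConfig(), seed = 1))
#' dim(mfcc(w))  # 40 x 517
#' @export
mfcc <- function(window, config = featureConfig(), sampleRate = NULL) {
  M <- melSpectrogram(window, config, sampleRate)
  Sdb <- 10 * log10(pmax(M, config$amin))
  C <- dctMatrix(config$nMfcc, config$nMels) %*% Sdb
  attr(C, "config") <- config
  attr(C, "time") <- attr(M, "time")
  class(C) <- c("MFCCMatrix", class(C))
  C
}

#' Aggregate an MFCC matrix into a fixed-length feature vector
#'
#' @param m an MFCC matrix (coefficients x frames).
#' @param mode "mean_std" (per-coefficient temporal mean then SD,
#'   concatenated; the default 2 x nMfcc = 80 dimensions), "mean_only",
#'   or "flatten" (row-major).
#' @return named numeric vector.
#' @examples
#' aggregateFeatures(matrix(1:6, 2, 3, byrow = TRUE), "flatten")
#' @export
aggregateFeatures <- function(m, mode = c("mean_std", "mean_only",
                                          "flatten")) {
  mode <- match.arg(mode)
  m <- unclass(m)
  nc <- nrow(m)
  switch(mode,
    mean_std = {
      mu <- rowMeans(m)
      sdv <- sqrt(rowMeans((m - mu)^2))
      stats::setNames(c(mu, sdv),
                      c(sprintf("mfcc_mean_%02d", seq_len(nc) - 1),
                        sprintf("mfcc_sd_%02d", seq_len(nc) - 1)))
    },
    mean_only = stats::setNames(rowMeans(m),
                                sprintf("mfcc_mean_%02d", seq_len(nc) - 1)),
    flatten = stats::setNames(as.vector(t(m)),
                              sprintf("mfcc_%02d_f%04d",
                                      rep(seq_len(nc) - 1, each = ncol(m)),
                                      rep(seq_len(ncol(m)), nc))))
}

#' Featurize a corpus of clips
#'
#' Runs each clip through denoise -> 6-s window -> MFCC -> aggregation
#' and returns one feature row per clip with its label.
#'
#' @param x a list of [AudioClip-class] objects, or a manifest
#'   data.frame with \code{path} and \code{label} columns (WAVs are read
#'   one at a time).
#' @param featureCfg a [featureConfig()].
#' @param denoiseCfg a [denoiseConfig()].
#' @param mode aggregation mode; see [aggregateFeatures()].
#' @return data.frame with columns clip_id, label, then the feature
#'   columns.
#' @export
featurizeCorpus <- function(x, featureCfg = featureConfig(),
                            denoiseCfg = denoiseConfig(),
                            mode = "mean_std") {
  if (is.data.frame(x)) {
    stopIf(nrow(x) > 0 && !"path" %in% names(x),
           "manifest must have a path column to featurize from disk")
    clips <- NULL
    n <- nrow(x)
  } else {
    clips <- x
    n <- length(clips)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    clip <- if (is.null(clips)) {
      if (!file.exists(x$path[i]))
        stop(sprintf("cannot read clip '%s': file '%s' missing",
                     x$clip_id[i], x$path[i]), call. = FALSE)
      readWav(x$path[i], clipId = x$clip_id[i], label = x$label[i])
    } else clips[[i]]
    w <- preprocessClip(clip, denoiseCfg)
    v <- aggregateFeatures(mfcc(w, featureCfg), mode)
    rows[[i]] <- c(list(clip_id = clipId(clip), label = clipLabel(clip)),
                   as.list(v))
  }
  if (n == 0L) {
    hdr <- aggregateFeatures(matrix(0, featureCfg$nMfcc, 2), mode)
    out <- as.data.frame(c(list(clip_id = character(0),
                                label = character(0)),
                           lapply(hdr, function(.) numeric(0))))
    return(out)
  }
  do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
}

featureMatrix <- function(featureTable) {
  as.matrix(featureTable[, setdiff(names(featureTable),
                                   c("clip_id", "label")), drop = FALSE])
}
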