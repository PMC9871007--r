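# Shared fixtures. Unit tests that only exercise shape/contract logic
# use a reduced 8 kHz sampling rate to stay fast; anything asserting
# an acoustic or statistical target uses the full 44.1 kHz defaults.

fastSynthConfig <- function(...) synthConfig(sampleRate = 8000, ...)

# Frequency (Hz) of the global FFT-magnitude maximum, zero-padded to 1 s.
peakFrequency <- function(w, sr) {
  n <- sr
  if (length(w) < n) w <- c(w, numeric(n - length(w)))
  sp <- abs(stats::fft(w[seq_len(n)]))[seq_len(n %/% 2)]
  (which.max(sp) - 1) * sr / n
}

# Mean power spectral density in [lo, hi] Hz via the raw periodogram.
bandPower <- function(x, sr, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * sr / n
  p <- abs(stats::fft(x))^2
  mean(p[f >= lo & f <= hi])
}

# Welch-averaged PSD (Hann, 50% overlap).
welchPSD <- function(x, sr, seg = 8192) {
  hop <- seg %/% 2
  starts <- seq(1, length(x) - seg + 1, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(seg - 1)) / seg)
  p <- 0
  for (s in starts) p <- p + abs(stats::fft(x[s:(s + seg - 1)] * win))^2
  list(f = (0:(seg %/% 2 - 1)) * sr / seg,
       p = (p / length(starts))[seq_len(seg %/% 2)])
}

# -3 dB corner of a smoothed PSD relative to its sub-100-Hz plateau.
psdCorner <- function(x, sr, bandWidth = 10) {
  w <- welchPSD(x, sr)
  band <- floor(w$f / bandWidth)
  ps <- tapply(w$p, band, mean)
  fs <- tapply(w$f, band, mean)
  plateau <- mean(ps[fs < 100])
  idx <- which(10 * log10(ps / plateau) < -3 & fs > 10)
  fs[[min(idx)]]
}

# Stub "SVM" members so voting and CV mechanics can be tested against
# hand-set outcomes. A member with a fixed `prob` always emits that
# positive-class probability; with prob = NULL it emits the first
# feature column as the probability (a "memorizing" member when that
# column encodes the truth).
stubMember <- function(prob = NULL, positive = "pos", negative = "neg") {
  structure(list(prob = prob, positive = positive, negative = negative),
            class = "stubsvm")
}

predict.stubsvm <- function(object, newdata, probability = TRUE, ...) {
  n <- nrow(as.matrix(newdata))
  p <- if (is.null(object$prob))
    pmin(1, pmax(0, as.matrix(newdata)[, 1]))
  else rep(object$prob, n)
  P <- cbind(p, 1 - p)
  colnames(P) <- c(object$positive, object$negative)
  out <- factor(ifelse(p > 0.5, object$positive, object$negative),
                levels = c(object$negative, object$positive))
  attr(out, "probabilities") <- P
  out
}
registerS3method("predict", "stubsvm", predict.stubsvm,
                 envir = asNamespace("stats"))

stubEnsemble <- function(probs, positive = "wheezing",
                         negative = "normal", featureDim = 1L) {
  members <- lapply(probs, function(p)
    stubMember(if (is.na(p)) NULL else p, positive, negative))
  new("SVMEnsemble", members = members,
      taskId = "normal_vs_wheezing", positiveClass = positive,
      classLevels = c(negative, positive),
      memberSeeds = as.numeric(seq_along(members)),
      featureDim = as.integer(featureDim), fingerprint = "stub")
}

featureMatrixForTest <- function(feat)
  as.matrix(feat[, setdiff(names(feat), c("clip_id", "label"))])
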