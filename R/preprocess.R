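#' Fixed six-second windowing by the duplicate-and-crop rule
#'
#' Clips longer than 6 s keep only their first 6 s; shorter clips are
#' concatenated with whole copies of themselves until longer than 6 s
#' and then cropped at 6 s. The result always has exactly
#' \code{round(6 * sampleRate)} samples, and the operation is idempotent
#' on its own output.
#'
#' @param signal non-empty numeric vector.
#' @param sampleRate Hz.
#' @return numeric vector of length \code{round(6 * sampleRate)}.
#' @examples
#' length(window6s(rnorm(1000), 1000))  # 6000
#' @export
window6s <- function(signal, sampleRate) {
  stopIf(length(signal) == 0L, "signal must be non-empty")
  stopIf(sampleRate <= 0, "sampleRate must be positive")
  target <- round(6 * sampleRate)
  if (length(signal) >= target) return(signal[seq_len(target)])
  reps <- ceiling(target / length(signal))
  rep(signal, reps)[seq_len(target)]
}

#' Denoise and window a clip
#'
#' Applies BayesShrink wavelet denoising to the full clip, then the
#' duplicate-and-crop 6-s rule, then peak normalization (so downstream
#' features are gain-invariant). Label and clip id are propagated.
#'
#' @param clip an [AudioClip-class].
#' @param config a [denoiseConfig()].
#' @param normalize peak-normalize the window (default TRUE).
#' @return a [FixedWindow-class].
#' @examples
#' w <- preprocessClip(synthClip("normal", synthConfig(), seed = 1))
#' length(samples(w)) == round(6 * sampleRate(w))
#' @export
preprocessClip <- function(clip, config = denoiseConfig(),
                           normalize = TRUE) {
  stopIf(!is(clip, "AudioClip"), "clip must be an AudioClip")
  x <- denoise(samples(clip), config)
  x <- window6s(x, sampleRate(clip))
  if (normalize) {
    pk <- max(abs(x))
    if (pk > 0) x <- x / pk
  }
  new("FixedWindow", samples = x, sampleRate = sampleRate(clip),
      sourceClipId = clipId(clip), label = clipLabel(clip))
}
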