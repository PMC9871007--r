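#' @import methods
NULL

LUNG_LABELS <- c("normal", "crackles", "wheezing")
TASK_IDS <- c("normal_vs_abnormal", "crackles_vs_wheezing",
              "normal_vs_crackles", "normal_vs_wheezing")

#' AudioClip: a labeled mono auscultation waveform
#'
#' The unit of corpus statistics: a short recording (one or two breath
#' cycles) with amplitude in [-1, 1], its sampling rate, a class label,
#' and generation metadata when the clip is synthetic.
#'
#' @slot samples numeric vector of amplitudes in [-1, 1].
#' @slot sampleRate sampling rate in Hz.
#' @slot label one of "normal", "crackles", "wheezing", or "unlabeled".
#' @slot breath list with respiratoryRate (breaths/min),
#'   inspirationFraction in (0,1), and cycleCount (1 or 2); may be empty
#'   for recorded clips.
#' @slot events list of event descriptors (kind, centerFrequency,
#'   duration, onset, amplitude) for synthetic clips.
#' @slot heartSound logical; whether heart sounds were mixed in.
#' @slot clipId character identifier.
#' @export
setClass("AudioClip",
  representation(samples = "numeric", sampleRate = "numeric",
                 label = "character", breath = "list", events = "list",
                 heartSound = "logical", clipId = "character"),
  prototype(breath = list(), events = list(), heartSound = FALSE,
            label = "unlabeled", clipId = ""))

setValidity("AudioClip", function(object) {
  msg <- character()
  if (length(object@samples) < 1L)
    msg <- c(msg, "samples must be non-empty")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  else if (max(abs(object@samples)) > 1 + 1e-9)
    msg <- c(msg, "samples must lie in [-1, 1]")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a positive scalar")
  if (!object@label %in% c(LUNG_LABELS, "unlabeled"))
    msg <- c(msg, "label must be normal/crackles/wheezing/unlabeled")
  kinds <- vapply(object@events, function(e) e$kind, character(1))
  if (object@label == "normal" && length(object@events) > 0L)
    msg <- c(msg, "normal clips must carry no adventitious events")
  # event metadata exists only for synthetic clips; recorded clips have
  # an empty event list whatever their label
  if (length(object@events) > 0L) {
    if (object@label == "crackles" &&
        !all(kinds %in% c("fine_crackle", "coarse_crackle")))
      msg <- c(msg, "crackle clips may only carry crackle events")
    if (object@label == "wheezing" && !any(kinds == "wheeze"))
      msg <- c(msg, "wheezing clips must carry at least one wheeze event")
  }
  if (length(msg)) msg else TRUE
})

#' FixedWindow: an exactly six-second analysis window
#'
#' Produced from an [AudioClip-class] by the duplicate-and-crop rule:
#' clips longer than 6 s are truncated to their first 6 s, shorter clips
#' are tiled (whole-copy concatenation) until longer than 6 s and then
#' cropped. Length is exactly \code{round(6 * sampleRate)} samples.
#'
#' @slot samples numeric amplitude vector, length 6 x sampleRate.
#' @slot sampleRate sampling rate in Hz.
#' @slot sourceClipId identifier of the originating clip.
#' @slot label class label carried through from the clip.
#' @export
setClass("FixedWindow",
  representation(samples = "numeric", sampleRate = "numeric",
                 sourceClipId = "character", label = "character"),
  prototype(sourceClipId = "", label = "unlabeled"))

setValidity("FixedWindow", function(object) {
  n <- round(6 * object@sampleRate)
  if (length(object@samples) != n)
    return(sprintf("samples must have length %d (6 s at %g Hz), got %d",
                   n, object@sampleRate, length(object@samples)))
  if (!all(is.finite(object@samples)))
    return("samples must be finite")
  TRUE
})

#' SVMEnsemble: a majority-voting ensemble of RBF-kernel SVMs
#'
#' A set of probabilistic binary SVM classifiers trained on seeded
#' bootstrap resamples for one binary task, combined by majority vote
#' with a mean-probability tie-break.
#'
#' @slot members list of fitted \code{e1071::svm} models.
#' @slot taskId one of the four binary task identifiers.
#' @slot positiveClass label treated as the positive class.
#' @slot classLevels the two binary class labels (negative, positive).
#' @slot memberSeeds integer seeds used for the bootstrap resamples.
#' @slot featureDim number of feature columns seen at training.
#' @slot fingerprint character hash of the training data and seeds.
#' @export
setClass("SVMEnsemble",
  representation(members = "list", taskId = "character",
                 positiveClass = "character", classLevels = "character",
                 memberSeeds = "numeric", featureDim = "integer",
                 fingerprint = "character"))

setValidity("SVMEnsemble", function(object) {
  msg <- character()
  if (length(object@members) < 1L)
    msg <- c(msg, "ensemble must have at least one member")
  if (length(object@members) != length(object@memberSeeds))
    msg <- c(msg, "one seed per member required")
  if (!object@taskId %in% TASK_IDS)
    msg <- c(msg, "unknown taskId")
  if (length(object@classLevels) != 2L)
    msg <- c(msg, "classLevels must have length 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AudioClip", function(object) {
  cat(sprintf("AudioClip '%s': %.3f s @ %g Hz, label=%s, %d event(s)%s\n",
              object@clipId,
              length(object@samples) / object@sampleRate,
              object@sampleRate, object@label, length(object@events),
              if (object@heartSound) ", heart sounds" else ""))
})

setMethod("show", "FixedWindow", function(object) {
  cat(sprintf("FixedWindow from '%s': 6 s @ %g Hz, label=%s\n",
              object@sourceClipId, object@sampleRate, object@label))
})

setMethod("show", "SVMEnsemble", function(object) {
  cat(sprintf("SVMEnsemble: %d RBF-SVM member(s), task=%s, positive=%s, d=%d\n",
              length(object@members), object@taskId, object@positiveClass,
              object@featureDim))
})
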