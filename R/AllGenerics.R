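#' Accessors for audio containers and ensembles
#'
#' @param x an [AudioClip-class], [FixedWindow-class] or
#'   [SVMEnsemble-class] object.
#' @return \code{samples}: numeric amplitude vector. \code{sampleRate}:
#'   Hz. \code{clipLabel}: class label. \code{clipId}: identifier.
#'   \code{clipDuration}: seconds. \code{clipEvents}: list of event
#'   descriptors. \code{nMembers}: member count. \code{taskId}: task
#'   identifier.
#' @examples
#' clip <- synthClip("normal", synthConfig(), seed = 1)
#' sampleRate(clip)
#' clipDuration(clip)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("clipLabel", function(x) standardGeneric("clipLabel"))
#' @rdname accessors
#' @export
setGeneric("clipId", function(x) standardGeneric("clipId"))
#' @rdname accessors
#' @export
setGeneric("clipDuration", function(x) standardGeneric("clipDuration"))
#' @rdname accessors
#' @export
setGeneric("clipEvents", function(x) standardGeneric("clipEvents"))
#' @rdname accessors
#' @export
setGeneric("nMembers", function(x) standardGeneric("nMembers"))
#' @rdname accessors
#' @export
setGeneric("taskId", function(x) standardGeneric("taskId"))

#' @rdname accessors
#' @export
setMethod("samples", "AudioClip", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("samples", "FixedWindow", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("sampleRate", "AudioClip", function(x) x@sampleRate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "FixedWindow", function(x) x@sampleRate)
#' @rdname accessors
#' @export
setMethod("clipLabel", "AudioClip", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("clipLabel", "FixedWindow", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("clipId", "AudioClip", function(x) x@clipId)
#' @rdname accessors
#' @export
setMethod("clipId", "FixedWindow", function(x) x@sourceClipId)
#' @rdname accessors
#' @export
setMethod("clipDuration", "AudioClip",
          function(x) length(x@samples) / x@sampleRate)
#' @rdname accessors
#' @export
setMethod("clipEvents", "AudioClip", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("nMembers", "SVMEnsemble", function(x) length(x@members))
#' @rdname accessors
#' @export
setMethod("taskId", "SVMEnsemble", function(x) x@taskId)
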