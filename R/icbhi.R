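#' Parse an ICBHI-2017-style annotation file
#'
#' Whitespace- or tab-delimited rows of four numeric fields: cycle
#' start (s), cycle end (s), crackle flag (0/1), wheeze flag (0/1).
#' Rows are returned sorted by cycle start; they must be non-overlapping
#' and each start must precede its end.
#'
#' @param path annotation text file.
#' @return data.frame with columns cycleStart, cycleEnd, crackleFlag,
#'   wheezeFlag; the recording id (file name without extension) is
#'   attached as attribute \code{"recordingId"}.
#' @export
parseICBHIAnnotation <- function(path) {
  stopIf(!file.exists(path), "annotation file not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) != 4L)
      stop(sprintf("parse error in '%s' at line %d: expected 4 fields, got %d",
                   path, i, length(f)), call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop(sprintf("parse error in '%s' at line %d: non-numeric field",
                   path, i), call. = FALSE)
    v
  })
  ann <- if (length(rows)) {
    m <- do.call(rbind, rows)
    data.frame(cycleStart = m[, 1], cycleEnd = m[, 2],
               crackleFlag = as.integer(m[, 3]),
               wheezeFlag = as.integer(m[, 4]))
  } else {
    data.frame(cycleStart = numeric(0), cycleEnd = numeric(0),
               crackleFlag = integer(0), wheezeFlag = integer(0))
  }
  stopIf(!all(ann$crackleFlag %in% 0:1 & ann$wheezeFlag %in% 0:1),
         "flags in '%s' must be 0 or 1", path)
  ann <- ann[order(ann$cycleStart), , drop = FALSE]
  rownames(ann) <- NULL
  stopIf(any(ann$cycleStart >= ann$cycleEnd),
         "'%s': every cycle start must precede its end", path)
  if (nrow(ann) > 1L)
    stopIf(any(ann$cycleStart[-1] < ann$cycleEnd[-nrow(ann)] - 1e-9),
           "'%s': cycles overlap after sorting", path)
  attr(ann, "recordingId") <- sub("\\.[^.]*$", "", basename(path))
  ann
}

#' Map ICBHI cycle flags to a class label
#'
#' (0,0) is normal, (1,0) crackles, (0,1) wheezing; (1,1) is returned
#' as "both" and is excluded from the three-class tasks.
#'
#' @param crackleFlag,wheezeFlag 0/1 vectors.
#' @return character vector of labels.
#' @examples
#' icbhiCycleToLabel(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' @export
icbhiCycleToLabel <- function(crackleFlag, wheezeFlag) {
  stopIf(!all(crackleFlag %in% 0:1) || !all(wheezeFlag %in% 0:1),
         "flags must be 0 or 1")
  ifelse(crackleFlag == 0 & wheezeFlag == 0, "normal",
  ifelse(crackleFlag == 1 & wheezeFlag == 0, "crackles",
  ifelse(crackleFlag == 0 & wheezeFlag == 1, "wheezing", "both")))
}

#' Extract labeled breath-cycle clips from a recording
#'
#' Slices the recording at each annotation row using the half-open
#' convention [start, end) in seconds, converted by
#' \code{floor(start * sr)} / \code{floor(end * sr)}, and labels the
#' slices via [icbhiCycleToLabel()].
#'
#' @param recording an [AudioClip-class] (label may be "unlabeled").
#' @param ann a [parseICBHIAnnotation()] data.frame.
#' @param excludeBoth drop cycles flagged as both crackle and wheeze
#'   (default TRUE).
#' @return list of labeled [AudioClip-class] objects.
#' @export
extractCycles <- function(recording, ann, excludeBoth = TRUE) {
  stopIf(!is(recording, "AudioClip"), "recording must be an AudioClip")
  sr <- sampleRate(recording)
  dur <- clipDuration(recording)
  bad <- which(ann$cycleEnd > dur + 1e-9)
  stopIf(length(bad) > 0,
         "annotation row(s) %s exceed the %.2f-s recording",
         paste(bad, collapse = ", "), dur)
  labels <- icbhiCycleToLabel(ann$crackleFlag, ann$wheezeFlag)
  out <- list()
  recId <- attr(ann, "recordingId")
  if (is.null(recId)) recId <- clipId(recording)
  for (i in seq_len(nrow(ann))) {
    if (excludeBoth && labels[i] == "both") next
    i0 <- floor(ann$cycleStart[i] * sr) + 1
    i1 <- floor(ann$cycleEnd[i] * sr)
    out[[length(out) + 1L]] <- new(
      "AudioClip", samples = samples(recording)[i0:i1],
      sampleRate = sr, label = labels[i],
      clipId = sprintf("%s_cycle%02d", recId, i))
  }
  out
}

#' Class composition of ICBHI annotations
#'
#' @param anns one annotation data.frame or a list of them.
#' @return named integer vector of cycle counts over
#'   normal/wheezing/crackles/both.
#' @export
icbhiClassCounts <- function(anns) {
  if (is.data.frame(anns)) anns <- list(anns)
  labels <- unlist(lapply(anns, function(a)
    icbhiCycleToLabel(a$crackleFlag, a$wheezeFlag)))
  vapply(c("normal", "wheezing", "crackles", "both"),
         function(l) sum(labels == l), integer(1))
}
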