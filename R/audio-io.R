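#' Read a WAV file into an AudioClip
#'
#' Supports mono or multi-channel PCM 16-bit and IEEE float32 WAV;
#' multi-channel input is down-mixed to mono by channel averaging.
#' Samples are returned on the [-1, 1] scale.
#'
#' @param path path to a WAV file.
#' @param clipId identifier to store; defaults to the file name without
#'   extension.
#' @param label optional class label ("normal", "crackles", "wheezing");
#'   defaults to "unlabeled".
#' @return an [AudioClip-class].
#' @examples
#' clip <- synthClip("normal", synthConfig(), seed = 1)
#' f <- tempfile(fileext = ".wav")
#' writeWav(clip, f)
#' rt <- readWav(f)
#' sampleRate(rt)
#' @export
readWav <- function(path, clipId = NULL,
                    label = "unlabeled") {
  if (!file.exists(path))
    stop(sprintf("WAV file not found: '%s'", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop(sprintf("'%s' is not a RIFF/WAV file", path), call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop(sprintf("'%s' is not a WAVE file", path), call. = FALSE)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audioFormat = readBin(con, "integer", 1, 2, endian = "little"),
        channels    = readBin(con, "integer", 1, 2, endian = "little"),
        sampleRate  = readBin(con, "integer", 1, 4, endian = "little"),
        byteRate    = readBin(con, "integer", 1, 4, endian = "little"),
        blockAlign  = readBin(con, "integer", 1, 2, endian = "little"),
        bits        = readBin(con, "integer", 1, 2, endian = "little"))
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      if (is.null(fmt))
        stop(sprintf("malformed WAV '%s': data before fmt chunk", path),
             call. = FALSE)
      dat <- if (fmt$audioFormat == 1L && fmt$bits == 16L) {
        # full-scale 32767 mirrors writeWav, so a round trip loses at
        # most half a quantization step
        readBin(con, "integer", sz / 2, 2, signed = TRUE,
                endian = "little") / 32767
      } else if (fmt$audioFormat == 3L && fmt$bits == 32L) {
        readBin(con, "double", sz / 4, 4, endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding in '%s' (format %d, %d bit)",
                     path, fmt$audioFormat, fmt$bits), call. = FALSE)
      }
      break
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
  }
  if (is.null(dat))
    stop(sprintf("malformed WAV '%s': no data chunk", path), call. = FALSE)
  if (fmt$channels > 1L) {
    n <- length(dat) %/% fmt$channels
    dat <- rowMeans(matrix(dat[seq_len(n * fmt$channels)],
                           nrow = n, byrow = TRUE))
  }
  dat <- pmin(1, pmax(-1, dat))
  if (is.null(clipId))
    clipId <- sub("\\.[^.]*$", "", basename(path))
  new("AudioClip", samples = dat, sampleRate = fmt$sampleRate,
      label = label, clipId = clipId)
}

#' Write an AudioClip (or numeric vector) to a WAV file
#'
#' @param x an [AudioClip-class], [FixedWindow-class] or numeric vector
#'   of amplitudes in [-1, 1].
#' @param path output file path.
#' @param sampleRate required when \code{x} is a bare numeric vector.
#' @param bitDepth 16 (PCM) or 32 (IEEE float).
#' @return \code{path}, invisibly.
#' @export
writeWav <- function(x, path, sampleRate = NULL, bitDepth = 16) {
  if (is(x, "AudioClip") || is(x, "FixedWindow")) {
    sampleRate <- sampleRate(x)
    x <- samples(x)
  }
  stopIf(is.null(sampleRate), "sampleRate required for numeric input")
  stopIf(!bitDepth %in% c(16, 32), "bitDepth must be 16 or 32")
  x <- pmin(1, pmax(-1, x))
  bytesPer <- bitDepth / 8
  dataSize <- length(x) * bytesPer
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bitDepth == 16) 1 else 3), con, 2,
           endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(sampleRate), con, 4, endian = "little")
  writeBin(as.integer(sampleRate * bytesPer), con, 4, endian = "little")
  writeBin(as.integer(bytesPer), con, 2, endian = "little")
  writeBin(as.integer(bitDepth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4, endian = "little")
  if (bitDepth == 16) {
    q <- as.integer(round(x * 32767))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}

#' Read and validate a corpus manifest
#'
#' A manifest is a CSV with at least \code{clip_id} and \code{label}
#' columns (plus \code{path} when it points at WAV files on disk);
#' clip_id must be unique and labels must be normal/crackles/wheezing.
#'
#' @param path CSV file path.
#' @return a data.frame.
#' @export
readManifest <- function(path) {
  stopIf(!file.exists(path), "manifest not found: '%s'", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateManifest(m)
  m
}

#' @rdname readManifest
#' @param manifest a manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  validateManifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validateManifest <- function(m) {
  stopIf(!all(c("clip_id", "label") %in% names(m)),
         "manifest needs clip_id and label columns")
  stopIf(anyDuplicated(m$clip_id) > 0, "manifest clip_id values must be unique")
  bad <- setdiff(unique(m$label), LUNG_LABELS)
  stopIf(length(bad) > 0, "invalid manifest label(s): %s",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
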