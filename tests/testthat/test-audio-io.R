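test_that("WAV round trip is bounded by quantization", {
  clip <- synthClip("normal", fastSynthConfig(), seed = 2)
  f <- withr::local_tempfile(fileext = ".wav")
  writeWav(clip, f)
  rt <- readWav(f)
  expect_equal(sampleRate(rt), 8000)
  expect_lte(max(abs(samples(rt) - samples(clip))), 1 / 32768)
  # float32 round trip is tighter
  f32 <- withr::local_tempfile(fileext = ".wav")
  writeWav(clip, f32, bitDepth = 32)
  expect_lte(max(abs(samples(readWav(f32)) - samples(clip))), 1e-7)
  expect_error(readWav(file.path(tempdir(), "no_such_file.wav")),
               "no_such_file")
  # recorded clips carry labels without event metadata
  labeled <- readWav(f, label = "wheezing")
  expect_equal(clipLabel(labeled), "wheezing")
  expect_length(clipEvents(labeled), 0)
})

test_that("stereo input with identical channels down-mixes unchanged", {
  x <- sin(2 * pi * 100 * (0:799) / 8000) * 0.5
  f <- withr::local_tempfile(fileext = ".wav")
  # hand-write a 2-channel PCM16 WAV with both channels equal
  con <- file(f, "wb")
  q <- as.integer(round(x * 32767))
  inter <- as.integer(rbind(q, q))
  dataSize <- length(inter) * 2
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(2L, con, 2, endian = "little")   # channels
  writeBin(8000L, con, 4, endian = "little")
  writeBin(8000L * 4L, con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, 4, endian = "little")
  writeBin(inter, con, 2, endian = "little")
  close(con)
  mono <- readWav(f)
  expect_equal(samples(mono), q / 32767, tolerance = 1e-12)
})

test_that("manifest validation catches duplicates and bad labels", {
  m <- data.frame(clip_id = c("a", "b"), label = c("normal", "wheezing"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeManifest(m, f)
  expect_equal(readManifest(f), m)
  expect_error(writeManifest(
    data.frame(clip_id = c("a", "a"), label = c("normal", "normal")), f),
    "unique")
  expect_error(writeManifest(
    data.frame(clip_id = "a", label = "murmur"), f), "invalid")
})

test_that("ICBHI annotations parse, sort, and reject malformed rows", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2.5\t5.1\t1\t0", "0.0\t2.5\t0\t0"), f)
  ann <- parseICBHIAnnotation(f)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$cycleStart, c(0.0, 2.5))  # sorted
  expect_equal(ann$crackleFlag, c(0L, 1L))
  writeLines(character(0), f)
  expect_equal(nrow(parseICBHIAnnotation(f)), 0)
  writeLines(c("0.0 2.5 0 0", "2.5 5.1 1"), f)
  expect_error(parseICBHIAnnotation(f), "line 2")
  writeLines(c("3.0 2.0 0 0"), f)
  expect_error(parseICBHIAnnotation(f), "precede")
})

test_that("cycle flags map to labels and class counts", {
  expect_equal(icbhiCycleToLabel(0, 0), "normal")
  expect_equal(icbhiCycleToLabel(1, 0), "crackles")
  expect_equal(icbhiCycleToLabel(0, 1), "wheezing")
  expect_equal(icbhiCycleToLabel(1, 1), "both")
  expect_error(icbhiCycleToLabel(2, 0), "flags")
  ann <- data.frame(cycleStart = c(0, 1, 2), cycleEnd = c(1, 2, 3),
                    crackleFlag = c(0L, 0L, 1L),
                    wheezeFlag = c(0L, 1L, 0L))
  counts <- icbhiClassCounts(ann)
  expect_equal(unname(counts[c("normal", "wheezing", "crackles", "both")]),
               c(1L, 1L, 1L, 0L))
})

test_that("extractCycles slices half-open intervals and keeps duration", {
  sr <- 8000
  rec <- new("AudioClip", samples = sin(2 * pi * 50 * (0:(10 * sr - 1)) / sr),
             sampleRate = sr, clipId = "rec01")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.0 2.5 0 0", "2.5 5.1 1 0"), f)
  ann <- parseICBHIAnnotation(f)
  clips <- extractCycles(rec, ann)
  expect_length(clips, 2)
  expect_equal(clipDuration(clips[[1]]), 2.5, tolerance = 1 / sr)
  expect_equal(clipDuration(clips[[2]]), 2.6, tolerance = 1 / sr)
  expect_equal(clipLabel(clips[[2]]), "crackles")
  # total labeled duration is preserved (sample-count identity)
  total <- sum(vapply(clips, function(cl) length(samples(cl)), numeric(1)))
  expect_equal(total, floor(5.1 * sr))
  writeLines("0.0 20.0 0 0", f)
  expect_error(extractCycles(rec, parseICBHIAnnotation(f)), "exceed")
  writeLines(character(0), f)
  expect_length(extractCycles(rec, parseICBHIAnnotation(f)), 0)
})
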