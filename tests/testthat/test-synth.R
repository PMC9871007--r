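test_that("breath envelope has the right cycle structure and emphasis", {
  sr <- 8000
  spec <- breathCycleSpec(30, 0.4, 2)
  env <- breathEnvelope(spec, 4, sr)
  expect_length(env, 4 * sr)
  expect_true(all(env >= 0 & env <= 1))
  # 60/30 = 2 s per cycle: exactly two local maxima-bearing cycles
  cyc1 <- env[1:(2 * sr)]
  cyc2 <- env[(2 * sr + 1):(4 * sr)]
  expect_equal(cyc1, cyc2, tolerance = 1e-12)
  # one full cycle when rate * duration = 60
  env1 <- breathEnvelope(breathCycleSpec(60, 0.4, 1), 1, sr)
  expect_length(env1, sr)
  # inspiration is louder than late expiration (time-averaged)
  t <- (seq_along(env) - 1) / sr
  p <- (t %% 2) / 2
  insp <- mean(env[p < 0.4])
  lateExp <- mean(env[p > 0.8])
  expect_gt(insp / lateExp, 1)
  expect_error(breathEnvelope(spec, -1, sr), "duration")
  expect_error(breathCycleSpec(-5), "respiratoryRate")
})

test_that("vesicular sound is low-pass noise with the configured corner", {
  cfg <- synthConfig()
  v <- synthVesicular(6, cfg, seed = 1)
  expect_length(v, 6 * 44100)
  expect_true(all(is.finite(v)))
  corner <- psdCorner(v, 44100)
  expect_lt(abs(corner - 200) / 200, 0.20)
  expect_identical(v, synthVesicular(6, cfg, seed = 1))
  expect_false(identical(v, synthVesicular(6, cfg, seed = 2)))
  expect_error(synthVesicular(0, cfg, seed = 1), "duration")
})

test_that("wheeze events are tonal, in band, and validated", {
  sr <- 44100
  w <- synthWheezeEvent(eventSpec("wheeze", 400, 0.2), sr, seed = 3)
  expect_length(w, round(0.2 * sr))
  pk <- peakFrequency(w, sr)
  expect_lt(abs(pk - 400) / 400, 0.10)
  expect_true(pk >= 100 && pk <= 1000)
  expect_error(eventSpec("wheeze", 400, 0.05), "0.080")
  expect_error(eventSpec("wheeze", 50, 0.2), "\\[100, 1000\\]")
  expect_error(
    synthWheezeEvent(eventSpec("fine_crackle"), sr), "wheeze")
})

test_that("crackle events decay within their nominal duration", {
  sr <- 44100
  fine <- synthCrackleEvent(eventSpec("fine_crackle"), sr)
  coarse <- synthCrackleEvent(eventSpec("coarse_crackle"), sr)
  expect_lt(abs(peakFrequency(fine, sr) - 650) / 650, 0.10)
  expect_lt(abs(peakFrequency(coarse, sr) - 350) / 350, 0.10)
  after <- function(w, d) max(abs(w[(round(d * sr) + 1):length(w)]))
  expect_lt(after(fine, 0.005) / max(abs(fine)), 0.05)
  expect_lt(after(coarse, 0.015) / max(abs(coarse)), 0.05)
  expect_error(eventSpec("fine_crackle", duration = 0), "positive")
})

test_that("heart sounds beat at the requested cadence, low frequency", {
  sr <- 8000
  h <- synthHeartSounds(6, 120, sr, seed = 1)
  # S1 events by envelope peak-picking: threshold above the S2 level
  env <- abs(h)
  thr <- 0.8 * max(env)
  above <- env > thr
  # count rising edges separated by > 100 ms
  idx <- which(above)
  s1 <- sum(diff(c(-sr, idx)) > 0.1 * sr)
  expect_equal(s1, 12)  # 120 bpm x 6 s / 60
  p <- abs(stats::fft(h))^2
  f <- (seq_along(p) - 1) * sr / length(p)
  half <- f <= sr / 2
  centroid <- sum(f[half] * p[half]) / sum(p[half])
  expect_lt(centroid, 150)
  expect_error(synthHeartSounds(6, 0, sr), "heartRate")
})

test_that("synthClip respects label semantics and determinism", {
  cfg <- fastSynthConfig()
  normal <- synthClip("normal", cfg, seed = 5)
  expect_length(clipEvents(normal), 0)
  wheeze <- synthClip("wheezing", cfg, seed = 5)
  kinds <- vapply(clipEvents(wheeze), function(e) e$kind, character(1))
  expect_true(any(kinds == "wheeze"))
  durs <- vapply(clipEvents(wheeze), function(e) e$duration, numeric(1))
  expect_true(all(durs[kinds == "wheeze"] > 0.080))
  crack <- synthClip("crackles", cfg, seed = 5)
  expect_true(all(vapply(clipEvents(crack), function(e) e$kind,
                         character(1)) %in%
                  c("fine_crackle", "coarse_crackle")))
  for (clip in list(normal, wheeze, crack)) {
    expect_lte(max(abs(samples(clip))), 1)
    expect_true(all(is.finite(samples(clip))))
  }
  expect_identical(samples(wheeze),
                   samples(synthClip("wheezing", cfg, seed = 5)))
  expect_error(synthClip("murmur", cfg), "label")
})

test_that("crackle clips contain bursts above the local envelope", {
  cfg <- synthConfig()
  ok <- vapply(1:5, function(i) {
    x <- abs(samples(synthClip("crackles", cfg, seed = 400 + i)))
    k <- 2L * round(0.025 * 44100) + 1L  # ~50 ms running median
    med <- stats::runmed(x, k)
    any(x > 3 * pmax(med, 1e-6))
  }, logical(1))
  expect_true(all(ok))
})

test_that("wheezing clips carry more 300-1000 Hz power than normal", {
  cfg <- synthConfig()
  wp <- vapply(1:25, function(i)
    bandPower(samples(synthClip("wheezing", cfg, seed = 200 + i)),
              44100, 300, 1000), numeric(1))
  np <- vapply(1:25, function(i)
    bandPower(samples(synthClip("normal", cfg, seed = 300 + i)),
              44100, 300, 1000), numeric(1))
  expect_gt(mean(wp), mean(np))
})

test_that("generateCorpus writes a reproducible manifest and WAVs", {
  cfg <- fastSynthConfig()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- generateCorpus(cfg, n = 6, outDir = d1, seed = 9)
  c2 <- generateCorpus(cfg, n = 6, outDir = d2, seed = 9)
  m <- c1$manifest
  expect_setequal(names(m),
                  c("clip_id", "label", "length_s", "respiratory_rate",
                    "cycle_count", "heart_sound_present", "seed", "path"))
  expect_false(anyDuplicated(m$clip_id) > 0)
  expect_true(all(m$label %in% c("normal", "crackles", "wheezing")))
  expect_true(all(m$cycle_count %in% 1:2))
  # byte-identical WAV output under the same seed
  for (i in seq_len(nrow(m)))
    expect_identical(readBin(c1$manifest$path[i], "raw", 1e6),
                     readBin(c2$manifest$path[i], "raw", 1e6))
  expect_error(generateCorpus(cfg, n = 0), "n must be")
  # class mix is honored as closely as n allows
  c3 <- generateCorpus(cfg, n = 9, seed = 1, keepClips = FALSE)
  expect_equal(unname(table(c3$manifest$label))[1:3], rep(3L, 3),
               ignore_attr = TRUE)
})
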