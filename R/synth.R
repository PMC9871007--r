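#' Configuration for the synthetic auscultation-audio generator
#'
#' Defaults reproduce the corpus statistics of the pediatric clinic
#' recordings the generator emulates: mean clip length 4.1 s (SD 1.8),
#' mean respiratory rate 30.2 breaths/min (SD 13.4), one breath cycle in
#' ~20% and two in ~80% of clips, audible heart sounds in 75% of clips,
#' and a vesicular (normal breath) spectrum whose energy drops 3 dB at
#' 200 Hz. Crackle and wheeze event parameters follow the standard
#' acoustic definitions: fine crackles 650 Hz / 5 ms, coarse crackles
#' 350 Hz / 15 ms, wheezes tonal within 100-1000 Hz lasting > 80 ms.
#'
#' Clip length and respiratory rate are drawn from truncated normal
#' distributions; the pre-truncation means are calibrated (once, at
#' config construction) so the *truncated* means equal the targets.
#'
#' @param sampleRate sampling rate in Hz.
#' @param clipLengthMean,clipLengthSd target mean/SD of clip length (s).
#' @param clipLengthBounds physiologic truncation bounds for length (s).
#' @param respRateMean,respRateSd target mean/SD respiratory rate (/min).
#' @param respRateBounds truncation bounds for respiratory rate (/min).
#' @param inspirationFraction fraction of the breath cycle spent in
#'   inspiration.
#' @param cycleCountProbs probabilities of 1 and 2 recorded breath
#'   cycles.
#' @param heartSoundProbability probability a clip carries audible heart
#'   sounds.
#' @param heartRateRange pediatric heart-rate range (beats/min).
#' @param classMix proportions over normal/crackles/wheezing used by
#'   [generateCorpus()].
#' @param vesicularCornerFrequency -3 dB corner of the vesicular
#'   low-pass spectrum (Hz).
#' @param snrRange ambient white-noise floor, dB SNR relative to the
#'   composed signal.
#' @param cracklesPerInspiration integer range of crackles placed in
#'   each inspiratory segment of a crackle clip.
#' @param fineCrackleProb probability an individual crackle is fine (vs
#'   coarse).
#' @param wheezeCount integer range of wheeze events per wheezing clip.
#' @param wheezePhaseCoverage fraction of a respiratory phase a wheeze
#'   spans.
#' @param wheezeFreqRange wheeze center-frequency range (Hz), within
#'   100-1000.
#' @param crackleAmplitude,wheezeAmplitude event amplitude ranges,
#'   relative to the vesicular RMS.
#' @param heartAmplitude heart-sound peak relative to vesicular RMS.
#' @param vesicularRMS RMS of the vesicular component before
#'   peak-normalization.
#' @return a validated list of class \code{"SynthConfig"}.
#' @examples
#' cfg <- synthConfig()
#' cfg$respRateMean
#' @export
synthConfig <- function(sampleRate = 44100,
                        clipLengthMean = 4.1, clipLengthSd = 1.8,
                        clipLengthBounds = c(1.5, 10),
                        respRateMean = 30.2, respRateSd = 13.4,
                        respRateBounds = c(12, 80),
                        inspirationFraction = 0.4,
                        cycleCountProbs = c(0.203, 0.797),
                        heartSoundProbability = 0.75,
                        heartRateRange = c(80, 160),
                        classMix = c(normal = 1/3, crackles = 1/3,
                                     wheezing = 1/3),
                        vesicularCornerFrequency = 200,
                        snrRange = c(15, 30),
                        cracklesPerInspiration = c(3, 10),
                        fineCrackleProb = 0.5,
                        wheezeCount = c(1, 2),
                        wheezePhaseCoverage = c(0.3, 0.9),
                        wheezeFreqRange = c(150, 900),
                        crackleAmplitude = c(1.0, 2.0),
                        wheezeAmplitude = c(4.0, 8.0),
                        heartAmplitude = 3.0,
                        vesicularRMS = 0.1) {
  stopIf(sampleRate <= 0, "sampleRate must be positive")
  stopIf(clipLengthMean <= 0 || clipLengthSd <= 0,
         "clip length parameters must be positive")
  stopIf(respRateMean <= 0 || respRateSd <= 0,
         "respiratory rate parameters must be positive")
  stopIf(clipLengthBounds[1] >= clipLengthMean ||
         clipLengthBounds[2] <= clipLengthMean,
         "clipLengthBounds must bracket clipLengthMean")
  stopIf(respRateBounds[1] >= respRateMean ||
         respRateBounds[2] <= respRateMean,
         "respRateBounds must bracket respRateMean")
  stopIf(inspirationFraction <= 0 || inspirationFraction >= 1,
         "inspirationFraction must lie in (0, 1)")
  stopIf(abs(sum(classMix) - 1) > 1e-8, "classMix must sum to 1")
  stopIf(length(classMix) != 3, "classMix needs 3 proportions")
  stopIf(heartSoundProbability < 0 || heartSoundProbability > 1,
         "heartSoundProbability must lie in [0, 1]")
  stopIf(vesicularCornerFrequency <= 0, "corner frequency must be positive")
  stopIf(wheezeFreqRange[1] < 100 || wheezeFreqRange[2] > 1000,
         "wheezeFreqRange must lie within [100, 1000] Hz")
  cfg <- list(
    sampleRate = sampleRate,
    clipLengthMean = clipLengthMean, clipLengthSd = clipLengthSd,
    clipLengthBounds = clipLengthBounds,
    clipLengthMu = calibrateTruncMean(clipLengthMean, clipLengthSd,
                                      clipLengthBounds),
    respRateMean = respRateMean, respRateSd = respRateSd,
    respRateBounds = respRateBounds,
    respRateMu = calibrateTruncMean(respRateMean, respRateSd,
                                    respRateBounds),
    inspirationFraction = inspirationFraction,
    cycleCountProbs = cycleCountProbs / sum(cycleCountProbs),
    heartSoundProbability = heartSoundProbability,
    heartRateRange = heartRateRange,
    classMix = classMix,
    vesicularCornerFrequency = vesicularCornerFrequency,
    snrRange = snrRange,
    cracklesPerInspiration = cracklesPerInspiration,
    fineCrackleProb = fineCrackleProb,
    wheezeCount = wheezeCount,
    wheezePhaseCoverage = wheezePhaseCoverage,
    wheezeFreqRange = wheezeFreqRange,
    crackleAmplitude = crackleAmplitude,
    wheezeAmplitude = wheezeAmplitude,
    heartAmplitude = heartAmplitude,
    vesicularRMS = vesicularRMS)
  class(cfg) <- "SynthConfig"
  cfg
}

# Pre-truncation mean mu such that E[X | lo <= X <= hi] = target for
# X ~ N(mu, sd). Closed-form truncated-normal mean, solved by uniroot.
calibrateTruncMean <- function(target, sd, bounds) {
  truncMean <- function(mu) {
    a <- (bounds[1] - mu) / sd
    b <- (bounds[2] - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  stats::uniroot(function(mu) truncMean(mu) - target,
                 lower = target - 3 * sd, upper = target + 3 * sd,
                 tol = 1e-10)$root
}

#' Breath-cycle specification
#'
#' @param respiratoryRate breaths per minute (> 0); one cycle lasts
#'   \code{60/respiratoryRate} seconds.
#' @param inspirationFraction fraction of the cycle spent in
#'   inspiration, in (0, 1).
#' @param cycleCount number of breath cycles recorded in the clip (1 or
#'   2).
#' @return a list of class \code{"BreathCycleSpec"}.
#' @export
breathCycleSpec <- function(respiratoryRate, inspirationFraction = 0.4,
                            cycleCount = 2) {
  stopIf(!is.numeric(respiratoryRate) || respiratoryRate <= 0,
         "respiratoryRate must be positive")
  stopIf(inspirationFraction <= 0 || inspirationFraction >= 1,
         "inspirationFraction must lie in (0, 1)")
  stopIf(!cycleCount %in% c(1, 2), "cycleCount must be 1 or 2")
  structure(list(respiratoryRate = respiratoryRate,
                 inspirationFraction = inspirationFraction,
                 cycleCount = as.integer(cycleCount)),
            class = "BreathCycleSpec")
}

#' Event specification for an adventitious sound
#'
#' Defaults encode the standard acoustic definitions: fine crackles at
#' 650 Hz lasting 5 ms, coarse crackles at 350 Hz lasting 15 ms, wheezes
#' tonal in 100-1000 Hz and longer than 80 ms.
#'
#' @param kind "wheeze", "fine_crackle" or "coarse_crackle".
#' @param centerFrequency Hz; defaults 650 (fine), 350 (coarse); no
#'   default for wheeze.
#' @param duration seconds; defaults 0.005 (fine), 0.015 (coarse).
#' @param onset seconds from clip start.
#' @param amplitude unitless, relative to the vesicular RMS.
#' @return a list of class \code{"EventSpec"}.
#' @export
eventSpec <- function(kind, centerFrequency = NULL, duration = NULL,
                      onset = 0, amplitude = 1) {
  stopIf(!kind %in% c("wheeze", "fine_crackle", "coarse_crackle"),
         "unknown event kind '%s'", kind)
  if (kind == "fine_crackle") {
    if (is.null(centerFrequency)) centerFrequency <- 650
    if (is.null(duration)) duration <- 0.005
  } else if (kind == "coarse_crackle") {
    if (is.null(centerFrequency)) centerFrequency <- 350
    if (is.null(duration)) duration <- 0.015
  }
  stopIf(is.null(centerFrequency) || is.null(duration),
         "wheeze events need explicit centerFrequency and duration")
  stopIf(duration <= 0, "event duration must be positive")
  if (kind == "wheeze") {
    stopIf(centerFrequency < 100 || centerFrequency > 1000,
           "wheeze centerFrequency must lie in [100, 1000] Hz")
    stopIf(duration <= 0.080, "wheeze duration must exceed 0.080 s")
  }
  structure(list(kind = kind, centerFrequency = centerFrequency,
                 duration = duration, onset = onset,
                 amplitude = amplitude),
            class = "EventSpec")
}

#' Respiratory amplitude envelope
#'
#' A smooth per-cycle gain emphasizing inspiration and early expiration,
#' where normal breath-sound power concentrates; late expiration is
#' nearly quiet. Values lie in [0, 1].
#'
#' @param spec a [breathCycleSpec()].
#' @param duration envelope duration in seconds (> 0).
#' @param sampleRate sampling rate in Hz.
#' @return numeric vector of length \code{round(duration * sampleRate)}.
#' @export
breathEnvelope <- function(spec, duration, sampleRate) {
  stopIf(!inherits(spec, "BreathCycleSpec"), "spec must be a BreathCycleSpec")
  stopIf(duration <= 0, "duration must be positive")
  stopIf(sampleRate <= 0, "sampleRate must be positive")
  n <- round(duration * sampleRate)
  t <- (seq_len(n) - 1) / sampleRate
  cycleDur <- 60 / spec$respiratoryRate
  p <- (t %% cycleDur) / cycleDur
  fi <- spec$inspirationFraction
  env <- numeric(n)
  insp <- p < fi
  env[insp] <- 0.25 + 0.75 * sin(pi * p[insp] / fi)
  q <- (p[!insp] - fi) / (1 - fi)
  env[!insp] <- 0.25 + 0.55 * sin(pi * q) * exp(-3 * q)
  env
}

#' Synthesize vesicular (normal) breath sound
#'
#' Gaussian noise shaped by a 2nd-order low-pass filter whose power
#' drops 3 dB at the configured corner frequency (200 Hz by default),
#' amplitude-modulated by the respiratory envelope and scaled to the
#' configured RMS. Deterministic given the seed.
#'
#' @param duration seconds (> 0).
#' @param config a [synthConfig()].
#' @param seed integer RNG seed.
#' @param breath optional [breathCycleSpec()]; defaults to a 2-cycle
#'   spec at the config's mean respiratory rate.
#' @return numeric waveform.
#' @export
synthVesicular <- function(duration, config = synthConfig(), seed = 1,
                           breath = NULL) {
  stopIf(duration <= 0, "duration must be positive")
  if (is.null(breath))
    breath <- breathCycleSpec(config$respRateMean,
                              config$inspirationFraction)
  n <- round(duration * config$sampleRate)
  x <- withSeed(seed, stats::rnorm(n))
  bf <- signal::butter(2, config$vesicularCornerFrequency /
                            (config$sampleRate / 2), type = "low")
  x <- as.numeric(signal::filter(bf, x))
  x <- x / sqrt(mean(x^2)) * config$vesicularRMS
  x * breathEnvelope(breath, duration, config$sampleRate)
}

#' Synthesize a wheeze event
#'
#' A tonal segment: a sinusoid with mild second-harmonic content and a
#' slow frequency drift bounded by +/-8%, tapered at both ends. The
#' dominant spectral peak lies within 10% of the requested center
#' frequency.
#'
#' @param spec an [eventSpec()] with kind "wheeze".
#' @param sampleRate Hz.
#' @param seed integer RNG seed (controls drift and phase).
#' @return numeric waveform of length \code{round(duration * sampleRate)},
#'   unit RMS times \code{spec$amplitude}.
#' @export
synthWheezeEvent <- function(spec, sampleRate, seed = 1) {
  stopIf(!inherits(spec, "EventSpec") || spec$kind != "wheeze",
         "spec must be a wheeze EventSpec")
  stopIf(spec$duration <= 0.080, "wheeze duration must exceed 0.080 s")
  stopIf(spec$centerFrequency < 100 || spec$centerFrequency > 1000,
         "wheeze centerFrequency must lie in [100, 1000] Hz")
  n <- round(spec$duration * sampleRate)
  t <- (seq_len(n) - 1) / sampleRate
  pars <- withSeed(seed, list(depth = stats::runif(1, 0.02, 0.08),
                              rate = stats::runif(1, 0.5, 2) / spec$duration,
                              phi = stats::runif(2, 0, 2 * pi)))
  finst <- spec$centerFrequency *
    (1 + pars$depth * sin(2 * pi * pars$rate * t + pars$phi[1]))
  phase <- 2 * pi * cumsum(finst) / sampleRate
  w <- sin(phase + pars$phi[2]) + 0.2 * sin(2 * (phase + pars$phi[2]))
  # 10% raised-cosine taper at each end for smooth onset/offset
  m <- max(2L, round(0.1 * n))
  taper <- rep(1, n)
  ramp <- 0.5 - 0.5 * cos(pi * (seq_len(m) - 1) / (m - 1))
  taper[seq_len(m)] <- ramp
  taper[n + 1 - seq_len(m)] <- ramp
  w <- w * taper
  w / sqrt(mean(w^2)) * spec$amplitude
}

#' Synthesize a crackle event
#'
#' An exponentially damped sinusoid \eqn{\sin(2\pi f t)\,e^{-t/\tau}}
#' whose envelope falls below 5% of its peak at the nominal duration
#' (\eqn{\tau = duration / 3.5}); the returned segment spans twice the
#' nominal duration so the tail decays fully. The spectral peak lies at
#' the requested center frequency (650 Hz fine, 350 Hz coarse by
#' default).
#'
#' @param spec an [eventSpec()] with a crackle kind.
#' @param sampleRate Hz.
#' @return numeric waveform, unit RMS times \code{spec$amplitude}.
#' @export
synthCrackleEvent <- function(spec, sampleRate) {
  stopIf(!inherits(spec, "EventSpec") ||
         !spec$kind %in% c("fine_crackle", "coarse_crackle"),
         "spec must be a fine_crackle or coarse_crackle EventSpec")
  stopIf(spec$duration <= 0, "crackle duration must be positive")
  n <- round(2 * spec$duration * sampleRate)
  t <- (seq_len(n) - 1) / sampleRate
  # The waveform peak sits a quarter-period after onset, so the decay
  # must be a little faster than exp(-3) for the envelope to fall below
  # 5% of that peak by t = duration.
  tau <- spec$duration / 3.5
  w <- sin(2 * pi * spec$centerFrequency * t) * exp(-t / tau)
  w / sqrt(mean(w^2)) * spec$amplitude
}

#' Synthesize heart-sound contamination
#'
#' Periodic S1/S2 pairs of low-frequency (roughly 40 and 60 Hz) damped
#' oscillations at the cadence \code{60/heartRate} seconds, S2 placed at
#' 35% of the beat interval with a smaller amplitude. Peak amplitude 1.
#'
#' @param duration seconds.
#' @param heartRate beats per minute.
#' @param sampleRate Hz.
#' @param seed integer RNG seed (small amplitude jitter).
#' @return numeric waveform.
#' @export
synthHeartSounds <- function(duration, heartRate, sampleRate, seed = 1) {
  stopIf(duration <= 0, "duration must be positive")
  stopIf(!is.numeric(heartRate) || heartRate <= 0 || heartRate > 300,
         "heartRate must lie in (0, 300] beats/min")
  n <- round(duration * sampleRate)
  out <- numeric(n)
  beat <- 60 / heartRate
  starts <- seq(0, duration - 1e-9, by = beat)
  amps <- withSeed(seed, list(s1 = stats::runif(length(starts), 0.95, 1.05),
                              s2 = stats::runif(length(starts), 0.5, 0.6)))
  thump <- function(f, tau, len) {
    t <- (seq_len(round(len * sampleRate)) - 1) / sampleRate
    sin(2 * pi * f * t) * exp(-t / tau)
  }
  s1 <- thump(40, 0.030, 0.12)
  s2 <- thump(60, 0.018, 0.08)
  addAt <- function(out, w, t0, a) {
    i0 <- round(t0 * sampleRate) + 1
    if (i0 > n) return(out)
    len <- min(length(w), n - i0 + 1)
    out[i0:(i0 + len - 1)] <- out[i0:(i0 + len - 1)] + a * w[seq_len(len)]
    out
  }
  for (k in seq_along(starts)) {
    out <- addAt(out, s1, starts[k], amps$s1[k])
    out <- addAt(out, s2, starts[k] + 0.35 * beat, amps$s2[k])
  }
  pk <- max(abs(out))
  if (pk > 0) out <- out / pk
  out
}

#' Synthesize one labeled auscultation clip
#'
#' Draws clip length and respiratory rate from the calibrated truncated
#' normals, composes vesicular breath sound with class-conditional
#' adventitious events (crackles placed within inspiratory segments;
#' wheezes spanning 30-90% of an inspiratory or expiratory phase), adds
#' heart sounds with the configured probability and an ambient white
#' noise floor, and peak-normalizes to 0.9. Deterministic given
#' (label, config, seed).
#'
#' @param label "normal", "crackles" or "wheezing".
#' @param config a [synthConfig()].
#' @param seed integer RNG seed.
#' @param clipId identifier; defaults to \code{"synth_<seed>"}.
#' @return an [AudioClip-class].
#' @examples
#' clip <- synthClip("wheezing", synthConfig(), seed = 7)
#' length(clipEvents(clip)) >= 1
#' @export
synthClip <- function(label, config = synthConfig(), seed = 1,
                      clipId = NULL) {
  stopIf(!label %in% LUNG_LABELS,
         "label must be one of normal/crackles/wheezing, got '%s'", label)
  if (is.null(clipId)) clipId <- sprintf("synth_%d", as.integer(seed))
  sr <- config$sampleRate

  draws <- withSeed(seed, {
    len <- rtruncnorm1(1, config$clipLengthMu, config$clipLengthSd,
                       config$clipLengthBounds[1], config$clipLengthBounds[2])
    rate <- rtruncnorm1(1, config$respRateMu, config$respRateSd,
                        config$respRateBounds[1], config$respRateBounds[2])
    cyc <- sample(1:2, 1, prob = config$cycleCountProbs)
    heart <- stats::runif(1) < config$heartSoundProbability
    heartRate <- stats::runif(1, config$heartRateRange[1],
                              config$heartRateRange[2])
    snr <- stats::runif(1, config$snrRange[1], config$snrRange[2])
    list(len = len, rate = rate, cyc = cyc, heart = heart,
         heartRate = heartRate, snr = snr)
  })
  breath <- breathCycleSpec(draws$rate, config$inspirationFraction,
                            draws$cyc)
  n <- round(draws$len * sr)
  dur <- n / sr

  x <- synthVesicular(dur, config, seed = childSeed(seed, 1),
                      breath = breath)
  vrms <- config$vesicularRMS

  events <- list()
  segs <- respiratorySegments(breath, dur)
  if (label == "crackles") {
    events <- withSeed(childSeed(seed, 2), {
      ev <- list()
      insp <- segs[segs$phase == "inspiration" & segs$len >= 0.05, ,
                   drop = FALSE]
      for (i in seq_len(nrow(insp))) {
        k <- sample(config$cracklesPerInspiration[1]:
                    config$cracklesPerInspiration[2], 1)
        for (j in seq_len(k)) {
          fine <- stats::runif(1) < config$fineCrackleProb
          kind <- if (fine) "fine_crackle" else "coarse_crackle"
          base <- eventSpec(kind)
          ev[[length(ev) + 1L]] <- eventSpec(
            kind,
            centerFrequency = base$centerFrequency *
              stats::runif(1, 0.95, 1.05),
            duration = base$duration,
            onset = stats::runif(1, insp$start[i],
                                 insp$start[i] + insp$len[i]),
            amplitude = stats::runif(1, config$crackleAmplitude[1],
                                     config$crackleAmplitude[2]))
        }
      }
      ev
    })
  } else if (label == "wheezing") {
    events <- withSeed(childSeed(seed, 2), {
      ev <- list()
      usable <- segs[segs$len >= 0.1, , drop = FALSE]
      nW <- sample(config$wheezeCount[1]:config$wheezeCount[2], 1)
      for (j in seq_len(nW)) {
        s <- usable[sample(nrow(usable), 1), ]
        cov <- stats::runif(1, config$wheezePhaseCoverage[1],
                            config$wheezePhaseCoverage[2])
        d <- min(max(0.081, cov * s$len), s$len)
        onset <- s$start + stats::runif(1, 0, max(0, s$len - d))
        ev[[length(ev) + 1L]] <- eventSpec(
          "wheeze",
          centerFrequency = stats::runif(1, config$wheezeFreqRange[1],
                                         config$wheezeFreqRange[2]),
          duration = d, onset = onset,
          amplitude = stats::runif(1, config$wheezeAmplitude[1],
                                   config$wheezeAmplitude[2]))
      }
      ev
    })
  }

  for (j in seq_along(events)) {
    e <- events[[j]]
    w <- if (e$kind == "wheeze")
      synthWheezeEvent(e, sr, seed = childSeed(seed, 100 + j))
    else synthCrackleEvent(e, sr)
    i0 <- round(e$onset * sr) + 1
    if (i0 > n) next
    len <- min(length(w), n - i0 + 1)
    x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] + vrms * w[seq_len(len)]
  }

  if (draws$heart)
    x <- x + config$heartAmplitude * vrms *
      synthHeartSounds(dur, draws$heartRate, sr,
                       seed = childSeed(seed, 3))

  sigRMS <- sqrt(mean(x^2))
  noise <- withSeed(childSeed(seed, 4), stats::rnorm(n))
  x <- x + noise * sigRMS / 10^(draws$snr / 20)

  x <- x / max(abs(x)) * 0.9
  new("AudioClip", samples = x, sampleRate = sr, label = label,
      breath = list(respiratoryRate = draws$rate,
                    inspirationFraction = config$inspirationFraction,
                    cycleCount = draws$cyc),
      events = events, heartSound = draws$heart, clipId = clipId)
}

# Inspiratory/expiratory segments of [0, dur) as a data.frame.
respiratorySegments <- function(breath, dur) {
  cd <- 60 / breath$respiratoryRate
  fi <- breath$inspirationFraction
  starts <- seq(0, dur, by = cd)
  out <- data.frame(start = numeric(0), len = numeric(0),
                    phase = character(0))
  for (s in starts) {
    iEnd <- min(s + fi * cd, dur)
    if (iEnd > s)
      out <- rbind(out, data.frame(start = s, len = iEnd - s,
                                   phase = "inspiration"))
    eStart <- s + fi * cd
    eEnd <- min(s + cd, dur)
    if (eEnd > eStart)
      out <- rbind(out, data.frame(start = eStart, len = eEnd - eStart,
                                   phase = "expiration"))
  }
  out
}

#' Generate a labeled synthetic corpus
#'
#' Synthesizes \code{n} clips with class proportions from
#' \code{config$classMix}, optionally writing one WAV per clip plus a
#' \code{manifest.csv}. Per-clip seeds are derived deterministically
#' from \code{seed}, so the corpus (including WAV bytes) is reproducible.
#'
#' @param config a [synthConfig()].
#' @param n number of clips (>= 1).
#' @param outDir output directory for WAVs + manifest, or \code{NULL}
#'   to skip writing.
#' @param seed integer corpus seed.
#' @param keepClips return the [AudioClip-class] objects in memory
#'   (default only when not writing and \code{n <= 200}).
#' @return a list with \code{manifest} (data.frame with columns
#'   clip_id, label, length_s, respiratory_rate, cycle_count,
#'   heart_sound_present, seed, and path when written) and
#'   \code{clips} (list or NULL).
#' @examples
#' corp <- generateCorpus(synthConfig(), n = 4, seed = 1)
#' corp$manifest$label
#' @export
generateCorpus <- function(config = synthConfig(), n, outDir = NULL,
                           seed = 1,
                           keepClips = is.null(outDir) && n <= 200) {
  stopIf(!is.numeric(n) || n < 1, "n must be >= 1")
  n <- as.integer(n)
  labels <- corpusLabels(config$classMix, n, seed)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    stopIf(!dir.exists(outDir), "cannot create output directory '%s'",
           outDir)
  }
  clips <- if (keepClips) vector("list", n) else NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- childSeed(seed, 10L + i)
    clip <- synthClip(labels[i], config, seed = cs,
                      clipId = sprintf("clip_%05d", i))
    path <- NA_character_
    if (!is.null(outDir)) {
      path <- file.path(outDir, paste0(clip@clipId, ".wav"))
      writeWav(clip, path)
    }
    rows[[i]] <- data.frame(
      clip_id = clip@clipId, label = clip@label,
      length_s = length(clip@samples) / clip@sampleRate,
      respiratory_rate = clip@breath$respiratoryRate,
      cycle_count = clip@breath$cycleCount,
      heart_sound_present = clip@heartSound,
      seed = cs, path = path, stringsAsFactors = FALSE)
    if (keepClips) clips[[i]] <- clip
  }
  manifest <- do.call(rbind, rows)
  if (is.null(outDir)) manifest$path <- NULL
  if (!is.null(outDir))
    writeManifest(manifest, file.path(outDir, "manifest.csv"))
  list(manifest = manifest, clips = clips)
}

# Deterministic label sequence matching the mix as closely as possible,
# shuffled under the corpus seed.
corpusLabels <- function(classMix, n, seed) {
  counts <- floor(classMix * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- classMix * n - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  labels <- rep(LUNG_LABELS, times = counts)
  withSeed(childSeed(seed, 1L), sample(labels))
}
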