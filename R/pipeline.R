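#' Full-pipeline configuration
#'
#' @param nTrain training corpus size (class mix from
#'   \code{synth$classMix}; default 300, 100 per class).
#' @param prospectiveCounts named clip counts for the prospective-style
#'   synthetic set (default 28 normal / 31 crackles / 31 wheezing).
#' @param K cross-validation fold count.
#' @param seed master seed; all stage seeds are derived from it (the
#'   prospective corpus uses a disjoint seed stream).
#' @param synth a [synthConfig()].
#' @param denoise a [denoiseConfig()].
#' @param features a [featureConfig()].
#' @param mode MFCC aggregation mode.
#' @param tasks tasks to run (integers 1-4).
#' @param averaging metric averaging mode.
#' @param umap an [embeddingConfig()].
#' @param doUmap compute UMAP embeddings and plots (needs python +
#'   umap-learn).
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(nTrain = 300,
                           prospectiveCounts = c(normal = 28,
                                                 crackles = 31,
                                                 wheezing = 31),
                           K = 10, seed = 1,
                           synth = synthConfig(),
                           denoise = denoiseConfig(),
                           features = featureConfig(),
                           mode = "mean_std", tasks = 1:4,
                           averaging = "macro",
                           umap = embeddingConfig(),
                           doUmap = TRUE) {
  stopIf(nTrain < 2, "nTrain must be >= 2")
  stopIf(!all(tasks %in% 1:4), "tasks must be integers in 1-4")
  structure(list(nTrain = as.integer(nTrain),
                 prospectiveCounts = prospectiveCounts,
                 K = as.integer(K), seed = seed, synth = synth,
                 denoise = denoise, features = features, mode = mode,
                 tasks = tasks, averaging = averaging, umap = umap,
                 doUmap = isTRUE(doUmap)),
            class = "PipelineConfig")
}

# Streaming synth -> preprocess -> featurize, one clip at a time.
synthFeatures <- function(labels, synthCfg, denoiseCfg, featureCfg,
                          mode, seed, idPrefix = "clip") {
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    cs <- childSeed(seed, 10L + i)
    clip <- synthClip(labels[i], synthCfg, seed = cs,
                      clipId = sprintf("%s_%05d", idPrefix, i))
    w <- preprocessClip(clip, denoiseCfg)
    v <- aggregateFeatures(mfcc(w, featureCfg), mode)
    rows[[i]] <- c(list(clip_id = clipId(clip), label = clipLabel(clip)),
                   as.list(v))
  }
  do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
}

metricsAsList <- function(m)
  list(accuracy = m$accuracy, precision = m$precision,
       recall = m$recall, f1 = m$f1)

#' Run the complete pipeline on synthetic data
#'
#' Synthesizes a training corpus and a prospective-style corpus,
#' featurizes both (denoise, 6-s window, 40 MFCCs, mean/SD
#' aggregation), runs stratified K-fold cross-validation for each
#' requested binary task, pools every fold's SVMs into the overall
#' nested ensemble, evaluates it on the prospective set, optionally
#' embeds the training features with UMAP, and writes all artifacts
#' plus a JSON summary under \code{outDir}.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, the summary list (also written as
#'   \code{summary.json}).
#' @export
runAll <- function(config = pipelineConfig(), outDir, quiet = FALSE) {
  stopIf(missing(outDir), "outDir is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stopIf(!dir.exists(outDir), "cannot create output directory '%s'", outDir)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  seed <- config$seed

  say("[synth] training corpus: %d clips (seed %d)", config$nTrain, seed)
  trainLabels <- corpusLabels(config$synth$classMix, config$nTrain, seed)
  trainFeat <- stage("featurize-train",
    synthFeatures(trainLabels, config$synth, config$denoise,
                  config$features, config$mode, seed, "train"))
  prosLabels <- rep(names(config$prospectiveCounts),
                    times = config$prospectiveCounts)
  prosSeed <- childSeed(seed, 900001L)
  say("[synth] prospective corpus: %d clips (seed %d)",
      length(prosLabels), prosSeed)
  prosFeat <- stage("featurize-prospective",
    synthFeatures(prosLabels, config$synth, config$denoise,
                  config$features, config$mode, prosSeed, "pros"))
  utils::write.csv(trainFeat, file.path(outDir, "features_train.csv"),
                   row.names = FALSE)
  utils::write.csv(prosFeat, file.path(outDir, "features_prospective.csv"),
                   row.names = FALSE)

  Xtr <- featureMatrix(trainFeat)
  Xpr <- featureMatrix(prosFeat)
  taskResults <- list()
  for (t in config$tasks) {
    ts <- taskSpec(t)
    say("[cv] task %d (%s), K = %d, %d member(s) per fold",
        t, ts$taskId, config$K, ts$defaultMembers)
    cv <- stage(paste0("cv-task", t),
      crossValidate(Xtr, trainFeat$label, ts, K = config$K,
                    seed = childSeed(seed, 5000L + t),
                    averaging = config$averaging))
    overall <- buildOverallEnsemble(cv$ensembles)
    pros <- stage(paste0("prospective-task", t),
      evaluateProspective(overall, Xpr, prosFeat$label,
                          averaging = config$averaging))
    taskResults[[ts$taskId]] <- list(
      task = t, K = cv$K, membersPerFold = ts$defaultMembers,
      overallMembers = nMembers(overall),
      perFold = lapply(cv$perFold, metricsAsList),
      pooled = metricsAsList(cv$pooled),
      prospective = metricsAsList(pros))
  }

  if (config$doUmap) {
    say("[umap] embedding training + prospective features")
    emb <- stage("umap", umapEmbed(rbind(trainFeat, prosFeat),
                                   config$umap))
    utils::write.csv(emb, file.path(outDir, "umap_embedding.csv"),
                     row.names = FALSE)
    stage("umap-plot",
          plotEmbedding(emb, file.path(outDir, "umap_embedding.png")))
  }

  summary <- list(
    seed = seed,
    nTrain = config$nTrain,
    nProspective = length(prosLabels),
    K = config$K,
    featureConfig = unclass(config$features),
    configFingerprint = contentFingerprint(
      seed, config$nTrain, config$K, unlist(config$features)),
    tasks = taskResults)
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] summary written to %s", file.path(outDir, "summary.json"))
  invisible(summary)
}

#' Persist / restore a trained ensemble
#'
#' Writes a directory with JSON metadata (task, seeds, feature
#' dimension, fingerprint) and the serialized members.
#'
#' @param ensemble an [SVMEnsemble-class].
#' @param dir archive directory.
#' @return \code{dir} (saveEnsemble) or the restored
#'   [SVMEnsemble-class] (loadEnsemble).
#' @export
saveEnsemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(format = 1L, taskId = ensemble@taskId,
         positiveClass = ensemble@positiveClass,
         classLevels = ensemble@classLevels,
         memberSeeds = ensemble@memberSeeds,
         featureDim = ensemble@featureDim,
         fingerprint = ensemble@fingerprint),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(ensemble@members, file.path(dir, "members.rds"))
  invisible(dir)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  new("SVMEnsemble", members = readRDS(file.path(dir, "members.rds")),
      taskId = meta$taskId, positiveClass = meta$positiveClass,
      classLevels = meta$classLevels, memberSeeds = meta$memberSeeds,
      featureDim = as.integer(meta$featureDim),
      fingerprint = meta$fingerprint)
}
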