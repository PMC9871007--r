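#' UMAP embedding configuration
#'
#' Defaults follow the study settings: 20 neighbors, minimum distance
#' 0.3, cosine metric. The embedding is seeded for reproducibility.
#'
#' @param nNeighbors neighborhood size (>= 2).
#' @param minDist minimum embedding distance (>= 0).
#' @param metric distance metric name understood by umap-learn.
#' @param seed integer random state.
#' @return a list of class \code{"EmbeddingConfig"}.
#' @export
embeddingConfig <- function(nNeighbors = 20, minDist = 0.3,
                            metric = "cosine", seed = 1) {
  stopIf(nNeighbors < 2, "nNeighbors must be >= 2")
  stopIf(minDist < 0, "minDist must be >= 0")
  structure(list(nNeighbors = as.integer(nNeighbors), minDist = minDist,
                 metric = metric, seed = as.integer(seed)),
            class = "EmbeddingConfig")
}

#' Render a mel spectrogram image
#'
#' Log-power (dB) mel spectrogram with an 80 dB dynamic-range floor,
#' written as a PNG; the time axis spans the 6-s window and the
#' frequency axis carries mel-spaced Hz labels.
#'
#' @param window a [FixedWindow-class].
#' @param config a [featureConfig()].
#' @param outPath PNG output path, or NULL to skip writing and only
#'   return the rendered matrix.
#' @param main plot title.
#' @return invisibly, a list with the dB matrix (\code{db}, mel bands x
#'   frames), frame times (\code{time}, s) and band center frequencies
#'   (\code{freq}, Hz).
#' @export
renderMelSpectrogram <- function(window, config = featureConfig(),
                                 outPath = NULL, main = "") {
  M <- melSpectrogram(window, config)
  db <- 10 * log10(pmax(M, config$amin))
  db <- pmax(db, max(db) - 80)  # 80 dB dynamic range
  tm <- attr(M, "time")
  fq <- attr(M, "centerHz")
  if (!is.null(outPath)) {
    ok <- tryCatch({
      grDevices::png(outPath, width = 900, height = 500)
      TRUE
    }, error = function(e) FALSE)
    if (!ok)
      stop(sprintf("cannot write spectrogram image to '%s'", outPath),
           call. = FALSE)
    on.exit(grDevices::dev.off())
    graphics::image(tm, seq_along(fq), t(db),
                    col = grDevices::hcl.colors(128, "inferno"),
                    xlab = "Time (s)", ylab = "Mel band", main = main,
                    useRaster = TRUE)
    at <- pretty(seq_along(fq), 6)
    at <- at[at >= 1 & at <= length(fq)]
    graphics::axis(4, at = at, labels = sprintf("%.0f", fq[at]))
  }
  invisible(list(db = db, time = tm, freq = fq))
}

#' 2-D UMAP embedding of feature vectors
#'
#' Embeds the rows of a feature table with uniform manifold
#' approximation and projection, using the umap-learn reference
#' implementation through the system \code{python} interpreter (see
#' \code{SystemRequirements}). Coordinates are deterministic given the
#' seed, and the output row order matches the input.
#'
#' @param features a feature table from [featurizeCorpus()] (clip_id
#'   and label columns are carried through) or a bare numeric matrix.
#' @param config an [embeddingConfig()].
#' @param python path to the python interpreter.
#' @return data.frame with columns UMAP1, UMAP2 and (when available)
#'   clip_id and label; the config is attached as attribute
#'   \code{"config"}.
#' @export
umapEmbed <- function(features, config = embeddingConfig(),
                      python = Sys.which("python")) {
  stopIf(!nzchar(python),
         "no python interpreter found; umapEmbed needs python + umap-learn")
  X <- if (is.data.frame(features)) featureMatrix(features)
       else as.matrix(features)
  stopIf(nrow(X) < config$nNeighbors + 1,
         "need at least nNeighbors + 1 = %d rows, got %d",
         config$nNeighbors + 1, nrow(X))
  inCsv <- tempfile(fileext = ".csv")
  outCsv <- tempfile(fileext = ".csv")
  on.exit(unlink(c(inCsv, outCsv)))
  utils::write.table(X, inCsv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- system.file("python", "umap_embed.py", package = "auscult")
  stopIf(!nzchar(script), "bundled umap_embed.py not found")
  res <- suppressWarnings(system2(
    python,
    c(shQuote(script), shQuote(inCsv), shQuote(outCsv),
      config$nNeighbors, config$minDist, shQuote(config$metric),
      config$seed),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop(sprintf("umap-learn failed:\n%s", paste(res, collapse = "\n")),
         call. = FALSE)
  coords <- utils::read.csv(outCsv, header = FALSE)
  names(coords) <- c("UMAP1", "UMAP2")
  stopIf(nrow(coords) != nrow(X), "embedding row count mismatch")
  if (is.data.frame(features)) {
    if ("clip_id" %in% names(features)) coords$clip_id <- features$clip_id
    if ("label" %in% names(features)) coords$label <- features$label
  }
  attr(coords, "config") <- config
  coords
}

#' Scatter plot of a 2-D embedding
#'
#' @param embedding a [umapEmbed()] result with a label column.
#' @param outPath PNG output path.
#' @return invisibly, \code{outPath}.
#' @export
plotEmbedding <- function(embedding, outPath) {
  stopIf(!"label" %in% names(embedding), "embedding has no label column")
  grDevices::png(outPath, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  cls <- factor(embedding$label)
  graphics::plot(embedding$UMAP1, embedding$UMAP2,
                 col = as.integer(cls) + 1, pch = 19, cex = 0.8,
                 xlab = "UMAP 1", ylab = "UMAP 2")
  graphics::legend("topright", legend = levels(cls),
                   col = seq_len(nlevels(cls)) + 1, pch = 19)
  invisible(outPath)
}
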