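# The iterative screening loop: train on the full noisy set, flag the
# images the trained model misclassifies, delete them, repeat. The
# mechanism relies on the class boundary lying in a low-density region:
# within a short training budget the model learns each class's common
# features from the high-density bulk, so records whose observed label
# contradicts their appearance (label noise) or whose content carries no
# class signal (background noise) end up misclassified and are flagged.

#' Construct a CleanerConfig
#'
#' Defaults follow the screening protocol: batches of 32 images at
#' 224 x 224, cross-entropy loss with an AdamW optimizer, learning rate
#' halved when the loss has not decreased over 200 batches, at most 10
#' screening rounds, stopping when under 0.5 percent of the current set
#' is flagged in a round. Desk-scale runs lower \code{imageSize} (the
#' synthetic benchmark uses 32).
#'
#' @param maxRounds,stopThreshold,epochsPerRound,batchSize,imageSize
#'   loop and data parameters; see \linkS4class{CleanerConfig}.
#' @param initialLearningRate,plateauWindow,lrHalvingFactor,minLearningRate,weightDecay
#'   optimizer parameters.
#' @param baseSeed seed; round r uses \code{baseSeed + r}.
#' @return a \linkS4class{CleanerConfig}.
#' @export
cleanerConfig <- function(maxRounds = 10L, stopThreshold = 0.005,
                          epochsPerRound = 5L, batchSize = 32L,
                          imageSize = 224L, initialLearningRate = 1e-3,
                          plateauWindow = 200L, lrHalvingFactor = 0.5,
                          minLearningRate = 1e-6, weightDecay = 0.01,
                          baseSeed = 1L) {
  new("CleanerConfig", maxRounds = as.integer(maxRounds),
      stopThreshold = stopThreshold,
      epochsPerRound = as.integer(epochsPerRound),
      batchSize = as.integer(batchSize), imageSize = as.integer(imageSize),
      initialLearningRate = initialLearningRate,
      plateauWindow = as.integer(plateauWindow),
      lrHalvingFactor = lrHalvingFactor,
      minLearningRate = minLearningRate, weightDecay = weightDecay,
      baseSeed = as.integer(baseSeed))
}

# Read one PNG as the internal (S*S, 3) pixel matrix (row-major spatial,
# w fastest), resizing when needed. NULL on read failure.
.readImagePixels <- function(path, S) {
  a <- tryCatch(png::readPNG(path), error = function(e) NULL,
                warning = function(w) NULL)
  if (is.null(a)) return(NULL)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[1] != S || dim(a)[2] != S) {
    img <- EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
    a <- aperm(as.array(EBImage::resize(img, w = S, h = S)), c(2, 1, 3))
  }
  cbind(as.vector(t(a[, , 1])), as.vector(t(a[, , 2])),
        as.vector(t(a[, , 3])))
}

# Load every manifest image into an array (S*S, 3, N). Unreadable files
# are reported in `bad` (by id) with zero-filled pixels.
.loadImages <- function(manifest, S) {
  rec <- records(manifest)
  N <- nrow(rec)
  X <- array(0, dim = c(S * S, 3L, N))
  bad <- character(0)
  for (i in seq_len(N)) {
    px <- .readImagePixels(rec$filepath[i], S)
    if (is.null(px)) bad <- c(bad, rec$image_id[i]) else X[, , i] <- px
  }
  list(x = X, bad = bad)
}

.labelIndex <- function(manifest) {
  match(records(manifest)$observed_label, classNames(manifest)) - 1L
}

#' Train the screening model for one round
#'
#' Builds a fresh model from \code{spec} (seed
#' \code{baseSeed + roundIndex}) and trains it on every image of the
#' manifest — the set to be cleaned is its own training set — for
#' \code{epochsPerRound} full passes with cross-entropy loss, an AdamW
#' optimizer, \code{batchSize} images per step, images resized to
#' \code{imageSize} squared, no augmentation. Deterministic given the
#' config and round index.
#'
#' @param manifest a non-empty \linkS4class{DatasetManifest} with both
#'   classes present.
#' @param spec the \linkS4class{ArchitectureSpec} to train.
#' @param config a \linkS4class{CleanerConfig}.
#' @param roundIndex 1-based round number (seeds the re-initialization).
#' @param images optional preloaded result of the internal image loader;
#'   used by \code{\link{cleanDataset}} to avoid re-reading files.
#' @return list with \code{model} (a trained
#'   \linkS4class{NeuralClassifier}), \code{lossHistory} (per-batch
#'   losses) and \code{finalLearningRate}.
#' @export
trainOneRound <- function(manifest, spec, config, roundIndex = 1L,
                          images = NULL) {
  stopifnot(is(manifest, "DatasetManifest"), is(spec, "ArchitectureSpec"),
            is(config, "CleanerConfig"))
  if (nRecords(manifest) == 0L) stop("manifest is empty")
  y <- .labelIndex(manifest)
  if (length(unique(y)) < 2L)
    stop("class_exhausted: both classes must be present for training")
  if (spec@inputSize != config@imageSize)
    stop("spec inputSize (", spec@inputSize, ") must match config imageSize (",
         config@imageSize, ")")
  if (is.null(images)) images <- .loadImages(manifest, config@imageSize)
  seed <- config@baseSeed + as.integer(roundIndex)
  model <- buildModel(spec, seed = seed)
  fit <- .nnFit(model, images$x, y, config, seed = seed)
  list(model = fit$model, lossHistory = fit$lossHistory,
       finalLearningRate = fit$finalLr)
}

#' Flag the images a trained model misclassifies
#'
#' Classifies every manifest image in inference mode (no augmentation,
#' batch-norm running statistics) and returns the ids whose predicted
#' class — the argmax of the logits, with exact ties resolving to class
#' 0 — differs from the observed label. Records whose image file cannot
#' be read are flagged as well (they are background-noise candidates by
#' definition) and reported via a warning.
#'
#' @param model a trained \linkS4class{NeuralClassifier}.
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param images optional preloaded images (internal loader format).
#' @return character vector of flagged image ids.
#' @export
flagMisclassified <- function(model, manifest, images = NULL) {
  stopifnot(is(model, "NeuralClassifier"), is(manifest, "DatasetManifest"))
  if (model@spec@numClasses != 2L)
    stop("screening assumes a two-class model")
  rec <- records(manifest)
  if (nrow(rec) == 0L) return(character(0))
  if (is.null(images)) images <- .loadImages(manifest, model@spec@inputSize)
  pred <- .nnPredict(model, images$x)
  obs <- .labelIndex(manifest)
  flagged <- rec$image_id[pred != obs]
  if (length(images$bad) > 0) {
    warning(length(images$bad), " unreadable image file(s) flagged: ",
            paste(utils::head(images$bad, 5), collapse = ", "))
    flagged <- union(flagged, images$bad)
  }
  flagged
}

#' Iteratively clean a two-class image dataset
#'
#' Runs the screening loop: (1) train a freshly initialized model on all
#' remaining images; (2) flag every image the trained model
#' misclassifies and delete the flagged records; (3) repeat. The loop
#' stops when the flagged fraction of the current set falls below
#' \code{stopThreshold} (\code{threshold_reached}), after
#' \code{maxRounds} rounds (\code{max_rounds}), or when a class runs out
#' of images (\code{class_exhausted}, reported rather than thrown).
#' Deletion is permanent within a run. The full run is reproducible
#' bit-for-bit given \code{baseSeed}.
#'
#' @param manifest a \linkS4class{DatasetManifest} with at least 2
#'   images per class.
#' @param spec the \linkS4class{ArchitectureSpec} of the screening model;
#'   its \code{inputSize} must equal the config's \code{imageSize}.
#' @param config a \linkS4class{CleanerConfig}.
#' @param verbose print one log line per round.
#' @return a \linkS4class{CleaningReport}.
#' @examples
#' \donttest{
#' m <- generateSyntheticDataset(60, 6, imageSize = 32, seed = 1,
#'                               dir = tempfile())
#' m <- injectIntraClassNoise(m, 2, seed = 2)
#' cfg <- cleanerConfig(imageSize = 32, maxRounds = 3, baseSeed = 1)
#' rep <- cleanDataset(m, smallReferenceSpec(32, 2), cfg)
#' stopReason(rep)
#' }
#' @export
cleanDataset <- function(manifest, spec, config = cleanerConfig(),
                         verbose = FALSE) {
  stopifnot(is(manifest, "DatasetManifest"), is(spec, "ArchitectureSpec"),
            is(config, "CleanerConfig"))
  cn <- classNames(manifest)
  counts <- table(factor(records(manifest)$observed_label, levels = cn))
  if (any(counts < 2L))
    stop("need at least 2 images per class to start cleaning")
  images <- .loadImages(manifest, config@imageSize)
  current <- manifest
  keep <- seq_len(nRecords(manifest))   # indices into the loaded array
  roundRows <- list()
  perRound <- list()
  stop_reason <- "max_rounds"
  for (r in seq_len(config@maxRounds)) {
    y <- .labelIndex(current)
    if (length(unique(y)) < 2L) {
      stop_reason <- "class_exhausted"
      break
    }
    sizeBefore <- nRecords(current)
    sub <- list(x = images$x[, , keep, drop = FALSE],
                bad = intersect(images$bad, records(current)$image_id))
    fit <- trainOneRound(current, spec, config, roundIndex = r,
                         images = sub)
    flagged <- suppressWarnings(
      flagMisclassified(fit$model, current, images = sub))
    frac <- length(flagged) / sizeBefore
    roundRows[[r]] <- data.frame(
      round_index = r, dataset_size_before = sizeBefore,
      flagged_count = length(flagged), flagged_fraction = frac,
      final_learning_rate = fit$finalLearningRate)
    perRound[[r]] <- flagged
    if (verbose)
      message(sprintf(
        "round %d: %d images, %d flagged (%.2f%%), final lr %.2e",
        r, sizeBefore, length(flagged), 100 * frac,
        fit$finalLearningRate))
    drop <- records(current)$image_id %in% flagged
    current <- .newManifest(records(current)[!drop, , drop = FALSE], cn)
    keep <- keep[!drop]
    if (frac < config@stopThreshold) {
      stop_reason <- "threshold_reached"
      break
    }
    remaining <- table(factor(records(current)$observed_label, levels = cn))
    if (any(remaining == 0L)) {
      stop_reason <- "class_exhausted"
      break
    }
  }
  rounds <- if (length(roundRows) > 0) do.call(rbind, roundRows) else
    data.frame(round_index = integer(0), dataset_size_before = integer(0),
               flagged_count = integer(0), flagged_fraction = numeric(0),
               final_learning_rate = numeric(0))
  new("CleaningReport", rounds = rounds, flaggedIds = perRound,
      deletedIds = unlist(perRound, use.names = FALSE) %||% character(0),
      stopReason = stop_reason, surviving = current, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
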