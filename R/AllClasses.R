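#' @import methods
NULL

.NOISE_TAGS <- c("clean", "intra_label", "extra_label", "background")
.MANIFEST_COLS <- c("image_id", "filepath", "observed_label", "group_id",
                    "true_label", "noise_tag")
.LAYER_KINDS <- c("conv", "batch_norm", "activation", "max_pool",
                  "global_avg_pool", "fully_connected")

#' DatasetManifest: an ordered two-class image collection
#'
#' Holds one row per image: a unique id, the image file path, the observed
#' (possibly wrong) class label, a patient-like group id, the optional
#' ground-truth label, and a noise tag recording how (if at all) the record
#' was corrupted. The class listed first in \code{classNames} is class
#' index 0 throughout the package.
#'
#' @slot records data.frame with columns \code{image_id}, \code{filepath},
#'   \code{observed_label}, \code{group_id}, \code{true_label},
#'   \code{noise_tag}. Labels are stored as class names; \code{true_label}
#'   is \code{NA} when unknown (out-of-class distractors).
#' @slot classNames character of length 2 giving the two class labels in
#'   index order.
#' @export
setClass("DatasetManifest",
  representation(records = "data.frame", classNames = "character"))

setValidity("DatasetManifest", function(object) {
  rec <- object@records
  cn <- object@classNames
  if (length(cn) != 2L || anyDuplicated(cn) || any(!nzchar(cn)))
    return("classNames must be two distinct non-empty labels")
  if (!all(.MANIFEST_COLS %in% names(rec)))
    return(paste("records must have columns:",
                 paste(.MANIFEST_COLS, collapse = ", ")))
  if (nrow(rec) > 0) {
    if (anyDuplicated(rec$image_id))
      return("image_id values must be unique")
    if (!all(rec$observed_label %in% cn))
      return("observed_label values must be one of classNames")
    if (!all(is.na(rec$true_label) | rec$true_label %in% cn))
      return("true_label values must be NA or one of classNames")
    if (!all(rec$noise_tag %in% .NOISE_TAGS))
      return(paste("noise_tag must be one of:",
                   paste(.NOISE_TAGS, collapse = ", ")))
    flip <- rec$noise_tag == "intra_label"
    if (any(flip & (is.na(rec$true_label) |
                    rec$observed_label == rec$true_label)))
      return("intra_label records must have observed_label != true_label")
    cl <- rec$noise_tag == "clean"
    if (any(cl & (is.na(rec$true_label) |
                  rec$observed_label != rec$true_label)))
      return("clean records must have observed_label == true_label")
  }
  TRUE
})

#' ArchitectureSpec: a declarative layer list
#'
#' A network is described as an ordered table of layers from which both the
#' trainable model and an analytic parameter budget are derived. Supported
#' layer kinds: \code{conv} (square kernel, stride 1, same padding),
#' \code{batch_norm}, \code{activation} (ReLU), \code{max_pool} (2x2,
#' stride 2), \code{global_avg_pool}, and \code{fully_connected}.
#'
#' @slot name label for the architecture.
#' @slot layers data.frame with columns \code{kind}, \code{in}, \code{out},
#'   \code{kernel}, \code{bias}.
#' @slot numClasses number of output classes.
#' @slot inputSize expected input edge length in pixels.
#' @export
setClass("ArchitectureSpec",
  representation(name = "character", layers = "data.frame",
                 numClasses = "integer", inputSize = "integer"))

setValidity("ArchitectureSpec", function(object) {
  msg <- tryCatch({
    .specWalkShapes(object)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(msg)) return(msg)
  TRUE
})

#' CleanerConfig: parameters of the iterative screening loop
#'
#' @slot maxRounds maximum number of train-flag-delete rounds.
#' @slot stopThreshold stop once the flagged fraction of the current set
#'   falls below this value (fraction in (0,1)).
#' @slot epochsPerRound full passes over the current set per round.
#' @slot batchSize images per optimizer step.
#' @slot imageSize training resolution (pixels per side); images are
#'   resized to \code{imageSize} x \code{imageSize}.
#' @slot initialLearningRate starting AdamW learning rate.
#' @slot plateauWindow batches per loss-plateau window; the learning rate
#'   is halved when the mean loss over the latest window does not fall
#'   below the mean over the preceding window.
#' @slot lrHalvingFactor multiplicative factor on plateau (0.5).
#' @slot minLearningRate floor for the learning rate.
#' @slot weightDecay decoupled AdamW weight decay.
#' @slot baseSeed round r re-initializes the model with seed
#'   \code{baseSeed + r}, making a full run reproducible.
#' @export
setClass("CleanerConfig",
  representation(maxRounds = "integer", stopThreshold = "numeric",
                 epochsPerRound = "integer", batchSize = "integer",
                 imageSize = "integer", initialLearningRate = "numeric",
                 plateauWindow = "integer", lrHalvingFactor = "numeric",
                 minLearningRate = "numeric", weightDecay = "numeric",
                 baseSeed = "integer"))

setValidity("CleanerConfig", function(object) {
  if (object@maxRounds < 1L) return("maxRounds must be >= 1")
  if (!(object@stopThreshold > 0 && object@stopThreshold < 1))
    return("stopThreshold must be in (0, 1)")
  if (object@epochsPerRound < 1L) return("epochsPerRound must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@imageSize < 4L) return("imageSize must be >= 4")
  if (object@initialLearningRate <= 0) return("initialLearningRate must be > 0")
  if (object@plateauWindow < 1L) return("plateauWindow must be >= 1")
  if (!(object@lrHalvingFactor > 0 && object@lrHalvingFactor <= 1))
    return("lrHalvingFactor must be in (0, 1]")
  if (object@minLearningRate <= 0) return("minLearningRate must be > 0")
  if (object@weightDecay < 0) return("weightDecay must be >= 0")
  TRUE
})

#' NeuralClassifier: a built (and possibly trained) network
#'
#' Parameters are plain numeric matrices/vectors grouped per layer;
#' batch-norm running statistics live in \code{state}. The trainable
#' parameter count of a built model always equals
#' \code{parameterBudget(spec(model))}.
#'
#' @slot spec the \linkS4class{ArchitectureSpec} the model was built from.
#' @slot params per-layer list of trainable arrays (W, b, gamma, beta).
#' @slot state per-layer list of non-trainable state (running mean/var).
#' @slot seed integer seed used for weight initialization.
#' @export
setClass("NeuralClassifier",
  representation(spec = "ArchitectureSpec", params = "list",
                 state = "list", seed = "integer"))

#' CleaningReport: the outcome of an iterative cleaning run
#'
#' @slot rounds data.frame with one row per screening round:
#'   \code{round_index}, \code{dataset_size_before}, \code{flagged_count},
#'   \code{flagged_fraction}, \code{final_learning_rate}.
#' @slot flaggedIds list of per-round character vectors of flagged ids
#'   (pairwise disjoint).
#' @slot deletedIds union of the per-round flagged sets.
#' @slot stopReason one of \code{threshold_reached}, \code{max_rounds},
#'   \code{class_exhausted}.
#' @slot surviving the \linkS4class{DatasetManifest} of records never
#'   flagged.
#' @slot config the \linkS4class{CleanerConfig} used (resolved defaults).
#' @export
setClass("CleaningReport",
  representation(rounds = "data.frame", flaggedIds = "list",
                 deletedIds = "character", stopReason = "character",
                 surviving = "DatasetManifest", config = "CleanerConfig"))

setValidity("CleaningReport", function(object) {
  if (!object@stopReason %in% c("threshold_reached", "max_rounds",
                                "class_exhausted"))
    return("unknown stopReason")
  ids <- unlist(object@flaggedIds, use.names = FALSE)
  if (anyDuplicated(ids))
    return("per-round flagged sets must be disjoint")
  if (!setequal(ids, object@deletedIds))
    return("deletedIds must be the union of per-round flagged sets")
  TRUE
})

#' CleaningEvaluation: screening counts and derived percentages
#'
#' Counts: \code{all} images in the dataset, \code{atw} true error images
#' present, \code{mw} flagged ("possible wrong") images, \code{tw} flagged
#' images that are true errors. Percentages (0-100 scale): error rate
#' \code{eRate} = 100*ATW/ALL, filtering accuracy \code{fAcc} = 100*TW/MW
#' (precision of the screen), filtering recall \code{fRec} = 100*TW/ATW.
#'
#' @slot all,atw,mw,tw integer counts.
#' @slot eRate,fAcc,fRec exact (unrounded) percentages; \code{fAcc} or
#'   \code{fRec} is \code{NA} when its denominator is zero.
#' @export
setClass("CleaningEvaluation",
  representation(all = "integer", atw = "integer", mw = "integer",
                 tw = "integer", eRate = "numeric", fAcc = "numeric",
                 fRec = "numeric"))

setValidity("CleaningEvaluation", function(object) {
  if (object@all <= 0L) return("all must be > 0")
  if (object@atw < 0L || object@atw > object@all)
    return("need 0 <= atw <= all")
  if (object@mw < 0L || object@mw > object@all)
    return("need 0 <= mw <= all")
  if (object@tw < 0L || object@tw > object@mw || object@tw > object@atw)
    return("need 0 <= tw <= min(mw, atw)")
  pct <- c(object@eRate, object@fAcc, object@fRec)
  if (any(!is.na(pct) & (pct < 0 | pct > 100)))
    return("percentages must lie in [0, 100]")
  TRUE
})
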