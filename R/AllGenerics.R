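#' Accessors for LabelSweep classes
#'
#' Small generics giving read access to the S4 containers: manifest
#' records and class names, report rounds and deleted ids, model
#' parameter counts.
#'
#' @param object a LabelSweep S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("classNames", function(object) standardGeneric("classNames"))

#' @rdname accessors
#' @export
setGeneric("nRecords", function(object) standardGeneric("nRecords"))

#' @rdname accessors
#' @export
setGeneric("rounds", function(object) standardGeneric("rounds"))

#' @rdname accessors
#' @export
setGeneric("deletedIds", function(object) standardGeneric("deletedIds"))

#' @rdname accessors
#' @export
setGeneric("flaggedIds", function(object) standardGeneric("flaggedIds"))

#' @rdname accessors
#' @export
setGeneric("stopReason", function(object) standardGeneric("stopReason"))

#' @rdname accessors
#' @export
setGeneric("survivingManifest",
           function(object) standardGeneric("survivingManifest"))

#' Analytic trainable-parameter budget of an architecture
#'
#' Sums learnable parameters layer by layer: a k x k convolution with
#' C_in inputs and C_out outputs contributes C_in * C_out * k^2 (+ C_out
#' with bias), batch norm contributes 2 * channels (scale and shift), a
#' fully connected layer contributes in * out (+ out with bias); pooling
#' and activations contribute nothing.
#'
#' @param object an \linkS4class{ArchitectureSpec}.
#' @return integer-valued numeric parameter count.
#' @examples
#' parameterBudget(vggNinSpec(2))    # 19982402
#' parameterBudget(vgg16bnSpec(2))   # 134277186
#' @export
setGeneric("parameterBudget",
           function(object) standardGeneric("parameterBudget"))

#' Count of trainable parameters held by a built model
#'
#' Counts the actual numeric entries of every weight, bias and batch-norm
#' scale/shift array of a \linkS4class{NeuralClassifier}; running
#' statistics are not trainable and are excluded. Always equal to
#' \code{\link{parameterBudget}} of the model's spec.
#'
#' @param object a \linkS4class{NeuralClassifier}.
#' @return integer-valued numeric count.
#' @export
setGeneric("trainableParameters",
           function(object) standardGeneric("trainableParameters"))

#' @rdname accessors
#' @export
setMethod("records", "DatasetManifest", function(object) object@records)

#' @rdname accessors
#' @export
setMethod("classNames", "DatasetManifest", function(object) object@classNames)

#' @rdname accessors
#' @export
setMethod("nRecords", "DatasetManifest", function(object) nrow(object@records))

#' @rdname accessors
#' @export
setMethod("rounds", "CleaningReport", function(object) object@rounds)

#' @rdname accessors
#' @export
setMethod("deletedIds", "CleaningReport", function(object) object@deletedIds)

#' @rdname accessors
#' @export
setMethod("flaggedIds", "CleaningReport", function(object) object@flaggedIds)

#' @rdname accessors
#' @export
setMethod("stopReason", "CleaningReport", function(object) object@stopReason)

#' @rdname accessors
#' @export
setMethod("survivingManifest", "CleaningReport",
          function(object) object@surviving)

setMethod("show", "DatasetManifest", function(object) {
  rec <- object@records
  cat(sprintf("DatasetManifest: %d records, classes [%s]\n", nrow(rec),
              paste(object@classNames, collapse = ", ")))
  if (nrow(rec) > 0) {
    tab <- table(factor(rec$observed_label, levels = object@classNames))
    cat(sprintf("  observed labels: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    nt <- table(factor(rec$noise_tag, levels = .NOISE_TAGS))
    cat(sprintf("  noise tags: %s\n",
                paste(sprintf("%s=%d", names(nt), nt), collapse = ", ")))
    cat(sprintf("  groups: %d\n", length(unique(rec$group_id))))
  }
  invisible(NULL)
})

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf("ArchitectureSpec '%s': %d layers, %d classes, input %dx%d\n",
              object@name, nrow(object@layers), object@numClasses,
              object@inputSize, object@inputSize))
  cat(sprintf("  parameter budget: %s\n",
              format(parameterBudget(object), big.mark = ",",
                     scientific = FALSE)))
  invisible(NULL)
})

setMethod("show", "NeuralClassifier", function(object) {
  cat(sprintf("NeuralClassifier on '%s' (seed %d): %s trainable parameters\n",
              object@spec@name, object@seed,
              format(trainableParameters(object), big.mark = ",",
                     scientific = FALSE)))
  invisible(NULL)
})

setMethod("show", "CleaningReport", function(object) {
  cat(sprintf("CleaningReport: %d round(s), %d deleted, stop: %s\n",
              nrow(object@rounds), length(object@deletedIds),
              object@stopReason))
  if (nrow(object@rounds) > 0) print(object@rounds, row.names = FALSE)
  cat(sprintf("  surviving records: %d\n", nRecords(object@surviving)))
  invisible(NULL)
})

setMethod("show", "CleaningEvaluation", function(object) {
  cat(sprintf("CleaningEvaluation: ALL=%d ATW=%d MW=%d TW=%d\n",
              object@all, object@atw, object@mw, object@tw))
  cat(sprintf("  error rate  E_rate = %s\n", formatPercent(object@eRate)))
  cat(sprintf("  accuracy    F_acc  = %s\n", formatPercent(object@fAcc)))
  cat(sprintf("  recall      F_rec  = %s\n", formatPercent(object@fRec)))
  invisible(NULL)
})

setMethod("show", "CleanerConfig", function(object) {
  cat("CleanerConfig:\n")
  for (nm in slotNames(object))
    cat(sprintf("  %s = %s\n", nm, format(slot(object, nm))))
  invisible(NULL)
})
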