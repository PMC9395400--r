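# Screening evaluation indicators.
#
# Three percentages summarize a screen of a dataset of ALL images that
# truly contains ATW erroneous ones, when the screen flags MW "possible
# wrong" images of which TW are truly erroneous:
#   error rate          E_rate = 100 * ATW / ALL
#   filtering accuracy  F_acc  = 100 * TW  / MW   (precision)
#   filtering recall    F_rec  = 100 * TW  / ATW
# All values are kept as exact ratios internally; rounding happens only
# at display time (see formatPercent).

.checkCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(name, " must be a single non-negative integer count")
  as.numeric(x)
}

#' Error rate of a dataset
#'
#' Percentage of a dataset's images that are truly erroneous:
#' \code{100 * atw / allCount}.
#'
#' @param atw count of true error images present (ATW).
#' @param allCount total image count (ALL), > 0.
#' @return percentage on the 0-100 scale.
#' @examples
#' errorRate(100, 3216)  # 3.1% regime
#' @export
errorRate <- function(atw, allCount) {
  atw <- .checkCount(atw, "atw")
  allCount <- .checkCount(allCount, "allCount")
  if (allCount == 0) stop("allCount must be > 0")
  if (atw > allCount) stop("atw cannot exceed allCount")
  100 * atw / allCount
}

#' Filtering accuracy (precision of the screen)
#'
#' Percentage of flagged "possible wrong" images that are truly
#' erroneous: \code{100 * tw / mw}.
#'
#' @param tw count of flagged images that are true errors (TW).
#' @param mw count of flagged images (MW), > 0.
#' @return percentage on the 0-100 scale.
#' @examples
#' filteringAccuracy(93, 192)  # 48.4375
#' @export
filteringAccuracy <- function(tw, mw) {
  tw <- .checkCount(tw, "tw")
  mw <- .checkCount(mw, "mw")
  if (mw == 0) stop("mw must be > 0: accuracy is undefined with no flags")
  if (tw > mw) stop("tw cannot exceed mw")
  100 * tw / mw
}

#' Filtering recall of the screen
#'
#' Percentage of all true error images that were flagged:
#' \code{100 * tw / atw}.
#'
#' @param tw count of flagged images that are true errors (TW).
#' @param atw count of true error images present (ATW), > 0.
#' @return percentage on the 0-100 scale.
#' @examples
#' filteringRecall(93, 100)  # 93
#' @export
filteringRecall <- function(tw, atw) {
  tw <- .checkCount(tw, "tw")
  atw <- .checkCount(atw, "atw")
  if (atw == 0) stop("atw must be > 0: recall is undefined with no errors")
  if (tw > atw) stop("tw cannot exceed atw")
  100 * tw / atw
}

#' Round a percentage half-away-from-zero
#'
#' Display rounding for the screening percentages: internal values are
#' exact ratios; reports round half away from zero at the requested
#' number of decimals (default one decimal; use \code{digits = 0} for
#' integer-percent display).
#'
#' @param x numeric percentage(s).
#' @param digits decimal places to keep.
#' @return rounded numeric.
#' @examples
#' roundPercent(filteringAccuracy(93, 192))      # 48.4
#' roundPercent(filteringAccuracy(54, 302), 0)   # 18
#' @export
roundPercent <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' @rdname roundPercent
#' @param suffix string appended after the number (default \code{"\%"}).
#' @return \code{formatPercent}: character representation with trailing
#'   zeros trimmed (e.g. \code{"48.4\%"}, \code{"93\%"}).
#' @export
formatPercent <- function(x, digits = 1L, suffix = "%") {
  ifelse(is.na(x), "NA",
         paste0(sub("\\.?0+$", "",
                    formatC(roundPercent(x, digits),
                            format = "f", digits = digits)),
                suffix))
}

#' Evaluate a cleaning run against ground truth
#'
#' Joins a flagged id set to the manifest's noise tags and fills a
#' \linkS4class{CleaningEvaluation}: ALL is the manifest size, ATW the
#' records whose noise tag marks a true error, MW the flagged count, TW
#' the flagged records that are true errors, plus the three derived
#' percentages. Which noise tags count as "true error" is configurable so
#' per-noise-type results can be reported separately.
#'
#' @param flagged character vector of flagged image ids (each must exist
#'   in the manifest).
#' @param manifest a \linkS4class{DatasetManifest} carrying ground-truth
#'   noise tags.
#' @param errorTags noise tags counted as true errors; default all three
#'   noise classes (\code{intra_label}, \code{extra_label},
#'   \code{background}).
#' @return a \linkS4class{CleaningEvaluation}.
#' @examples
#' # a perfect screen flags exactly the corrupted records
#' m <- generateSyntheticDataset(10, 4, imageSize = 16, seed = 1,
#'                               dir = tempfile())
#' m <- injectIntraClassNoise(m, 2, seed = 2)
#' bad <- records(m)$image_id[records(m)$noise_tag != "clean"]
#' evaluateCleaning(bad, m)
#' @export
evaluateCleaning <- function(flagged, manifest,
                             errorTags = c("intra_label", "extra_label",
                                           "background")) {
  stopifnot(is(manifest, "DatasetManifest"))
  rec <- records(manifest)
  if (nrow(rec) == 0) stop("manifest is empty")
  flagged <- unique(as.character(flagged))
  missing <- setdiff(flagged, rec$image_id)
  if (length(missing) > 0)
    stop("flagged id(s) absent from manifest: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (any(is.na(rec$noise_tag)))
    stop("manifest lacks ground-truth noise tags")
  errorTags <- match.arg(errorTags, .NOISE_TAGS[-1], several.ok = TRUE)
  isErr <- rec$noise_tag %in% errorTags
  all_n <- nrow(rec)
  atw <- sum(isErr)
  mw <- length(flagged)
  tw <- sum(rec$image_id[isErr] %in% flagged)
  new("CleaningEvaluation",
      all = as.integer(all_n), atw = as.integer(atw),
      mw = as.integer(mw), tw = as.integer(tw),
      eRate = 100 * atw / all_n,
      fAcc = if (mw > 0) 100 * tw / mw else NA_real_,
      fRec = if (atw > 0) 100 * tw / atw else NA_real_)
}

#' Serialize an evaluation as a flat JSON report
#'
#' @param evaluation a \linkS4class{CleaningEvaluation}.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when written to a file. Keys:
#'   \code{all}, \code{atw}, \code{mw}, \code{tw}, \code{e_rate},
#'   \code{f_acc}, \code{f_rec}.
#' @export
evaluationToJSON <- function(evaluation, path = NULL) {
  stopifnot(is(evaluation, "CleaningEvaluation"))
  x <- list(all = evaluation@all, atw = evaluation@atw,
            mw = evaluation@mw, tw = evaluation@tw,
            e_rate = evaluation@eRate, f_acc = evaluation@fAcc,
            f_rec = evaluation@fRec)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
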