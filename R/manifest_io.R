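# Manifest and report I/O. The manifest CSV is the single interchange
# format: a first comment line records the class order (class index 0
# first), then a header and one row per image:
#   image_id,filepath,observed_label,group_id,true_label,noise_tag
# with the empty string for an unknown true label.

#' Write a manifest as CSV
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "DatasetManifest"))
  rec <- records(manifest)
  rec$true_label[is.na(rec$true_label)] <- ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# classes: ",
                    paste(classNames(manifest), collapse = ",")), con)
  utils::write.csv(rec[, .MANIFEST_COLS], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a manifest CSV
#'
#' Restores class order from the leading \code{# classes:} comment line;
#' without one, class order falls back to the sorted unique observed
#' labels.
#'
#' @param path manifest CSV file.
#' @return a \linkS4class{DatasetManifest}.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  first <- readLines(path, n = 1L)
  hasHeader <- startsWith(first, "# classes:")
  rec <- utils::read.csv(path, skip = if (hasHeader) 1L else 0L,
                         colClasses = "character")
  if (!all(.MANIFEST_COLS %in% names(rec)))
    stop("manifest must have columns: ",
         paste(.MANIFEST_COLS, collapse = ", "))
  rec$true_label[rec$true_label == ""] <- NA_character_
  cn <- if (hasHeader) {
    trimws(strsplit(sub("^# classes:", "", first), ",")[[1]])
  } else sort(unique(rec$observed_label))
  .newManifest(rec[, .MANIFEST_COLS], cn)
}

#' Build a manifest from a class-per-subfolder image tree
#'
#' Adapts a conventional image folder layout (one subfolder per class,
#' e.g. a cats-vs-dogs tree) to the manifest format. Files directly
#' inside a class folder form one group per file stem prefix; with
#' \code{groupLevel = TRUE}, one further folder level below each class
#' folder is read as the group (patient) id.
#'
#' @param root directory containing exactly the two class subfolders.
#' @param classNames optional two folder names in class-index order;
#'   default: the first two subfolders, sorted.
#' @param groupLevel if TRUE, \code{root/class/group/img.png}; otherwise
#'   \code{root/class/img.png} with each file its own group.
#' @return a \linkS4class{DatasetManifest} of clean-tagged records (no
#'   ground-truth noise information is assumed).
#' @export
manifestFromFolders <- function(root, classNames = NULL,
                                groupLevel = FALSE) {
  if (!dir.exists(root)) stop("directory not found: ", root)
  subs <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (is.null(classNames)) {
    if (length(subs) < 2L) stop("need two class subfolders under ", root)
    classNames <- subs[1:2]
  }
  if (!all(classNames %in% subs))
    stop("class folder(s) missing under ", root, ": ",
         paste(setdiff(classNames, subs), collapse = ", "))
  rows <- list()
  for (k in 1:2) {
    cdir <- file.path(root, classNames[k])
    files <- list.files(cdir, pattern = "\\.png$", recursive = groupLevel,
                        full.names = FALSE, ignore.case = TRUE)
    if (length(files) == 0) next
    grp <- if (groupLevel) dirname(files) else
      tools::file_path_sans_ext(basename(files))
    grp[grp == "."] <- tools::file_path_sans_ext(basename(files))[grp == "."]
    rows[[k]] <- data.frame(
      image_id = paste0(classNames[k], "_",
                        tools::file_path_sans_ext(basename(files))),
      filepath = file.path(cdir, files),
      observed_label = classNames[k],
      group_id = paste0(classNames[k], "_", grp),
      true_label = classNames[k], noise_tag = "clean",
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  if (is.null(rec) || nrow(rec) == 0)
    stop("no .png files found under ", root)
  .newManifest(rec, classNames)
}

#' Write the files of a cleaning run
#'
#' Writes, under \code{dir}: \code{report.json} (rounds, per-round
#' flagged ids, deleted ids, stop reason, and the fully resolved
#' configuration including the seed), \code{surviving_manifest.csv} and
#' \code{deleted_manifest.csv} in the manifest format, and
#' \code{rounds.log} with one line per screening round.
#'
#' @param report a \linkS4class{CleaningReport}.
#' @param inputManifest the manifest the run started from (used to
#'   recover the deleted records).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCleaningReport <- function(report, inputManifest, dir) {
  stopifnot(is(report, "CleaningReport"), is(inputManifest, "DatasetManifest"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- records(inputManifest)
  deleted <- .newManifest(rec[rec$image_id %in% deletedIds(report), ,
                              drop = FALSE], classNames(inputManifest))
  writeManifest(survivingManifest(report),
                file.path(dir, "surviving_manifest.csv"))
  writeManifest(deleted, file.path(dir, "deleted_manifest.csv"))
  cfg <- report@config
  cfgList <- setNames(lapply(slotNames(cfg), function(s) slot(cfg, s)),
                      slotNames(cfg))
  js <- list(rounds = rounds(report), flagged_ids = flaggedIds(report),
             deleted_ids = deletedIds(report),
             stop_reason = stopReason(report), config = cfgList)
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  rr <- rounds(report)
  lines <- sprintf(
    "round %d | size %d | flagged %d | fraction %.6f | final_lr %.3e",
    rr$round_index, rr$dataset_size_before, rr$flagged_count,
    rr$flagged_fraction, rr$final_learning_rate)
  writeLines(c(lines, paste("stop:", stopReason(report))),
             file.path(dir, "rounds.log"))
  invisible(dir)
}
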