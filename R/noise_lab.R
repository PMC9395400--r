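# Synthetic dataset generation and controlled noise injection.
#
# The generator emulates the statistical structure of a two-class
# endoscopy frame collection at desk scale: two visually separable
# parametric texture families (class 0: oriented sinusoidal stripe field
# with a warm, red-dominant tint; class 1: Gaussian blob field with a
# green-dominant tint), a patient-like grouping where all images of a
# group share an appearance shift, and three corruption operators
# mirroring the field's noise taxonomy: intra-class label flips,
# out-of-class distractors relabeled into the two classes, and background
# degradation (blur / occlusion / shrunken target).

.clip01 <- function(x) pmin(pmax(x, 0), 1)

.pixelGrid <- function(S) {
  list(x = matrix(rep((seq_len(S) - 0.5) / S, each = S), S, S),
       y = matrix(rep((seq_len(S) - 0.5) / S, S), S, S))
}

# class 0: oriented stripe field, warm tint
.stripeImage <- function(S, theta, freq, phase, shift) {
  g <- .pixelGrid(S)
  u <- cos(theta) * g$x + sin(theta) * g$y
  s <- 0.5 + 0.5 * sin(2 * pi * freq * u + phase)
  a <- array(0, dim = c(S, S, 3))
  a[, , 1] <- 0.55 + 0.30 * s + shift[1]
  a[, , 2] <- 0.35 + 0.12 * s + shift[2]
  a[, , 3] <- 0.33 + 0.05 * s + shift[3]
  a
}

# class 1: blob field, green tint
.blobImage <- function(S, centers, sigmas, shift) {
  g <- .pixelGrid(S)
  b <- matrix(0, S, S)
  for (j in seq_len(nrow(centers))) {
    d2 <- (g$x - centers[j, 1])^2 + (g$y - centers[j, 2])^2
    b <- b + exp(-d2 / (2 * sigmas[j]^2))
  }
  if (max(b) > 0) b <- b / max(b)
  a <- array(0, dim = c(S, S, 3))
  a[, , 1] <- 0.33 + 0.08 * b + shift[1]
  a[, , 2] <- 0.55 + 0.30 * b + shift[2]
  a[, , 3] <- 0.40 + 0.06 * b + shift[3]
  a
}

# distractor family: diagonal checkerboard, blue tint (unlike both classes)
.checkerImage <- function(S, cells, theta, shift) {
  g <- .pixelGrid(S)
  u <- cos(theta) * g$x + sin(theta) * g$y
  v <- -sin(theta) * g$x + cos(theta) * g$y
  cpat <- (floor(cells * u) + floor(cells * v)) %% 2
  a <- array(0, dim = c(S, S, 3))
  a[, , 1] <- 0.45 + 0.10 * cpat + shift[1]
  a[, , 2] <- 0.42 + 0.10 * cpat + shift[2]
  a[, , 3] <- 0.62 + 0.25 * cpat + shift[3]
  a
}

.addPixelNoise <- function(a, sd = 0.04) {
  .clip01(a + stats::rnorm(length(a), sd = sd))
}

.writeImage <- function(a, path) {
  png::writePNG(.clip01(a), path)
}

.newManifest <- function(records, classNames) {
  rownames(records) <- NULL
  new("DatasetManifest", records = records, classNames = classNames)
}

#' Generate a clean synthetic two-class image dataset
#'
#' Writes PNG images of the two parametric texture families to \code{dir}
#' and returns a manifest in which every record is tagged \code{clean}
#' with \code{true_label == observed_label}. Images within a patient-like
#' group share a group appearance shift (color offset and texture
#' parameter base), emulating the per-patient correlation that motivates
#' group-disjoint splitting. Fully deterministic given \code{seed}: the
#' same call produces byte-identical PNG files.
#'
#' The two families are separable by first-order color statistics by
#' construction — a nearest-centroid classifier on raw pixels exceeds 95
#' percent accuracy — which gives the screening mechanism the class
#' signal it relies on.
#'
#' @param nPerClass images per class (>= 2).
#' @param nGroups total number of groups ("patients", >= 2); each group
#'   belongs to one class, as a patient carries one diagnosis.
#' @param imageSize edge length in pixels (default 32).
#' @param seed integer seed.
#' @param dir output directory for PNG files (created if needed).
#' @param classNames two class labels; the first is class index 0.
#' @return a \linkS4class{DatasetManifest}.
#' @examples
#' m <- generateSyntheticDataset(5, 2, imageSize = 16, seed = 1,
#'                               dir = tempfile())
#' nRecords(m)
#' @export
generateSyntheticDataset <- function(nPerClass, nGroups, imageSize = 32L,
                                     seed = 1L, dir = tempfile("sweepdata"),
                                     classNames = c("classA", "classB")) {
  if (nPerClass < 2L) stop("nPerClass must be >= 2")
  if (nGroups < 2L) stop("nGroups must be >= 2")
  stopifnot(length(classNames) == 2L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  S <- as.integer(imageSize)
  n <- 2L * nPerClass
  .withSeed(as.integer(seed), {
    nG0 <- ceiling(nGroups / 2)
    groupClass <- rep(c(0L, 1L), c(nG0, nGroups - nG0))
    groupShift <- matrix(stats::rnorm(3L * nGroups, sd = 0.03), ncol = 3)
    groupTheta <- stats::runif(nGroups, -0.3, 0.3)
    groupFreq <- stats::runif(nGroups, 3.5, 4.5)
    ids <- sprintf("img%05d", seq_len(n))
    labels <- rep(classNames, each = nPerClass)
    cls <- rep(c(0L, 1L), each = nPerClass)
    grp <- integer(n)
    for (k in 0:1) {
      pool <- which(groupClass == k)
      grp[cls == k] <- pool[1L + (sample.int(length(pool),
                                             nPerClass, replace = TRUE) - 1L)]
    }
    paths <- file.path(dir, paste0(ids, ".png"))
    for (i in seq_len(n)) {
      gshift <- groupShift[grp[i], ]
      a <- if (cls[i] == 0L) {
        .stripeImage(S,
                     theta = groupTheta[grp[i]] + stats::runif(1, -0.15, 0.15),
                     freq = groupFreq[grp[i]] + stats::runif(1, -0.5, 0.5),
                     phase = stats::runif(1, 0, 2 * pi),
                     shift = gshift)
      } else {
        K <- sample(3:6, 1)
        .blobImage(S,
                   centers = cbind(stats::runif(K, 0.15, 0.85),
                                   stats::runif(K, 0.15, 0.85)),
                   sigmas = 0.10 + 0.04 * stats::runif(K),
                   shift = gshift)
      }
      .writeImage(.addPixelNoise(a), paths[i])
    }
    rec <- data.frame(image_id = ids, filepath = paths,
                      observed_label = labels,
                      group_id = sprintf("grp%03d", grp),
                      true_label = labels, noise_tag = "clean",
                      stringsAsFactors = FALSE)
    .newManifest(rec, classNames)
  })
}

#' Inject intra-class label flips
#'
#' Randomly selects exactly \code{nPerClass} clean records of each class
#' and swaps their observed label to the other class, tagging them
#' \code{intra_label}. True labels and image files are untouched; the
#' record count is unchanged.
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param nPerClass flips per class; each class must have at least this
#'   many clean records.
#' @param seed integer seed (the flipped id set is deterministic).
#' @return the modified \linkS4class{DatasetManifest}.
#' @export
injectIntraClassNoise <- function(manifest, nPerClass, seed = 1L) {
  stopifnot(is(manifest, "DatasetManifest"), nPerClass >= 0L)
  if (nPerClass == 0L) return(manifest)
  rec <- records(manifest)
  cn <- classNames(manifest)
  .withSeed(as.integer(seed), {
    for (k in 1:2) {
      pool <- which(rec$noise_tag == "clean" & rec$observed_label == cn[k])
      if (length(pool) < nPerClass)
        stop("class '", cn[k], "' has only ", length(pool),
             " clean records; cannot flip ", nPerClass)
      pick <- pool[sample.int(length(pool), nPerClass)]
      rec$observed_label[pick] <- cn[3L - k]
      rec$noise_tag[pick] <- "intra_label"
    }
    .newManifest(rec, cn)
  })
}

#' Append out-of-class distractor images
#'
#' Generates \code{2 * nPerClass} images of a third parametric family
#' (visually unlike either class), labels \code{nPerClass} of them as
#' each class, tags them \code{extra_label} with unknown true label, and
#' appends them to the manifest. New records get fresh ids and fresh
#' group ids (distractors come from other "patients").
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param nPerClass distractors relabeled into each class (>= 0).
#' @param seed integer seed.
#' @param dir directory for the new PNG files; defaults to the directory
#'   of the manifest's first image.
#' @return the grown \linkS4class{DatasetManifest}.
#' @export
injectExtraClassNoise <- function(manifest, nPerClass, seed = 1L,
                                  dir = NULL) {
  stopifnot(is(manifest, "DatasetManifest"), nPerClass >= 0L)
  if (nPerClass == 0L) return(manifest)
  rec <- records(manifest)
  if (is.null(dir)) {
    if (nrow(rec) == 0) stop("empty manifest: supply `dir` explicitly")
    dir <- dirname(rec$filepath[1])
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cn <- classNames(manifest)
  S <- .manifestImageSize(manifest)
  n <- 2L * nPerClass
  .withSeed(as.integer(seed), {
    ids <- sprintf("xtr%05d", seq_len(n))
    stem <- 0L
    while (any(ids %in% rec$image_id)) {   # avoid collisions on re-use
      stem <- stem + n
      ids <- sprintf("xtr%05d", stem + seq_len(n))
    }
    nGrp <- max(2L, ceiling(n / 10))
    grp <- sprintf("xgrp%03d", sample.int(nGrp, n, replace = TRUE))
    paths <- file.path(dir, paste0(ids, ".png"))
    for (i in seq_len(n)) {
      a <- .checkerImage(S, cells = sample(3:6, 1),
                         theta = stats::runif(1, 0, pi / 2),
                         shift = stats::rnorm(3, sd = 0.03))
      .writeImage(.addPixelNoise(a), paths[i])
    }
    add <- data.frame(image_id = ids, filepath = paths,
                      observed_label = rep(cn, each = nPerClass),
                      group_id = grp, true_label = NA_character_,
                      noise_tag = "extra_label", stringsAsFactors = FALSE)
    .newManifest(rbind(rec, add), cn)
  })
}

# Edge length of the manifest's images (from the first readable file).
.manifestImageSize <- function(manifest) {
  rec <- records(manifest)
  for (p in rec$filepath) {
    a <- tryCatch(png::readPNG(p), error = function(e) NULL)
    if (!is.null(a)) return(dim(a)[1])
  }
  stop("no readable image in manifest")
}

#' Degrade image backgrounds
#'
#' Rewrites the image files of a random fraction of the still-clean
#' records with one of three degradations — heavy Gaussian blur,
#' occluding rectangles, or the content shrunk to under 10 percent of
#' the frame — and tags them \code{background}. Labels are untouched:
#' background-noise images are correctly labeled but harmful to train
#' on. Degradation is applied before any label injection in the staged
#' experiments, so only \code{clean}-tagged records are eligible.
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param fraction fraction of eligible records to degrade, in [0, 1].
#' @param seed integer seed.
#' @return the modified \linkS4class{DatasetManifest}.
#' @export
degradeBackground <- function(manifest, fraction, seed = 1L) {
  stopifnot(is(manifest, "DatasetManifest"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  rec <- records(manifest)
  pool <- which(rec$noise_tag == "clean")
  nPick <- round(fraction * length(pool))
  if (nPick == 0L) return(manifest)
  # degraded frames converge on a class-neutral "generic mucosa" look:
  # the diagnostic texture/tint is what blur washes out, occlusion hides
  # and a remote target leaves behind
  neutral <- c(0.45, 0.42, 0.42)
  .withSeed(as.integer(seed), {
    pick <- pool[sample.int(length(pool), nPick)]
    ops <- sample(c("blur", "occlude", "shrink"), nPick, replace = TRUE)
    for (j in seq_along(pick)) {
      i <- pick[j]
      a <- png::readPNG(rec$filepath[i])
      if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
      S <- dim(a)[1]
      bg <- array(rep(neutral, each = S * S), c(S, S, 3))
      a <- switch(ops[j],
        blur = {   # heavy blur plus contrast collapse toward neutral
          img <- EBImage::Image(aperm(a[, , 1:3], c(2, 1, 3)),
                                colormode = "Color")
          bl <- aperm(as.array(EBImage::gblur(img, sigma = S / 8)),
                      c(2, 1, 3))
          bg + 0.35 * (bl - bg)
        },
        occlude = {
          for (r in 1:4) {
            side <- max(2L, round(S * stats::runif(1, 0.35, 0.55)))
            y0 <- sample.int(S - side + 1L, 1)
            x0 <- sample.int(S - side + 1L, 1)
            a[y0:(y0 + side - 1L), x0:(x0 + side - 1L), ] <-
              rep(neutral + stats::rnorm(3, sd = 0.02),
                  each = side * side)
          }
          a
        },
        shrink = {   # target reduced to ~6% of the frame area
          small <- max(2L, round(S * 0.25))
          img <- EBImage::Image(aperm(a[, , 1:3], c(2, 1, 3)),
                                colormode = "Color")
          tiny <- aperm(as.array(EBImage::resize(img, w = small, h = small)),
                        c(2, 1, 3))
          y0 <- sample.int(S - small + 1L, 1)
          x0 <- sample.int(S - small + 1L, 1)
          bg[y0:(y0 + small - 1L), x0:(x0 + small - 1L), ] <- tiny
          bg
        })
      .writeImage(a, rec$filepath[i])
      rec$noise_tag[i] <- "background"
    }
    .newManifest(rec, classNames(manifest))
  })
}

#' Group-disjoint train/validation/test split
#'
#' Assigns whole groups ("patients") to the three splits so that no
#' group's images appear in more than one split, greedily steering each
#' split toward its target image fraction: groups are taken in a seeded
#' random order, largest first, and each goes to the split with the
#' largest remaining image deficit (ties favor train, then validation).
#'
#' @param manifest a \linkS4class{DatasetManifest} with at least 3 groups.
#' @param fractions three target image fractions summing to 1
#'   (default 70/15/15).
#' @param seed integer seed controlling tie-breaking order.
#' @return named list of three \linkS4class{DatasetManifest}s:
#'   \code{train}, \code{validation}, \code{test}.
#' @export
splitByGroup <- function(manifest, fractions = c(0.7, 0.15, 0.15),
                         seed = 1L) {
  stopifnot(is(manifest, "DatasetManifest"))
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three non-negative values summing to 1")
  rec <- records(manifest)
  sizes <- table(rec$group_id)
  if (length(sizes) < 3L)
    stop("need at least 3 groups to form 3 group-disjoint splits")
  .withSeed(as.integer(seed), {
    ord <- sample(names(sizes))                      # random tie order
    ord <- ord[order(-as.integer(sizes[ord]))]       # stable: largest first
    target <- fractions * nrow(rec)
    got <- c(0, 0, 0)
    assign3 <- setNames(integer(length(ord)), ord)
    for (g in ord) {
      deficit <- target - got
      k <- which.max(deficit)                        # ties -> train,val,test
      assign3[g] <- k
      got[k] <- got[k] + as.integer(sizes[g])
    }
    out <- lapply(1:3, function(k) {
      keep <- rec$group_id %in% names(assign3)[assign3 == k]
      .newManifest(rec[keep, , drop = FALSE], classNames(manifest))
    })
    names(out) <- c("train", "validation", "test")
    out
  })
}
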