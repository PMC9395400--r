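# Shared fixtures and independent oracles for the test suite.

# --- analytic layerwise parameter oracle, independent of the package's
# ArchitectureSpec walk: hard-coded standard VGG16-bn widths.
vggTrunkOracle <- function() {
  widths <- list(c(3, 64), c(64, 64), c(64, 128), c(128, 128),
                 c(128, 256), c(256, 256), c(256, 256),
                 c(256, 512), c(512, 512), c(512, 512),
                 c(512, 512), c(512, 512), c(512, 512))
  sum(vapply(widths, function(w) {
    conv <- w[1] * w[2] * 9 + w[2]   # 3x3 kernel + bias
    bn <- 2 * w[2]
    conv + bn
  }, numeric(1)))
}

vggNinOracle <- function(numClasses) {
  head <- (512 * 2048 + 2048) + 2 * 2048 +       # 1x1 conv + bn
          (2048 * 2048 + 2048) + 2 * 2048 +      # 1x1 conv + bn
          (2048 * numClasses + numClasses)       # linear head
  vggTrunkOracle() + head
}

vgg16bnOracle <- function(numClasses) {
  head <- (25088 * 4096 + 4096) + (4096 * 4096 + 4096) +
          (4096 * numClasses + numClasses)
  vggTrunkOracle() + head
}

# --- nearest-centroid classifier on raw pixels: the independent
# separability / flagging oracle.
manifestPixelMatrix <- function(manifest, imageSize) {
  imgs <- asNamespace("LabelSweep")$.loadImages(manifest, imageSize)
  t(apply(imgs$x, 3, as.vector))
}

centroidPredict <- function(feat, labels01, featNew = feat) {
  c0 <- colMeans(feat[labels01 == 0L, , drop = FALSE])
  c1 <- colMeans(feat[labels01 == 1L, , drop = FALSE])
  d0 <- rowSums(sweep(featNew, 2, c0)^2)
  d1 <- rowSums(sweep(featNew, 2, c1)^2)
  as.integer(d1 < d0)
}

observedIndex <- function(manifest) {
  match(records(manifest)$observed_label, classNames(manifest)) - 1L
}

# --- dataset builders. Image-backed sets are cached per parameter combo
# so repeated tests do not regenerate files.
.dsCache <- new.env()
cachedDataset <- function(nPerClass, nGroups, imageSize, seed) {
  key <- paste(nPerClass, nGroups, imageSize, seed, sep = "_")
  if (is.null(.dsCache[[key]])) {
    dir <- file.path(tempdir(), paste0("lsds_", key))
    .dsCache[[key]] <- generateSyntheticDataset(
      nPerClass, nGroups, imageSize = imageSize, seed = seed, dir = dir)
  }
  .dsCache[[key]]
}

# a manifest with no image files behind it (for metric / split tests)
recordsOnlyManifest <- function(n, nGroups = 4, classNames = c("a", "b"),
                                seed = 1) {
  set.seed(seed)
  lab <- classNames[1L + (seq_len(n) %% 2L)]
  rec <- data.frame(
    image_id = sprintf("r%04d", seq_len(n)),
    filepath = sprintf("/nonexistent/r%04d.png", seq_len(n)),
    observed_label = lab,
    group_id = sprintf("g%02d", sample.int(nGroups, n, replace = TRUE)),
    true_label = lab, noise_tag = "clean", stringsAsFactors = FALSE)
  new("DatasetManifest", records = rec, classNames = classNames)
}

# flip k records of a manifest in place (records-only manifests included)
flipRecords <- function(manifest, idx) {
  rec <- records(manifest)
  cn <- classNames(manifest)
  rec$observed_label[idx] <- cn[3L - match(rec$observed_label[idx], cn)]
  rec$noise_tag[idx] <- "intra_label"
  new("DatasetManifest", records = rec, classNames = cn)
}
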