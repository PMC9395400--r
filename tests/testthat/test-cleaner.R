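# Tests of the iterative screening loop on small synthetic sets.

smallCfg <- function(...) {
  args <- utils::modifyList(list(imageSize = 16, epochsPerRound = 8,
                                 maxRounds = 4, baseSeed = 13),
                            list(...))
  do.call(cleanerConfig, args)
}

test_that("a clean separable set passes screening almost untouched", {
  m <- cachedDataset(40, 4, 16, seed = 51)
  rep <- cleanDataset(m, smallReferenceSpec(16, 2), smallCfg())
  expect_equal(stopReason(rep), "threshold_reached")
  expect_equal(rounds(rep)$flagged_count[1], 0)
  expect_equal(nRecords(survivingManifest(rep)), 80)
})

test_that("a constant classifier flags every image of the other class", {
  m <- cachedDataset(5, 2, 16, seed = 52)
  model <- buildModel(smallReferenceSpec(16, 2), seed = 1)
  # force constant logits favoring class 0
  i <- nrow(model@spec@layers)
  model@params[[i]]$W[] <- 0
  model@params[[i]]$b <- c(10, -10)
  flagged <- flagMisclassified(model, m)
  rec <- records(m)
  expect_setequal(flagged,
                  rec$image_id[rec$observed_label == classNames(m)[2]])
  # and exactly equal logits resolve deterministically to class 0
  model@params[[i]]$b <- c(0, 0)
  expect_setequal(flagMisclassified(model, m),
                  rec$image_id[rec$observed_label == classNames(m)[2]])
})

test_that("flips are recovered exactly on a small separable set", {
  m <- cachedDataset(40, 4, 16, seed = 53)
  m2 <- injectIntraClassNoise(m, 4, seed = 3)
  rec <- records(m2)
  flips <- rec$image_id[rec$noise_tag == "intra_label"]
  fit <- trainOneRound(m2, smallReferenceSpec(16, 2), smallCfg(), 1)
  flagged <- flagMisclassified(fit$model, m2)
  # independent oracle: nearest-centroid on raw pixels, trained on the
  # same noisy labels, misclassifies exactly the flipped records
  feat <- manifestPixelMatrix(m2, 16)
  y <- observedIndex(m2)
  oracleWrong <- rec$image_id[centroidPredict(feat, y) != y]
  expect_setequal(oracleWrong, flips)
  expect_setequal(flagged, flips)
})

test_that("cleaning conserves records and keeps flagged sets disjoint", {
  m <- cachedDataset(40, 4, 16, seed = 53)
  m2 <- injectIntraClassNoise(m, 4, seed = 3)
  rep <- cleanDataset(m2, smallReferenceSpec(16, 2), smallCfg())
  expect_equal(nRecords(survivingManifest(rep)) + length(deletedIds(rep)),
               nRecords(m2))
  expect_equal(anyDuplicated(unlist(flaggedIds(rep))), 0)
  expect_setequal(unlist(flaggedIds(rep)), deletedIds(rep))
  # dataset size is non-increasing across rounds
  rr <- rounds(rep)
  if (nrow(rr) > 1) expect_true(all(diff(rr$dataset_size_before) <= 0))
  # survivors and deleted partition the input ids
  expect_setequal(c(records(survivingManifest(rep))$image_id,
                    deletedIds(rep)), records(m2)$image_id)
})

test_that("a full cleaning run is reproducible bit for bit", {
  m <- cachedDataset(20, 4, 16, seed = 54)
  m2 <- injectIntraClassNoise(m, 2, seed = 5)
  cfg <- smallCfg(maxRounds = 2)
  r1 <- cleanDataset(m2, smallReferenceSpec(16, 2), cfg)
  r2 <- cleanDataset(m2, smallReferenceSpec(16, 2), cfg)
  expect_identical(rounds(r1), rounds(r2))
  expect_identical(deletedIds(r1), deletedIds(r2))
  expect_identical(records(survivingManifest(r1)),
                   records(survivingManifest(r2)))
})

test_that("exhausting a class stops the run with a report, not an error", {
  # four stripe-textured images mislabeled as class B among forty true
  # class-A images: the model learns A and flags all of "B"
  m <- cachedDataset(22, 4, 16, seed = 55)
  rec <- records(m)
  cn <- classNames(m)
  keep <- which(rec$observed_label == cn[1])
  relab <- keep[1:4]
  rec2 <- rec[keep, ]
  rec2$observed_label[rec2$image_id %in% rec$image_id[relab]] <- cn[2]
  rec2$noise_tag[rec2$image_id %in% rec$image_id[relab]] <- "intra_label"
  m2 <- new("DatasetManifest", records = rec2, classNames = cn)
  rep <- cleanDataset(m2, smallReferenceSpec(16, 2), smallCfg())
  expect_equal(stopReason(rep), "class_exhausted")
  expect_true(all(records(survivingManifest(rep))$observed_label == cn[1]))
})

test_that("training refuses an empty or single-class manifest", {
  m <- cachedDataset(5, 2, 16, seed = 52)
  rec <- records(m)
  one <- new("DatasetManifest",
             records = rec[rec$observed_label == classNames(m)[1], ],
             classNames = classNames(m))
  expect_error(trainOneRound(one, smallReferenceSpec(16, 2), smallCfg(), 1),
               "class_exhausted")
  empty <- new("DatasetManifest", records = rec[0, ],
               classNames = classNames(m))
  expect_error(trainOneRound(empty, smallReferenceSpec(16, 2), smallCfg(), 1),
               "empty")
})

test_that("unreadable image files are flagged, not skipped", {
  m <- cachedDataset(5, 2, 16, seed = 52)
  rec <- records(m)
  rec$filepath[3] <- file.path(tempdir(), "does_not_exist.png")
  m2 <- new("DatasetManifest", records = rec, classNames = classNames(m))
  fit <- trainOneRound(m2, smallReferenceSpec(16, 2), smallCfg(), 1)
  expect_warning(flagged <- flagMisclassified(fit$model, m2), "unreadable")
  expect_true(rec$image_id[3] %in% flagged)
})

test_that("stop threshold of ~1 stops after a single round", {
  m <- cachedDataset(10, 4, 16, seed = 56)
  cfg <- smallCfg(stopThreshold = 0.999, maxRounds = 5)
  rep <- cleanDataset(m, smallReferenceSpec(16, 2), cfg)
  expect_equal(nrow(rounds(rep)), 1)
  expect_equal(stopReason(rep), "threshold_reached")
})
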