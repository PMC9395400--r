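test_that("the generator emits the requested records, cleanly tagged", {
  m <- generateSyntheticDataset(10, 4, imageSize = 32, seed = 1,
                                dir = file.path(tempdir(), "gen_basic"))
  rec <- records(m)
  expect_equal(nrow(rec), 20)
  expect_equal(anyDuplicated(rec$image_id), 0)
  expect_setequal(unique(rec$observed_label), classNames(m))
  expect_true(all(rec$noise_tag == "clean"))
  expect_true(all(rec$true_label == rec$observed_label))
  expect_true(all(file.exists(rec$filepath)))
  expect_error(generateSyntheticDataset(1, 4), "nPerClass")
  expect_error(generateSyntheticDataset(10, 1), "nGroups")
})

test_that("the same seed reproduces byte-identical images", {
  d1 <- file.path(tempdir(), "gen_rep1")
  d2 <- file.path(tempdir(), "gen_rep2")
  m1 <- generateSyntheticDataset(4, 2, imageSize = 16, seed = 77, dir = d1)
  m2 <- generateSyntheticDataset(4, 2, imageSize = 16, seed = 77, dir = d2)
  h1 <- unname(tools::md5sum(records(m1)$filepath))
  h2 <- unname(tools::md5sum(records(m2)$filepath))
  expect_identical(h1, h2)
  m3 <- generateSyntheticDataset(4, 2, imageSize = 16, seed = 78,
                                 dir = file.path(tempdir(), "gen_rep3"))
  expect_false(identical(h1, unname(tools::md5sum(records(m3)$filepath))))
})

test_that("the two classes are separable by the centroid oracle", {
  m <- cachedDataset(100, 10, 32, seed = 5)
  feat <- manifestPixelMatrix(m, 32)
  y <- observedIndex(m)
  expect_gte(mean(centroidPredict(feat, y) == y), 0.95)
})

test_that("group structure induces within-group appearance correlation", {
  m <- cachedDataset(100, 10, 32, seed = 5)
  rec <- records(m)
  feat <- manifestPixelMatrix(m, 32)
  y <- observedIndex(m)
  # within one class, images of the same group sit closer together than
  # images of different groups
  f0 <- feat[y == 0, ]
  g0 <- rec$group_id[y == 0]
  d <- as.matrix(dist(f0))
  same <- d[outer(g0, g0, "==") & upper.tri(d)]
  diff <- d[outer(g0, g0, "!=") & upper.tri(d)]
  expect_lt(mean(same), mean(diff))
})

test_that("intra-class flips change exactly the requested records", {
  m <- cachedDataset(20, 4, 16, seed = 31)
  m2 <- injectIntraClassNoise(m, 3, seed = 8)
  rec <- records(m2)
  expect_equal(nrow(rec), 40)                       # count unchanged
  expect_identical(rec$image_id, records(m)$image_id)
  flips <- rec[rec$noise_tag == "intra_label", ]
  expect_equal(nrow(flips), 6)
  expect_equal(sum(flips$true_label == classNames(m)[1]), 3)
  expect_equal(sum(flips$true_label == classNames(m)[2]), 3)
  expect_true(all(flips$observed_label != flips$true_label))
  # ground truth survives injection
  expect_identical(rec$true_label, records(m)$true_label)
  # determinism and the trivial cases
  m3 <- injectIntraClassNoise(m, 3, seed = 8)
  expect_identical(records(m3), rec)
  expect_identical(records(injectIntraClassNoise(m, 0)), records(m))
  expect_error(injectIntraClassNoise(m, 21, seed = 1), "clean records")
})

test_that("flip rate yields the designed error percentage", {
  # 50 flips per class in a 3216-image set gives the 3.1% regime
  expect_equal(roundPercent(errorRate(2 * 50, 3216)), 3.1)
})

test_that("distractors append with the right labels and stand apart", {
  m <- cachedDataset(20, 4, 16, seed = 31)
  m2 <- injectExtraClassNoise(m, 5, seed = 9)
  rec <- records(m2)
  expect_equal(nrow(rec), 50)
  extras <- rec[rec$noise_tag == "extra_label", ]
  expect_equal(nrow(extras), 10)
  expect_true(all(is.na(extras$true_label)))
  expect_equal(as.vector(table(extras$observed_label)), c(5, 5))
  expect_false(any(extras$group_id %in%
                   rec$group_id[rec$noise_tag == "clean"]))
  # centroid-margin check: distractors sit farther from both class
  # centroids than the classes' own members do on average
  feat <- manifestPixelMatrix(m2, 16)
  y <- observedIndex(m)
  base <- feat[seq_len(nRecords(m)), , drop = FALSE]
  xf <- feat[rec$noise_tag == "extra_label", , drop = FALSE]
  for (k in 0:1) {
    ck <- colMeans(base[y == k, , drop = FALSE])
    own <- mean(rowSums(sweep(base[y == k, , drop = FALSE], 2, ck)^2))
    far <- mean(rowSums(sweep(xf, 2, ck)^2))
    expect_gt(far, own)
  }
  expect_identical(records(injectExtraClassNoise(m, 0)), records(m))
})

test_that("background degradation rewrites images and hurts the oracle", {
  dir <- file.path(tempdir(), "deg_a")
  m <- generateSyntheticDataset(15, 4, imageSize = 16, seed = 41, dir = dir)
  # fraction 0: nothing happens, files untouched
  h0 <- unname(tools::md5sum(records(m)$filepath))
  m0 <- degradeBackground(m, 0, seed = 1)
  expect_identical(records(m0), records(m))
  expect_identical(unname(tools::md5sum(records(m)$filepath)), h0)
  # keep a pristine pixel copy, then degrade every record
  pristine <- manifestPixelMatrix(m, 16)
  y <- observedIndex(m)
  m1 <- degradeBackground(m, 1, seed = 2)
  expect_true(all(records(m1)$noise_tag == "background"))
  expect_identical(records(m1)$observed_label, records(m)$observed_label)
  degraded <- manifestPixelMatrix(m1, 16)
  errPrist <- mean(centroidPredict(pristine, y) != y)
  errDegr <- mean(centroidPredict(pristine, y, featNew = degraded) != y)
  expect_gt(errDegr, errPrist)
})

test_that("group-disjoint splitting hits the 70/15/15 group allocation", {
  # ten equal groups: the greedy allocator must land on 7/2/1
  rec <- records(recordsOnlyManifest(100, nGroups = 1, seed = 1))
  rec$group_id <- sprintf("g%02d", rep(1:10, each = 10))
  m <- new("DatasetManifest", records = rec, classNames = c("a", "b"))
  sp <- splitByGroup(m, c(0.7, 0.15, 0.15), seed = 3)
  ngroups <- vapply(sp, function(x) length(unique(records(x)$group_id)),
                    numeric(1))
  expect_equal(unname(ngroups), c(7, 2, 1))
  expect_equal(sum(vapply(sp, nRecords, numeric(1))), 100)
})

test_that("no group ever appears in two splits", {
  for (seed in 1:5) {
    m <- recordsOnlyManifest(80, nGroups = 9, seed = seed)
    sp <- splitByGroup(m, seed = seed)
    gs <- lapply(sp, function(x) unique(records(x)$group_id))
    expect_length(intersect(gs$train, gs$validation), 0)
    expect_length(intersect(gs$train, gs$test), 0)
    expect_length(intersect(gs$validation, gs$test), 0)
    expect_setequal(unlist(gs), unique(records(m)$group_id))
    # union of records is the input
    expect_setequal(unlist(lapply(sp, function(x) records(x)$image_id)),
                    records(m)$image_id)
  }
})

test_that("one group per image degenerates to a per-image split", {
  rec <- records(recordsOnlyManifest(40, seed = 2))
  rec$group_id <- rec$image_id
  m <- new("DatasetManifest", records = rec, classNames = c("a", "b"))
  sp <- splitByGroup(m, c(0.7, 0.15, 0.15), seed = 1)
  expect_equal(unname(vapply(sp, nRecords, numeric(1))), c(28, 6, 6))
  expect_error(splitByGroup(m, c(0.5, 0.5, 0.1)), "summing to 1")
  few <- new("DatasetManifest",
             records = transform(rec, group_id = "g1"),
             classNames = c("a", "b"))
  expect_error(splitByGroup(few), "at least 3 groups")
})
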