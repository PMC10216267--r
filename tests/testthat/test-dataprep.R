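test_that("mask merging is an OR with identity and idempotence", {
  m <- randomMask(8, 8)
  zero <- matrix(0, 8, 8)
  expect_identical(mergeMasks(list(m, zero)), m * 1)
  expect_identical(mergeMasks(list(m, m)), m * 1)
  a <- matrix(0, 4, 4); a[1, 1] <- 1
  b <- matrix(0, 4, 4); b[4, 4] <- 1
  expect_equal(sum(mergeMasks(list(a, b))), 2)
  expect_error(mergeMasks(list(a, matrix(0, 3, 3))), "mismatch")
})

test_that("empty-liver slices are filtered out, preserving order", {
  dir <- tempfile(); dir.create(dir)
  n <- 5L
  empty <- c(2L, 4L)
  paths <- character(n)
  for (i in seq_len(n)) {
    m <- if (i %in% empty) matrix(0, 8, 8) else randomMask(8, 8, 0.5)
    paths[i] <- file.path(dir, sprintf("liv%d.png", i))
    writeImagePNG(m, paths[i])
  }
  man <- DatasetManifest(data.frame(
    id = paste0("r", 1:n), image_path = paths, liver_mask_path = paths,
    tumor_mask_path = paths, label = "benign", split = "unassigned"))
  out <- filterEmptySlices(man)
  expect_equal(nrow(out@records), 3L)
  expect_identical(out@records$id, c("r1", "r3", "r5"))

  ## all nonempty -> unchanged; empty manifest -> empty manifest
  man2 <- man; man2@records <- man@records[-empty, , drop = FALSE]
  expect_identical(filterEmptySlices(man2)@records, man2@records)
  man3 <- man; man3@records <- man@records[0, , drop = FALSE]
  expect_equal(nrow(filterEmptySlices(man3)@records), 0L)

  ## missing file errors, naming the record
  man4 <- man
  man4@records$liver_mask_path[1] <- file.path(dir, "nope.png")
  expect_error(filterEmptySlices(man4), "r1")
})

test_that("preprocessing resizes by 0.25 and min-max normalizes", {
  img <- matrix(runif(512 * 512), 512, 512)
  out <- preprocessImage(img)
  expect_equal(dim(out), c(128L, 128L))
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)

  expect_identical(preprocessImage(matrix(7, 16, 16)),
                   matrix(0, 4, 4))

  ## linear min-max: value 15 in [10, 20] maps to 0.5 (no resize)
  img2 <- matrix(c(10, 20, 15, 12), 2, 2)
  out2 <- preprocessImage(img2, factor = 1)
  expect_equal(out2[1, 2], 0.5)
  expect_error(preprocessImage(matrix(numeric(0), 0, 0)), "empty")

  ## masks stay binary under nearest-neighbor resize
  m <- randomMask(64, 64)
  mm <- preprocessMask(m)
  expect_equal(dim(mm), c(16L, 16L))
  expect_true(all(mm %in% c(0, 1)))
})

test_that("dataset splitting honors ratios, stratification and determinism", {
  rec <- data.frame(id = paste0("s", 1:500),
                    image_path = "x", liver_mask_path = "x",
                    tumor_mask_path = "x",
                    label = rep(c("benign", "malignant"), each = 250),
                    split = "unassigned")
  man <- DatasetManifest(rec)
  out <- splitDataset(man, splitRatios(preset = "classification"), seed = 2L)
  expect_equal(sum(out@records$split == "train"), 360L)
  expect_equal(sum(out@records$split == "val"), 40L)
  expect_equal(sum(out@records$split == "test"), 100L)
  ## per-class counts under stratification
  tab <- table(out@records$split, out@records$label)
  expect_equal(unname(tab["train", ]), c(180L, 180L))
  ## partition: disjoint and exhaustive
  expect_true(all(out@records$split %in% c("train", "val", "test")))
  ## deterministic
  out2 <- splitDataset(man, splitRatios(preset = "classification"), seed = 2L)
  expect_identical(out@records, out2@records)
  out3 <- splitDataset(man, splitRatios(preset = "classification"), seed = 3L)
  expect_false(identical(out@records$split, out3@records$split))

  all.train <- splitDataset(man, splitRatios(1, 0, 0), seed = 1L)
  expect_true(all(all.train@records$split == "train"))

  seg <- splitRatios(preset = "segmentation")
  expect_equal(unname(seg), c(0.63, 0.17, 0.20))
  expect_error(splitRatios(0.5, 0.2, 0.2), "sum to 1")
})

test_that("k-fold driver partitions records across folds", {
  rec <- data.frame(id = paste0("s", 1:40), image_path = "x",
                    liver_mask_path = "x", tumor_mask_path = "x",
                    label = "benign", split = "unassigned")
  folds <- kfoldSplits(DatasetManifest(rec), k = 5L, seed = 1L)
  expect_length(folds, 5L)
  testIds <- lapply(folds, function(f) f@records$id[f@records$split == "test"])
  expect_equal(sort(unlist(testIds)), sort(rec$id))
  expect_equal(anyDuplicated(unlist(testIds)), 0L)
})

test_that("augmentation multiplies records and preserves mask structure", {
  samples <- phantomSet(3, imageSize = 32L, seed = 5L)
  aug <- augmentRecords(samples, factor = 32L, seed = 1L)
  expect_length(aug, 96L)
  ## 63 x 32 = 2016 bookkeeping on a synthetic length-63 list
  aug63 <- augmentRecords(rep(samples, length.out = 63), factor = 32L, seed = 1L)
  expect_length(aug63, 2016L)

  expect_identical(augmentRecords(samples, factor = 1L, seed = 1L), samples)
  expect_error(augmentRecords(samples, factor = 0L), "factor")

  for (s in aug) {
    expect_equal(dim(s@image)[1:2], dim(samples[[1]]@image)[1:2])
    expect_true(all(s@liverMask %in% c(0, 1)))
    expect_true(all(s@tumorMask <= s@liverMask))
    expect_true(all(s@image >= 0 & s@image <= 1))
  }
  ## deterministic
  aug2 <- augmentRecords(samples, factor = 32L, seed = 1L)
  expect_identical(aug[[50]]@image, aug2[[50]]@image)
})

test_that("manifest round-trips through CSV", {
  rec <- data.frame(id = c("a", "b"), image_path = c("1.png", "2.png"),
                    liver_mask_path = c("l1", "l2"),
                    tumor_mask_path = c("t1", "t2"),
                    label = c("benign", "malignant"),
                    split = c("train", "test"))
  man <- DatasetManifest(rec, provenance = "unit test")
  f <- tempfile(fileext = ".csv")
  writeManifest(man, f)
  back <- readManifest(f)
  expect_identical(back@records$id, rec$id)
  expect_identical(back@records$split, rec$split)
  expect_error(DatasetManifest(data.frame(id = c("a", "a"), image_path = "x",
                                          liver_mask_path = "x",
                                          tumor_mask_path = "x",
                                          label = "benign", split = "train")),
               "unique")
})
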