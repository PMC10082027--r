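# Dataset discovery, patch extraction, normalization, splitting,
# validation derivation, augmentation and k-fold splits.

test_that("discover_dataset returns deterministic sorted records", {
  root <- make_image_tree(tempfile("tree"))
  writeLines("not an image", file.path(root, "Grade0", "notes.txt"))
  expect_warning(rec <- discover_dataset(root), "non-image")
  expect_equal(nrow(rec), 10L)
  expect_equal(sort(unique(rec$label)), 0:4)
  expect_equal(attr(rec, "class_map"),
               setNames(0:4, paste0("Grade", 0:4)))
  rec2 <- suppressWarnings(discover_dataset(root))
  expect_identical(rec$path, rec2$path)

  dir.create(file.path(root, "GradeX"))
  expect_warning(expect_warning(discover_dataset(root), "non-image"),
                 "no images")
  expect_error(discover_dataset(tempfile("nope")), "not found")
})

test_that("extract_patches tiles without overlap and drops partial edges", {
  img <- array(runif(448 * 448 * 3), c(448, 448, 3))
  expect_length(extract_patches(img, 224), 4L)

  # 500x500: floor(500/224)^2 = 4 patches, edges dropped
  img <- array(runif(500 * 500 * 3), c(500, 500, 3))
  tiles <- extract_patches(img, 224)
  expect_length(tiles, 4L)
  expect_equal(dim(tiles[[1]]), c(224L, 224L, 3L))
  # the first tile is the exact top-left block
  expect_identical(tiles[[1]], img[1:224, 1:224, , drop = FALSE])

  # patch-sized image passes through bitwise
  img <- array(runif(224 * 224 * 3), c(224, 224, 3))
  tiles <- extract_patches(img, 224)
  expect_length(tiles, 1L)
  expect_identical(tiles[[1]], img)

  # undersized image: single whole-image resize
  img <- array(runif(100 * 100 * 3), c(100, 100, 3))
  expect_message(tiles <- extract_patches(img, 224), "resizing")
  expect_equal(dim(tiles[[1]]), c(224L, 224L, 3L))
})

test_that("normalize_patch standardizes to zero mean, unit variance", {
  p <- array(5, c(8, 8, 3))
  expect_true(all(normalize_patch(p) == 0))  # constant patch, eps guard

  p <- array(runif(224 * 224 * 3), c(224, 224, 3))
  n <- normalize_patch(p)
  expect_lt(abs(mean(n)), 1e-6)
  expect_lt(abs(stats::sd(n) - 1), 1e-5)

  # equal numbers of 0 and 2 map exactly to -1 and +1
  p <- array(rep(c(0, 2), 32), c(8, 8, 1))
  n <- normalize_patch(p)
  expect_equal(sort(unique(as.vector(n))), c(-1, 1))
})

test_that("split_train_test stratifies at the configured fraction", {
  rec <- data.frame(label = rep(0:4, each = 20),
                    class_name = rep(paste0("Grade", 0:4), each = 20),
                    path = sprintf("p%03d", 1:100),
                    source_id = sprintf("p%03d", 1:100))
  sp <- split_train_test(rec, 0.8, seed = 4)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$test), 20L)
  for (l in 0:4) {
    expect_equal(sum(sp$train$label == l), 16L)
    expect_equal(sum(sp$test$label == l), 4L)
  }
  # same seed, same split
  sp2 <- split_train_test(rec, 0.8, seed = 4)
  expect_identical(sp$train$path, sp2$train$path)
  # train and test are disjoint
  expect_length(intersect(sp$train$path, sp$test$path), 0L)
})

test_that("the kidney-study class sizes split to the published counts", {
  sizes <- c(203L, 135L, 124L, 120L, 140L)
  rec <- do.call(rbind, lapply(0:4, function(g)
    data.frame(label = g, class_name = paste0("Grade", g),
               path = sprintf("g%d_%03d", g, seq_len(sizes[g + 1])),
               source_id = sprintf("g%d_%03d", g, seq_len(sizes[g + 1])))))
  sp <- split_train_test(rec, 0.8, seed = 1)
  counts <- split_counts(sp)
  expect_equal(counts$training_patches, c(162L, 108L, 99L, 96L, 112L, 577L))
  expect_equal(counts$test_patches, c(41L, 27L, 25L, 24L, 28L, 145L))
})

test_that("single-record classes go to training with a warning", {
  rec <- data.frame(label = c(0, 0, 1), class_name = c("a", "a", "b"),
                    path = c("x", "y", "z"), source_id = c("x", "y", "z"))
  expect_warning(sp <- split_train_test(rec, 0.8, seed = 1), "single")
  expect_true("z" %in% sp$train$path)
})

test_that("derive_validation crops a disjoint region per training patch", {
  ps <- small_patch_set(per_class = 4L, out_size = 32L)
  val <- derive_validation(ps)
  expect_equal(length(val$y), length(ps$y))       # one crop per patch
  expect_identical(val$y, ps$y)                   # labels inherited
  expect_length(intersect(attr(val, "train_region"),
                          attr(val, "val_region")), 0L)
  val2 <- derive_validation(ps)
  expect_identical(val$x, val2$x)                 # reproducible
  expect_error(derive_validation(ps, crop_size = 32L), "smaller")
})

test_that("flip augmentation has exact multiplicity and is involutive", {
  ps <- small_patch_set(per_class = 4L, out_size = 32L)
  n <- length(ps$y)
  aug <- augment_flips(ps, "flips")
  expect_equal(length(aug$y), 3L * n)
  # the h-flip of the h-flip is the original
  hf <- rccgnet:::.flip_h(ps$x)
  expect_identical(rccgnet:::.flip_h(hf), ps$x)
  # block 2 of the augmented set is the h-flip, block 3 the v-flip
  expect_identical(aug$x[, , , n + 1], rccgnet:::.flip_h(ps$x)[, , , 1])
  expect_identical(aug$x[, , , 2 * n + 1], rccgnet:::.flip_v(ps$x)[, , , 1])

  aug2 <- augment_flips(ps, "flips+crops", n_crops = 2L, seed = 3)
  expect_equal(length(aug2$y), 5L * n)
  aug3 <- augment_flips(ps, "flips+crops", n_crops = 2L, seed = 3)
  expect_identical(aug2$x, aug3$x)                # seeded crops
  expect_identical(augment_flips(ps, "none"), ps)
})

test_that("kfold_split stratifies and partitions the data", {
  rec <- data.frame(label = rep(0:4, each = 9),
                    class_name = rep(paste0("Grade", 0:4), each = 9),
                    path = sprintf("p%02d", 1:45),
                    source_id = sprintf("p%02d", 1:45))
  folds <- kfold_split(rec, k = 3L, seed = 2)
  expect_length(folds, 3L)
  for (f in folds) {
    for (l in 0:4) expect_equal(sum(f$test$label == l), 3L)
    expect_length(intersect(f$train$path, f$test$path), 0L)
  }
  # union of test folds is the whole dataset, pairwise disjoint
  tests <- lapply(folds, function(f) f$test$path)
  expect_setequal(unlist(tests), rec$path)
  expect_equal(sum(lengths(tests)), 45L)
  # determinism
  folds2 <- kfold_split(rec, k = 3L, seed = 2)
  expect_identical(folds[[1]]$test$path, folds2[[1]]$test$path)
  # class smaller than k
  rec$label[1:9] <- c(0, rep(1, 8))
  expect_error(kfold_split(rec[1:10, ], k = 3L), "fewer than k")
})

test_that("round-trip: written synthetic images reload identically", {
  root <- tempfile("ds")
  spec <- synthetic_spec(per_class = rep(2L, 5L), size = 64L, seed = 5)
  generate_dataset(spec, root)
  rec <- discover_dataset(root)
  expect_equal(nrow(rec), 10L)
  ps <- load_patches(rec, patch_size = 64L, out_size = 32L)
  expect_equal(dim(ps$x), c(32L, 32L, 3L, 10L))
  expect_equal(ps$y, rec$label)
  # per-patch normalization applied
  expect_lt(max(abs(apply(ps$x, 4, mean))), 1e-6)
})
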