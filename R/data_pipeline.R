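# Folder-per-class ingestion, patch extraction, normalization, splitting
# and augmentation for histopathology patch datasets.

.IMG_EXT <- c("png", "jpg", "jpeg", "tif", "tiff")

#' Read an RGB image as an H x W x 3 array with unit-range values
#'
#' PNG files are read natively; JPEG and TIFF require the `EBImage`
#' package.  Grayscale images are replicated to three channels and any
#' alpha channel is dropped.
#'
#' @param path image file path.
#' @return `H x W x 3` numeric array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% .IMG_EXT) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading ", ext, " files requires the EBImage package")
    e <- EBImage::readImage(path)
    img <- aperm(array(as.numeric(e), dim(e)),
                 if (length(dim(e)) == 3L) c(2L, 1L, 3L) else c(2L, 1L))
  } else stop("unsupported image format: ", path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3L] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Discover a folder-per-class image dataset
#'
#' Scans `root`, whose immediate subdirectories are the classes.  Classes
#' and files are ordered lexicographically, so the same tree always
#' yields the same records and label map.
#'
#' @param root dataset root directory.
#' @return data frame with columns `path`, `label` (0-based, following
#'   the sorted class names), `class_name` and `source_id`; the class
#'   name to label map is attached as attribute `class_map`.
#' @export
discover_dataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop("no class subdirectories under ", root)
  rows <- lapply(seq_along(classes), function(i) {
    files <- sort(list.files(file.path(root, classes[i]), full.names = TRUE))
    keep <- tolower(tools::file_ext(files)) %in% .IMG_EXT
    if (any(!keep))
      warning("skipping ", sum(!keep), " non-image file(s) in ", classes[i])
    files <- files[keep]
    if (length(files) == 0L) {
      warning("class folder '", classes[i], "' contains no images")
      return(NULL)
    }
    data.frame(path = files, label = i - 1L, class_name = classes[i],
               source_id = basename(files))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "class_map") <- setNames(seq_along(classes) - 1L, classes)
  out
}

#' Extract non-overlapping square patches
#'
#' Tiles the image on a non-overlapping grid of `patch_size` cells;
#' partial edge tiles are dropped.  An image smaller than one cell is
#' resized whole to `patch_size` (with a message).
#'
#' @param image `H x W x C` array.
#' @param patch_size tile side length, default 224.
#' @return list of `patch_size x patch_size x C` arrays.
#' @export
extract_patches <- function(image, patch_size = 224L) {
  d <- dim(image)
  nh <- d[1L] %/% patch_size
  nw <- d[2L] %/% patch_size
  if (nh == 0L || nw == 0L) {
    message("image smaller than one ", patch_size, "-cell; resizing whole")
    return(list(cpp_resize_bilinear(image, patch_size, patch_size)))
  }
  out <- vector("list", nh * nw)
  k <- 1L
  for (i in seq_len(nh))
    for (j in seq_len(nw)) {
      out[[k]] <- image[(i - 1L) * patch_size + seq_len(patch_size),
                        (j - 1L) * patch_size + seq_len(patch_size), ,
                        drop = FALSE]
      k <- k + 1L
    }
  out
}

#' Normalize a patch to zero mean and unit variance
#'
#' `(x - mean) / max(sd, 1e-7)`, with the statistics (population form)
#' taken over all pixels and channels of the patch; a constant patch
#' maps to all zeros.
#'
#' @param patch numeric array.
#' @return the normalized patch.
#' @export
normalize_patch <- function(patch) {
  m <- mean(patch)
  s <- sqrt(mean((patch - m)^2))
  (patch - m) / max(s, 1e-7)
}

#' Load dataset records into a patch set
#'
#' Reads every image, extracts `patch_size` tiles, optionally resizes
#' them to `out_size` (bilinear) and normalizes each patch.
#'
#' @param records data frame from [discover_dataset()] (or a subset).
#' @param patch_size tiling size on the source image.
#' @param out_size side length of the stored patches (defaults to
#'   `patch_size`; use a smaller size for desk-scale training).
#' @param normalize normalize each patch to zero mean, unit variance.
#' @return a [patch_set()].
#' @export
load_patches <- function(records, patch_size = 224L, out_size = patch_size,
                         normalize = TRUE) {
  xs <- list()
  ys <- integer()
  ids <- character()
  for (i in seq_len(nrow(records))) {
    tiles <- extract_patches(read_image(records$path[i]), patch_size)
    for (tl in tiles) {
      if (out_size != dim(tl)[1L])
        tl <- cpp_resize_bilinear(tl, out_size, out_size)
      if (normalize) tl <- normalize_patch(tl)
      xs[[length(xs) + 1L]] <- tl
      ys <- c(ys, records$label[i])
      ids <- c(ids, records$source_id[i])
    }
  }
  x <- array(unlist(xs), c(out_size, out_size, 3L, length(xs)))
  patch_set(x, ys, ids)
}

#' Stratified train/test split
#'
#' Shuffles within each class with the given seed and assigns
#' `round(train_fraction * n_class)` records to training.  A class with a
#' single record goes entirely to training (with a warning).
#'
#' @param records data frame with a `label` column.
#' @param train_fraction fraction of each class used for training.
#' @param seed RNG seed.
#' @return list with data frames `train` and `test` (class
#'   `rccg_split`); per-class counts are available via [split_counts()].
#' @export
split_train_test <- function(records, train_fraction = 0.8, seed = 1L) {
  set.seed(seed)
  tr <- list()
  te <- list()
  for (lab in sort(unique(records$label))) {
    rc <- records[records$label == lab, , drop = FALSE]
    nc <- nrow(rc)
    if (nc == 1L) {
      warning("class ", lab, " has a single record; assigning it to train")
      tr[[length(tr) + 1L]] <- rc
      next
    }
    ord <- sample.int(nc)
    ntr <- max(1L, round(train_fraction * nc))
    tr[[length(tr) + 1L]] <- rc[ord[seq_len(ntr)], , drop = FALSE]
    te[[length(te) + 1L]] <- rc[ord[-seq_len(ntr)], , drop = FALSE]
  }
  structure(list(train = do.call(rbind, tr), test = do.call(rbind, te),
                 fold_id = NULL),
            class = "rccg_split")
}

#' Per-class counts of a split, one row per grade
#'
#' @param split an `rccg_split`.
#' @return data frame with columns `type`, `training_patches`,
#'   `test_patches`, including a final `Total` row.
#' @export
split_counts <- function(split) {
  labs <- sort(unique(c(split$train$label, split$test$label)))
  cls <- vapply(labs, function(l) {
    nm <- unique(c(split$train$class_name[split$train$label == l],
                   split$test$class_name[split$test$label == l]))
    nm[1L]
  }, character(1))
  out <- data.frame(
    type = cls,
    training_patches = vapply(labs, function(l)
      sum(split$train$label == l), integer(1)),
    test_patches = vapply(labs, function(l)
      sum(split$test$label == l), integer(1)))
  rbind(out, data.frame(type = "Total",
                        training_patches = nrow(split$train),
                        test_patches = nrow(split$test)))
}

#' Derive a validation set by cropping training patches
#'
#' Every training patch contributes one validation patch: a fixed
#' `crop_size` corner crop taken from the bottom-right region, which is
#' pixel-disjoint from the designated top-left "training crop" region of
#' the same patch, resized back to the full patch size.  Labels are
#' inherited and validation is never augmented.
#'
#' @param train a [patch_set()] of training patches.
#' @param crop_size side of the crop; must be at most half the patch side
#'   (so the two regions cannot overlap).  Default: half.
#' @return a [patch_set()] with attributes `train_region` and
#'   `val_region` (the row/column index sets of the two regions).
#' @export
derive_validation <- function(train, crop_size = NULL) {
  sz <- dim(train$x)[1L]
  if (is.null(crop_size)) crop_size <- sz %/% 2L
  if (crop_size >= sz)
    stop("crop_size must be smaller than the patch size")
  if (crop_size > sz %/% 2L)
    stop("crop_size above half the patch size would overlap the training region")
  n <- dim(train$x)[4L]
  idx <- sz - crop_size + seq_len(crop_size)  # bottom-right corner
  out <- array(0, c(sz, sz, 3L, n))
  for (i in seq_len(n)) {
    crop <- train$x[idx, idx, , i, drop = TRUE]
    out[, , , i] <- cpp_resize_bilinear(crop, sz, sz)
  }
  vs <- patch_set(out, train$y, train$source_id)
  attr(vs, "train_region") <- seq_len(crop_size)
  attr(vs, "val_region") <- idx
  vs
}

.flip_h <- function(x) x[, rev(seq_len(dim(x)[2L])), , , drop = FALSE]
.flip_v <- function(x) x[rev(seq_len(dim(x)[1L])), , , , drop = FALSE]

#' Flip (and crop) augmentation for training patches
#'
#' `"flips"` emits the original, the horizontal flip and the vertical
#' flip of every patch (a 3x multiplicity); `"flips+crops"` additionally
#' emits `n_crops` seeded random crops (resized back to full size) per
#' patch.  Augmentation is only ever applied to training data.
#'
#' @param train a [patch_set()].
#' @param mode `"none"`, `"flips"` or `"flips+crops"`.
#' @param n_crops random crops per patch in `"flips+crops"` mode.
#' @param crop_fraction linear size of a random crop relative to the
#'   patch.
#' @param seed RNG seed for the crop positions.
#' @return the augmented [patch_set()].
#' @export
augment_flips <- function(train, mode = c("none", "flips", "flips+crops"),
                          n_crops = 2L, crop_fraction = 0.75, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "none") return(train)
  x <- train$x
  parts <- list(x, .flip_h(x), .flip_v(x))
  y <- rep(train$y, 3L)
  ids <- rep(train$source_id, 3L)
  if (mode == "flips+crops") {
    set.seed(seed)
    sz <- dim(x)[1L]
    cs <- max(2L, round(crop_fraction * sz))
    n <- dim(x)[4L]
    for (k in seq_len(n_crops)) {
      crops <- array(0, dim(x))
      for (i in seq_len(n)) {
        r0 <- sample.int(sz - cs + 1L, 1L) - 1L
        c0 <- sample.int(sz - cs + 1L, 1L) - 1L
        crop <- x[r0 + seq_len(cs), c0 + seq_len(cs), , i, drop = TRUE]
        crops[, , , i] <- cpp_resize_bilinear(crop, sz, sz)
      }
      parts[[length(parts) + 1L]] <- crops
      y <- c(y, train$y)
      ids <- c(ids, train$source_id)
    }
  }
  d <- dim(x)
  out <- array(unlist(parts), c(d[1:3], length(y)))
  patch_set(out, y, ids)
}

#' Stratified k-fold cross-validation splits
#'
#' Each class is shuffled (seeded) and dealt into `k` folds of
#' near-equal size; run `i` trains on the other `k - 1` folds and tests
#' on fold `i`.
#'
#' @param records data frame with a `label` column.
#' @param k number of folds (3 in the published protocol).
#' @param seed RNG seed.
#' @return list of `k` `rccg_split` objects with `fold_id` set.
#' @export
kfold_split <- function(records, k = 3L, seed = 1L) {
  set.seed(seed)
  fold <- integer(nrow(records))
  for (lab in sort(unique(records$label))) {
    sel <- which(records$label == lab)
    if (length(sel) < k)
      stop("class ", lab, " has fewer than k = ", k, " records")
    fold[sel] <- sample(rep_len(seq_len(k), length(sel)))
  }
  lapply(seq_len(k), function(i) {
    structure(list(train = records[fold != i, , drop = FALSE],
                   test = records[fold == i, , drop = FALSE],
                   fold_id = i),
              class = "rccg_split")
  })
}

#' Write a split manifest as CSV
#'
#' One row per record with columns `path`, `label`, `subset` and `fold`.
#'
#' @param split an `rccg_split`.
#' @param path output CSV path.
#' @return the manifest data frame, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  man <- rbind(
    data.frame(path = split$train$path, label = split$train$label,
               subset = "train", fold = split$fold_id %||% NA_integer_),
    data.frame(path = split$test$path, label = split$test$label,
               subset = "test", fold = split$fold_id %||% NA_integer_))
  write.csv(man, path, row.names = FALSE)
  invisible(man)
}
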