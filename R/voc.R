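# Pascal-VOC segmentation dataset handling: index, sample loading, Labelme
# polygon conversion, dataset expansion and leakage-safe splitting.

new_dataset_index <- function(root, ids, split_of, provenance = NULL) {
  if (is.null(provenance))
    provenance <- data.frame(id = ids, source = ids, stringsAsFactors = FALSE)
  structure(list(root = root, ids = ids, split_of = split_of,
                 provenance = provenance),
            class = "rds_dataset_index")
}

write_split_lists <- function(index) {
  dir <- file.path(index$root, "ImageSets", "Segmentation")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in c("train", "val", "test")) {
    ids <- index$ids[index$split_of[index$ids] == s]
    if (s == "train" || length(ids) > 0)
      writeLines(ids, file.path(dir, paste0(s, ".txt")))
  }
  invisible(index)
}

#' Read a VOC-layout dataset index from disk
#'
#' Reconstructs the index from `ImageSets/Segmentation/{train,val,test}.txt`.
#'
#' @param root dataset root directory.
#' @return a `rds_dataset_index`.
#' @export
read_dataset_index <- function(root) {
  dir <- file.path(root, "ImageSets", "Segmentation")
  if (!dir.exists(dir)) rds_io_error(sprintf("no ImageSets/Segmentation under %s", root))
  ids <- character(0)
  split_of <- character(0)
  for (s in c("train", "val", "test")) {
    f <- file.path(dir, paste0(s, ".txt"))
    if (file.exists(f)) {
      sid <- readLines(f)
      sid <- sid[nzchar(sid)]
      ids <- c(ids, sid)
      split_of[sid] <- s
    }
  }
  if (length(ids) == 0) rds_io_error(sprintf("no samples listed under %s", dir))
  src <- sub("_a[0-9]+$", "", ids)
  new_dataset_index(root, ids, split_of,
                    data.frame(id = ids, source = src, stringsAsFactors = FALSE))
}

sample_paths <- function(index, id) {
  list(image = file.path(index$root, "JPEGImages", paste0(id, ".jpg")),
       mask = file.path(index$root, "SegmentationClass", paste0(id, ".png")))
}

#' Load one labeled sample
#'
#' Decodes the JPEG image to 8-bit RGB and the palette-PNG mask to class
#' indices, resizing to `size x size` when needed (image: bilinear; mask:
#' nearest-neighbour, so labels are never interpolated).
#'
#' @param index a `rds_dataset_index`.
#' @param id sample identifier.
#' @param size target side in pixels (default 224); `NULL` keeps the stored
#'   resolution.
#' @return a [labeled_scene()].
#' @export
load_sample <- function(index, id, size = 224L) {
  if (!id %in% index$ids) rds_io_error(sprintf("sample '%s' is not in the index", id))
  p <- sample_paths(index, id)
  if (!file.exists(p$image)) rds_io_error(sprintf("missing image file %s", p$image))
  img <- jpeg::readJPEG(p$image)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  img <- img[, , 1:3, drop = FALSE] * 255
  mask <- read_mask_png(p$mask)
  if (!is.null(size) && (nrow(mask) != size || ncol(mask) != size)) {
    img <- cpp_resize(img, size, size, TRUE)
    mask <- matrix(as.integer(cpp_resize(array(mask, dim = c(dim(mask), 1L)),
                                         size, size, FALSE)), size, size)
  }
  labeled_scene(img, mask)
}

#' Convert a Labelme JSON annotation to a class-index mask
#'
#' Polygons are rasterized in file order (later polygons overwrite earlier
#' ones) with an even-odd pixel-center test; `class_names[k]` maps to class
#' index `k`. Pixel centers sit at `(i + 0.5, j + 0.5)` in Labelme's 0-based
#' x-right / y-down coordinates, so an axis-aligned polygon with corners
#' (10,10)-(20,20) covers exactly the 10x10 pixel block [10,20).
#'
#' @param json_path Labelme JSON file.
#' @param class_names ordered foreground label names; defaults to
#'   `c("corn", "grass")` mapping to classes 1 and 2.
#' @return a [labeled_scene()]; the image is the decoded `imageData`-free
#'   canvas (zeros) unless a sibling image file named by `imagePath` exists.
#' @export
labelme_to_voc <- function(json_path, class_names = c("corn", "grass")) {
  if (!file.exists(json_path)) rds_io_error(sprintf("annotation not found: %s", json_path))
  j <- jsonlite::fromJSON(json_path, simplifyVector = FALSE)
  H <- as.integer(j$imageHeight); W <- as.integer(j$imageWidth)
  if (is.na(H) || is.na(W)) rds_format_error("labelme json lacks imageHeight/imageWidth")
  mask <- matrix(0L, H, W)
  px <- rep(seq_len(W) - 0.5, each = H)  # pixel-center x per column
  py <- rep(seq_len(H) - 0.5, times = W) # pixel-center y per row
  for (shape in j$shapes) {
    lab <- shape$label
    cls <- match(lab, class_names)
    if (is.na(cls)) rds_format_error(sprintf("unknown annotation label '%s' (expected one of: %s)",
                                             lab, paste(class_names, collapse = ", ")))
    pts <- do.call(rbind, lapply(shape$points, function(p) c(p[[1]], p[[2]])))
    if (nrow(pts) < 3L) next
    inside <- rep(FALSE, H * W)
    nv <- nrow(pts)
    xs <- pts[, 1]; ys <- pts[, 2]
    jv <- nv
    for (iv in seq_len(nv)) { # even-odd ray casting, vectorized over pixels
      cond <- (ys[iv] > py) != (ys[jv] > py)
      if (any(cond)) {
        xint <- (xs[jv] - xs[iv]) * (py - ys[iv]) / (ys[jv] - ys[iv]) + xs[iv]
        inside <- xor(inside, cond & (px < xint))
      }
      jv <- iv
    }
    mask[matrix(inside, H, W)] <- cls
  }
  img_path <- if (!is.null(j$imagePath)) file.path(dirname(json_path), j$imagePath) else ""
  img <- if (nzchar(img_path) && file.exists(img_path)) {
    jpeg::readJPEG(img_path)[, , 1:3, drop = FALSE] * 255
  } else array(0, dim = c(H, W, 3L))
  labeled_scene(img, mask)
}

#' Expand a dataset to a target size with augmented replicates
#'
#' Originals are kept; augmented copies (named `<source>_a<k>`) are added
#' round-robin over the source ids until the total reaches
#' `config$target_count`. Deterministic under `config$seed`; provenance maps
#' every replicate to its source.
#'
#' @param index a `rds_dataset_index`.
#' @param config an [augmentation_config()].
#' @return the expanded `rds_dataset_index`.
#' @export
expand_dataset <- function(index, config) {
  n0 <- length(index$ids)
  if (n0 == 0) rds_spec_error("expand_dataset: input dataset is empty")
  target <- config$target_count
  if (target < n0)
    rds_spec_error(sprintf("expand_dataset: target_count (%d) below current count (%d)", target, n0))
  n_extra <- target - n0
  if (n_extra == 0) return(index)
  sources <- index$ids[((seq_len(n_extra) - 1L) %% n0) + 1L]
  rep_no <- stats::ave(seq_len(n_extra), sources, FUN = seq_along)
  new_ids <- sprintf("%s_a%d", sources, rep_no)
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, n_extra))
  for (k in seq_len(n_extra)) {
    sc <- load_sample(index, sources[k], size = NULL)
    aug <- augment(sc, config, seed = seeds[k])
    p <- sample_paths(index, new_ids[k])
    jpeg::writeJPEG(aug$image / 255, p$image, quality = 0.95)
    write_palette_png(aug$mask, p$mask)
  }
  ids <- c(index$ids, new_ids)
  split_of <- stats::setNames(rep("train", length(ids)), ids)
  prov <- data.frame(id = ids, source = c(index$provenance$source, sources),
                     stringsAsFactors = FALSE)
  idx <- new_dataset_index(index$root, ids, split_of, prov)
  write_split_lists(idx)
  idx
}

#' Split a dataset into train/val/test
#'
#' Ids are shuffled by `seed`; the test split receives `round(N *
#' test_fraction)` samples and the remainder is split again by
#' `val_fraction` into validation and training. All augmented replicates of
#' one source sample are assigned to the same split, so replicates never
#' leak across the train/test boundary.
#'
#' @param index a `rds_dataset_index`.
#' @param test_fraction,val_fraction fractions in (0, 1).
#' @param seed shuffle seed.
#' @return the index with `split_of` reassigned and list files rewritten.
#' @export
split_dataset <- function(index, test_fraction = 0.2, val_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1 || val_fraction <= 0 || val_fraction >= 1)
    rds_spec_error("split_dataset: fractions must lie in (0, 1)")
  N <- length(index$ids)
  prov <- index$provenance
  sources <- unique(prov$source)
  group_n <- table(prov$source)[sources]
  ord <- with_seed(seed, sample(length(sources)))
  sources <- sources[ord]
  group_n <- as.integer(group_n[ord])

  n_test <- round(N * test_fraction)
  n_val <- round((N - n_test) * val_fraction)
  assign_until <- function(target, avail_idx) {
    got <- 0L; take <- integer(0)
    for (i in avail_idx) {
      if (got >= target) break
      # take the group unless it overshoots the target by more than it helps
      if (got + group_n[i] - target > target - got) break
      take <- c(take, i); got <- got + group_n[i]
    }
    take
  }
  idx_all <- seq_along(sources)
  take_test <- assign_until(n_test, idx_all)
  rest <- setdiff(idx_all, take_test)
  take_val <- assign_until(n_val, rest)
  take_train <- setdiff(rest, take_val)
  split_src <- stats::setNames(rep("train", length(sources)), sources)
  split_src[sources[take_test]] <- "test"
  split_src[sources[take_val]] <- "val"
  split_of <- stats::setNames(unname(split_src[prov$source]), prov$id)
  sizes <- table(factor(split_of, levels = c("train", "val", "test")))
  if (any(sizes == 0))
    rds_spec_error(sprintf("split_dataset: empty split (train/val/test = %s)",
                           paste(sizes, collapse = "/")))
  idx <- new_dataset_index(index$root, index$ids, split_of[index$ids], prov)
  write_split_lists(idx)
  idx
}

#' Ids belonging to one split
#' @param index a `rds_dataset_index`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @export
split_ids <- function(index, split) index$ids[index$split_of[index$ids] == split]

#' @export
print.rds_dataset_index <- function(x, ...) {
  sizes <- table(factor(x$split_of, levels = c("train", "val", "test")))
  cat(sprintf("VOC segmentation dataset at %s: %d samples (train/val/test = %s)\n",
              x$root, length(x$ids), paste(sizes, collapse = "/")))
  invisible(x)
}
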