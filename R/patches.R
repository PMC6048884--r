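#' Map an annotation point to voxel indices
#'
#' Annotation x/y are 0-based column/row pixel indices (x is the column
#' axis); they map to 1-based voxel `row = y + 1`, `col = x + 1`. The slice
#' is resolved by exact SOP-UID match when the point carries one; otherwise
#' by the nearest slice z within half the median slice spacing.
#'
#' @param point list with `x`, `y` and at least one of `sop_uid`, `z_mm`.
#' @param volume a [ct_volume()].
#' @return Integer vector `(row, col, slice)` (1-based).
#' @export
map_mark_to_voxel <- function(point, volume) {
  stopifnot(inherits(volume, "ct_volume"))
  slice <- NA_integer_
  if (!is.null(point$sop_uid) && !is.na(point$sop_uid)) {
    hit <- match(point$sop_uid, volume$slice_uids)
    if (!is.na(hit)) slice <- hit
  }
  if (is.na(slice)) {
    if (is.null(point$z_mm) || is.na(point$z_mm))
      stop("point carries neither a resolvable SOP UID nor a z position")
    nz <- length(volume$slice_z)
    tol <- if (nz >= 2) stats::median(diff(volume$slice_z)) / 2 else Inf
    d <- abs(volume$slice_z - point$z_mm)
    slice <- which.min(d)
    if (d[slice] > tol)
      stop(sprintf(
        "z = %g mm resolves to no slice within %.3g mm (volume z range %g..%g mm)",
        point$z_mm, tol, min(volume$slice_z), max(volume$slice_z)))
  }
  c(row = as.integer(round(point$y)) + 1L,
    col = as.integer(round(point$x)) + 1L,
    slice = as.integer(slice))
}

#' Crop a raw HU patch around a voxel
#'
#' Cuts the half-open window `[row - size/2, row + size/2)` (and the
#' analogous columns) from one slice, so the mark sits at pixel
#' `(size/2 + 1, size/2 + 1)` of the patch. Positions outside the image are
#' filled with -1000 HU (air) rather than shifting the window, which would
#' decenter the lesion.
#'
#' @param volume a [ct_volume()].
#' @param center `(row, col, slice)` voxel indices (1-based).
#' @param size patch side: 16, 32 or 64.
#' @return `size x size` numeric matrix of Hounsfield units.
#' @export
extract_patch <- function(volume, center, size) {
  stopifnot(inherits(volume, "ct_volume"), size %in% c(16L, 32L, 64L))
  d <- dim(volume$voxels)
  slice <- center[[3]]
  if (slice < 1L || slice > d[3]) stop("slice index ", slice, " out of range")
  half <- size %/% 2L
  rows <- (center[[1]] - half):(center[[1]] + half - 1L)
  cols <- (center[[2]] - half):(center[[2]] + half - 1L)
  patch <- matrix(-1000, size, size)
  rok <- rows >= 1L & rows <= d[1]
  cok <- cols >= 1L & cols <= d[2]
  if (any(rok) && any(cok))
    patch[rok, cok] <- volume$voxels[rows[rok], cols[cok], slice]
  patch
}

#' Normalize a raw HU patch to \[0, 1\]
#'
#' Clips to the lung window \[-1000, 400\] HU and maps it affinely onto
#' \[0, 1\], so air is 0 and dense soft tissue saturates at 1.
#'
#' @param raw numeric matrix of Hounsfield units.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
normalize_patch <- function(raw) {
  if (any(!is.finite(raw))) stop("patch contains non-finite HU values")
  (pmin(pmax(raw, -1000), 400) + 1000) / 1400
}

#' Extract the labelled patch dataset from annotated scans
#'
#' For every micro-nodule and non-nodule mark of every reading session
#' (marks from different readers are kept separate — each yields its own
#' patch), crops and normalizes one patch per requested size. Nodule
#' (>= 3 mm) contour marks produce nothing. Marks whose slice cannot be
#' resolved are skipped and logged with the reason.
#'
#' @param scans list of `scan_annotation` objects (already
#'   duplicate-filtered; see [exclude_duplicates()]).
#' @param volumes named list of [ct_volume()] keyed by `patient_id`.
#' @param sizes patch sizes to extract, default `c(16, 32, 64)`.
#' @return A list of class `"patch_dataset"`:
#'   `patches` — named list by size of `[size, size, n]` arrays;
#'   `labels` — 0/1 vector (1 = micro-nodule), shared across sizes;
#'   `manifest` — data.frame with provenance, label, size and center voxel
#'   per patch; `skipped` — data.frame of skipped marks with reasons.
#' @export
build_patch_dataset <- function(scans, volumes, sizes = c(16L, 32L, 64L)) {
  sizes <- as.integer(sizes)
  stopifnot(all(sizes %in% c(16L, 32L, 64L)))
  keep <- list(); centers <- list(); skipped <- list()
  for (scan in scans) {
    vol <- volumes[[scan$patient_id]]
    if (is.null(vol)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(patient_id = scan$patient_id, mark_id = NA_character_,
                   reason = "no volume for patient")
      next
    }
    for (si in seq_along(scan$sessions)) for (mark in scan$sessions[[si]]) {
      if (!mark$category %in% c("micro_nodule", "non_nodule")) next
      ctr <- tryCatch(map_mark_to_voxel(mark$points[[1]], vol),
                      error = function(e) e)
      if (inherits(ctr, "error")) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(patient_id = scan$patient_id, mark_id = mark$mark_id,
                     reason = conditionMessage(ctr))
        next
      }
      keep[[length(keep) + 1L]] <- list(scan = scan, mark = mark, vol = vol)
      centers[[length(centers) + 1L]] <- ctr
    }
  }
  n <- length(keep)
  labels <- if (n) vapply(keep, function(k)
    as.integer(k$mark$category == "micro_nodule"), 0L) else integer(0)
  patches <- list(); manifest <- list()
  for (size in sizes) {
    arr <- array(0, dim = c(size, size, n))
    for (i in seq_len(n))
      arr[, , i] <- normalize_patch(
        extract_patch(keep[[i]]$vol, centers[[i]], size))
    patches[[as.character(size)]] <- arr
    if (n) manifest[[as.character(size)]] <- data.frame(
      patient_id = vapply(keep, function(k) k$scan$patient_id, ""),
      reader_index = vapply(keep, function(k) k$mark$reader_index, 0L),
      mark_id = vapply(keep, function(k) k$mark$mark_id, ""),
      category = vapply(keep, function(k) k$mark$category, ""),
      label = labels,
      size = size,
      row = vapply(centers, `[[`, 0L, 1L),
      col = vapply(centers, `[[`, 0L, 2L),
      slice = vapply(centers, `[[`, 0L, 3L))
  }
  structure(list(
    patches = patches,
    labels = labels,
    manifest = if (length(manifest)) do.call(rbind, c(manifest, list(make.row.names = FALSE)))
               else data.frame(),
    skipped = if (length(skipped)) do.call(rbind, c(skipped, list(make.row.names = FALSE)))
              else data.frame()
  ), class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("Patch dataset: %d marks (%d micro-nodule, %d non-nodule) x sizes {%s}\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L),
              paste(names(x$patches), collapse = ", ")))
  if (nrow(x$skipped)) cat("  skipped marks:", nrow(x$skipped), "\n")
  invisible(x)
}

#' Save / load a patch dataset
#'
#' One array container per size (RDS) plus a CSV manifest, laid out for
#' random access during cross-validation.
#'
#' @param dataset a `patch_dataset`.
#' @param dir output directory (created if needed).
#' @return `save_patch_dataset`: `dir` invisibly; `load_patch_dataset`:
#'   a `patch_dataset`.
#' @export
save_patch_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "patch_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (size in names(dataset$patches))
    saveRDS(dataset$patches[[size]],
            file.path(dir, paste0("patches_", size, ".rds")))
  saveRDS(dataset$labels, file.path(dir, "labels.rds"))
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (nrow(dataset$skipped))
    utils::write.csv(dataset$skipped, file.path(dir, "skipped.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname save_patch_dataset
#' @export
load_patch_dataset <- function(dir) {
  files <- list.files(dir, pattern = "^patches_\\d+\\.rds$")
  sizes <- sub("^patches_(\\d+)\\.rds$", "\\1", files)
  patches <- stats::setNames(
    lapply(file.path(dir, files), readRDS), sizes)
  skipped_path <- file.path(dir, "skipped.csv")
  structure(list(
    patches = patches,
    labels = readRDS(file.path(dir, "labels.rds")),
    manifest = utils::read.csv(file.path(dir, "manifest.csv")),
    skipped = if (file.exists(skipped_path)) utils::read.csv(skipped_path)
              else data.frame()
  ), class = "patch_dataset")
}
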