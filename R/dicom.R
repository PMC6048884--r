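# Minimal DICOM Part-10 I/O (explicit VR little endian only), covering the
# tags the patch pipeline needs: SOP/series identifiers, patient ID, image
# position, pixel spacing, rescale slope/intercept and 16-bit pixel data.
# Deliberately narrow: it reads what write_dicom_slice() emits plus any
# well-formed explicit-VR-LE file restricted to these tags, skipping
# everything else.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

# short-form element (UI/LO/DS/US/IS): VR + 2-byte length
dcm_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2 == 1)
    value_raw <- c(value_raw, if (vr == "UI") as.raw(0) else charToRaw(" "))
  c(u16le(group), u16le(element), charToRaw(vr), u16le(length(value_raw)),
    value_raw)
}

dcm_str_element <- function(group, element, vr, value)
  dcm_element(group, element, vr, charToRaw(as.character(value)))

dcm_us_element <- function(group, element, value)
  dcm_element(group, element, "US", u16le(value))

#' Write one CT slice as a DICOM file
#'
#' Emits a minimal explicit-VR little-endian DICOM Part-10 file with 16-bit
#' signed pixel data. Intended for the synthetic scan fixtures; the stored
#' values relate to Hounsfield units through the written rescale slope and
#' intercept.
#'
#' @param path output file path.
#' @param pixels integer matrix (rows x columns) of stored values.
#' @param sop_uid,series_uid DICOM unique identifiers.
#' @param patient_id patient identifier string.
#' @param z_mm axial position (third component of ImagePositionPatient).
#' @param pixel_spacing `(row mm, col mm)`.
#' @param slope,intercept rescale mapping: HU = stored * slope + intercept.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(path, pixels, sop_uid, series_uid, patient_id,
                              z_mm, pixel_spacing = c(0.7, 0.7),
                              slope = 1, intercept = -1024) {
  stopifnot(is.matrix(pixels))
  stored <- round(pixels)
  storage.mode(stored) <- "integer"
  if (any(stored < -32768L | stored > 32767L)) stop("stored values exceed int16")
  ts_uid <- "1.2.840.10008.1.2.1"  # explicit VR little endian
  meta <- dcm_str_element(0x0002, 0x0010, "UI", ts_uid)
  header <- c(raw(128), charToRaw("DICM"),
              dcm_element(0x0002, 0x0000, "UL", u32le(length(meta))), meta)
  # pixel data: row-major per DICOM, int16 little endian
  px_raw <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  body <- c(
    dcm_str_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_str_element(0x0010, 0x0020, "LO", patient_id),
    dcm_str_element(0x0020, 0x000E, "UI", series_uid),
    dcm_str_element(0x0020, 0x0032, "DS",
                    sprintf("0\\0\\%g", z_mm)),
    dcm_us_element(0x0028, 0x0010, nrow(pixels)),
    dcm_us_element(0x0028, 0x0011, ncol(pixels)),
    dcm_str_element(0x0028, 0x0030, "DS",
                    sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2])),
    dcm_us_element(0x0028, 0x0100, 16L),
    dcm_us_element(0x0028, 0x0103, 1L),
    dcm_str_element(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
    dcm_str_element(0x0028, 0x1053, "DS", sprintf("%g", slope)),
    u16le(0x7FE0), u16le(0x0010), charToRaw("OW"), raw(2),
    u32le(length(px_raw)), px_raw)
  writeBin(c(header, body), path)
  invisible(path)
}

raw_u16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
raw_u32 <- function(r, i)
  as.integer(r[i]) + 256 * as.integer(r[i + 1L]) +
    65536 * as.integer(r[i + 2L]) + 16777216 * as.integer(r[i + 3L])

long_form_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

#' Read one DICOM slice
#'
#' Parses an explicit-VR little-endian DICOM file, returning the tags the
#' pipeline needs. Unknown tags are skipped; sequences with undefined
#' length are not supported.
#'
#' @param path DICOM file path.
#' @return A list: `sop_uid`, `series_uid`, `patient_id`, `z_mm`,
#'   `pixel_spacing`, `slope`, `intercept`, `rows`, `cols`, and `pixels`
#'   (integer matrix of stored values, rows x columns).
#' @export
read_dicom_slice <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  i <- 133L
  out <- list(slope = 1, intercept = 0)
  needed <- c("0008,0018", "0010,0020", "0020,000E", "0020,0032",
              "0028,0010", "0028,0011", "0028,0030", "0028,1052",
              "0028,1053", "7FE0,0010")
  px_raw <- NULL
  while (i + 7L <= length(r)) {
    group <- raw_u16(r, i); element <- raw_u16(r, i + 2L)
    vr <- rawToChar(r[(i + 4L):(i + 5L)])
    if (vr %in% long_form_vrs) {
      len <- raw_u32(r, i + 8L)
      if (len == 4294967295) stop("undefined-length element not supported at byte ", i)
      val_start <- i + 12L
    } else {
      len <- raw_u16(r, i + 6L)
      val_start <- i + 8L
    }
    tag <- dcm_tag(group, element)
    if (tag %in% needed) {
      val <- r[val_start:(val_start + len - 1L)]
      switch(tag,
        "0008,0018" = out$sop_uid <- trimws(rawToChar(val[val != as.raw(0)])),
        "0010,0020" = out$patient_id <- trimws(rawToChar(val)),
        "0020,000E" = out$series_uid <- trimws(rawToChar(val[val != as.raw(0)])),
        "0020,0032" = out$z_mm <- as.numeric(strsplit(rawToChar(val), "\\\\")[[1]])[3],
        "0028,0010" = out$rows <- raw_u16(val, 1L),
        "0028,0011" = out$cols <- raw_u16(val, 1L),
        "0028,0030" = out$pixel_spacing <-
          as.numeric(strsplit(rawToChar(val), "\\\\")[[1]]),
        "0028,1052" = out$intercept <- as.numeric(rawToChar(val)),
        "0028,1053" = out$slope <- as.numeric(rawToChar(val)),
        "7FE0,0010" = px_raw <- val)
    }
    i <- val_start + len
  }
  for (f in c("sop_uid", "series_uid", "z_mm", "rows", "cols")) {
    if (is.null(out[[f]]) || (is.numeric(out[[f]]) && anyNA(out[[f]])))
      stop("missing required DICOM tag for ", f, " in ", path)
  }
  if (is.null(px_raw)) stop("missing required DICOM tag for pixels in ", path)
  stored <- readBin(px_raw, "integer", n = out$rows * out$cols,
                    size = 2, endian = "little", signed = TRUE)
  out$pixels <- matrix(stored, nrow = out$rows, ncol = out$cols, byrow = TRUE)
  out
}

#' In-memory CT volume
#'
#' Constructs the ordered slice stack used by patch extraction. Slices are
#' reordered by ascending axial position.
#'
#' @param voxels numeric `H x W x S` array in Hounsfield units.
#' @param slice_z length-S axial positions (mm).
#' @param slice_uids length-S SOP instance identifiers.
#' @param pixel_spacing `(row mm, col mm)`.
#' @param patient_id optional patient identifier.
#' @return An object of class `"ct_volume"`.
#' @export
ct_volume <- function(voxels, slice_z, slice_uids,
                      pixel_spacing = c(0.7, 0.7), patient_id = NA_character_) {
  stopifnot(length(dim(voxels)) == 3L,
            dim(voxels)[3] == length(slice_z),
            length(slice_z) == length(slice_uids))
  o <- order(slice_z)
  slice_z <- slice_z[o]
  if (any(diff(slice_z) <= 0))
    stop("slice z positions must be strictly ascending after sorting")
  structure(list(voxels = voxels[, , o, drop = FALSE],
                 slice_z = slice_z, slice_uids = slice_uids[o],
                 pixel_spacing = pixel_spacing, patient_id = patient_id),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d x %d x %d slices, spacing %.3g x %.3g mm, z %g..%g mm\n",
              d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2],
              min(x$slice_z), max(x$slice_z)))
  invisible(x)
}

#' Load a CT series from DICOM slice files
#'
#' Reads every slice, checks that all belong to one series, sorts by
#' ascending axial position and converts stored values to Hounsfield units
#' via each slice's rescale slope and intercept.
#'
#' @param paths character vector of DICOM file paths, or a single directory
#'   (all `*.dcm` files within are read).
#' @return A [ct_volume()].
#' @export
read_ct_series <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.dcm$", full.names = TRUE)
  if (length(paths) == 0L) stop("no DICOM files to read")
  slices <- lapply(paths, read_dicom_slice)
  series <- unique(vapply(slices, `[[`, "", "series_uid"))
  if (length(series) != 1L)
    stop("mixed series: found ", length(series), " distinct series UIDs")
  dims <- unique(t(vapply(slices, function(s) c(s$rows, s$cols), integer(2))))
  if (nrow(dims) != 1L) stop("slices disagree on image dimensions")
  vox <- vapply(slices,
                function(s) s$pixels * s$slope + s$intercept,
                matrix(0, dims[1, 1], dims[1, 2]))
  ct_volume(vox,
            slice_z = vapply(slices, `[[`, 0, "z_mm"),
            slice_uids = vapply(slices, `[[`, "", "sop_uid"),
            pixel_spacing = slices[[1]]$pixel_spacing,
            patient_id = if (!is.null(slices[[1]]$patient_id))
              slices[[1]]$patient_id else NA_character_)
}
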