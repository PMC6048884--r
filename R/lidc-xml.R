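# LIDC/IDRI response-dialect annotation parsing.
#
# Each scan's XML holds up to four reading sessions (one per expert, the
# final unblinded reads). Inside a session, nodule elements carry one or
# more ROIs of edge-map points; non-nodule elements carry a single "Locus"
# point. Lesion taxonomy: a nodule element whose ROI set reduces to one
# distinct point is a micro-nodule (< 3 mm, annotated by its 3D
# center-of-mass only); a nodule element with a closed contour of >= 3
# points is a nodule (3-30 mm); a locus-bearing element is a non-nodule.

new_lesion_mark <- function(mark_id, reader_index, category, points,
                            contours = NULL) {
  structure(list(mark_id = mark_id, reader_index = reader_index,
                 category = category, points = points, contours = contours),
            class = "lesion_mark")
}

xml_num <- function(node, xpath) {
  v <- xml2::xml_text(xml2::xml_find_first(node, xpath))
  if (is.na(v) || v == "") NA_real_ else as.numeric(v)
}

xml_chr <- function(node, xpath) {
  v <- xml2::xml_text(xml2::xml_find_first(node, xpath))
  if (is.na(v) || v == "") NA_character_ else trimws(v)
}

# FNV-style fingerprint of the sorted slice-UID set: two independent
# rolling hashes, concatenated as hex, so equality identifies a scan.
string_fingerprint <- function(uids) {
  s <- paste(sort(unique(uids)), collapse = "|")
  bytes <- utf8ToInt(s)
  h1 <- 2166136261; h2 <- 5381
  for (b in bytes) {
    h1 <- ((h1 * 16777619) %% 2147483629 + b) %% 2147483629
    h2 <- ((h2 * 33) %% 2147483647 + b) %% 2147483647
  }
  sprintf("%08x%08x", h1, h2)
}

parse_roi_points <- function(roi) {
  z <- xml_num(roi, "./imageZposition")
  uid <- xml_chr(roi, "./imageSOP_UID")
  edges <- xml2::xml_find_all(roi, "./edgeMap")
  lapply(edges, function(e) list(
    x = xml_num(e, "./xCoord"), y = xml_num(e, "./yCoord"),
    sop_uid = uid, z_mm = z))
}

parse_nodule_element <- function(node, reader_index) {
  mark_id <- xml_chr(node, "./noduleID")
  rois <- xml2::xml_find_all(node, "./roi")
  pts_by_roi <- lapply(rois, parse_roi_points)
  all_pts <- do.call(c, pts_by_roi)
  if (length(all_pts) == 0L)
    stop("nodule element ", mark_id, ": no edge-map points")
  xy <- unique(t(vapply(all_pts, function(p) c(p$x, p$y, p$z_mm), numeric(3))))
  if (nrow(xy) == 1L) {
    # single distinct point: micro-nodule, center-of-mass annotation
    return(new_lesion_mark(mark_id, reader_index, "micro_nodule",
                           all_pts[1]))
  }
  n_per_roi <- lengths(pts_by_roi)
  if (!any(n_per_roi >= 3L))
    stop("nodule element ", mark_id,
         ": multiple distinct points but no contour of >= 3 points")
  new_lesion_mark(mark_id, reader_index, "nodule", all_pts,
                  contours = pts_by_roi[n_per_roi >= 3L])
}

parse_non_nodule_element <- function(node, reader_index) {
  mark_id <- xml_chr(node, "./nonNoduleID")
  locus <- xml2::xml_find_first(node, "./locus")
  if (inherits(locus, "xml_missing"))
    stop("non-nodule element ", mark_id, ": no locus point")
  pt <- list(x = xml_num(locus, "./xCoord"), y = xml_num(locus, "./yCoord"),
             sop_uid = xml_chr(node, "./imageSOP_UID"),
             z_mm = xml_num(node, "./imageZposition"))
  new_lesion_mark(mark_id, reader_index, "non_nodule", list(pt))
}

#' Parse an LIDC-dialect annotation XML file
#'
#' Reads one scan's annotation document into typed lesion marks, one per
#' lesion element per reading session. Categories: a non-nodule element
#' (identified by its Locus point) maps to `non_nodule`; a nodule element
#' whose ROI set reduces to a single distinct point to `micro_nodule`; any
#' other nodule element to `nodule` (contours retained, but nodules
#' produce no patches downstream). A lesion element with neither edge
#' points nor a locus is recorded as a mark-level error and the scan is
#' still returned.
#'
#' @param path XML file path (or an `xml2` document).
#' @return An object of class `"scan_annotation"`: `patient_id`,
#'   `series_uid`, `series_fingerprint` (hash of the sorted referenced
#'   slice-UID set), `sessions` (list of reading sessions, each a list of
#'   `lesion_mark`), `errors` (character vector of mark-level problems).
#' @export
read_lidc_xml <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else
    tryCatch(xml2::read_xml(path), error = function(e) {
      # name the byte offset of the failure for malformed documents
      msg <- conditionMessage(e)
      loc <- regmatches(msg, regexpr("line \\d+", msg))
      offset <- NA_integer_
      if (length(loc) && is.character(path) && file.exists(path)) {
        ln <- as.integer(sub("line ", "", loc))
        lines <- readLines(path, warn = FALSE)
        offset <- sum(nchar(utils::head(lines, ln - 1L), type = "bytes") + 1L)
      }
      stop("malformed XML in ", path,
           if (!is.na(offset)) paste0(" at byte offset ", offset),
           ": ", msg, call. = FALSE)
    })
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_root(doc)
  patient_id <- xml_chr(root, ".//ResponseHeader/PatientID")
  series_uid <- xml_chr(root, ".//ResponseHeader/SeriesInstanceUid")
  if (is.na(patient_id)) patient_id <- series_uid
  session_nodes <- xml2::xml_find_all(root, "./readingSession")
  if (length(session_nodes) > 4L)
    stop("more than four reading sessions in ", format(path))
  errors <- character(0)
  sessions <- lapply(seq_along(session_nodes), function(si) {
    sn <- session_nodes[[si]]
    reader <- si - 1L
    marks <- list()
    for (node in xml2::xml_find_all(sn, "./unblindedReadNodule")) {
      m <- tryCatch(parse_nodule_element(node, reader), error = function(e) e)
      if (inherits(m, "error")) errors <<- c(errors, conditionMessage(m))
      else marks[[length(marks) + 1L]] <- m
    }
    for (node in xml2::xml_find_all(sn, "./nonNodule")) {
      m <- tryCatch(parse_non_nodule_element(node, reader), error = function(e) e)
      if (inherits(m, "error")) errors <<- c(errors, conditionMessage(m))
      else marks[[length(marks) + 1L]] <- m
    }
    marks
  })
  uids <- unlist(lapply(sessions, function(ses)
    lapply(ses, function(m) vapply(m$points, function(p)
      if (is.null(p$sop_uid)) NA_character_ else p$sop_uid, ""))))
  uids <- uids[!is.na(uids)]
  structure(list(
    patient_id = patient_id,
    series_uid = series_uid,
    series_fingerprint = string_fingerprint(
      if (length(uids)) uids else series_uid),
    sessions = sessions,
    errors = errors
  ), class = "scan_annotation")
}

#' @export
print.scan_annotation <- function(x, ...) {
  counts <- table(factor(
    unlist(lapply(x$sessions, function(s) vapply(s, `[[`, "", "category"))),
    levels = c("nodule", "micro_nodule", "non_nodule")))
  cat(sprintf("Scan %s: %d reading sessions; %s\n", x$patient_id,
              length(x$sessions),
              paste(names(counts), counts, sep = "=", collapse = ", ")))
  if (length(x$errors)) cat("  mark-level errors:", length(x$errors), "\n")
  invisible(x)
}

#' Drop duplicated scans
#'
#' At most one scan per distinct series fingerprint survives; within a
#' fingerprint group the scan with the lexicographically smallest
#' `patient_id` + fingerprint is kept. Input order is preserved and the
#' operation is idempotent.
#'
#' @param scans list of `scan_annotation`.
#' @return Filtered list of `scan_annotation`.
#' @export
exclude_duplicates <- function(scans) {
  if (length(scans) == 0L) return(scans)
  fp <- vapply(scans, `[[`, "", "series_fingerprint")
  key <- paste0(vapply(scans, `[[`, "", "patient_id"), fp)
  keep <- logical(length(scans))
  for (f in unique(fp)) {
    grp <- which(fp == f)
    keep[grp[which.min(rank(key[grp], ties.method = "first"))]] <- TRUE
  }
  scans[keep]
}

#' Center of mass of a lesion mark
#'
#' Single-point marks (micro-nodules and non-nodules) return their point
#' unchanged. Contour marks return the unweighted arithmetic mean of all
#' contour vertices, with the slice reference of the contour slice nearest
#' the mean z.
#'
#' @param mark a `lesion_mark` with at least one point.
#' @return A point list: `x`, `y`, `sop_uid`, `z_mm`.
#' @export
center_of_mass <- function(mark) {
  stopifnot(inherits(mark, "lesion_mark"))
  if (length(mark$points) == 0L) stop("mark has no points")
  if (length(mark$points) == 1L) return(mark$points[[1]])
  xyz <- t(vapply(mark$points, function(p) c(p$x, p$y, p$z_mm), numeric(3)))
  cx <- mean(xyz[, 1]); cy <- mean(xyz[, 2]); cz <- mean(xyz[, 3])
  nearest <- mark$points[[which.min(abs(xyz[, 3] - cz))]]
  list(x = cx, y = cy, sop_uid = nearest$sop_uid, z_mm = nearest$z_mm)
}

#' Tabular mark manifest
#'
#' One row per lesion mark over all reading sessions of the given scans;
#' contour marks are summarized by their center of mass.
#'
#' @param scans a `scan_annotation` or list of them.
#' @return data.frame with columns `patient_id`, `reader_index`,
#'   `mark_id`, `category`, `x`, `y`, `sop_uid`, `z_mm`.
#' @export
mark_manifest <- function(scans) {
  if (inherits(scans, "scan_annotation")) scans <- list(scans)
  rows <- list()
  for (scan in scans) for (ses in scan$sessions) for (m in ses) {
    p <- center_of_mass(m)
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = scan$patient_id, reader_index = m$reader_index,
      mark_id = m$mark_id, category = m$category,
      x = p$x, y = p$y,
      sop_uid = if (is.null(p$sop_uid)) NA_character_ else p$sop_uid,
      z_mm = if (is.null(p$z_mm)) NA_real_ else p$z_mm)
  }
  if (!length(rows))
    return(data.frame(patient_id = character(), reader_index = integer(),
                      mark_id = character(), category = character(),
                      x = numeric(), y = numeric(),
                      sop_uid = character(), z_mm = numeric()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write the mark manifest as CSV
#'
#' @param scans as in [mark_manifest()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mark_manifest <- function(scans, path) {
  utils::write.csv(mark_manifest(scans), path, row.names = FALSE)
  invisible(path)
}
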