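# Synthetic fixtures: (a) miniature DICOM + annotation-XML scan fixtures
# with planted ground truth, exercising every parser/extraction branch;
# (b) labelled patch datasets with controllable class separability for
# training and evaluation tests. Background texture is seeded correlated
# (smoothed white) noise, not real CT texture: the aim is pipeline
# verification, not radiological realism.

#' Plan a synthetic annotated scan
#'
#' @param marks data.frame with columns `category` (`"micro_nodule"`,
#'   `"non_nodule"` or `"nodule"`), `row`, `col`, `slice` (1-based voxel
#'   indices) and `reader_index` (0-3).
#' @param h,w,n_slices volume geometry (slices are `h x w`).
#' @param pixel_spacing `(row mm, col mm)`.
#' @param slice_spacing axial step in mm.
#' @param n_sessions reading sessions to emit (empty ones included), at
#'   least `max(reader_index) + 1`, at most 4.
#' @param patient_id,series_uid identifiers written into DICOM and XML.
#' @param contour_radius_px radius of the polygonal contour planted for
#'   `nodule` marks.
#' @param seed integer seed fixing the voxel texture.
#' @return A list of class `"fixture_plan"`.
#' @export
fixture_plan <- function(marks, h = 64L, w = 64L, n_slices = 3L,
                         pixel_spacing = c(0.7, 0.7), slice_spacing = 2.5,
                         n_sessions = NULL, patient_id = "SYN-0001",
                         series_uid = "1.2.826.0.1.synthetic.1",
                         contour_radius_px = 4L, seed = 1L) {
  stopifnot(is.data.frame(marks),
            all(c("category", "row", "col", "slice", "reader_index")
                %in% names(marks)))
  if (nrow(marks)) {
    stopifnot(all(marks$category %in% c("micro_nodule", "non_nodule", "nodule")),
              all(marks$reader_index %in% 0:3))
    margin <- ifelse(marks$category == "nodule", contour_radius_px, 0L)
    if (any(marks$row - margin < 1 | marks$row + margin > h |
            marks$col - margin < 1 | marks$col + margin > w |
            marks$slice < 1 | marks$slice > n_slices))
      stop("planted mark (or its contour) falls outside the volume")
  }
  if (is.null(n_sessions))
    n_sessions <- max(1L, if (nrow(marks)) max(marks$reader_index) + 1L else 1L)
  stopifnot(n_sessions >= 1L, n_sessions <= 4L,
            !nrow(marks) || n_sessions > max(marks$reader_index))
  structure(list(marks = marks, h = as.integer(h), w = as.integer(w),
                 n_slices = as.integer(n_slices),
                 pixel_spacing = pixel_spacing, slice_spacing = slice_spacing,
                 n_sessions = as.integer(n_sessions),
                 patient_id = patient_id, series_uid = series_uid,
                 contour_radius_px = as.integer(contour_radius_px),
                 seed = as.integer(seed)),
            class = "fixture_plan")
}

# row-smoothing matrix with per-row unit-variance normalization for white
# noise input: smoothed = K Z K^T has var = rs(K^2)_i * rs(K^2)_j
smoothing_matrix <- function(n, sigma = 1.5) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-d^2 / (2 * sigma^2))
  K / rowSums(K)
}

correlated_noise <- function(h, w, sigma = 1.5) {
  Kh <- smoothing_matrix(h, sigma)
  Kw <- smoothing_matrix(w, sigma)
  Z <- matrix(stats::rnorm(h * w), h, w)
  S <- Kh %*% Z %*% t(Kw)
  S / sqrt(outer(rowSums(Kh^2), rowSums(Kw^2)))
}

gaussian_blob <- function(h, w, row, col, sigma) {
  dr <- outer(seq_len(h) - row, rep(1, w))
  dc <- outer(rep(1, h), seq_len(w) - col)
  exp(-(dr^2 + dc^2) / (2 * sigma^2))
}

#' Generate a synthetic annotated scan fixture
#'
#' Writes a DICOM slice series (correlated-noise lung-density background
#' with a bright blob planted at every mark) and an LIDC-dialect annotation
#' XML encoding the planted marks: micro-nodules as single-point nodule
#' elements, non-nodules as locus-bearing elements, nodules as polygonal
#' edge-map contours. Annotation x/y are written 0-based (x = column - 1,
#' y = row - 1), matching the coordinate convention the parser assumes.
#'
#' @param plan a [fixture_plan()].
#' @param out_dir output directory (created if needed).
#' @return The planted ground-truth manifest: a data.frame with the plan's
#'   mark columns plus `sop_uid`, `z_mm`, `patient_id`, and attributes
#'   `xml_path` and `dicom_paths`.
#' @export
generate_scan_fixture <- function(plan, out_dir) {
  stopifnot(inherits(plan, "fixture_plan"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(plan$seed)
  z <- (seq_len(plan$n_slices) - 1L) * plan$slice_spacing
  uids <- sprintf("%s.%d", plan$series_uid, seq_len(plan$n_slices))
  vol <- array(0, dim = c(plan$h, plan$w, plan$n_slices))
  for (s in seq_len(plan$n_slices))
    vol[, , s] <- -800 + 90 * correlated_noise(plan$h, plan$w)
  if (nrow(plan$marks)) for (i in seq_len(nrow(plan$marks))) {
    m <- plan$marks[i, ]
    sigma <- switch(m$category, micro_nodule = 1.2, non_nodule = 1.8,
                    nodule = plan$contour_radius_px / 2)
    vol[, , m$slice] <- vol[, , m$slice] +
      700 * gaussian_blob(plan$h, plan$w, m$row, m$col, sigma)
  }
  dicom_paths <- character(plan$n_slices)
  for (s in seq_len(plan$n_slices)) {
    dicom_paths[s] <- file.path(out_dir, sprintf("slice_%03d.dcm", s))
    write_dicom_slice(dicom_paths[s],
                      pixels = round(vol[, , s]) + 1024,
                      sop_uid = uids[s], series_uid = plan$series_uid,
                      patient_id = plan$patient_id, z_mm = z[s],
                      pixel_spacing = plan$pixel_spacing,
                      slope = 1, intercept = -1024)
  }
  xml_path <- file.path(out_dir, paste0(plan$patient_id, ".xml"))
  write_fixture_xml(plan, uids, z, xml_path)
  manifest <- plan$marks
  manifest$sop_uid <- if (nrow(manifest)) uids[manifest$slice] else character(0)
  manifest$z_mm <- if (nrow(manifest)) z[manifest$slice] else numeric(0)
  manifest$patient_id <- rep(plan$patient_id, nrow(manifest))
  attr(manifest, "xml_path") <- xml_path
  attr(manifest, "dicom_paths") <- dicom_paths
  manifest
}

write_fixture_xml <- function(plan, uids, z, xml_path) {
  doc <- xml2::xml_new_root("LidcReadMessage")
  header <- xml2::xml_add_child(doc, "ResponseHeader")
  xml2::xml_add_child(header, "SeriesInstanceUid", plan$series_uid)
  xml2::xml_add_child(header, "PatientID", plan$patient_id)
  add_edge <- function(roi, row, col) {
    e <- xml2::xml_add_child(roi, "edgeMap")
    xml2::xml_add_child(e, "xCoord", as.character(col - 1L))
    xml2::xml_add_child(e, "yCoord", as.character(row - 1L))
  }
  for (si in seq_len(plan$n_sessions)) {
    session <- xml2::xml_add_child(doc, "readingSession")
    xml2::xml_add_child(session, "servicingRadiologistID",
                        sprintf("reader-%d", si - 1L))
    marks <- plan$marks[plan$marks$reader_index == si - 1L, , drop = FALSE]
    if (!nrow(marks)) next
    for (i in seq_len(nrow(marks))) {
      m <- marks[i, ]
      if (m$category == "non_nodule") {
        nn <- xml2::xml_add_child(session, "nonNodule")
        xml2::xml_add_child(nn, "nonNoduleID", sprintf("NN%03d", i))
        xml2::xml_add_child(nn, "imageZposition", as.character(z[m$slice]))
        xml2::xml_add_child(nn, "imageSOP_UID", uids[m$slice])
        locus <- xml2::xml_add_child(nn, "locus")
        xml2::xml_add_child(locus, "xCoord", as.character(m$col - 1L))
        xml2::xml_add_child(locus, "yCoord", as.character(m$row - 1L))
      } else {
        nd <- xml2::xml_add_child(session, "unblindedReadNodule")
        xml2::xml_add_child(nd, "noduleID",
                            sprintf("%s%03d",
                                    if (m$category == "micro_nodule") "MN" else "N",
                                    i))
        roi <- xml2::xml_add_child(nd, "roi")
        xml2::xml_add_child(roi, "imageZposition", as.character(z[m$slice]))
        xml2::xml_add_child(roi, "imageSOP_UID", uids[m$slice])
        xml2::xml_add_child(roi, "inclusion", "TRUE")
        if (m$category == "micro_nodule") {
          add_edge(roi, m$row, m$col)
        } else {
          theta <- seq(0, 2 * pi, length.out = 13L)[-13L]
          for (t in theta)
            add_edge(roi, round(m$row + plan$contour_radius_px * sin(t)),
                     round(m$col + plan$contour_radius_px * cos(t)))
        }
      }
    }
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}

#' Generate a labelled synthetic patch dataset
#'
#' Class 1 (micro-nodule analogue) patches carry a centred Gaussian bright
#' blob whose diameter is drawn in the sub-3 mm range at the nominal pixel
#' spacing; class 0 (non-nodule analogue) patches carry an elongated
#' vessel-like ridge displaced from the centre. Both structures sit on
#' correlated background texture, and both amplitudes equal
#' `separation * noise_sd`, so at `separation = 0` the two class
#' distributions are identical by construction. Fully reproducible from
#' `seed`.
#'
#' @param n_pos,n_neg patch counts per class.
#' @param size patch side: 16, 32 or 64.
#' @param separation non-negative contrast parameter: structure amplitude
#'   in units of `noise_sd`. The default of 5 gives clearly learnable
#'   classes; 0 is the permutation-style null.
#' @param noise_sd background texture standard deviation (intensity units
#'   on the \[0, 1\] scale).
#' @param diameter_range_mm blob diameter range, honouring the < 3 mm
#'   micro-nodule definition.
#' @param pixel_spacing_mm nominal in-plane spacing converting mm to
#'   pixels.
#' @param seed integer seed.
#' @return A list: `patches` (`[size, size, n_pos + n_neg]` array in
#'   \[0, 1\], positives first) and `labels` (0/1 vector).
#' @examples
#' d <- generate_patch_dataset(n_pos = 5, n_neg = 5, size = 16, seed = 1)
#' dim(d$patches)
#' @export
generate_patch_dataset <- function(n_pos, n_neg, size = 32L, separation = 5,
                                   noise_sd = 0.08,
                                   diameter_range_mm = c(1, 2.9),
                                   pixel_spacing_mm = 0.7, seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0, size %in% c(16L, 32L, 64L),
            separation >= 0, noise_sd > 0)
  set.seed(seed)
  n <- n_pos + n_neg
  labels <- rep(c(1L, 0L), c(n_pos, n_neg))
  patches <- array(0, dim = c(size, size, n))
  amp <- separation * noise_sd
  centre <- size %/% 2L + 1L   # patch pixel holding the mark
  for (i in seq_len(n)) {
    bg <- 0.3 + noise_sd * correlated_noise(size, size)
    if (labels[i] == 1L) {
      d_mm <- stats::runif(1, diameter_range_mm[1], diameter_range_mm[2])
      sigma <- (d_mm / pixel_spacing_mm) / 2.355  # FWHM = planted diameter
      bg <- bg + amp * gaussian_blob(size, size, centre, centre, sigma)
    } else {
      # vessel-like ridge: a line whose perpendicular distance from the
      # centre is at least size/4, so its profile stays clear of the mark
      theta <- stats::runif(1, 0, pi)            # ridge orientation
      nvec <- c(-sin(theta), cos(theta))         # unit normal of the line
      off <- sample(c(-1, 1), 1) * stats::runif(1, size / 4, 0.4 * size)
      p0 <- c(centre, centre) + off * nvec
      dr <- outer(seq_len(size) - p0[1], rep(1, size))
      dc <- outer(rep(1, size), seq_len(size) - p0[2])
      dist <- abs(dr * nvec[1] + dc * nvec[2])
      width <- stats::runif(1, 0.8, 1.5)
      bg <- bg + amp * exp(-dist^2 / (2 * width^2))
    }
    patches[, , i] <- pmin(pmax(bg, 0), 1)
  }
  list(patches = patches, labels = labels)
}
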