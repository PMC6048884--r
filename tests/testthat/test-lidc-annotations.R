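lidc_xml_text <- function(sessions) {
  paste0(
    '<LidcReadMessage><ResponseHeader>',
    '<SeriesInstanceUid>1.2.840.1</SeriesInstanceUid>',
    '<PatientID>LIDC-TEST-0001</PatientID></ResponseHeader>',
    paste0(vapply(sessions, function(s)
      paste0("<readingSession>", s, "</readingSession>"), ""), collapse = ""),
    '</LidcReadMessage>')
}

nodule_elem <- function(id, pts, z = 0, uid = "1.2.840.1.1") {
  paste0('<unblindedReadNodule><noduleID>', id, '</noduleID><roi>',
         '<imageZposition>', z, '</imageZposition>',
         '<imageSOP_UID>', uid, '</imageSOP_UID><inclusion>TRUE</inclusion>',
         paste0(sprintf('<edgeMap><xCoord>%d</xCoord><yCoord>%d</yCoord></edgeMap>',
                        pts[, 1], pts[, 2]), collapse = ""),
         '</roi></unblindedReadNodule>')
}

non_nodule_elem <- function(id, x, y, z = 0, uid = "1.2.840.1.1") {
  paste0('<nonNodule><nonNoduleID>', id, '</nonNoduleID>',
         '<imageZposition>', z, '</imageZposition>',
         '<imageSOP_UID>', uid, '</imageSOP_UID>',
         '<locus><xCoord>', x, '</xCoord><yCoord>', y, '</yCoord></locus>',
         '</nonNodule>')
}

read_xml_string <- function(text) {
  path <- tempfile(fileext = ".xml")
  writeLines(text, path)
  on.exit(unlink(path))
  read_lidc_xml(path)
}

test_that("lesion elements map to the three categories", {
  contour <- cbind(x = c(10, 12, 14, 14, 12, 10, 8, 8, 9, 10, 11, 10),
                   y = c(8, 8, 10, 12, 14, 14, 12, 10, 9, 8, 8, 8))
  scan <- read_xml_string(lidc_xml_text(list(paste0(
    nodule_elem("N1", contour),                 # 12-point edge map: nodule
    nodule_elem("MN1", cbind(100, 120)),        # single point: micro-nodule
    non_nodule_elem("NN1", 30, 40)))))          # locus: non-nodule
  marks <- scan$sessions[[1]]
  expect_length(marks, 3L)
  cats <- vapply(marks, `[[`, "", "category")
  expect_setequal(cats, c("nodule", "micro_nodule", "non_nodule"))

  micro <- marks[[which(cats == "micro_nodule")]]
  expect_length(micro$points, 1L)
  expect_equal(micro$points[[1]]$x, 100)
  expect_equal(micro$points[[1]]$y, 120)

  nn <- marks[[which(cats == "non_nodule")]]
  expect_length(nn$points, 1L)
  expect_equal(nn$points[[1]]$x, 30)

  nod <- marks[[which(cats == "nodule")]]
  expect_length(nod$contours, 1L)
  expect_length(nod$contours[[1]], 12L)
})

test_that("empty sessions, session caps and mark-level errors are handled", {
  scan <- read_xml_string(lidc_xml_text(list(
    nodule_elem("MN1", cbind(5, 6)), "")))
  expect_length(scan$sessions, 2L)
  expect_length(scan$sessions[[2]], 0L)

  # a lesion with neither edge points nor locus is recorded, scan returned
  bad <- '<unblindedReadNodule><noduleID>B1</noduleID><roi><imageZposition>0</imageZposition><imageSOP_UID>u</imageSOP_UID></roi></unblindedReadNodule>'
  scan <- read_xml_string(lidc_xml_text(list(paste0(
    bad, non_nodule_elem("NN1", 1, 2)))))
  expect_length(scan$sessions[[1]], 1L)
  expect_match(scan$errors, "B1")

  expect_error(read_xml_string(lidc_xml_text(as.list(rep("", 5)))),
               "four reading sessions")
})

test_that("malformed XML reports a byte offset", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<LidcReadMessage>", "<broken"), path)
  expect_error(read_lidc_xml(path), "byte offset")
})

test_that("per-reader marks are kept separate across sessions", {
  scan <- read_xml_string(lidc_xml_text(list(
    nodule_elem("MN1", cbind(5, 6)),
    nodule_elem("MN1", cbind(5, 6)))))
  all_marks <- unlist(scan$sessions, recursive = FALSE)
  expect_length(all_marks, 2L)
  expect_equal(vapply(all_marks, `[[`, 0L, "reader_index"), c(0L, 1L))
})

test_that("duplicate exclusion keeps one scan per fingerprint, idempotently", {
  mk <- function(pid, fp) structure(
    list(patient_id = pid, series_fingerprint = fp, sessions = list()),
    class = "scan_annotation")
  scans <- list(mk("P2", "f1"), mk("P1", "f1"), mk("P3", "f2"))
  out <- exclude_duplicates(scans)
  expect_length(out, 2L)
  expect_equal(vapply(out, `[[`, "", "patient_id"), c("P1", "P3"))
  expect_identical(exclude_duplicates(out), out)

  # all distinct: identity
  distinct <- list(mk("A", "x"), mk("B", "y"))
  expect_identical(exclude_duplicates(distinct), distinct)

  # three copies: exactly one survivor
  out <- exclude_duplicates(list(mk("A", "z"), mk("B", "z"), mk("C", "z")))
  expect_length(out, 1L)
})

test_that("center of mass is exact on points, symmetric shapes and brute force", {
  pt <- list(x = 100, y = 120, sop_uid = "S", z_mm = 2.5)
  mark <- structure(list(mark_id = "m", reader_index = 0L,
                         category = "micro_nodule", points = list(pt)),
                    class = "lesion_mark")
  expect_identical(center_of_mass(mark), pt)

  square <- lapply(list(c(10, 10), c(10, 12), c(12, 10), c(12, 12)),
                   function(p) list(x = p[1], y = p[2], sop_uid = "S", z_mm = 0))
  mark <- structure(list(mark_id = "m", reader_index = 0L, category = "nodule",
                         points = square, contours = list(square)),
                    class = "lesion_mark")
  cm <- center_of_mass(mark)
  expect_equal(cm$x, 11); expect_equal(cm$y, 11)

  set.seed(31)
  xy <- matrix(runif(10, 0, 50), 5, 2)
  pts <- lapply(seq_len(5), function(i)
    list(x = xy[i, 1], y = xy[i, 2], sop_uid = "S", z_mm = 0))
  mark <- structure(list(mark_id = "m", reader_index = 0L, category = "nodule",
                         points = pts, contours = list(pts)),
                    class = "lesion_mark")
  cm <- center_of_mass(mark)
  expect_equal(cm$x, mean(xy[, 1]))   # brute-force vertex average
  expect_equal(cm$y, mean(xy[, 2]))
})

test_that("the mark manifest has the documented columns", {
  scan <- read_xml_string(lidc_xml_text(list(paste0(
    nodule_elem("MN1", cbind(7, 9), z = 2.5),
    non_nodule_elem("NN1", 3, 4)))))
  man <- mark_manifest(scan)
  expect_identical(names(man), c("patient_id", "reader_index", "mark_id",
                                 "category", "x", "y", "sop_uid", "z_mm"))
  expect_equal(nrow(man), 2L)
  expect_equal(man$patient_id, rep("LIDC-TEST-0001", 2))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_mark_manifest(scan, csv)
  expect_equal(nrow(utils::read.csv(csv)), 2L)
})
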