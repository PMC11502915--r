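#' Read a grayscale PNG radiograph
#'
#' Multi-channel PNGs are collapsed to grayscale by channel averaging.
#'
#' @param path File path.
#' @return Numeric matrix with intensities in \[0, 1\].
#' @export
readImagePNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3L, dim(x)[3]), drop = FALSE],
                                       c(1, 2), mean)
  x
}

#' Write a radiograph as 8-bit PNG
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param path File path.
#' @return Invisibly `path`.
#' @export
writeImagePNG <- function(image, path) {
  stopIfNot2dImage(image)
  png::writePNG(image, path)
  invisible(path)
}

# Minimal single-frame DICOM parser: little-endian implicit or explicit
# VR, uncompressed monochrome pixel data, linear rescale only. Enough for
# the standard exported grayscale radiograph; anything else errors.
parseDicomElements <- function(raw, start, explicit, stop_group = NULL) {
  n <- length(raw)
  pos <- start
  elements <- list()
  u16 <- function(at) readBin(raw[at:(at + 1)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3)], "integer", size = 4,
                              endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= n) {
    group <- u16(pos); elem <- u16(pos + 2)
    if (!is.null(stop_group) && group != stop_group) break
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4):(pos + 5)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8); hdr <- 12L
      } else {
        len <- u16(pos + 6); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4); hdr <- 8L
    }
    if (len < 0) stop("unsupported DICOM: undefined-length element", call. = FALSE)
    key <- sprintf("%04x,%04x", group, elem)
    elements[[key]] <- list(vr = vr, value = raw[(pos + hdr):(pos + hdr + len - 1)],
                            len = len)
    pos <- pos + hdr + len
    if (key == "7fe0,0010") break
  }
  list(elements = elements, pos = pos)
}

#' Read a single-frame DICOM radiograph
#'
#' Supports uncompressed little-endian transfer syntaxes (implicit and
#' explicit VR), 8- or 16-bit monochrome pixel data, linear rescale
#' (slope/intercept), and both photometric interpretations: MONOCHROME1
#' is inverted to the MONOCHROME2 convention (higher value = brighter).
#' Output is min-max normalized to \[0, 1\].
#'
#' @param path File path.
#' @return Numeric matrix in \[0, 1\].
#' @export
readImageDICOM <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 200 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM magic)", call. = FALSE)
  meta <- parseDicomElements(raw, 133L, explicit = TRUE, stop_group = 2L)
  ts <- meta$elements[["0002,0010"]]
  ts_uid <- if (is.null(ts)) "1.2.840.10008.1.2.1" else
    sub("\\x00+$", "", rawToChar(ts$value))
  explicit <- switch(ts_uid,
    "1.2.840.10008.1.2" = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stop("unsupported DICOM transfer syntax: ", ts_uid, call. = FALSE))
  body <- parseDicomElements(raw, meta$pos, explicit = explicit)$elements
  getStr <- function(key, default = NULL) {
    e <- body[[key]]
    if (is.null(e)) return(default)
    trimws(sub("\\x00+$", "", rawToChar(e$value)))
  }
  getU16 <- function(key, default = NULL) {
    e <- body[[key]]
    if (is.null(e)) return(default)
    readBin(e$value, "integer", size = 2, endian = "little", signed = FALSE)
  }
  rows <- getU16("0028,0010"); cols <- getU16("0028,0011")
  bits <- getU16("0028,0100", 16L)
  pixrep <- getU16("0028,0103", 0L)
  photometric <- getStr("0028,0004", "MONOCHROME2")
  slope <- as.numeric(getStr("0028,1053", "1"))
  intercept <- as.numeric(getStr("0028,1052", "0"))
  pix <- body[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(pix))
    stop("DICOM is missing Rows/Columns/PixelData", call. = FALSE)
  if (!bits %in% c(8L, 16L))
    stop("unsupported DICOM: BitsAllocated must be 8 or 16", call. = FALSE)
  vals <- readBin(pix$value, "integer", n = rows * cols, size = bits / 8,
                  endian = "little", signed = (pixrep == 1L && bits == 16L))
  if (bits == 8L) vals <- as.integer(vals) %% 256L
  vals <- slope * vals + intercept
  img <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  rng <- range(img)
  img <- if (diff(rng) == 0) matrix(0, rows, cols) else
    (img - rng[1]) / diff(rng)
  if (startsWith(photometric, "MONOCHROME1")) img <- 1 - img
  img
}

#' Write a case set to disk (PNG images + JSON manifest)
#'
#' @param case_set A [CxrCaseSet-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly the manifest path.
#' @export
writeCaseManifest <- function(case_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- caseLabels(case_set)
  entries <- lapply(case_set@cases, function(cs) {
    paths <- vapply(seq_along(cs@images), function(ii) {
      p <- file.path(dir, sprintf("%s_img%d.png", cs@case_id, ii))
      writeImagePNG(cs@images[[ii]], p)
      basename(p)
    }, "")
    li <- lab[lab$case_id == cs@case_id, ]
    cats <- lapply(seq_len(nrow(li)), function(i) {
      bx <- case_set@labeler_boxes
      bx <- bx[bx$case_id == cs@case_id & bx$category == li$category[i], ,
               drop = FALSE]
      list(category = li$category[i], k = li$k[i], n = li$n[i],
           reference = li$reference[i],
           boxes = unname(lapply(seq_len(nrow(bx)), function(j)
             c(bx$row0[j], bx$col0[j], bx$row1[j], bx$col1[j]))))
    })
    list(case_id = cs@case_id, image_paths = as.list(paths),
         patient_meta = cs@patient_meta, labels = cats)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write/read a reader-study table as CSV
#'
#' Schema: `reader_id, specialty, case_id, session, condition, category,
#' confidence, read_time_s` plus the joined `reference` column.
#'
#' @param table Reader-study data.frame.
#' @param path CSV path.
#' @return `writeReaderStudyCSV` invisibly returns the path;
#'   `readReaderStudyCSV` the validated data.frame.
#' @export
writeReaderStudyCSV <- function(table, path) {
  validateReaderStudyTable(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReaderStudyCSV
#' @export
readReaderStudyCSV <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateReaderStudyTable(tab)
  tab
}

#' Write device outputs as JSON
#'
#' Per case and category: the binary determination, the posterior-mean
#' score, and any extracted boxes as `[r0, c0, r1, c1]`.
#'
#' @param determinations Output of [applyOperatingPoints()].
#' @param path JSON path.
#' @return Invisibly the path.
#' @export
writePredictionsJSON <- function(determinations, path) {
  boxes <- attr(determinations, "boxes")
  out <- lapply(split(determinations, determinations$case_id), function(d) {
    cats <- lapply(seq_len(nrow(d)), function(i) {
      bx <- if (is.null(boxes)) NULL else
        boxes[boxes$case_id == d$case_id[i] & boxes$category == d$category[i], ,
              drop = FALSE]
      list(category = d$category[i],
           present = d$determination[i] == "present",
           score = d$score[i],
           boxes = if (is.null(bx) || !nrow(bx)) list() else
             unname(lapply(seq_len(nrow(bx)), function(j)
               c(bx$row0[j], bx$col0[j], bx$row1[j], bx$col1[j]))))
    })
    list(case_id = d$case_id[1], categories = cats)
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize operating points alongside a model checkpoint
#'
#' @param op An [OperatingPoints-class].
#' @param path JSON path.
#' @return Invisibly the path (write) or the restored object (read).
#' @export
writeOperatingPoints <- function(op, path) {
  jsonlite::write_json(list(
    decision_thresholds = as.list(op@decision_thresholds),
    map_thresholds = as.list(op@map_thresholds),
    achieved = op@achieved, fingerprint = op@fingerprint),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeOperatingPoints
#' @export
readOperatingPoints <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("OperatingPoints",
      decision_thresholds = unlist(x$decision_thresholds),
      map_thresholds = unlist(x$map_thresholds),
      achieved = as.data.frame(x$achieved),
      fingerprint = as.list(x$fingerprint))
}
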