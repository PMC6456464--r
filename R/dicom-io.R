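# Minimal DICOM Part 10 codec: explicit and implicit VR little endian,
# defined- and undefined-length sequences, single-frame 16-bit grayscale
# pixel data. Covers the modality tags this package emits and consumes;
# unknown explicit-VR tags are decoded by their VR, unknown implicit-VR
# tags are kept as raw strings.

#' @export
DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

#' @export
DICOM_TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

# VRs whose explicit encoding uses the 2-byte reserved field + 4-byte length
.dicom_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dicom_dict <- local({
  d <- matrix(c(
    "0002", "0001", "FileMetaInformationVersion", "OB",
    "0002", "0002", "MediaStorageSOPClassUID", "UI",
    "0002", "0003", "MediaStorageSOPInstanceUID", "UI",
    "0002", "0010", "TransferSyntaxUID", "UI",
    "0002", "0012", "ImplementationClassUID", "UI",
    "0008", "0016", "SOPClassUID", "UI",
    "0008", "0018", "SOPInstanceUID", "UI",
    "0008", "0020", "StudyDate", "DA",
    "0008", "0030", "StudyTime", "TM",
    "0008", "0060", "Modality", "CS",
    "0008", "0070", "Manufacturer", "LO",
    "0008", "0081", "InstitutionAddress", "ST",
    "0008", "0100", "CodeValue", "SH",
    "0008", "0102", "CodingSchemeDesignator", "SH",
    "0008", "0104", "CodeMeaning", "LO",
    "0008", "1010", "StationName", "SH",
    "0010", "0020", "PatientID", "LO",
    "0010", "1010", "PatientAge", "AS",
    "0018", "0060", "KVP", "DS",
    "0018", "1000", "DeviceSerialNumber", "LO",
    "0018", "1114", "EstimatedRadiographicMagnificationFactor", "DS",
    "0018", "1150", "ExposureTime", "IS",
    "0018", "1166", "Grid", "CS",
    "0018", "11A0", "BodyPartThickness", "DS",
    "0018", "11A2", "CompressionForce", "DS",
    "0018", "1405", "RelativeXRayExposure", "IS",
    "0018", "7026", "DetectorActiveDimensions", "DS",
    "0020", "0020", "PatientOrientation", "CS",
    "0028", "0002", "SamplesPerPixel", "US",
    "0028", "0004", "PhotometricInterpretation", "CS",
    "0028", "0010", "Rows", "US",
    "0028", "0011", "Columns", "US",
    "0028", "0100", "BitsAllocated", "US",
    "0028", "0101", "BitsStored", "US",
    "0028", "0102", "HighBit", "US",
    "0028", "0103", "PixelRepresentation", "US",
    "0054", "0220", "ViewCodeSequence", "SQ",
    "0054", "0222", "ViewModifierCodeSequence", "SQ",
    "7FE0", "0010", "PixelData", "OW"
  ), ncol = 4, byrow = TRUE)
  df <- data.frame(
    group = strtoi(d[, 1], 16L), element = strtoi(d[, 2], 16L),
    keyword = d[, 3], vr = d[, 4], stringsAsFactors = FALSE
  )
  df$key <- sprintf("%04X%04X", df$group, df$element)
  df
})

.dict_by_keyword <- function(keyword) {
  i <- match(keyword, .dicom_dict$keyword)
  if (is.na(i)) stop("unknown DICOM keyword: ", keyword)
  .dicom_dict[i, ]
}

.dict_by_tag <- function(group, element) {
  i <- match(sprintf("%04X%04X", group, element), .dicom_dict$key)
  if (is.na(i)) NULL else .dicom_dict[i, ]
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

.enc_string <- function(x, nul_pad = FALSE) {
  r <- charToRaw(paste(as.character(x), collapse = "\\"))
  .pad_even(r, if (nul_pad) as.raw(0x00) else as.raw(0x20))
}

.enc_uint16s <- function(x) {
  x <- as.integer(round(x))
  x <- ifelse(x > 32767L, x - 65536L, x)
  writeBin(x, raw(), size = 2, endian = "little")
}

# value -> raw, given VR
.encode_value <- function(value, vr, explicit) {
  switch(vr,
    UI = .enc_string(value, nul_pad = TRUE),
    DA = , TM = , CS = , LO = , SH = , ST = , AS = , PN = .enc_string(value),
    DS = .enc_string(vapply(value, function(v) format(v, digits = 10, trim = TRUE), "")),
    IS = .enc_string(as.character(as.integer(value))),
    US = .enc_uint16s(value),
    UL = .u32(value),
    OB = .pad_even(as.raw(value), as.raw(0)),
    OW = .enc_uint16s(value),
    stop("unsupported VR for encoding: ", vr)
  )
}

.encode_element <- function(group, element, vr, payload, explicit) {
  tag <- c(.u16(group), .u16(element))
  if (explicit) {
    if (vr %in% .dicom_long_vrs) {
      c(tag, charToRaw(vr), as.raw(c(0, 0)), .u32(length(payload)), payload)
    } else {
      if (length(payload) > 65534) stop("value too long for short VR ", vr)
      c(tag, charToRaw(vr), .u16(length(payload)), payload)
    }
  } else {
    c(tag, .u32(length(payload)), payload)
  }
}

.encode_sequence <- function(items, explicit) {
  do.call(c, c(list(raw(0)), lapply(items, function(item) {
    body <- .encode_dataset(item, explicit)
    c(.u16(0xFFFE), .u16(0xE000), .u32(length(body)), body)
  })))
}

# tags: named list keyword -> value (sequences: list of item named-lists)
.encode_dataset <- function(tags, explicit) {
  if (length(tags) == 0L) return(raw(0))
  info <- lapply(names(tags), .dict_by_keyword)
  ord <- order(
    vapply(info, `[[`, 0, "group") * 2^16 +
      vapply(info, `[[`, 0, "element")
  )
  parts <- lapply(ord, function(i) {
    d <- info[[i]]
    value <- tags[[i]]
    payload <- if (d$vr == "SQ") .encode_sequence(value, explicit)
    else .encode_value(value, d$vr, explicit)
    .encode_element(d$group, d$element, d$vr, payload, explicit)
  })
  do.call(c, parts)
}

#' Write a DICOM Part 10 file
#'
#' Serializes a named list of header tags (DICOM keywords) and an optional
#' 16-bit grayscale pixel matrix to a Part 10 file with a standard preamble
#' and file meta group. Sequence-valued tags (e.g. `ViewModifierCodeSequence`)
#' are given as a list of items, each item a named list of keywords.
#'
#' @param path output file path.
#' @param tags named list mapping DICOM keywords to values.
#' @param pixels optional integer matrix (rows x columns) of intensities in
#'   \[0, 65535\]; written as 16-bit little-endian `PixelData` together with
#'   the structural image tags.
#' @param transfer_syntax `"1.2.840.10008.1.2.1"` (explicit VR little endian,
#'   default) or `"1.2.840.10008.1.2"` (implicit VR little endian).
#' @param sop_instance_uid UID written to the file meta group.
#' @return `path`, invisibly.
#' @export
dicom_write <- function(path, tags, pixels = NULL,
                        transfer_syntax = DICOM_TS_EXPLICIT_LE,
                        sop_instance_uid = "1.2.826.0.1.3680043.9999.1") {
  stopifnot(transfer_syntax %in% c(DICOM_TS_EXPLICIT_LE, DICOM_TS_IMPLICIT_LE))
  explicit <- transfer_syntax == DICOM_TS_EXPLICIT_LE
  tags <- as.list(tags)
  if (!is.null(pixels)) {
    pixels <- as.matrix(pixels)
    structural <- list(
      SamplesPerPixel = 1L, PhotometricInterpretation = "MONOCHROME2",
      Rows = nrow(pixels), Columns = ncol(pixels),
      BitsAllocated = 16L, BitsStored = 12L, HighBit = 11L,
      PixelRepresentation = 0L
    )
    for (k in names(structural)) if (is.null(tags[[k]])) tags[[k]] <- structural[[k]]
    # pixels written column-per-row order (row-major, as DICOM expects)
    tags$PixelData <- as.integer(t(pixels))
  }
  meta <- list(
    FileMetaInformationVersion = c(0L, 1L),
    MediaStorageSOPClassUID = "1.2.840.10008.5.1.4.1.1.1.2",
    MediaStorageSOPInstanceUID = sop_instance_uid,
    TransferSyntaxUID = transfer_syntax,
    ImplementationClassUID = "1.2.826.0.1.3680043.9999.0.1"
  )
  meta_body <- .encode_dataset(meta, explicit = TRUE)
  group_len <- .encode_element(0x0002, 0x0000, "UL", .u32(length(meta_body)), TRUE)
  body <- .encode_dataset(tags, explicit)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta_body, body), con)
  invisible(path)
}

.read_u16 <- function(r, pos) {
  readBin(r[pos:(pos + 1L)], "integer", size = 2, endian = "little", signed = FALSE)
}

.read_len32 <- function(r, pos) {
  # signed read; 0xFFFFFFFF (undefined length) comes back as -1
  readBin(r[pos:(pos + 3L)], "integer", size = 4, endian = "little")
}

.trim_dicom_string <- function(x) sub("[ ]+$", "", x)

.raw_to_string <- function(payload) {
  # strip padding (trailing NUL or space) before conversion; embedded NULs
  # are invalid in the string VRs we emit
  while (length(payload) > 0L &&
         payload[length(payload)] %in% as.raw(c(0x00, 0x20))) {
    payload <- payload[-length(payload)]
  }
  rawToChar(payload)
}

.decode_value <- function(payload, vr) {
  if (length(payload) == 0L) return(NULL)
  str <- function() {
    s <- .trim_dicom_string(.raw_to_string(payload))
    parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
    if (length(parts) == 0L) NULL else parts
  }
  switch(vr,
    UI = , DA = , TM = , CS = , LO = , SH = , ST = , AS = , PN = , UT = str(),
    DS = suppressWarnings(as.numeric(str())),
    IS = suppressWarnings(as.integer(str())),
    US = readBin(payload, "integer", size = 2, n = length(payload) / 2,
                 endian = "little", signed = FALSE),
    UL = readBin(payload, "integer", size = 4, n = length(payload) / 4,
                 endian = "little"),
    OB = payload,
    OW = readBin(payload, "integer", size = 2, n = length(payload) / 2,
                 endian = "little", signed = FALSE),
    # unknown VR: keep printable bytes as a string, else raw
    {
      s <- tryCatch(rawToChar(payload), error = function(e) NULL)
      if (is.null(s)) payload else .trim_dicom_string(s)
    }
  )
}

# parse one dataset from r[pos..end]; returns list(tags=, pos=)
.parse_dataset <- function(r, pos, end, explicit, want_pixels, env = NULL) {
  tags <- list()
  while (pos <= end - 7L) {
    group <- .read_u16(r, pos); element <- .read_u16(r, pos + 2L)
    if (group == 0xFFFE) {
      # item/sequence delimiters are handled by sequence parsers; stop here
      break
    }
    pos <- pos + 4L
    d <- .dict_by_tag(group, element)
    if (explicit) {
      vr <- rawToChar(r[pos:(pos + 1L)]); pos <- pos + 2L
      if (vr %in% .dicom_long_vrs) {
        len <- .read_len32(r, pos + 2L); pos <- pos + 6L
      } else {
        len <- .read_u16(r, pos); pos <- pos + 2L
      }
    } else {
      len <- .read_len32(r, pos); pos <- pos + 4L
      vr <- if (!is.null(d)) d$vr else if (len == -1L) "SQ" else "UN"
    }
    name <- if (!is.null(d)) d$keyword else sprintf("Tag%04X%04X", group, element)
    if (vr == "SQ") {
      parsed <- .parse_sequence(r, pos, len, end, explicit, want_pixels)
      tags[[name]] <- parsed$items
      pos <- parsed$pos
    } else {
      if (len == -1L) stop("undefined length outside a sequence at tag ", name)
      if (name == "PixelData" && !want_pixels) {
        tags[[name]] <- NULL
      } else if (len > 0L) {
        tags[[name]] <- .decode_value(r[pos:(pos + len - 1L)], vr)
      } else {
        tags[name] <- list(NULL) # zero-length element: present but empty
      }
      pos <- pos + len
    }
  }
  list(tags = tags, pos = pos)
}

.parse_sequence <- function(r, pos, len, end, explicit, want_pixels) {
  items <- list()
  seq_end <- if (len == -1L) end else pos + len
  while (pos <= seq_end - 7L) {
    group <- .read_u16(r, pos); element <- .read_u16(r, pos + 2L)
    item_len <- .read_len32(r, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && element == 0xE0DD) break # sequence delimitation
    if (!(group == 0xFFFE && element == 0xE000)) {
      stop("malformed sequence: expected item tag")
    }
    item_end <- if (item_len == -1L) seq_end else pos + item_len
    parsed <- .parse_dataset(r, pos, item_end, explicit, want_pixels)
    items[[length(items) + 1L]] <- parsed$tags
    pos <- parsed$pos
    if (item_len == -1L) {
      # expect an item delimitation tag
      if (.read_u16(r, pos) == 0xFFFE && .read_u16(r, pos + 2L) == 0xE00D) {
        pos <- pos + 8L
      }
    }
  }
  list(items = items, pos = pos)
}

#' Read a DICOM Part 10 file
#'
#' Parses the file meta group and main dataset of a Part 10 file (explicit or
#' implicit VR little endian). Pixel data is skipped unless requested, so
#' header extraction never decodes images.
#'
#' @param path file to read.
#' @param read_pixels if `TRUE`, decode `PixelData` into an integer matrix.
#' @return a list with elements `meta` (file meta tags), `tags` (dataset tags,
#'   sequences as lists of item lists), `transfer_syntax`, and `pixels`
#'   (matrix or `NULL`).
#' @export
dicom_read <- function(path, read_pixels = FALSE) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM") {
    stop("not a DICOM Part 10 file: ", path)
  }
  pos <- 133L
  # file meta group: always explicit VR
  meta <- list()
  while (pos <= length(r) - 7L && .read_u16(r, pos) == 0x0002) {
    parsed_one <- .parse_dataset(r, pos, .meta_element_end(r, pos), TRUE, TRUE)
    meta <- c(meta, parsed_one$tags)
    pos <- parsed_one$pos
  }
  ts <- meta$TransferSyntaxUID
  if (is.null(ts)) ts <- DICOM_TS_EXPLICIT_LE
  explicit <- !identical(ts, DICOM_TS_IMPLICIT_LE)
  parsed <- .parse_dataset(r, pos, length(r), explicit, read_pixels)
  tags <- parsed$tags
  pixels <- NULL
  if (read_pixels && !is.null(tags$PixelData)) {
    nr <- tags$Rows; nc <- tags$Columns
    if (!is.null(nr) && !is.null(nc) && length(tags$PixelData) == nr * nc) {
      pixels <- matrix(tags$PixelData, nrow = nr, ncol = nc, byrow = TRUE)
    }
    tags$PixelData <- NULL
  }
  list(meta = meta, tags = tags, transfer_syntax = ts, pixels = pixels)
}

# end position for a single meta element starting at pos (helper so the meta
# loop can parse element-by-element and stop exactly when group changes)
.meta_element_end <- function(r, pos) {
  vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
  if (vr %in% .dicom_long_vrs) {
    pos + 12L + .read_len32(r, pos + 8L)
  } else {
    pos + 8L + .read_u16(r, pos + 6L)
  }
}
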