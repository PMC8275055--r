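# Minimal DICOM CT Image Storage writer/reader (explicit VR little endian).
# Covers exactly the tags needed to round-trip a rendered slice: geometry
# (ImagePositionPatient, ImageOrientationPatient, PixelSpacing), the pixel
# matrix, and the CT rescale tags.  DICOM patient coordinates are LPS;
# frame coordinates (+x patient-right, +y anterior) convert by negating
# the x and y components.

lps_from_frame <- function(p) c(-p[1], -p[2], p[3])
frame_from_lps <- function(p) c(-p[1], -p[2], p[3])

fmt_ds <- function(x) paste(formatC(x, format = "g", digits = 15), collapse = "\\")

dcm_uid_root <- "1.2.826.0.1.3680043.10.1217."

.dcm_raw <- function(...) unlist(list(...))

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# One data element. Even-pads string payloads.
dcm_elem <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2 == 1)
      value <- c(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  stopifnot(is.raw(value))
  head <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_u32(length(value)), value)
  } else {
    c(head, dcm_u16(length(value)), value)
  }
}

#' Write a rendered slice as a DICOM CT image
#'
#' Stores the pixel matrix as signed 16-bit CT Image Storage with the
#' plane pose encoded in the standard geometry tags:
#' `ImagePositionPatient` is the LPS position of the top-left pixel
#' centre and `ImageOrientationPatient` holds the LPS row then column
#' direction cosines. [read_dicom_ct()] recovers the `stereo_plane` from
#' these tags.
#'
#' @param image a `stereo_image` from [render_ct()].
#' @param path output file path.
#' @param instance integer used to derive deterministic SOP instance
#'   UIDs for multi-slice series.
#' @return `path`, invisibly.
#' @export
write_dicom_ct <- function(image, path, instance = 1) {
  stopifnot(inherits(image, "stereo_image"))
  px <- round(image$pixels)
  rows <- nrow(px); cols <- ncol(px)
  s <- image$pixel_spacing
  pl <- image$plane
  uv11 <- pixel_to_uv(1, 1, rows, cols, s)
  p11 <- pl$origin + uv11[1] * pl$e_u + uv11[2] * pl$e_v
  ipp <- lps_from_frame(p11)
  row_dir <- lps_from_frame(pl$e_u)    # along increasing column
  col_dir <- lps_from_frame(-pl$e_v)   # along increasing row
  sop_uid <- paste0(dcm_uid_root, "1.", instance)

  ds <- c(
    dcm_elem(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_elem(0x0008, 0x0018, "UI", sop_uid),
    dcm_elem(0x0008, 0x0060, "CS", "CT"),
    dcm_elem(0x0020, 0x0032, "DS", fmt_ds(ipp)),
    dcm_elem(0x0020, 0x0037, "DS", fmt_ds(c(row_dir, col_dir))),
    dcm_elem(0x0028, 0x0002, "US", dcm_u16(1)),
    dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_elem(0x0028, 0x0010, "US", dcm_u16(rows)),
    dcm_elem(0x0028, 0x0011, "US", dcm_u16(cols)),
    dcm_elem(0x0028, 0x0030, "DS", fmt_ds(c(s, s))),
    dcm_elem(0x0028, 0x0100, "US", dcm_u16(16)),
    dcm_elem(0x0028, 0x0101, "US", dcm_u16(16)),
    dcm_elem(0x0028, 0x0102, "US", dcm_u16(15)),
    dcm_elem(0x0028, 0x0103, "US", dcm_u16(1)),
    dcm_elem(0x0028, 0x1052, "DS", "0"),
    dcm_elem(0x0028, 0x1053, "DS", "1"),
    dcm_elem(0x7FE0, 0x0010, "OW",
             writeBin(as.integer(t(px)), raw(), size = 2, endian = "little"))
  )
  meta_body <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_elem(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_elem(0x0002, 0x0003, "UI", sop_uid),
    dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_elem(0x0002, 0x0012, "UI", paste0(dcm_uid_root, "0.1"))
  )
  meta <- c(dcm_elem(0x0002, 0x0000, "UL", dcm_u32(length(meta_body))), meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

#' Read a DICOM CT image written by [write_dicom_ct()]
#'
#' Parses an explicit-VR little-endian CT file and reconstructs both the
#' pixel matrix and the `stereo_plane` from `ImagePositionPatient`,
#' `ImageOrientationPatient` and `PixelSpacing`.
#'
#' @param path DICOM file path.
#' @return A `stereo_image` (pixel values after rescale slope/intercept).
#' @export
read_dicom_ct <- function(path) {
  buf <- readBin(path, "raw", file.info(path)$size)
  if (!identical(rawToChar(buf[129:132]), "DICM"))
    stop_classed("stereoloc_bad_dicom", "not a DICOM part-10 file")
  pos <- 133
  tags <- list()
  u16 <- function(at) readBin(buf[at:(at + 1)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(buf[at:(at + 3)], "integer", size = 4,
                              endian = "little")
  while (pos + 7 <= length(buf)) {
    group <- u16(pos); elem <- u16(pos + 2)
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8); body <- pos + 12
    } else {
      len <- u16(pos + 6); body <- pos + 8
    }
    key <- sprintf("%04x%04x", group, elem)
    tags[[key]] <- list(vr = vr, raw = buf[body:(body + len - 1)])
    pos <- body + len
  }
  gets <- function(key) {
    r <- tags[[key]]$raw
    sub(" +$", "", rawToChar(r[r != as.raw(0)]))
  }
  getds <- function(key) as.numeric(strsplit(gets(key), "\\\\")[[1]])
  getu16 <- function(key) readBin(tags[[key]]$raw, "integer", size = 2,
                                  endian = "little", signed = FALSE)
  rows <- getu16("00280010"); cols <- getu16("00280011")
  spacing <- getds("00280030")[1]
  ipp <- getds("00200032"); iop <- getds("00200037")
  intercept <- getds("00281052"); slope <- getds("00281053")
  pxv <- readBin(tags[["7fe00010"]]$raw, "integer", n = rows * cols,
                 size = 2, endian = "little", signed = TRUE)
  px <- t(matrix(pxv, cols, rows)) * slope + intercept
  e_u <- frame_from_lps(iop[1:3])
  e_v <- -frame_from_lps(iop[4:6])
  p11 <- frame_from_lps(ipp)
  uv11 <- pixel_to_uv(1, 1, rows, cols, spacing)
  origin <- p11 - uv11[1] * e_u - uv11[2] * e_v
  plane <- structure(list(origin = origin, e_u = e_u, e_v = e_v,
                          normal = cross3(e_u, e_v)),
                     class = "stereo_plane")
  structure(list(pixels = px, plane = plane, pixel_spacing = spacing,
                 rod_diameter = 3, rod_value = max(px),
                 background_value = min(px)),
            class = "stereo_image")
}
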