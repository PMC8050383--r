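# Minimal DICOM series I/O (explicit-VR little endian, uncompressed,
# single-frame CT slices). This is deliberately small plumbing: enough to
# round-trip the package's own volumes and read well-formed scanner exports
# of the same transfer syntax; it is not a general DICOM toolkit.

dcm_uid_root <- "2.25."

dcm_pad <- function(s, nul = FALSE) {
  b <- charToRaw(as.character(s))
  if (length(b) %% 2 == 1) b <- c(b, if (nul) as.raw(0) else charToRaw(" "))
  b
}

dcm_element <- function(group, element, vr, value) {
  head <- writeBin(as.integer(c(group, element)), raw(), size = 2, endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    body <- value
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(body), raw(), size = 4, endian = "little"), body)
  } else {
    body <- if (vr == "US") {
      writeBin(as.integer(value), raw(), size = 2, endian = "little")
    } else {
      dcm_pad(value, nul = vr == "UI")
    }
    c(head, charToRaw(vr),
      writeBin(length(body), raw(), size = 2, endian = "little"), body)
  }
}

#' Write a CT volume as a DICOM series
#'
#' Emits one explicit-VR little-endian CT slice file per z index
#' (`slice_0001.dcm`, ...), with geometry tags (ImagePositionPatient,
#' ImageOrientationPatient, PixelSpacing, SliceThickness) taken from the
#' volume and intensities stored as signed 16-bit HU (rescale 1/0).
#'
#' @param volume a `ct_volume`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(volume, dir) {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$voxels)
  iop <- sprintf("%.10g", c(volume$orientation[, 1], volume$orientation[, 2]))
  series_uid <- paste0(dcm_uid_root, "1", format(round(abs(sum(volume$voxels)) %% 1e8)))
  ds <- function(x) paste(sprintf("%.10g", x), collapse = "\\")
  for (k in seq_len(d[3])) {
    ipp <- volume$origin + volume$orientation[, 3] * volume$spacing[3] * (k - 1)
    slice <- volume$voxels[, , k]
    pix <- as.integer(round(pmin(pmax(slice, -32768), 32767)))
    pixel_raw <- writeBin(pix, raw(), size = 2, endian = "little")
    meta <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_element(0x0002, 0x0003, "UI", paste0(series_uid, ".", k)),
      dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
      dcm_element(0x0002, 0x0012, "UI", paste0(dcm_uid_root, "999"))
    )
    group_len <- c(writeBin(as.integer(c(0x0002, 0x0000)), raw(), size = 2, endian = "little"),
                   charToRaw("UL"),
                   writeBin(4L, raw(), size = 2, endian = "little"),
                   writeBin(length(meta), raw(), size = 4, endian = "little"))
    dataset <- c(
      dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_element(0x0008, 0x0018, "UI", paste0(series_uid, ".", k)),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0018, 0x0050, "DS", sprintf("%.10g", volume$spacing[3])),
      dcm_element(0x0020, 0x000D, "UI", paste0(series_uid, ".0")),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_element(0x0020, 0x0032, "DS", ds(ipp)),
      dcm_element(0x0020, 0x0037, "DS", paste(iop, collapse = "\\")),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[2]), # Rows (y)
      dcm_element(0x0028, 0x0011, "US", d[1]), # Columns (x)
      dcm_element(0x0028, 0x0030, "DS", ds(c(volume$spacing[2], volume$spacing[1]))),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 1L),
      dcm_element(0x0028, 0x1052, "DS", "0"),
      dcm_element(0x0028, 0x1053, "DS", "1"),
      dcm_element(0x7FE0, 0x0010, "OW", pixel_raw)
    )
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(group_len, meta, dataset), con)
    close(con)
  }
  invisible(dir)
}

# parse one explicit-VR little-endian file into a tag list
dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stopf("not a DICOM file (missing DICM magic): %s", path)
  pos <- 133L
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8 <= length(raw) + 1) {
    grp <- readBin(raw[pos:(pos + 1)], "integer", size = 2, endian = "little", signed = FALSE)
    ele <- readBin(raw[(pos + 2):(pos + 3)], "integer", size = 2, endian = "little", signed = FALSE)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- readBin(raw[(pos + 8):(pos + 11)], "integer", size = 4, endian = "little")
      vstart <- pos + 12L
    } else {
      len <- readBin(raw[(pos + 6):(pos + 7)], "integer", size = 2, endian = "little", signed = FALSE)
      vstart <- pos + 8L
    }
    if (len < 0 || vstart + len - 1 > length(raw))
      stopf("truncated DICOM element (%04x,%04x) in %s", grp, ele, path)
    val_raw <- if (len > 0) raw[vstart:(vstart + len - 1)] else raw(0)
    key <- sprintf("%04x,%04x", grp, ele)
    out[[key]] <- switch(vr,
      US = readBin(val_raw, "integer", n = len / 2, size = 2, endian = "little", signed = FALSE),
      UL = readBin(val_raw, "integer", n = len / 4, size = 4, endian = "little"),
      OW = val_raw,
      OB = val_raw,
      trimws(rawToChar(val_raw[val_raw != as.raw(0)]), which = "right")
    )
    pos <- vstart + len
  }
  out
}

dcm_numeric <- function(tags, key, path) {
  v <- tags[[key]]
  if (is.null(v)) stopf("DICOM tag (%s) missing in %s", key, path)
  if (is.character(v)) as.numeric(strsplit(v, "\\", fixed = TRUE)[[1]]) else as.numeric(v)
}

#' Read a DICOM series directory into a CT volume
#'
#' All slices must share orientation and a uniform slice spacing (tolerance
#' 1e-3 mm); a gap in the slice positions is reported as a missing slice
#' with its index. Intensities are rescaled to HU via RescaleSlope and
#' RescaleIntercept.
#'
#' @param dir directory containing `.dcm` files of one series.
#' @return A `ct_volume`.
#' @export
read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stopf("DICOM directory not found: %s", dir)
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) < 2) stopf("need at least 2 DICOM slices in %s", dir)
  slices <- lapply(files, function(f) {
    tags <- dcm_parse_file(f)
    rows <- dcm_numeric(tags, "0028,0010", f)
    cols <- dcm_numeric(tags, "0028,0011", f)
    psp <- dcm_numeric(tags, "0028,0030", f) # row spacing (y), col spacing (x)
    ipp <- dcm_numeric(tags, "0020,0032", f)
    iop <- dcm_numeric(tags, "0020,0037", f)
    slope <- tryCatch(dcm_numeric(tags, "0028,1053", f), error = function(e) 1)
    inter <- tryCatch(dcm_numeric(tags, "0028,1052", f), error = function(e) 0)
    pix_raw <- tags[["7fe0,0010"]]
    if (is.null(pix_raw)) stopf("no pixel data in %s", f)
    pix <- readBin(pix_raw, "integer", n = rows * cols, size = 2, endian = "little")
    list(ipp = ipp, iop = iop, nx = cols, ny = rows,
         sp = c(psp[2], psp[1]), hu = pix * slope + inter)
  })
  iop0 <- slices[[1]]$iop
  for (s in slices)
    if (max(abs(s$iop - iop0)) > 1e-6)
      stopf("slices disagree on image orientation in %s", dir)
  rdir <- iop0[1:3]; cdir <- iop0[4:6]
  normal <- crossprod3(rdir, cdir)
  pos <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]
  dz <- diff(pos)
  step <- stats::median(dz)
  if (step <= 0) stopf("duplicate slice positions in %s", dir)
  gaps <- which(abs(dz - step) > 1e-3)
  if (length(gaps))
    stopf("non-uniform slice spacing in %s: missing slice at index %d (gap %.4g mm, expected %.4g mm)",
          dir, gaps[1] + 1L, dz[gaps[1]], step)
  nx <- slices[[1]]$nx; ny <- slices[[1]]$ny
  vox <- array(NA_real_, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$hu
  ct_volume(vox,
            spacing = c(slices[[1]]$sp, step),
            origin = slices[[1]]$ipp,
            orientation = cbind(rdir, cdir, normal))
}
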