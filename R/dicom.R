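# Minimal DICOM support for CT slice stacks.
#
# Scope: uncompressed single-frame grayscale slices in Explicit VR Little
# Endian (transfer syntax 1.2.840.10008.1.2.1) or Implicit VR Little
# Endian (1.2.840.10008.1.2), 16-bit pixel data. This covers standard
# exported CT series; encapsulated/compressed transfer syntaxes are
# rejected with a clear error. Rescale slope/intercept are applied so
# voxels come back in HU.

DICM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICM_IMPLICIT_LE <- "1.2.840.10008.1.2"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length.
.vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_uint <- function(raw, size) {
  sum(as.integer(raw[seq_len(size)]) * 256^(seq_len(size) - 1))
}

# Parse one DICOM file into a named list of elements keyed "gggg,eeee".
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  n <- length(raw)
  elements <- list()
  explicit <- TRUE   # file meta group is always explicit
  ts <- DICM_EXPLICIT_LE
  meta_done <- FALSE

  while (pos + 7L <= n) {
    group <- read_uint(raw[pos:(pos + 1L)], 2L)
    elem <- read_uint(raw[(pos + 2L):(pos + 3L)], 2L)
    pos <- pos + 4L
    if (!meta_done && group != 2L) {
      meta_done <- TRUE
      explicit <- identical(ts, DICM_EXPLICIT_LE)
    }
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% .vr_long) {
        len <- read_uint(raw[(pos + 4L):(pos + 7L)], 4L)
        pos <- pos + 8L
      } else {
        len <- read_uint(raw[(pos + 2L):(pos + 3L)], 2L)
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- read_uint(raw[pos:(pos + 3L)], 4L)
      pos <- pos + 4L
    }
    if (len == 0xFFFFFFFF)
      stop("undefined-length DICOM elements are not supported: ", path)
    if (pos + len - 1L > n)
      stop("corrupt DICOM file (element overruns file): ", path)
    key <- sprintf("%04x,%04x", group, elem)
    elements[[key]] <- raw[seq.int(pos, length.out = len)]
    pos <- pos + len
    if (key == "0002,0010") {
      ts <- trimws(rawToChar(strip_nul(elements[[key]])))
      if (!ts %in% c(DICM_EXPLICIT_LE, DICM_IMPLICIT_LE))
        stop("unsupported DICOM transfer syntax '", ts, "' in ", path)
    }
  }
  elements
}

strip_nul <- function(v) {
  while (length(v) && v[length(v)] == as.raw(0L)) v <- v[-length(v)]
  v
}

dicom_string <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(strip_nul(v)))
}

dicom_numbers <- function(el, key) {
  s <- dicom_string(el, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_uint16 <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  read_uint(v, 2L)
}

# Read one directory of DICOM slices into a phase_volume. All slices must
# share dimensions, in-plane pixel spacing and image orientation; slices
# are stacked in ascending order of the z component of Image Position
# (Patient). HU = stored * RescaleSlope + RescaleIntercept.
read_dicom_series <- function(dir, phase_label = NULL) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files))
    files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no DICOM files found in ", dir)

  slices <- lapply(files, function(f) {
    el <- parse_dicom_file(f)
    rows <- dicom_uint16(el, "0028,0010")
    cols <- dicom_uint16(el, "0028,0011")
    if (is.null(rows) || is.null(cols))
      stop("corrupt DICOM file (missing Rows/Columns): ", f)
    bits <- dicom_uint16(el, "0028,0100")
    if (!is.null(bits) && bits != 16L)
      stop("only 16-bit DICOM pixel data is supported: ", f)
    signed <- identical(dicom_uint16(el, "0028,0103"), 1L) ||
      identical(dicom_uint16(el, "0028,0103"), 1)
    px <- el[["7fe0,0010"]]
    if (is.null(px) || length(px) < 2L * rows * cols)
      stop("corrupt DICOM file (missing pixel data): ", f)
    stored <- readBin(px, "integer", n = rows * cols, size = 2L,
                      signed = signed, endian = "little")
    slope <- dicom_numbers(el, "0028,1053")
    inter <- dicom_numbers(el, "0028,1052")
    if (is.null(slope)) slope <- 1
    if (is.null(inter)) inter <- 0
    pspc <- dicom_numbers(el, "0028,0030")
    if (is.null(pspc)) pspc <- c(1, 1)
    ipp <- dicom_numbers(el, "0020,0032")
    if (is.null(ipp)) ipp <- c(0, 0, 0)
    iop <- dicom_numbers(el, "0020,0037")
    if (is.null(iop)) iop <- c(1, 0, 0, 0, 1, 0)
    # PixelData runs column-fastest within a row, rows top to bottom, so
    # matrix(nrow = cols) yields [x, y].
    list(pix = matrix(stored * slope + inter, nrow = cols),
         spacing = pspc, ipp = ipp, iop = iop,
         thickness = dicom_numbers(el, "0018,0050"), file = f)
  })

  ref <- slices[[1L]]
  for (s in slices) {
    if (!identical(dim(s$pix), dim(ref$pix)))
      stop("DICOM series has mixed slice dimensions in ", dir)
    if (max(abs(s$spacing - ref$spacing)) > 1e-6)
      stop("DICOM series has mixed in-plane spacing in ", dir)
    if (max(abs(s$iop - ref$iop)) > 1e-6)
      stop("DICOM series has mixed image orientation in ", dir)
  }
  zs <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(zs)
  slices <- slices[ord]
  zs <- zs[ord]
  nz <- length(slices)
  dz <- if (nz > 1L) {
    steps <- diff(zs)
    if (max(steps) - min(steps) > 1e-3)
      stop("DICOM series has non-uniform slice positions in ", dir)
    mean(steps)
  } else if (!is.null(ref$thickness)) ref$thickness else 1
  if (dz <= 0) stop("DICOM slice positions are not strictly increasing")

  arr <- array(0, dim = c(dim(ref$pix), nz))
  for (k in seq_len(nz)) arr[, , k] <- slices[[k]]$pix
  # DICOM PixelSpacing is (row spacing, column spacing) = (dy, dx).
  phase_volume(arr,
               spacing = c(ref$spacing[2], ref$spacing[1], dz),
               origin = slices[[1L]]$ipp,
               phase_label = phase_label)
}

# --- writer (fixture/export support) ---------------------------------------

raw_uint <- function(x, size) {
  out <- raw(size)
  x <- as.numeric(x)
  for (i in seq_len(size)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

dicom_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("OB", "UI")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- c(raw_uint(group, 2L), raw_uint(elem, 2L), charToRaw(vr))
  if (vr %in% .vr_long) {
    c(head, raw(2L), raw_uint(length(value_raw), 4L), value_raw)
  } else {
    c(head, raw_uint(length(value_raw), 2L), value_raw)
  }
}

dicom_str_element <- function(group, elem, vr, s) {
  dicom_element(group, elem, vr, charToRaw(s))
}

#' Write one synthetic DICOM CT slice
#'
#' Writes a minimal single-frame CT slice in Explicit VR Little Endian with
#' 16-bit signed pixel data. Intended for building small synthetic series
#' (fixtures, phantom export); it emits only the geometry, rescale and
#' pixel-data elements that [read_phase_volume] consumes.
#'
#' @param pixels Numeric matrix `[x, y]` of slice values, stored as
#'   `round((pixels - intercept) / slope)`.
#' @param path Output file path.
#' @param spacing In-plane `(dx, dy)` spacing in mm.
#' @param position Image Position (Patient), mm; the z component orders the
#'   slices of a series.
#' @param slope,intercept Rescale slope/intercept relating stored values to
#'   HU.
#' @param orientation Image Orientation (Patient) direction cosines.
#' @param thickness Slice thickness in mm.
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(pixels, path, spacing = c(1, 1),
                              position = c(0, 0, 0), slope = 1,
                              intercept = 0,
                              orientation = c(1, 0, 0, 0, 1, 0),
                              thickness = 1) {
  stopifnot(is.matrix(pixels))
  stored <- round((pixels - intercept) / slope)
  if (any(stored < -32768 | stored > 32767))
    stop("stored pixel values exceed 16-bit signed range")
  ds <- function(x) paste(format(x, trim = TRUE, scientific = FALSE),
                          collapse = "\\")
  meta <- c(
    dicom_str_element(0x0002, 0x0010, "UI", DICM_EXPLICIT_LE))
  body <- c(
    dicom_str_element(0x0008, 0x0060, "CS", "CT"),
    dicom_str_element(0x0018, 0x0050, "DS", ds(thickness)),
    dicom_str_element(0x0020, 0x0032, "DS", ds(position)),
    dicom_str_element(0x0020, 0x0037, "DS", ds(orientation)),
    dicom_element(0x0028, 0x0010, "US", raw_uint(ncol(pixels), 2L)),  # Rows
    dicom_element(0x0028, 0x0011, "US", raw_uint(nrow(pixels), 2L)),  # Cols
    # PixelSpacing is (row spacing, column spacing) = (dy, dx)
    dicom_str_element(0x0028, 0x0030, "DS", ds(c(spacing[2], spacing[1]))),
    dicom_element(0x0028, 0x0100, "US", raw_uint(16L, 2L)),
    dicom_element(0x0028, 0x0101, "US", raw_uint(16L, 2L)),
    dicom_element(0x0028, 0x0102, "US", raw_uint(15L, 2L)),
    dicom_element(0x0028, 0x0103, "US", raw_uint(1L, 2L)),
    dicom_str_element(0x0028, 0x1052, "DS", ds(intercept)),
    dicom_str_element(0x0028, 0x1053, "DS", ds(slope)),
    dicom_element(0x7fe0, 0x0010, "OW",
                  writeBin(as.integer(stored), raw(), size = 2L,
                           endian = "little")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}
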