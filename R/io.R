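#' Read and write dose/density grids
#'
#' Two on-disk representations are supported and auto-detected by file
#' extension:
#'
#' * **Internal grid format** (`.ccd`): one line of JSON metadata
#'   (`dims`, `spacing_mm`, `origin_mm`, `unit`, `format_version`) followed
#'   by the voxel values as flat little-endian 32-bit floats in x-fastest
#'   order. Round trips preserve geometry exactly and values to single
#'   precision.
#' * **DICOM RT Dose** (`.dcm`): a GRID-type single frame-of-reference
#'   subset, explicit VR little endian. `DoseGridScaling`,
#'   `GridFrameOffsetVector`, `PixelSpacing` and `ImagePositionPatient` are
#'   honored; 32-bit unsigned pixel data. Only uniform frame offsets are
#'   accepted.
#'
#' @param path file path; extension `.dcm`/`.DCM` selects DICOM, anything
#'   else the internal format.
#' @param grid a [grid3d()] to write.
#' @param unit value unit recorded in the header (internal format only).
#' @return `read_dose_grid` returns a [grid3d()].
#' @export
read_dose_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.dcm$", path, ignore.case = TRUE)) read_rtdose_dicom(path)
  else read_ccd(path)
}

#' @rdname read_dose_grid
#' @export
write_dose_grid <- function(grid, path, unit = "Gy") {
  stopifnot(inherits(grid, "grid3d"))
  if (grepl("\\.dcm$", path, ignore.case = TRUE)) write_rtdose_dicom(grid, path)
  else write_ccd(grid, path, unit)
  invisible(path)
}

read_ccd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated header in ", path)
    if (ch == "\n") break
    header <- c(header, ch)
  }
  h <- jsonlite::fromJSON(paste(header, collapse = ""))
  for (f in c("dims", "spacing_mm", "origin_mm"))
    if (is.null(h[[f]])) stop("internal grid header missing field: ", f)
  n <- prod(h$dims)
  vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (length(vals) != n) stop("truncated value block in ", path)
  grid3d(array(vals, dim = h$dims), h$spacing_mm, h$origin_mm)
}

write_ccd <- function(grid, path, unit = "Gy") {
  h <- jsonlite::toJSON(list(format_version = 1L,
                             dims = dim(grid$values),
                             spacing_mm = grid$spacing,
                             origin_mm = grid$origin,
                             unit = unit),
                        auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(h, "\n"), con, eos = NULL)
  writeBin(as.numeric(grid$values), con, size = 4L, endian = "little")
}

## ---- minimal DICOM RT Dose (explicit VR little endian) ----

UID_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
dcm_uint32 <- function(x) {
  # R has no unsigned type; values < 2^31 only
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- c(dcm_uint16(group), dcm_uint16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "UN", "SQ", "UT")) {
    c(head, as.raw(c(0L, 0L)), dcm_uint32(length(value_raw)), value_raw)
  } else {
    c(head, dcm_uint16(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))
dcm_us  <- function(group, elem, x) dcm_element(group, elem, "US", dcm_uint16(x))
dcm_ds  <- function(group, elem, x, digits = 10)
  dcm_str(group, elem, "DS",
          paste(trimws(formatC(x, digits = digits, format = "g")),
                collapse = "\\"))

ccdose_uid <- function() {
  # private test-range root; uniqueness within a session is all that is
  # needed. A process counter keeps this off the user's RNG stream.
  k <- get0("uid_counter", envir = .ccdose_env, ifnotfound = 0L) + 1L
  assign("uid_counter", k, envir = .ccdose_env)
  paste0("1.2.826.0.1.3680043.9999.",
         format(floor(as.numeric(Sys.time())), scientific = FALSE),
         ".", Sys.getpid(), ".", k)
}

write_rtdose_dicom <- function(grid, path) {
  d <- dim(grid$values)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  vmax <- max(grid$values, 0)
  scaling <- if (vmax > 0) vmax / (2^31 - 1) else 1.0
  stored <- as.integer(round(grid$values / scaling))
  # frame-major, row (y) then column (x): x fastest within a row
  px <- writeBin(as.vector(stored), raw(), size = 4L, endian = "little")
  inst_uid <- ccdose_uid()

  meta <- c(
    dcm_str(0x0002, 0x0002, "UI", UID_RTDOSE),
    dcm_str(0x0002, 0x0003, "UI", inst_uid),
    dcm_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_str(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9999.1")
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint32(length(meta))), meta)

  offsets <- (seq_len(nz) - 1) * grid$spacing[3]
  body <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_RTDOSE),
    dcm_str(0x0008, 0x0018, "UI", inst_uid),
    dcm_str(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_ds(0x0020, 0x0032, grid$origin),
    dcm_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_str(0x0028, 0x0008, "IS", as.character(nz)),
    dcm_element(0x0028, 0x0009, "AT", c(dcm_uint16(0x3004), dcm_uint16(0x000C))),
    dcm_us(0x0028, 0x0010, ny),          # Rows
    dcm_us(0x0028, 0x0011, nx),          # Columns
    dcm_ds(0x0028, 0x0030, grid$spacing[c(2, 1)]),  # row, col spacing
    dcm_us(0x0028, 0x0100, 32L),
    dcm_us(0x0028, 0x0101, 32L),
    dcm_us(0x0028, 0x0102, 31L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_str(0x3004, 0x0002, "CS", "GY"),
    dcm_str(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_str(0x3004, 0x000A, "CS", "PLAN"),
    dcm_ds(0x3004, 0x000C, offsets, digits = 10),
    dcm_ds(0x3004, 0x000E, scaling, digits = 16),
    dcm_element(0x7FE0, 0x0010, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0L), 128L), con)
  writeChar("DICM", con, eos = NULL)
  writeBin(c(meta, body), con)
}

read_dcm_elements <- function(raw) {
  pos <- 1L
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM magic)")
  pos <- 133L
  out <- list()
  n <- length(raw)
  u16 <- function(i) readBin(raw[i:(i + 1L)], "integer", size = 2L,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(raw[i:(i + 3L)], "integer", size = 4L,
                             endian = "little")
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "UN", "SQ", "UT")) {
      len <- u32(pos + 8L); data_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); data_at <- pos + 8L
    }
    if (len < 0L) stop("unsupported undefined-length element")
    out[[sprintf("%04X,%04X", group, elem)]] <-
      list(vr = vr, data = if (len > 0L) raw[data_at:(data_at + len - 1L)] else raw(0))
    pos <- data_at + len
  }
  out
}

dcm_get <- function(els, key, what = c("str", "num", "us")) {
  what <- match.arg(what)
  e <- els[[key]]
  if (is.null(e)) stop("DICOM RT Dose missing required tag (", key, ")")
  txt <- function(d) sub(" +$", "", rawToChar(d[d != as.raw(0L)]))
  switch(what,
         str = txt(e$data),
         num = as.numeric(strsplit(txt(e$data), "\\\\")[[1]]),
         us  = readBin(e$data, "integer", size = 2L, endian = "little",
                       signed = FALSE))
}

read_rtdose_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  els <- read_dcm_elements(raw)
  nx <- dcm_get(els, "0028,0011", "us")
  ny <- dcm_get(els, "0028,0010", "us")
  nz <- as.integer(dcm_get(els, "0028,0008", "str"))
  ps <- dcm_get(els, "0028,0030", "num")     # row (dy), col (dx)
  origin <- dcm_get(els, "0020,0032", "num")
  gfov <- dcm_get(els, "3004,000C", "num")
  scaling <- dcm_get(els, "3004,000E", "num")
  if (length(gfov) != nz) stop("GridFrameOffsetVector length mismatch")
  dz <- diff(gfov)
  if (nz > 1 && (any(dz <= 0) || max(abs(dz - dz[1])) > 1e-6 * max(abs(dz))))
    stop("non-uniform GridFrameOffsetVector is not supported")
  dz1 <- if (nz > 1) dz[1] else ps[2]
  px <- els[["7FE0,0010"]]
  if (is.null(px)) stop("DICOM RT Dose missing required tag (7FE0,0010)")
  stored <- readBin(px$data, "integer", n = nx * ny * nz, size = 4L,
                    endian = "little")
  grid3d(array(stored * scaling, dim = c(nx, ny, nz)),
         spacing = c(ps[2], ps[1], dz1),
         origin = origin + c(0, 0, gfov[1]))
}
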