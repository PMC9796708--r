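# Minimal C3D motion-capture reader/writer.
#
# Supports the common modern variant of the format: Intel (little-endian)
# byte order, 32-bit float point data, point labels / units / rate in the
# parameter section. Analog channels and integer-scaled point data are out
# of scope; files using them are rejected with a clear error.

C3D_BLOCK <- 512L

#' Read point data from a C3D file
#'
#' @param path path to a `.c3d` file.
#' @return A list with `positions` (frames x markers x 3 array, labelled),
#'   `sampling_rate` (frames/s) and `units` (`"m"` or `"mm"`).
#' @export
read_c3d <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = C3D_BLOCK)
  u8 <- function(x, i) as.integer(x[i])
  u16 <- function(x, i) u8(x, i) + 256L * u8(x, i + 1L)
  f32 <- function(x, i) readBin(x[i:(i + 3L)], "double", size = 4, endian = "little")

  param_block <- u8(hdr, 1)
  if (u8(hdr, 2) != 80L) stop_kin("not a C3D file (magic byte): ", path)
  n_points <- u16(hdr, 3)
  n_analog <- u16(hdr, 5)
  first_frame <- u16(hdr, 7)
  last_frame <- u16(hdr, 9)
  scale <- f32(hdr, 13)
  data_start <- u16(hdr, 17)
  rate <- f32(hdr, 21)
  n_frames <- last_frame - first_frame + 1L

  if (scale >= 0) stop_kin("integer-scaled C3D point data not supported")
  if (n_analog != 0L) stop_kin("C3D analog channels not supported")

  # ---- parameter section -------------------------------------------------
  seek(con, (param_block - 1L) * C3D_BLOCK)
  phdr <- readBin(con, "raw", n = 4L)
  n_param_blocks <- as.integer(phdr[3])
  proc <- as.integer(phdr[4])
  if (proc != 84L) stop_kin("only Intel-processor C3D files are supported")
  praw <- readBin(con, "raw", n = n_param_blocks * C3D_BLOCK - 4L)

  labels <- NULL
  units <- "m"
  pos <- 1L
  groups <- character(0) # id -> name
  repeat {
    if (pos + 1L > length(praw)) break
    n_name <- readBin(praw[pos], "integer", size = 1, signed = TRUE)
    gid <- readBin(praw[pos + 1L], "integer", size = 1, signed = TRUE)
    if (n_name == 0L) break
    n_name <- abs(n_name)
    name <- rawToChar(praw[(pos + 2L):(pos + 1L + n_name)])
    off_at <- pos + 2L + n_name
    offset <- u16(praw, off_at)
    # offset counts from the byte following the 2-byte pointer
    nxt <- if (offset == 0L) NA_integer_ else off_at + 2L + offset
    body_end <- if (is.na(nxt)) length(praw) else min(length(praw), nxt - 1L)
    if (gid < 0) {
      groups[as.character(-gid)] <- name
    } else {
      gname <- unname(groups[as.character(gid)])
      p <- parse_c3d_parameter(praw[(off_at + 2L):body_end])
      if (identical(gname, "POINT")) {
        if (name == "LABELS") labels <- p
        if (name == "UNITS") units <- trimws(p[1])
      }
    }
    if (is.na(nxt)) break
    pos <- nxt
  }

  # ---- point data --------------------------------------------------------
  seek(con, (data_start - 1L) * C3D_BLOCK)
  vals <- readBin(
    con, "double", n = n_frames * n_points * 4L, size = 4, endian = "little"
  )
  m <- matrix(vals, ncol = 4L, byrow = TRUE) # x, y, z, residual
  arr <- array(NA_real_, c(n_frames, n_points, 3))
  for (k in 1:3) {
    arr[, , k] <- matrix(m[, k], nrow = n_frames, ncol = n_points, byrow = TRUE)
  }
  if (!is.null(labels)) {
    labels <- trimws(labels)[seq_len(n_points)]
    dimnames(arr) <- list(NULL, labels, c("x", "y", "z"))
  }
  list(
    positions = arr,
    sampling_rate = rate,
    units = if (tolower(units) %in% c("mm", "millimeter", "millimeters")) "mm" else "m"
  )
}

# body = raw bytes of one parameter record after the 2-byte offset field
parse_c3d_parameter <- function(body) {
  type <- readBin(body[1], "integer", size = 1, signed = TRUE)
  n_dim <- as.integer(body[2])
  dims <- if (n_dim > 0) as.integer(body[3:(2L + n_dim)]) else integer(0)
  dstart <- 3L + n_dim
  n_elem <- if (length(dims)) prod(dims) else 1L
  if (type == -1L) { # char data; first dim = string length
    width <- if (length(dims)) dims[1] else n_elem
    n_str <- if (length(dims) > 1) prod(dims[-1]) else 1L
    out <- character(n_str)
    for (i in seq_len(n_str)) {
      from <- dstart + (i - 1L) * width
      out[i] <- rawToChar(body[from:(from + width - 1L)])
    }
    out
  } else if (type == 4L) {
    readBin(body[dstart:(dstart + 4L * n_elem - 1L)], "double",
            n = n_elem, size = 4, endian = "little")
  } else if (type == 2L) {
    readBin(body[dstart:(dstart + 2L * n_elem - 1L)], "integer",
            n = n_elem, size = 2, endian = "little")
  } else {
    readBin(body[dstart:(dstart + n_elem - 1L)], "integer",
            n = n_elem, size = 1, signed = TRUE)
  }
}

#' Write point data to a C3D file
#'
#' Writes the Intel/float variant read by [read_c3d()]: point positions,
#' labels, units and frame rate. Residuals are written as zero. Positions
#' are stored as 32-bit floats, the format's native precision.
#'
#' @param positions frames x markers x 3 array with marker labels as the
#'   second dimnames.
#' @param path output path.
#' @param sampling_rate frames per second.
#' @param units `"m"` or `"mm"` (declared in `POINT:UNITS`).
#' @return `path`, invisibly.
#' @export
write_c3d <- function(positions, path, sampling_rate = 120, units = "m") {
  stopifnot(length(dim(positions)) == 3L, dim(positions)[3] == 3L)
  labels <- dimnames(positions)[[2]]
  if (is.null(labels)) stop_kin("positions must carry marker labels")
  n_frames <- dim(positions)[1]
  n_points <- dim(positions)[2]

  # parameter section: POINT group with USED, LABELS, RATE, UNITS, SCALE
  label_width <- max(nchar(labels), 4L)
  labels_pad <- formatC(labels, width = label_width, flag = "-")

  f32raw <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")
  i16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  grp <- function(id, name) {
    nm <- charToRaw(name)
    # body after offset field: 1 byte description length (0)
    c(as.raw(length(nm)), as.raw(256L - id), nm, i16raw(1L), as.raw(0L))
  }
  par_rec <- function(gid, name, type, dims, data_raw, last = FALSE) {
    nm <- charToRaw(name)
    body <- c(
      as.raw(type + if (type < 0) 256L else 0L),
      as.raw(length(dims)), as.raw(dims),
      data_raw, as.raw(0L) # no description
    )
    offset <- if (last) 0L else length(body)
    c(as.raw(length(nm)), as.raw(gid), nm, i16raw(offset), body)
  }

  params <- c(
    grp(1L, "POINT"),
    par_rec(1L, "USED", 2L, 0L[0], i16raw(n_points)),
    par_rec(1L, "FRAMES", 2L, 0L[0], i16raw(n_frames)),
    par_rec(1L, "RATE", 4L, 0L[0], f32raw(sampling_rate)),
    par_rec(1L, "SCALE", 4L, 0L[0], f32raw(-1)),
    par_rec(1L, "UNITS", -1L, c(2L), charToRaw(formatC(units, width = 2, flag = "-"))),
    par_rec(1L, "LABELS", -1L, c(label_width, n_points),
            charToRaw(paste(labels_pad, collapse = "")), last = TRUE)
  )
  n_param_blocks <- ceiling((length(params) + 4L) / C3D_BLOCK)
  data_start_block <- 2L + n_param_blocks

  con <- file(path, "wb")
  on.exit(close(con))

  # header block
  hdr <- raw(C3D_BLOCK)
  hdr[1] <- as.raw(2L) # parameter section starts at block 2
  hdr[2] <- as.raw(80L)
  hdr[3:4] <- i16raw(n_points)
  hdr[5:6] <- i16raw(0L) # no analog
  hdr[7:8] <- i16raw(1L) # first frame
  hdr[9:10] <- i16raw(n_frames)
  hdr[11:12] <- i16raw(0L) # max interpolation gap
  hdr[13:16] <- f32raw(-1) # negative scale: float data
  hdr[17:18] <- i16raw(data_start_block)
  hdr[19:20] <- i16raw(0L) # analog samples per frame
  hdr[21:24] <- f32raw(sampling_rate)
  writeBin(hdr, con)

  # parameter section header + records, padded to whole blocks
  psec <- c(as.raw(c(1L, 80L)), as.raw(n_param_blocks), as.raw(84L), params)
  psec <- c(psec, raw(n_param_blocks * C3D_BLOCK - length(psec)))
  writeBin(psec, con)

  # frame-major point data: x, y, z, residual per point
  out <- array(0, c(4L, n_points, n_frames))
  for (k in 1:3) out[k, , ] <- t(positions[, , k])
  writeBin(f32raw(as.numeric(out)), con)
  invisible(path)
}
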