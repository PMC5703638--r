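## Minimal MRC-2014 volume I/O (modes 0, 1, 2), little-endian. The voxel
## size is taken from the cella/mx header fields. Data are stored
## column-major with x fastest (MRC convention); in memory the package
## uses (z, y, x) axis order, so axes are permuted on read/write.

#' Read an MRC volume
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32). The voxel size is
#' cella.x / mx when the header carries one; otherwise \code{voxelSize}
#' must be supplied.
#'
#' @param path MRC file path.
#' @param voxelSize override/fallback voxel size in nm (MRC headers store
#'   Angstroms; those are converted to nm on read).
#' @param polarity volume polarity tag, default "bf".
#' @return a \linkS4class{VolumeGrid}.
#' @export
readMRC <- function(path, voxelSize = NULL, polarity = "bf") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdrInt <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdrInt[1]; ny <- hdrInt[2]; nz <- hdrInt[3]; mode <- hdrInt[4]
  mxyz <- hdrInt[8:10]
  cella <- readBin(con, "numeric", n = 6, size = 4, endian = "little")[1:3]
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (nx <= 0 || ny <= 0 || nz <= 0) stop("malformed MRC header")
  seek(con, 1024 + nsymbt)
  n <- as.numeric(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    stop("unsupported MRC mode: ", mode))
  if (length(data) != n) stop("truncated MRC data block")
  arr <- array(data, dim = c(nx, ny, nz))
  arr <- aperm(arr, c(3, 2, 1))  # (x,y,z) -> (z,y,x)
  vs <- voxelSize
  if (is.null(vs)) {
    if (mxyz[1] > 0 && cella[1] > 0) vs <- cella[1] / mxyz[1] / 10
    else stop("MRC header has no voxel size; supply voxelSize=")
  }
  volumeGrid(arr, vs, polarity)
}

#' Write an MRC volume
#'
#' @param volume a \linkS4class{VolumeGrid} or \linkS4class{LabelVolume}.
#' @param path output path.
#' @param mode 2 (float32, default for intensity volumes), 0 or 1 (integer
#'   modes, used for label volumes; values are truncated to the type's
#'   range).
#' @return the path, invisibly.
#' @export
writeMRC <- function(volume, path, mode = NULL) {
  if (is(volume, "LabelVolume")) {
    arr <- volume@labels
    vs <- volume@voxelSize
    if (is.null(mode)) mode <- if (volume@nComponents < 128L) 0 else 1
  } else if (is(volume, "VolumeGrid")) {
    arr <- volume@data
    vs <- volume@voxelSize
    if (is.null(mode)) mode <- 2
  } else stop("volume must be a VolumeGrid or LabelVolume")
  d <- dim(arr)  # (z, y, x)
  arr <- aperm(arr, c(3, 2, 1))  # -> (x, y, z), x fastest on disk
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- integer(256)
  hdr[1] <- d[3]; hdr[2] <- d[2]; hdr[3] <- d[1]  # nx ny nz
  hdr[4] <- mode
  hdr[8] <- d[3]; hdr[9] <- d[2]; hdr[10] <- d[1] # mx my mz
  writeBin(as.integer(hdr[1:10]), con, size = 4, endian = "little")
  writeBin(as.numeric(c(d[3], d[2], d[1]) * vs * 10), con, size = 4,
           endian = "little")                      # cella, Angstrom
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 2, 3)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(arr), max(arr), mean(arr))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(0, 0)), con, size = 4, endian = "little") # ispg, nsymbt
  writeBin(raw(1024 - 96), con)
  ## MAP format stamp at byte offset 208
  seek(con, 208)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  seek(con, 1024)
  vals <- as.vector(arr)
  if (mode == 2) writeBin(as.numeric(vals), con, size = 4,
                          endian = "little")
  else writeBin(as.integer(vals), con,
                size = if (mode == 0) 1 else 2, endian = "little")
  invisible(path)
}
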