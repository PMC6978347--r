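#' Minimal MRC2014 volume/image I/O
#'
#' Reads and writes MRC2014 files in mode 2 (32-bit float), the interchange
#' format for cryo-EM images, volumes and tomograms. Only the fields needed
#' for calibrated grids are interpreted: dimensions, mode, cell dimensions
#' (voxel size = cell / n), and axis order 1,2,3. Data are written
#' little-endian with the standard machine stamp.
#'
#' @param path file path.
#' @param unit unit to attach to the returned grid ("A" or "nm"); the MRC
#'   header itself stores Angstrom by convention, so "nm" rescales by 10.
#' @return \code{read_mrc} returns an \code{image_grid} (nz == 1) or
#'   \code{volume_grid}; \code{write_mrc} returns \code{path} invisibly.
#' @export
read_mrc <- function(path, unit = c("A", "nm")) {
  unit <- match.arg(unit)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  if (mode != 2) stop("only MRC mode 2 (float32) is supported, got mode ", mode)
  hdr_flt <- readBin(con, "numeric", n = 6, size = 4, endian = "little")
  cella <- hdr_flt[1:3] # header words 11-13 = cell dimensions in Angstrom
  # skip the remainder of the 1024-byte header (already read 10*4 + 6*4 = 64)
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  vals <- readBin(con, "numeric", n = nx * ny * nz, size = 4,
                  endian = "little")
  voxel_A <- if (nx > 0 && cella[1] > 0) cella[1] / nx else 1
  voxel <- if (unit == "nm") voxel_A / 10 else voxel_A
  if (nz == 1L) {
    image_grid(matrix(vals, nx, ny), voxel)
  } else {
    volume_grid(array(vals, dim = c(nx, ny, nz)), voxel, unit = unit)
  }
}

#' @rdname read_mrc
#' @param grid an \code{image_grid} or \code{volume_grid}.
#' @export
write_mrc <- function(grid, path) {
  if (inherits(grid, "image_grid")) {
    vals <- grid$values
    d <- c(dim(vals), 1L)
    voxel_A <- grid$pixel_A
  } else if (inherits(grid, "volume_grid")) {
    vals <- grid$values
    d <- dim(vals)
    voxel_A <- if (grid$unit == "nm") grid$voxel * 10 else grid$voxel
  } else stop("grid must be an image_grid or volume_grid")

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2)                      # mode 2 = float32
  wi(c(0, 0, 0))             # nxstart nystart nzstart
  wi(d)                      # mx my mz
  wf(d * voxel_A)            # cella (Angstrom)
  wf(c(90, 90, 90))          # cellb
  wi(c(1, 2, 3))             # mapc mapr maps
  v <- as.numeric(vals)
  wf(c(min(v), max(v), mean(v)))   # dmin dmax dmean
  wi(c(1, 0))                # ispg, nsymbt
  wi(rep(0L, 25))            # extra (words 26-50)
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v))           # rms
  wi(0)                      # nlabl
  writeBin(raw(800), con)    # labels
  wf(v)
  invisible(path)
}
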