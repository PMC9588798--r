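# Minimal MRC/CCP4 volume reader and writer (MRC2014, mode 2 float32).
#
# Axis order is fixed to the column/row/section = x/y/z convention
# (mapc,mapr,maps = 1,2,3); the voxel size is recorded through the cell
# dimensions and the origin through the ORIGIN header words, so both
# survive a round trip bit-exactly at float32 precision.

#' Write a density map to an MRC/CCP4 file
#'
#' @param map a `density_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                              # nx, ny, nz
  wi(2)                              # mode 2: float32
  wi(c(0, 0, 0))                     # nxstart
  wi(d)                              # mx, my, mz
  wf(d * map$voxel)                  # cella
  wf(c(90, 90, 90))                  # cellb
  wi(c(1, 2, 3))                     # mapc, mapr, maps
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(1)                              # ispg
  wi(0)                              # nsymbt
  wi(rep(0L, 25))                    # extra (words 26-49, incl. exttyp slot)
  wf(map$origin)                     # origin x, y, z
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(map$values))          # rms
  wi(0)                              # nlabl
  writeBin(raw(800), con)            # labels
  wf(as.numeric(map$values))
  invisible(path)
}

#' Read a density map from an MRC/CCP4 file
#'
#' Supports mode 2 (float32) and mode 0 (int8) volumes with
#' mapc,mapr,maps = 1,2,3.
#'
#' @param path input path.
#' @return a `density_map`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (!mode %in% c(0, 2)) stop("unsupported MRC mode: ", mode)
  ri(3)                    # nxstart
  m <- ri(3)               # mx, my, mz
  cella <- rf(3)
  rf(3)                    # cellb
  axes <- ri(3)
  if (!identical(axes, c(1L, 2L, 3L)))
    stop("unsupported axis order (mapc,mapr,maps = ",
         paste(axes, collapse = ","), ")")
  rf(3); ri(1); ri(1)      # stats, ispg, nsymbt
  ri(25)                   # extra
  origin <- rf(3)
  seek(con, 1024)
  n <- prod(d)
  vals <- if (mode == 2) rf(n)
  else as.numeric(readBin(con, "integer", n, size = 1, endian = "little"))
  if (length(vals) != n) stop("truncated MRC data block in ", path)
  voxel <- cella[1] / m[1]
  density_map(array(vals, d), voxel, origin)
}
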