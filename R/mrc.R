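#' Construct a micrograph object
#'
#' A micrograph is a single 2D intensity image with a physical pixel size.
#' Matrices are indexed `image[y + 1, x + 1]` with 0-based pixel-center
#' coordinates `x` (column) and `y` (row) used everywhere in the package.
#'
#' @param image numeric matrix, rows = y, cols = x; all values finite,
#'   both dimensions at least 64
#' @param pixel_size pixel size in angstrom per pixel (> 0)
#' @param id stable identifier (defaults to `"micrograph"`)
#' @return an object of class `micrograph`
#' @export
micrograph <- function(image, pixel_size, id = "micrograph") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix")
  }
  if (any(!is.finite(image))) stop("image contains non-finite values")
  if (nrow(image) < 64 || ncol(image) < 64) {
    stop("micrograph dimensions must be at least 64x64, got ",
         nrow(image), "x", ncol(image))
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("pixel_size must be a single positive number")
  }
  structure(list(image = image, pixel_size = as.numeric(pixel_size),
                 id = as.character(id)),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph '%s': %d x %d px, %.4g A/px>\n",
              x$id, ncol(x$image), nrow(x$image), x$pixel_size))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$image)

.mrc_modes <- c(`0` = "int8", `1` = "int16", `2` = "float32")

#' Read an MRC2014 image file
#'
#' Reads modes 0 (signed 8-bit), 1 (signed 16-bit) and 2 (32-bit float),
#' single-section 2D images only. The pixel size is taken from the header
#' cell dimensions (`xlen/mx`); when the header stores a zero voxel size the
#' supplied default is used with a warning.
#'
#' @param path path to an MRC file
#' @param default_pixel_size fallback pixel size in angstrom when the header
#'   voxel size is zero
#' @param id identifier for the micrograph; defaults to the file name
#'   without extension
#' @return a [micrograph()]
#' @export
read_mrc <- function(path, default_pixel_size = 1.0, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  if (length(hdr_int) < 256) stop("MRC format error: truncated header in ", path)
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  mx <- hdr_int[8]; xlen <- hdr_num[11]
  nsymbt <- hdr_int[24]
  if (!as.character(mode) %in% names(.mrc_modes)) {
    stop("MRC format error: unsupported mode ", mode, " in ", path)
  }
  if (nx < 1 || ny < 1 || nz < 1 || nx > 65536 || ny > 65536) {
    stop("MRC format error: implausible dimensions in ", path)
  }
  if (nz > 1) {
    stop("MRC shape error: expected a single 2D section, found ",
         nz, " sections in ", path)
  }
  seek(con, 1024 + nsymbt)
  n <- nx * ny
  data <- switch(as.character(mode),
    `0` = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    `1` = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    `2` = readBin(con, "numeric", n = n, size = 4, endian = "little"))
  if (length(data) < n) {
    stop("MRC format error: truncated data block in ", path,
         " (expected ", n, " values, read ", length(data), ")")
  }
  # file stores x fastest; transpose to rows = y
  image <- t(matrix(as.numeric(data), nrow = nx, ncol = ny))
  if (mx > 0 && xlen > 0) {
    pixel_size <- xlen / mx
  } else {
    warning("MRC header of ", basename(path), " has zero voxel size; ",
            "using default ", default_pixel_size, " A/px")
    pixel_size <- default_pixel_size
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  micrograph(image, pixel_size, id = id)
}

#' Write a 2D image as MRC2014 mode 2 (32-bit float)
#'
#' @param x a [micrograph()] or numeric matrix
#' @param path output path
#' @param pixel_size pixel size in angstrom; taken from the micrograph when
#'   `x` is one
#' @return `path`, invisibly
#' @export
write_mrc <- function(x, path, pixel_size = NULL) {
  if (inherits(x, "micrograph")) {
    pixel_size <- pixel_size %||% x$pixel_size
    image <- x$image
  } else {
    pixel_size <- pixel_size %||% 1.0
    image <- x
  }
  nx <- ncol(image); ny <- nrow(image)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(c(nx, ny, 1, 2))                       # nx ny nz mode
  wi(c(0, 0, 0))                            # nxstart..
  wi(c(nx, ny, 1))                          # mx my mz
  wf(c(nx * pixel_size, ny * pixel_size, pixel_size))  # cella
  wf(c(90, 90, 90))                         # cellb
  wi(c(1, 2, 3))                            # mapc mapr maps
  wf(c(min(image), max(image), mean(image)))
  wi(c(0, 0))                               # ispg nsymbt
  wi(rep(0L, 25))                           # extra
  wf(c(0, 0, 0))                            # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(image))                      # rms
  wi(0L)                                    # nlabl
  writeBin(raw(800), con)                   # labels
  wf(as.numeric(t(image)))                  # x fastest
  invisible(path)
}
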