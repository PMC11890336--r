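#' In-memory image containers
#'
#' `image2d` holds one 2D slice; `image_stack` a stack of slices (a 3D
#' ultrasound volume reconstructed at fixed slice spacing). Data are stored
#' as R arrays indexed `[row, col(, slice)]` where rows advance along +y and
#' columns along +x; the physical center of pixel `(i, j)` (1-based) is
#' `origin + ((j - 0.5) * sx, (i - 0.5) * sy)`.
#'
#' @param data numeric matrix (`image2d`) or 3D array (`image_stack`).
#' @param pixel_spacing_mm positive spacing per axis: length 2 `(sx, sy)` for
#'   a slice, length 3 `(sx, sy, sz)` for a stack. The study's volumes use
#'   0.076 x 0.076 mm in-plane and 0.5 mm between slices.
#' @param origin_mm physical position of the image corner.
#' @export
image2d <- function(data, pixel_spacing_mm, origin_mm = c(0, 0)) {
  stopifnot(is.matrix(data))
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    stop_sp("image2d: pixel_spacing_mm must be 2 positive values")
  structure(list(data = data, spacing = as.numeric(pixel_spacing_mm),
                 origin = as.numeric(origin_mm)),
            class = "image2d")
}

#' @rdname image2d
#' @export
image_stack <- function(data, pixel_spacing_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(pixel_spacing_mm) != 3L || any(pixel_spacing_mm <= 0))
    stop_sp("image_stack: pixel_spacing_mm must be 3 positive values")
  structure(list(data = data, spacing = as.numeric(pixel_spacing_mm),
                 origin = as.numeric(origin_mm)),
            class = "image_stack")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %d x %d px, spacing %g x %g mm>\n",
              nrow(x$data), ncol(x$data), x$spacing[1], x$spacing[2]))
  invisible(x)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack %d x %d px x %d slices, spacing %g x %g x %g mm>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

as_grid_spec <- function(img) grid_spec(dim(img$data)[1:2], img$spacing[1:2], img$origin[1:2])

## ------------------------------- NRRD ---------------------------------

nrrd_type <- function(data) if (is.integer(data) || all(data == round(data) & data >= 0 & data <= 255)) "unsigned char" else "double"

#' Write / read NRRD
#'
#' Minimal NRRD (NRRD0004) support for the fields the pipeline uses: `type`
#' (`double`, `unsigned char`, and the common integer/float aliases on read),
#' `sizes`, `spacings` or diagonal `space directions`, `axis mins` /
#' `space origin`, `endian`, and `raw` or `ascii` encoding. Data are stored
#' in NRRD's x-fastest order. Spacing metadata is mandatory on read: a header
#' without any spacing field is an error, never silently assumed to be 1 mm.
#'
#' @param img an [image2d()] or [image_stack()].
#' @param path file path.
#' @param encoding `"raw"` (binary, exact) or `"ascii"` (text, full
#'   precision via 17 significant digits).
#' @return `read_nrrd` returns an [image2d()] or [image_stack()].
#' @export
write_nrrd <- function(img, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(img, "image2d") || inherits(img, "image_stack"))
  d <- dim(img$data)
  ndim <- length(d)
  type <- nrrd_type(img$data)
  # x-fastest: permute (row,col,...) -> (col,row,...)
  perm <- if (ndim == 2L) c(2L, 1L) else c(2L, 1L, 3L)
  vec <- as.vector(aperm(img$data, perm))
  sizes <- d[perm]
  hdr <- c("NRRD0004",
           "# generated by sonopath",
           paste0("type: ", type),
           paste0("dimension: ", ndim),
           paste0("sizes: ", paste(sizes, collapse = " ")),
           paste0("spacings: ", paste(sprintf("%.17g", img$spacing), collapse = " ")),
           paste0("axis mins: ", paste(sprintf("%.17g", img$origin), collapse = " ")),
           "endian: little",
           paste0("encoding: ", encoding),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(sprintf("%.17g", vec), collapse = " "), con)
  } else if (type == "unsigned char") {
    writeBin(as.raw(vec), con)
  } else {
    writeBin(as.numeric(vec), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) stop_sp("read_nrrd: file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!length(magic) || !grepl("^NRRD000[0-9]$", magic))
    stop_sp("read_nrrd: not an NRRD file (bad magic line): %s", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop_sp("read_nrrd: truncated header (no blank line before data)")
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(m) != 3L) stop_sp("read_nrrd: malformed header line: '%s'", line)
    fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  need <- function(f) {
    if (is.null(fields[[f]])) stop_sp("read_nrrd: required header field missing: '%s'", f)
    fields[[f]]
  }
  sizes <- as.integer(strsplit(need("sizes"), "[[:space:]]+")[[1]])
  ndim <- length(sizes)
  type <- need("type")
  encoding <- need("encoding")
  spacing <- if (!is.null(fields[["spacings"]])) {
    as.numeric(strsplit(fields[["spacings"]], "[[:space:]]+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    vapply(vecs, function(v) {
      sqrt(sum(as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])^2))
    }, 0, USE.NAMES = FALSE)
  } else {
    stop_sp("read_nrrd: no spacing metadata ('spacings' or 'space directions'); refusing to assume 1 mm")
  }
  origin <- if (!is.null(fields[["axis mins"]])) {
    as.numeric(strsplit(fields[["axis mins"]], "[[:space:]]+")[[1]])
  } else if (!is.null(fields[["space origin"]])) {
    as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  } else rep(0, ndim)
  n <- prod(sizes)
  vec <- if (encoding == "ascii") {
    scan(con, what = double(), n = n, quiet = TRUE)
  } else if (encoding == "raw") {
    endian <- fields[["endian"]] %||% "little"
    if (type %in% c("unsigned char", "uchar", "uint8", "uint8_t")) {
      as.integer(readBin(con, "raw", n = n))
    } else if (type %in% c("double", "float64")) {
      readBin(con, "double", n = n, size = 8L, endian = endian)
    } else if (type %in% c("float", "float32")) {
      readBin(con, "double", n = n, size = 4L, endian = endian)
    } else if (type %in% c("short", "int16", "int16_t", "int", "int32", "int32_t")) {
      sz <- if (grepl("16|short", type)) 2L else 4L
      readBin(con, "integer", n = n, size = sz, endian = endian)
    } else stop_sp("read_nrrd: unsupported type '%s'", type)
  } else stop_sp("read_nrrd: unsupported encoding '%s'", encoding)
  if (length(vec) != n) stop_sp("read_nrrd: data shorter than promised by 'sizes'")
  arr <- array(vec, dim = sizes)   # x-fastest
  perm <- if (ndim == 2L) c(2L, 1L) else c(2L, 1L, 3L)
  arr <- aperm(arr, perm)
  if (type %in% c("unsigned char", "uchar", "uint8", "uint8_t")) storage.mode(arr) <- "integer"
  if (ndim == 2L) image2d(arr, spacing, origin) else image_stack(arr, spacing, origin)
}

## ------------------------------- NIfTI --------------------------------

write_nifti_stack <- function(img, path) {
  d <- dim(img$data)
  arr <- if (length(d) == 2L) aperm(img$data, c(2L, 1L)) else aperm(img$data, c(2L, 1L, 3L))
  ni <- RNifti::asNifti(arr)
  RNifti::`pixdim<-`(ni, img$spacing) -> ni
  RNifti::writeNifti(ni, path)
  invisible(path)
}

read_nifti_stack <- function(path) {
  ni <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(ni)
  d <- dim(ni)
  arr <- array(as.numeric(ni), dim = d)
  if (length(d) == 3L && d[3] == 1L) { arr <- arr[, , 1L]; d <- d[1:2]; spacing <- spacing[1:2] }
  if (length(d) == 2L) {
    image2d(aperm(arr, c(2L, 1L)), spacing[1:2])
  } else if (length(d) == 3L) {
    image_stack(aperm(arr, c(2L, 1L, 3L)), spacing[1:3])
  } else stop_sp("read_volume: NIfTI with %d dimensions not supported", length(d))
}

## ---------------------------- dispatchers ------------------------------

#' Read / write an image volume
#'
#' Dispatches on file extension: `.nrrd` for NRRD, `.nii` / `.nii.gz` for
#' NIfTI-1. Round-trips preserve intensities exactly; spacing is exact for
#' NRRD and limited to single (32-bit float) precision for NIfTI because the
#' NIfTI-1 header stores `pixdim` as float32.
#'
#' @param path file path ending in `.nrrd`, `.nii` or `.nii.gz`.
#' @param img an [image2d()] or [image_stack()].
#' @param ... passed to the format writer (e.g. `encoding` for NRRD).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_sp("read_volume: file not found: %s", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) read_nrrd(path)
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) read_nifti_stack(path)
  else stop_sp("read_volume: unrecognized extension (want .nrrd, .nii, .nii.gz): %s", path)
}

#' @rdname read_volume
#' @export
write_volume <- function(img, path, ...) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) write_nrrd(img, path, ...)
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) write_nifti_stack(img, path)
  else stop_sp("write_volume: unrecognized extension (want .nrrd, .nii, .nii.gz): %s", path)
}

#' Read / write a 2D raster (PNG or TIFF)
#'
#' PNG and TIFF carry no physical spacing, so the reader requires it
#' explicitly; histology rasters exported at an arbitrary resolution are
#' accepted as long as their spacing is known.
#'
#' @param img an [image2d()] with intensities in `[0, 1]`.
#' @param path file ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_spacing_mm explicit pixel spacing for the reader.
#' @export
write_raster <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  z <- img$data
  if (min(z) < 0 || max(z) > 1) z <- (z - min(z)) / max(max(z) - min(z), 1e-12)
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(z, path)
  else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::writeTIFF(z, path, bits.per.sample = 16L)
  else stop_sp("write_raster: unrecognized extension (want .png/.tif): %s", path)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, pixel_spacing_mm) {
  if (missing(pixel_spacing_mm))
    stop_sp("read_raster: pixel_spacing_mm is required (PNG/TIFF store no spacing)")
  z <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) tiff::readTIFF(path)
       else stop_sp("read_raster: unrecognized extension: %s", path)
  if (length(dim(z)) == 3L) z <- z[, , 1L]
  image2d(z, pixel_spacing_mm)
}
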