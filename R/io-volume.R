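#' Read a labeled volume from TIFF or NRRD
#'
#' Multi-page TIFF (one page per z slice, 8/16-bit integer) and NRRD
#' (attached, `raw` or `text` encoding, integer type) are supported. NRRD
#' headers carry physical voxel spacings; plain TIFF does not, so reading a
#' TIFF requires an explicit `voxel_size` — the voxel size is never silently
#' assumed to be 1 um.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.nrrd`.
#' @param voxel_size optional `(dz, dy, dx)` um override; mandatory for TIFF.
#' @return a [labeled_volume()].
#' @export
read_labeled_volume <- function(path, voxel_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    hdr <- tiff::readTIFF(path, payload = FALSE)
    if (any(hdr$bits.per.sample > 16L))
      stop("TIFF has non-integer (float) pixel type; labeled volumes ",
           "must be 8- or 16-bit integer")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (!all(vapply(pages, is.integer, logical(1))))
      stop("TIFF has non-integer pixel type; labeled volumes must be integer")
    nz <- length(pages)
    ny <- nrow(pages[[1]])
    nx <- ncol(pages[[1]])
    lab <- array(0L, c(nz, ny, nx))
    for (k in seq_len(nz)) lab[k, , ] <- pages[[k]]
    if (is.null(voxel_size))
      stop("TIFF carries no voxel size; pass `voxel_size = c(dz, dy, dx)` um")
    labeled_volume(lab, voxel_size)
  } else if (ext == "nrrd") {
    vol <- read_nrrd(path)
    if (!is.null(voxel_size)) vol$voxel_size <- as.numeric(voxel_size)
    if (is.null(vol$voxel_size))
      stop("NRRD has no spacings; pass `voxel_size = c(dz, dy, dx)` um")
    labeled_volume(vol$labels, vol$voxel_size)
  } else {
    stop("unsupported volume format: .", ext)
  }
}

#' Write a labeled volume to TIFF or NRRD
#'
#' TIFF output is 16-bit multi-page (labels must be < 65536); NRRD output is
#' `int32` raw little-endian with voxel spacings in the header.
#'
#' @param volume a [labeled_volume()].
#' @param path destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_labeled_volume <- function(volume, path) {
  ext <- tolower(tools::file_ext(path))
  lab <- volume$labels
  if (ext %in% c("tif", "tiff")) {
    if (max(lab) > 65535L)
      stop("labels exceed 16-bit range; use NRRD for large label sets")
    pages <- lapply(seq_len(dim(lab)[1]),
                    function(k) lab[k, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "LZW")
  } else if (ext == "nrrd") {
    write_nrrd(lab, volume$voxel_size, path)
  } else {
    stop("unsupported volume format: .", ext)
  }
  invisible(path)
}

# --- minimal NRRD reader/writer (attached data, raw or text encoding) -------
# Axis order on disk: fastest-first = z, so sizes are (nz, ny, nx) and
# spacings (dz, dy, dx), matching the in-memory layout.

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ": ?", fixed = FALSE)[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  type <- fields[["type"]]
  if (is.null(type) || !grepl("int|short|char|long", type))
    stop("NRRD pixel type '", type, "' is not integer")
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  spacing <- NULL
  if (!is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(trimws(fields[["spacings"]]), "\\s+")[[1]])
  enc <- tolower(fields[["encoding"]])
  n <- prod(sizes)
  if (enc == "raw") {
    bytes <- switch(type,
                    "int8" = 1L, "uint8" = 1L, "short" = 2L, "int16" = 2L,
                    "uint16" = 2L, "int" = 4L, "int32" = 4L, "uint32" = 4L,
                    4L)
    endian <- if (!is.null(fields[["endian"]]) &&
                  fields[["endian"]] == "big") "big" else "little"
    vals <- readBin(con, "integer", n = n, size = bytes, endian = endian,
                    signed = !(bytes < 4L && grepl("^u", type)) )
  } else if (enc %in% c("text", "txt", "ascii")) {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    stop("NRRD encoding '", enc, "' not supported (raw/text only)")
  }
  list(labels = array(as.integer(vals), sizes), voxel_size = spacing)
}

write_nrrd <- function(labels, voxel_size, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# labeled cell volume",
           "type: int32",
           "dimension: 3",
           sprintf("sizes: %d %d %d", dim(labels)[1], dim(labels)[2],
                   dim(labels)[3]),
           sprintf("spacings: %.10g %.10g %.10g", voxel_size[1],
                   voxel_size[2], voxel_size[3]),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.integer(labels), con, size = 4L, endian = "little")
  invisible(path)
}
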