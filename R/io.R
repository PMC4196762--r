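#' Read a 3D volume from disk
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`; via the RNifti package),
#' multi-page TIFF (`.tif`/`.tiff`; via the tiff package, pages along z),
#' NRRD (`.nrrd`, raw or gzip encoding, attached header), and raw binary with
#' a JSON sidecar (`.raw` + `.json` carrying `dtype`, `shape`, `spacing`).
#' Data are returned in the canonical internal axis order (x, y, z).
#'
#' @param path file path; format inferred from the extension.
#' @return A [new_volume()] object.
#' @export
read_volume <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return(read_volume_nifti(path))
  if (grepl("\\.tiff?$", lp)) return(read_volume_tiff(path))
  if (grepl("\\.nrrd$", lp)) return(read_volume_nrrd(path))
  if (grepl("\\.raw$", lp)) return(read_volume_raw(path))
  stop("unrecognized volume extension: ", path)
}

#' Write a 3D volume to disk
#'
#' Counterpart of [read_volume()]; the format is chosen by extension. TIFF
#' output is 32-bit float (the format's widest numeric type), all other
#' formats round-trip doubles exactly.
#'
#' @param vol a [new_volume()] object (cost volumes are accepted too).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) write_volume_nifti(vol, path)
  else if (grepl("\\.tiff?$", lp)) write_volume_tiff(vol, path)
  else if (grepl("\\.nrrd$", lp)) write_volume_nrrd(vol, path)
  else if (grepl("\\.raw$", lp)) write_volume_raw(vol, path)
  else stop("unrecognized volume extension: ", path)
  invisible(path)
}

read_volume_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support needs the RNifti package")
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  new_volume(a, ifelse(is.finite(sp) & sp > 0, sp, 1))
}

write_volume_nifti <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support needs the RNifti package")
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "double")
}

# TIFF pages along z; within a page rows = y, cols = x.
read_volume_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("TIFF support needs the tiff package")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  a <- vapply(pages, function(p) t(p[, , drop = TRUE][, , drop = TRUE]),
              matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  new_volume(array(a, c(dim(a)[1], dim(a)[2], length(pages))))
}

write_volume_tiff <- function(vol, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("TIFF support needs the tiff package")
  pages <- lapply(seq_len(dim(vol$data)[3]), function(k) t(vol$data[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = TRUE)
}

read_volume_raw <- function(path) {
  side <- sub("\\.raw$", ".json", path)
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  what <- switch(meta$dtype, float64 = "double", float32 = "double",
                 int16 = "integer", int32 = "integer",
                 stop("unsupported dtype: ", meta$dtype))
  size <- switch(meta$dtype, float64 = 8L, float32 = 4L, int16 = 2L, int32 = 4L)
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, what, n = prod(shape), size = size)
  new_volume(array(as.numeric(v), shape), as.numeric(meta$spacing))
}

write_volume_raw <- function(vol, path) {
  side <- sub("\\.raw$", ".json", path)
  con <- file(path, "wb")
  writeBin(as.vector(vol$data), con, size = 8L)
  close(con)
  jsonlite::write_json(list(dtype = "float64", shape = dim(vol$data),
                            spacing = vol$spacing, axis_order = c("x", "y", "z")),
                       side, auto_unbox = FALSE, digits = NA)
}

# Minimal NRRD: attached header, encodings raw | gzip, type double/float/short.
read_volume_nrrd <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  hdr_bytes <- nchar(magic, type = "bytes") + 1L
  repeat {
    line <- readLines(con, n = 1L)
    hdr_bytes <- hdr_bytes + nchar(line, type = "bytes") + 1L
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ": ?", fixed = FALSE)[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  type <- fields$type
  enc <- fields$encoding
  spacing <- c(1, 1, 1)
  if (!is.null(fields$spacings))
    spacing <- as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]])
  # reopen to skip the header exactly, then read payload
  close(con); on.exit(NULL)
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", n = hdr_bytes)
  payload <- readBin(con, "raw", n = file.size(path))
  if (identical(enc, "gzip")) payload <- memDecompress(payload, type = "gzip")
  else if (!identical(enc, "raw")) stop("unsupported NRRD encoding: ", enc)
  what <- switch(type, double = "double", float = "double", short = "integer",
                 stop("unsupported NRRD type: ", type))
  size <- switch(type, double = 8L, float = 4L, short = 2L)
  v <- readBin(payload, what, n = prod(sizes), size = size,
               endian = if (!is.null(fields$endian)) fields$endian else "little")
  new_volume(array(as.numeric(v), sizes), spacing)
}

write_volume_nrrd <- function(vol, path, encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  d <- dim(vol$data)
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.17g %.17g %.17g",
                   vol$spacing[1], vol$spacing[2], vol$spacing[3]),
           "endian: little",
           sprintf("encoding: %s", encoding),
           "")
  payload <- writeBin(as.vector(vol$data), raw(), size = 8L, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(payload, con)
}
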