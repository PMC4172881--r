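#' Read a 3-D volume from NIfTI or MetaImage
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`, via RNifti) and MetaImage
#' (`.mha` single file or `.mhd` + `.raw`/`.zraw` pair). Spacing and origin
#' are taken from the header; intensities are promoted to double. Direction
#' matrices are assumed axis-aligned (identity); oblique orientations are not
#' supported.
#'
#' @param path file path.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path) {
  v <- read_volume_raw(path)
  volume_grid(v$values, v$spacing, v$origin)
}

#' @rdname read_volume
#' @details `read_mask()` binarizes on read: any value > 0 becomes 1, so
#'   masks coded 0/255 load as 0/1.
#' @export
read_mask <- function(path) {
  v <- read_volume_raw(path)
  label_volume(array(as.numeric(v$values > 0), dim(v$values)),
               v$spacing, v$origin)
}

read_volume_raw <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim = dim(img))
    if (length(dim(vals)) != 3L) stop("not a 3-D volume: ", path)
    # spacing and origin from the xform; our grids are axis-aligned
    xf <- RNifti::xform(img)
    spacing <- as.numeric(xf[cbind(1:3, 1:3)])
    if (any(spacing <= 0)) stop("non-positive spacing in header: ", path)
    origin <- as.numeric(xf[1:3, 4])
    list(values = vals, spacing = spacing, origin = origin)
  } else if (grepl("\\.(mha|mhd)$", lp)) {
    read_metaimage(path)
  } else {
    stop("unsupported volume format (expect .nii/.nii.gz/.mha/.mhd): ", path)
  }
}

#' Write a volume to NIfTI or MetaImage
#'
#' The format is chosen from the file extension. NIfTI volumes are written
#' with an axis-aligned sform carrying spacing and origin; MetaImage as
#' uncompressed `MET_DOUBLE` raw data (bit-exact round-trips).
#'
#' @param volume a [volume_grid()] or [label_volume()].
#' @param path output path (`.nii`, `.nii.gz`, `.mha`, `.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::asNifti(volume$values)
    xf <- rbind(cbind(diag(volume$spacing), volume$origin), c(0, 0, 0, 1))
    img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (grepl("\\.(mha|mhd)$", lp)) {
    write_metaimage(volume, path)
  } else {
    stop("unsupported output format: ", path)
  }
  invisible(path)
}

# ---- MetaImage (.mha/.mhd) ---------------------------------------------

meta_dtypes <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]] %||% "3")
  if (ndims != 3L) stop("only 3-D MetaImage supported: ", path)
  dim3 <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1]])
  if (any(spacing <= 0)) stop("non-positive spacing in header: ", path)
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% hdr[["Origin"]] %||% "0 0 0",
                                "\\s+")[[1]])
  dt <- meta_dtypes[[hdr[["ElementType"]] %||% "MET_DOUBLE"]]
  if (is.null(dt)) stop("unsupported MetaImage ElementType: ", hdr[["ElementType"]])
  byte_order_msb <- identical(hdr[["ElementByteOrderMSB"]] %||%
                              hdr[["BinaryDataByteOrderMSB"]] %||% "False", "True")
  endian <- if (byte_order_msb) "big" else "little"
  n <- prod(dim3)
  datafile <- hdr[["ElementDataFile"]]
  compressed <- identical(hdr[["CompressedData"]] %||% "False", "True")
  if (identical(datafile, "LOCAL")) {
    if (compressed) stop("compressed LOCAL MetaImage data not supported: ", path)
    raw_vals <- readBin(con, dt$what, n = n, size = dt$size,
                        signed = dt$signed, endian = endian)
  } else {
    dpath <- file.path(dirname(path), datafile)
    if (!file.exists(dpath)) stop("MetaImage data file missing: ", dpath)
    dcon <- if (compressed || grepl("\\.zraw$", tolower(dpath)))
      gzfile(dpath, "rb") else file(dpath, "rb")
    on.exit(close(dcon), add = TRUE)
    raw_vals <- readBin(dcon, dt$what, n = n, size = dt$size,
                        signed = dt$signed, endian = endian)
  }
  if (length(raw_vals) != n) stop("MetaImage data shorter than DimSize: ", path)
  list(values = array(as.numeric(raw_vals), dim3), spacing = spacing,
       origin = origin)
}

write_metaimage <- function(volume, path) {
  d <- dim(volume$values)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g", volume$spacing[1],
            volume$spacing[2], volume$spacing[3]),
    sprintf("Offset = %.17g %.17g %.17g", volume$origin[1],
            volume$origin[2], volume$origin[3]),
    "ElementType = MET_DOUBLE"
  )
  if (grepl("\\.mha$", tolower(path))) {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con, sep = "\n")
    writeBin(as.numeric(volume$values), con, size = 8L, endian = "little")
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(hdr, paste("ElementDataFile =", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.numeric(volume$values), con, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
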