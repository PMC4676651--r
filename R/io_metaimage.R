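# MetaImage (.mhd text header + .raw payload) reader/writer.
# Header order is (x, y, z) per the MetaImage convention; internal order is
# (z, y, x), so DimSize/ElementSpacing/Offset are reversed on the way in/out.
# Supported element types: MET_SHORT, MET_UCHAR, MET_FLOAT; uncompressed only.

# shortest decimal representation that parses back to the same double,
# so grid geometry survives header round-trips bit-exactly
fmt_double <- function(x) {
  vapply(x, function(v) {
    for (dgt in 1:17) {
      s <- sprintf(paste0("%.", dgt, "g"), v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, "")
}

MHD_TYPES <- list(
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_FLOAT = list(what = "numeric", size = 4L, signed = TRUE)
)

#' Read a MetaImage volume
#'
#' Reads an uncompressed MetaImage header (`.mhd`) and its raw payload into a
#' [volume_image()]. Element types `MET_SHORT`, `MET_UCHAR` and `MET_FLOAT`
#' are supported; byte order defaults to little-endian and honours
#' `ElementByteOrderMSB`/`BinaryDataByteOrderMSB` when present.
#'
#' @param path Path to the `.mhd` header file.
#' @return A [volume_image()] with spacing/origin in `(z, y, x)` order.
#' @export
read_metaimage <- function(path) {
  if (!file.exists(path)) stop("header file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, function(p) trimws(p[1]), "")
  vals <- vapply(kv, function(p) trimws(p[2]), "")
  names(vals) <- keys
  getv <- function(k) if (k %in% keys) vals[[k]] else NULL

  if (is.null(getv("DimSize")) || is.null(getv("ElementSpacing")))
    stop("MetaImage header must declare DimSize and ElementSpacing")
  ndims <- if (!is.null(getv("NDims"))) as.integer(getv("NDims")) else 3L
  if (ndims != 3L) stop("only 3D MetaImage volumes are supported")
  dim_xyz <- as.integer(strsplit(getv("DimSize"), "\\s+")[[1]])
  sp_xyz <- as.numeric(strsplit(getv("ElementSpacing"), "\\s+")[[1]])
  off <- getv("Offset")
  if (is.null(off)) off <- getv("Position")
  if (is.null(off)) off <- getv("Origin")
  org_xyz <- if (is.null(off)) c(0, 0, 0) else as.numeric(strsplit(off, "\\s+")[[1]])
  comp <- getv("CompressedData")
  if (!is.null(comp) && tolower(comp) == "true")
    stop("compressed MetaImage data is not supported")
  etype <- getv("ElementType")
  if (is.null(etype) || !etype %in% names(MHD_TYPES))
    stop("unsupported MetaImage element type: ",
         if (is.null(etype)) "<missing>" else etype)
  msb <- getv("ElementByteOrderMSB")
  if (is.null(msb)) msb <- getv("BinaryDataByteOrderMSB")
  endian <- if (!is.null(msb) && tolower(msb) == "true") "big" else "little"
  datafile <- getv("ElementDataFile")
  if (is.null(datafile)) stop("MetaImage header lacks ElementDataFile")
  if (toupper(datafile) == "LOCAL")
    stop("ElementDataFile = LOCAL is not supported; use a separate .raw file")
  raw_path <- if (file.exists(datafile)) datafile else file.path(dirname(path), datafile)
  if (!file.exists(raw_path)) stop("raw data file not found: ", raw_path)

  tt <- MHD_TYPES[[etype]]
  n <- prod(dim_xyz)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = tt$what, n = n, size = tt$size,
               signed = tt$signed, endian = endian)
  if (length(v) != n)
    stop("raw file truncated: expected ", n, " elements, got ", length(v))
  arr <- array(as.numeric(v), dim = dim_xyz)   # (x, y, z), x fastest
  arr <- aperm(arr, c(3, 2, 1))                # -> (z, y, x)
  volume_image(arr, spacing = rev(sp_xyz), origin = rev(org_xyz))
}

#' Write a MetaImage volume or mask
#'
#' Emits a `.mhd` header plus `.raw` payload readable by [read_metaimage()]
#' and standard MetaImage readers. Volumes are written as `MET_SHORT` when all
#' values are 16-bit integers, otherwise `MET_FLOAT`; masks as 8-bit 0/1
#' `MET_UCHAR`.
#'
#' @param volume A [volume_image()] or [binary_mask()].
#' @param path Output `.mhd` path; the payload goes to the matching `.raw`.
#' @return Invisibly, `path`.
#' @export
write_metaimage <- function(volume, path) {
  is_mask <- inherits(volume, "binary_mask")
  if (!is_mask && !inherits(volume, "volume_image"))
    stop("`volume` must be a volume_image or binary_mask")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory not writable: ", dir)
  data <- volume$data
  if (is_mask) {
    etype <- "MET_UCHAR"
    vals <- as.integer(data)
  } else {
    intish <- all(data == round(data)) && max(abs(data)) <= 32767
    etype <- if (intish) "MET_SHORT" else "MET_FLOAT"
    vals <- if (intish) as.integer(data) else as.numeric(data)
  }
  d <- dim(data)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  if (identical(raw_name, basename(path))) raw_name <- paste0(basename(path), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(rev(d), collapse = " ")),
    paste("ElementSpacing =", paste(fmt_double(rev(volume$spacing)),
                                    collapse = " ")),
    paste("Offset =", paste(fmt_double(rev(volume$origin)), collapse = " ")),
    paste("ElementType =", etype),
    paste("ElementDataFile =", raw_name)
  )
  writeLines(hdr, path)
  tt <- MHD_TYPES[[etype]]
  v <- aperm(array(vals, dim = d), c(3, 2, 1))  # -> x fastest on disk
  con <- file(file.path(dir, raw_name), "wb")
  on.exit(close(con))
  writeBin(if (tt$what == "integer") as.integer(v) else as.numeric(v),
           con, size = tt$size, endian = "little")
  invisible(path)
}

#' Read a MetaImage mask
#'
#' Convenience wrapper: reads with [read_metaimage()] and converts nonzero
#' voxels to a [binary_mask()].
#' @param path Path to the `.mhd` header.
#' @return A [binary_mask()].
#' @export
read_metaimage_mask <- function(path) {
  v <- read_metaimage(path)
  binary_mask(array(v$data != 0, dim = dim(v$data)),
              spacing = v$spacing, origin = v$origin)
}
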