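#' 3D scalar volume with voxel spacing and origin
#'
#' The environment the agent moves in: a 3D intensity grid indexed `(x, y, z)`
#' (first array index varies along x), per-axis voxel size in mm, and the
#' world coordinate of voxel `(0, 0, 0)`. Voxel indices are 0-based
#' throughout the package; `world = origin + voxel * spacing`.
#'
#' @param data Numeric 3D array of intensities, indexed `(x, y, z)`.
#' @param spacing Numeric length-3, voxel size in mm per axis; strictly
#'   positive.
#' @param origin Numeric length-3, world coordinate (mm) of voxel `(0,0,0)`.
#' @return An object of class `"volume"`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("'data' must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1)) stop("all three dimensions must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("'origin' must be three finite values (mm)", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume")
}

#' @export
dim.volume <- function(x) dim(x$data)

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Convert between voxel and world coordinates
#'
#' @param v A [volume].
#' @param voxel,world Numeric length-3 coordinate (0-based voxel index /
#'   world mm).
#' @return The converted length-3 coordinate.
#' @export
voxel_to_world <- function(v, voxel) v$origin + as.numeric(voxel) * v$spacing

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(v, world) (as.numeric(world) - v$origin) / v$spacing

#' Is a voxel index inside the grid?
#' @param v A [volume].
#' @param voxel Numeric length-3, 0-based voxel index.
#' @return Logical.
#' @export
in_bounds <- function(v, voxel) {
  all(voxel >= 0) && all(voxel <= dim(v$data) - 1)
}

vol_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.(mhd|mha)$", lp)) return("metaimage")
  stop(sprintf("unrecognized volume format: '%s' (expected .nii, .nii.gz, .mhd or .mha)",
               basename(path)), call. = FALSE)
}

#' Read a volume from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) and MetaImage (`.mhd` + `.raw`, or
#' single-file `.mha`). Spacing and origin metadata are honored; a MetaImage
#' header without `ElementSpacing`/`ElementSize` is an error (spacing is
#' never silently assumed to be 1 mm).
#'
#' @param path Path to the volume file.
#' @return A [volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  switch(vol_format(path),
         nifti = read_volume_nifti(path),
         metaimage = read_volume_meta(path))
}

#' Write a volume to disk
#'
#' @param v A [volume].
#' @param path Destination path; the format is chosen from the extension
#'   (`.nii`/`.nii.gz`, `.mhd`, `.mha`).
#' @param element_type MetaImage element type, one of `"MET_DOUBLE"`,
#'   `"MET_FLOAT"`, `"MET_SHORT"`, `"MET_USHORT"`, `"MET_UCHAR"`. Ignored for
#'   NIfTI.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, element_type = "MET_DOUBLE") {
  stopifnot(inherits(v, "volume"))
  switch(vol_format(path),
         nifti = write_volume_nifti(v, path),
         metaimage = write_volume_meta(v, path, element_type))
  invisible(path)
}

read_volume_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop(sprintf("failed to read NIfTI file '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  d <- dim(img)
  if (length(d) != 3)
    stop(sprintf("'%s': expected a 3D NIfTI volume, got %d dimensions",
                 path, length(d)), call. = FALSE)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("'%s': NIfTI pixdim is missing or non-positive", path),
         call. = FALSE)
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  volume(arr, spacing = spacing, origin = origin)
}

write_volume_nifti <- function(v, path) {
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  aff <- diag(c(v$spacing, 1))
  aff[1:3, 4] <- v$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
}

meta_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

# MetaImage is a plain "Key = Value" header optionally followed by the raw
# payload (ElementDataFile = LOCAL) or naming a sidecar .raw file. No
# installed package reads it, so the small subset needed here is implemented
# directly.
read_volume_meta <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  # header is ASCII lines up to and including the ElementDataFile line
  nl <- which(raw_all == as.raw(10L))
  header_lines <- character()
  data_offset <- NA_integer_
  start <- 1L
  for (pos in nl) {
    line <- rawToChar(raw_all[start:(pos - 1L)])
    line <- sub("\r$", "", line)
    header_lines <- c(header_lines, line)
    start <- pos + 1L
    if (grepl("^\\s*ElementDataFile\\s*=", line)) { data_offset <- start; break }
  }
  if (is.na(data_offset))
    stop(sprintf("MetaImage '%s': header has no ElementDataFile entry", path),
         call. = FALSE)
  kv <- list()
  for (line in header_lines) {
    if (!grepl("=", line, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    kv[[key]] <- val
  }
  get_num <- function(key) {
    if (is.null(kv[[key]])) return(NULL)
    as.numeric(strsplit(trimws(kv[[key]]), "\\s+")[[1]])
  }
  ndims <- get_num("NDims")
  if (!is.null(ndims) && ndims != 3)
    stop(sprintf("MetaImage '%s': only NDims = 3 is supported", path), call. = FALSE)
  dims <- get_num("DimSize")
  if (is.null(dims) || length(dims) != 3)
    stop(sprintf("MetaImage '%s': missing or malformed DimSize", path), call. = FALSE)
  spacing <- get_num("ElementSpacing") %||% get_num("ElementSize")
  if (is.null(spacing))
    stop(sprintf("MetaImage '%s': missing ElementSpacing (spacing is never assumed)",
                 path), call. = FALSE)
  origin <- get_num("Offset") %||% get_num("Origin") %||% get_num("Position") %||%
    c(0, 0, 0)
  if (!is.null(kv[["CompressedData"]]) && toupper(kv[["CompressedData"]]) == "TRUE")
    stop(sprintf("MetaImage '%s': compressed payloads are not supported", path),
         call. = FALSE)
  type <- kv[["ElementType"]] %||% "MET_FLOAT"
  tinfo <- meta_types[[type]]
  if (is.null(tinfo))
    stop(sprintf("MetaImage '%s': unsupported ElementType '%s'", path, type),
         call. = FALSE)
  msb <- toupper(kv[["ElementByteOrderMSB"]] %||% kv[["BinaryDataByteOrderMSB"]] %||%
                   "FALSE") == "TRUE"
  n_vox <- prod(dims)
  datafile <- kv[["ElementDataFile"]]
  if (toupper(datafile) == "LOCAL") {
    payload <- raw_all[data_offset:length(raw_all)]
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop(sprintf("MetaImage '%s': data file '%s' not found", path, datafile),
           call. = FALSE)
    payload <- readBin(rawpath, "raw", n = file.size(rawpath))
  }
  need <- n_vox * tinfo$size
  if (length(payload) < need)
    stop(sprintf("MetaImage '%s': truncated payload (%d bytes, need %d)",
                 path, length(payload), need), call. = FALSE)
  vals <- readBin(payload, tinfo$what, n = n_vox, size = tinfo$size,
                  signed = tinfo$signed, endian = if (msb) "big" else "little")
  arr <- array(as.double(vals), dim = dims)
  volume(arr, spacing = spacing, origin = origin)
}

write_volume_meta <- function(v, path, element_type = "MET_DOUBLE") {
  tinfo <- meta_types[[element_type]]
  if (is.null(tinfo) || !element_type %in%
      c("MET_UCHAR", "MET_SHORT", "MET_USHORT", "MET_FLOAT", "MET_DOUBLE"))
    stop(sprintf("unsupported MetaImage element type '%s'", element_type),
         call. = FALSE)
  mha <- grepl("\\.mha$", tolower(path))
  datafile <- if (mha) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(v$data), collapse = " ")),
    paste("ElementSpacing =", paste(format(v$spacing, digits = 15), collapse = " ")),
    paste("Offset =", paste(format(v$origin, digits = 15), collapse = " ")),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", datafile))
  vals <- as.vector(v$data)
  if (tinfo$what == "integer") vals <- as.integer(round(vals))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  if (mha) {
    writeBin(vals, con, size = tinfo$size, endian = "little")
  } else {
    rawcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rawcon), add = TRUE)
    writeBin(vals, rawcon, size = tinfo$size, endian = "little")
  }
  invisible(path)
}
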