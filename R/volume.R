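#' 3-D scalar volume with voxel geometry
#'
#' The universal image carrier of the package: a 3-D intensity array plus
#' voxel spacing and origin in millimetres. World coordinates follow the
#' voxel-centre convention: the centre of voxel `(i, j, k)` (0-based) sits at
#' `origin + c(i, j, k) * spacing`.
#'
#' @param intensities 3-D numeric array of voxel intensities (all finite).
#' @param spacing Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin Numeric length-3, world position of the first voxel centre
#'   in mm. Defaults to `c(0, 0, 0)`.
#' @param mask Optional logical array of the same dims marking valid voxels;
#'   `NULL` (default) means every voxel is valid. Resampling operations
#'   mark voxels that left the field of view invalid, and invalid voxels are
#'   excluded from joint histograms.
#' @return A `volume_grid` object.
#' @examples
#' v <- volume_grid(array(0, c(4, 4, 2)), spacing = c(1, 1, 2))
#' dim(v$intensities)
#' @export
volume_grid <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        mask = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  if (any(dim(intensities) < 1L))
    stop("all dims must be >= 1", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("all intensities must be finite", call. = FALSE)
  storage.mode(intensities) <- "double"
  if (!is.null(mask)) {
    if (!is.array(mask) || !identical(dim(mask), dim(intensities)))
      stop("`mask` must be a logical array matching `intensities`", call. = FALSE)
    storage.mode(mask) <- "logical"
    if (all(mask)) mask <- NULL # a full mask carries no information
  }
  structure(
    list(intensities = intensities, spacing = spacing, origin = origin,
         dims = dim(intensities), mask = mask),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$dims, collapse = " x "), " voxels, spacing ",
      paste(format(x$spacing, digits = 4), collapse = " x "), " mm\n", sep = "")
  cat("  origin (mm): ", paste(format(x$origin, digits = 4), collapse = ", "),
      "\n  intensity range: [",
      format(min(x$intensities), digits = 5), ", ",
      format(max(x$intensities), digits = 5), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) x$dims

#' @export
as.array.volume_grid <- function(x, ...) x$intensities

is_volume_grid <- function(x) inherits(x, "volume_grid")

assert_volume <- function(x, arg = deparse(substitute(x))) {
  if (!is_volume_grid(x))
    stop(sprintf("`%s` must be a volume_grid", arg), call. = FALSE)
  invisible(x)
}

#' Physical centre of a volume
#'
#' World coordinates (mm) of the centre of the volume's bounding box, the
#' default rotation centre for rigid transforms.
#'
#' @param vol A [volume_grid()].
#' @return Numeric length-3 (mm).
#' @export
volume_center <- function(vol) {
  assert_volume(vol)
  vol$origin + (vol$dims - 1) * vol$spacing / 2
}

#' Read a volume from disk
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) via \pkg{RNifti} and MetaImage
#' (`.mha`, `.mhd`). Files missing spacing metadata are rejected rather than
#' silently defaulting.
#'
#' @param path Path to the image file.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(sub("^.*?((\\.nii\\.gz)|(\\.[^.]+))$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    pix <- attr(img, "pixdim")
    if (is.null(pix) || length(pix) < 3 || any(pix[1:3] <= 0))
      stop("NIfTI file lacks valid voxel spacing: ", path, call. = FALSE)
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    hdr <- RNifti::niftiHeader(img)
    origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
    if (any(!is.finite(origin))) origin <- c(0, 0, 0)
    return(volume_grid(arr, spacing = pix[1:3], origin = origin))
  }
  if (ext %in% c(".mha", ".mhd")) return(read_metaimage(path))
  stop("unrecognized volume extension '", ext,
       "'; supported: .nii, .nii.gz, .mha, .mhd", call. = FALSE)
}

#' Write a volume to disk
#'
#' @param vol A [volume_grid()].
#' @param path Output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mha`, `.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  assert_volume(vol)
  ext <- tolower(sub("^.*?((\\.nii\\.gz)|(\\.[^.]+))$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(vol$intensities)
    img <- RNifti::`pixdim<-`(img, vol$spacing)
    hdr <- list(qoffset_x = vol$origin[1], qoffset_y = vol$origin[2],
                qoffset_z = vol$origin[3], qform_code = 1L)
    img <- RNifti::asNifti(img, hdr)
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (ext %in% c(".mha", ".mhd")) return(write_metaimage(vol, path))
  stop("unrecognized volume extension '", ext,
       "'; supported: .nii, .nii.gz, .mha, .mhd", call. = FALSE)
}

# --- MetaImage (.mha single-file / .mhd header + .raw) ----------------------
# The format is a plain key = value text header followed by (or pointing to)
# a raw little-endian data block. Only the subset needed for scalar 3-D
# volumes is implemented.

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("malformed MetaImage header: ", path, call. = FALSE)
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  names(vals) <- keys
  getv <- function(k) if (k %in% keys) vals[[k]] else NULL

  dims <- as.integer(strsplit(getv("DimSize"), "\\s+")[[1]])
  sp_raw <- getv("ElementSpacing")
  if (is.null(sp_raw)) stop("MetaImage file lacks ElementSpacing: ", path, call. = FALSE)
  spacing <- as.numeric(strsplit(sp_raw, "\\s+")[[1]])
  off <- getv("Offset")
  origin <- if (is.null(off)) c(0, 0, 0) else as.numeric(strsplit(off, "\\s+")[[1]])
  etype <- getv("ElementType")
  what <- switch(etype,
    MET_DOUBLE = list(type = "double", size = 8L),
    MET_FLOAT  = list(type = "double", size = 4L),
    MET_SHORT  = list(type = "integer", size = 2L),
    MET_INT    = list(type = "integer", size = 4L),
    MET_UCHAR  = list(type = "integer", size = 1L),
    stop("unsupported MetaImage ElementType: ", etype, call. = FALSE))
  n <- prod(dims)
  datafile <- getv("ElementDataFile")
  if (identical(datafile, "LOCAL")) {
    raw <- readBin(con, what$type, n = n, size = what$size, endian = "little",
                   signed = !identical(etype, "MET_UCHAR"))
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop("MetaImage data file not found: ", rawpath, call. = FALSE)
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    raw <- readBin(con2, what$type, n = n, size = what$size, endian = "little",
                   signed = !identical(etype, "MET_UCHAR"))
  }
  if (length(raw) != n) stop("truncated MetaImage data block: ", path, call. = FALSE)
  volume_grid(array(as.double(raw), dims), spacing = spacing, origin = origin)
}

write_metaimage <- function(vol, path) {
  ext <- tolower(sub("^.*(\\.[^.]+)$", "\\1", path))
  local <- identical(ext, ".mha")
  datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(vol$dims, collapse = " ")),
    paste("ElementSpacing =", paste(vol$spacing, collapse = " ")),
    paste("Offset =", paste(vol$origin, collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", datafile)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local) {
    writeBin(as.double(vol$intensities), con, size = 8L, endian = "little")
  } else {
    con2 <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con2), add = TRUE)
    writeBin(as.double(vol$intensities), con2, size = 8L, endian = "little")
  }
  invisible(path)
}
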