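#' @useDynLib trabdvc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile rnorm sd lm coef predict residuals
#'   pt cor optim
NULL

#' Construct an image volume
#'
#' The raw currency of the pipeline: a 3D scalar grid with an isotropic voxel
#' size. The third array dimension is the z (loading, supero-inferior) axis.
#' Voxel indexing is 0-based with voxel centers at integer coordinates; in R,
#' `vol$data[i, j, k]` holds the voxel at coordinate `(i-1, j-1, k-1)`.
#'
#' @param data 3D numeric array. 8-bit volumes hold values in `[0, 255]`.
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @return An object of class `image_volume` with elements `data` and
#'   `voxel_size`.
#' @export
image_volume <- function(data, voxel_size) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometres)")
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels @ %.3g um (range %.4g..%.4g)\n",
              d[1], d[2], d[3], x$voxel_size,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a binary mask
#'
#' A 3D logical grid on the same lattice as an [image_volume()], marking bone
#' voxels (segmentation) or the bone's external contour (registration mask).
#'
#' @param data 3D logical array.
#' @param voxel_size Isotropic voxel size in micrometres.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, voxel_size) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "logical"
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d voxels @ %.3g um (%.1f%% foreground)\n",
              d[1], d[2], d[3], x$voxel_size, 100 * mean(x$data)))
  invisible(x)
}

as_vol_array <- function(x) {
  if (inherits(x, "image_volume") || inherits(x, "binary_mask")) x$data else x
}

vol_dims <- function(x) dim(as_vol_array(x))

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(vol_dims(a), vol_dims(b)))
    stop(sprintf("%s must share dimensions (%s vs %s)", what,
                 paste(vol_dims(a), collapse = "x"),
                 paste(vol_dims(b), collapse = "x")))
  invisible(TRUE)
}

#' Read an image stack from disk
#'
#' Reads a multi-page 8-bit grayscale TIFF (with a JSON sidecar carrying the
#' voxel size) or an MHD/RAW pair. The voxel size must be recoverable from
#' the sidecar or header; there is no silent default.
#'
#' For a TIFF `vol.tif`, the sidecar is `vol.tif.json` (or `vol.json`) and
#' must contain at least `{"voxel_size_um": <number>}`.
#'
#' @param path Path to a `.tif`/`.tiff` file or a `.mhd` header.
#' @return An [image_volume()].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    dims <- lapply(pages, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
      stop("inconsistent slice dimensions in ", path)
    d <- dims[[1]]
    arr <- array(0, dim = c(d[1], d[2], length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- round(pages[[k]] * 255)
    sidecars <- c(paste0(path, ".json"),
                  paste0(tools::file_path_sans_ext(path), ".json"))
    sc <- sidecars[file.exists(sidecars)]
    if (length(sc) == 0)
      stop("no JSON sidecar with voxel_size_um found for ", path,
           " (expected ", sidecars[1], ")")
    meta <- jsonlite::fromJSON(sc[1])
    if (is.null(meta$voxel_size_um))
      stop("sidecar ", sc[1], " does not define voxel_size_um")
    image_volume(arr, meta$voxel_size_um)
  } else if (ext == "mhd") {
    hdr <- readLines(path)
    kv <- strsplit(hdr, "\\s*=\\s*")
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    get <- function(key) {
      i <- match(key, keys)
      if (is.na(i)) NA_character_ else trimws(vals[i])
    }
    dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
    spac <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
    etyp <- get("ElementType")
    dfile <- get("ElementDataFile")
    if (anyNA(dims) || length(dims) != 3) stop("bad DimSize in ", path)
    if (anyNA(spac)) stop("missing ElementSpacing (voxel size) in ", path)
    if (length(unique(spac)) != 1) stop("anisotropic spacing not supported")
    if (!identical(etyp, "MET_UCHAR")) stop("only MET_UCHAR raw data supported")
    rawpath <- file.path(dirname(path), dfile)
    n <- prod(dims)
    bytes <- readBin(rawpath, "integer", n = n, size = 1L, signed = FALSE)
    image_volume(array(as.numeric(bytes), dim = dims), spac[1])
  } else {
    stop("unsupported stack format: .", ext)
  }
}

#' Write an image stack to disk
#'
#' Writes a multi-page 8-bit grayscale TIFF plus a JSON sidecar
#' (`<path>.json`) carrying the voxel size and optional metadata, or an
#' MHD/RAW pair. Round trips of 8-bit data are bit-exact.
#'
#' @param vol An [image_volume()] with values in `[0, 255]`.
#' @param path Output path ending in `.tif`/`.tiff` or `.mhd`.
#' @param meta Optional named list merged into the JSON sidecar (e.g. the
#'   generating seed or ground-truth parameters).
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path, meta = list()) {
  stopifnot(inherits(vol, "image_volume"))
  if (min(vol$data) < 0 || max(vol$data) > 255)
    stop("volume must be 8-bit (values in [0, 255]) before writing")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    d <- dim(vol$data)
    pages <- lapply(seq_len(d[3]), function(k)
      matrix(round(vol$data[, , k]) / 255, nrow = d[1], ncol = d[2]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    sidecar <- c(list(voxel_size_um = vol$voxel_size, axis_order = "xyz"), meta)
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (ext == "mhd") {
    rawname <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
    hdr <- c("ObjectType = Image", "NDims = 3",
             paste("DimSize =", paste(dim(vol$data), collapse = " ")),
             paste("ElementSpacing =",
                   paste(rep(vol$voxel_size, 3), collapse = " ")),
             "ElementType = MET_UCHAR",
             paste("ElementDataFile =", rawname))
    writeLines(hdr, path)
    writeBin(as.raw(round(as.vector(vol$data))),
             file.path(dirname(path), rawname))
  } else {
    stop("unsupported stack format: .", ext)
  }
  invisible(path)
}
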