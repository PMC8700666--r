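#' Phase codes used in label volumes
#'
#' Label volumes code the four phases of a segmented frozen porous food
#' tomogram as integers: air = 0, ice outside the matrix = 1, ice inside
#' the matrix = 2, starch = 3.
#'
#' @return A named integer vector of the four phase codes.
#' @export
#' @examples
#' phase_codes()
phase_codes <- function() {
  c(air = 0L, ice_outside = 1L, ice_inside = 2L, starch = 3L)
}

# resolve a phase selector ("air", "ice", code, ...) to integer codes
resolve_phase <- function(phase) {
  codes <- phase_codes()
  if (is.numeric(phase)) {
    ph <- as.integer(phase)
    if (!all(ph %in% codes)) abort("unknown phase code", class = "icemorph_error")
    return(ph)
  }
  out <- integer(0)
  for (p in phase) {
    if (p == "ice") {
      out <- c(out, codes[["ice_outside"]], codes[["ice_inside"]])
    } else if (p == "solid") {
      out <- c(out, codes[["ice_inside"]], codes[["starch"]])
    } else if (p %in% names(codes)) {
      out <- c(out, codes[[p]])
    } else {
      abort(paste0("unknown phase '", p, "'"), class = "icemorph_error")
    }
  }
  unique(out)
}

new_volume <- function(data, voxel_size, class) {
  structure(list(data = data, voxel_size = voxel_size),
            class = c(class, "ct_volume"))
}

#' Grey-level and label volume containers
#'
#' A `grey_volume` wraps a 3D numeric array of grey values; a
#' `label_volume` wraps a 3D integer array of phase codes (see
#' [phase_codes()]). Arrays are indexed `[y, x, z]` (1-based, z = slice /
#' TIFF page), and carry an isotropic physical voxel size in micrometres.
#' The voxel size always comes from the user or a config file, never from
#' TIFF metadata, which is unreliable across tomography exporters.
#'
#' @param data A 3D array (grey values, or integer phase codes).
#' @param voxel_size Isotropic voxel edge length in micrometres (> 0).
#' @return A `grey_volume` or `label_volume` object.
#' @export
#' @examples
#' g <- grey_volume(array(0, c(4, 4, 4)), voxel_size = 0.65)
#' dim(g)
grey_volume <- function(data, voxel_size) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    abort("voxel_size must be a single positive number (micrometres)",
          class = "icemorph_error")
  new_volume(data, as.numeric(voxel_size), "grey_volume")
}

#' @rdname grey_volume
#' @export
label_volume <- function(data, voxel_size) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    abort("voxel_size must be a single positive number (micrometres)",
          class = "icemorph_error")
  storage.mode(data) <- "integer"
  bad <- setdiff(unique(as.vector(data)), unname(phase_codes()))
  if (length(bad))
    abort(paste("label volume contains undefined phase codes:",
                paste(bad, collapse = ", ")), class = "icemorph_error")
  new_volume(data, as.numeric(voxel_size), "label_volume")
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels @ %g um/vx (%.3g x %.3g x %.3g mm)\n",
              class(x)[1], d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size / 1000, d[2] * x$voxel_size / 1000,
              d[3] * x$voxel_size / 1000))
  if (inherits(x, "label_volume")) {
    tab <- tabulate(as.vector(x$data) + 1L, nbins = 4L)
    cat("  phases:",
        paste(sprintf("%s=%d", names(phase_codes()), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Read a volume from a multi-page TIFF (or directory of TIFF slices)
#'
#' Pages are stacked along the third (z) axis in ascending page / file
#' order. Integer sample values are preserved as stored (`as.is`), so a
#' write/read round trip is bit exact for 8- and 16-bit data.
#'
#' @param path A multi-page TIFF file, or a directory containing
#'   single-page TIFF files whose sorted names define the z order.
#' @param voxel_size Voxel size in micrometres (required; TIFF resolution
#'   tags are ignored).
#' @param type `"grey"` (default) or `"label"`; labels are validated
#'   against [phase_codes()].
#' @return A [grey_volume()] or [label_volume()].
#' @export
read_volume <- function(path, voxel_size, type = c("grey", "label")) {
  type <- match.arg(type)
  if (!file.exists(path))
    abort(paste("cannot read", path), class = "icemorph_io_error")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files))
      abort(paste("no TIFF files in", path), class = "icemorph_io_error")
    pages <- unlist(lapply(files, function(f) {
      p <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
      if (!is.list(p)) p <- list(p)
      p
    }), recursive = FALSE)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  shp <- dim(pages[[1]])
  if (length(shp) != 2L)
    abort("only single-channel TIFF volumes are supported",
          class = "icemorph_format_error")
  ok <- vapply(pages, function(p) identical(dim(p), shp), logical(1))
  if (!all(ok))
    abort("TIFF pages have inconsistent shapes", class = "icemorph_format_error")
  arr <- array(0, c(shp[1], shp[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  if (type == "grey") grey_volume(arr, voxel_size)
  else label_volume(arr, voxel_size)
}

#' Write a volume as a multi-page TIFF
#'
#' Grey volumes are written as 8- or 16-bit integer samples; label volumes
#' are always written 8-bit with the raw phase codes. Values must lie in
#' `[0, 2^bits - 1]`.
#'
#' @param volume A [grey_volume()] or [label_volume()].
#' @param path Output file path.
#' @param bits Bits per sample for grey data (8 or 16).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, bits = if (inherits(volume, "label_volume")) 8L else 16L) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!bits %in% c(8L, 16L))
    abort("bits must be 8 or 16", class = "icemorph_error")
  mx <- 2^bits - 1
  v <- volume$data
  if (min(v) < 0 || max(v) > mx)
    abort(sprintf("values outside [0, %d]; rescale before writing", mx),
          class = "icemorph_error")
  nz <- dim(v)[3]
  pages <- lapply(seq_len(nz), function(k) round(v[, , k]) / mx)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
                 error = function(e) abort(paste("cannot write", path),
                                           class = "icemorph_io_error"))
  invisible(path)
}

#' Crop a centred cubic sub-volume
#'
#' Extracts the axis-aligned cube of edge `size` voxels centred at
#' `center` (1-based `(y, x, z)` indices). For even sizes the centre voxel
#' is the lower-middle voxel of the cube. Requests extending beyond the
#' volume raise an error; there is no silent clipping.
#'
#' @param volume A [grey_volume()] or [label_volume()].
#' @param center Integer vector of length 3, `(y, x, z)` centre indices;
#'   default is the volume centre.
#' @param size Cube edge length in voxels.
#' @return A volume of the same class with dimensions `c(size, size, size)`.
#' @export
crop_subvolume <- function(volume, size, center = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$data)
  size <- as.integer(size)
  if (size < 1L) abort("size must be >= 1", class = "icemorph_error")
  if (is.null(center)) center <- (d %/% 2L) + 1L
  center <- as.integer(center)
  lo <- center - size %/% 2L
  hi <- lo + size - 1L
  if (any(lo < 1L) || any(hi > d))
    abort(sprintf("requested %d^3 cube at (%s) exceeds volume bounds %s",
                  size, paste(center, collapse = ","),
                  paste(d, collapse = "x")),
          class = "icemorph_bounds_error")
  out <- volume
  out$data <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out
}
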