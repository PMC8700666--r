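#' Exact Euclidean distance transform of a 3D mask
#'
#' Separable exact squared Euclidean distance transform (Saito-Toriwaki
#' family): for every voxel, the squared distance in voxel units to the
#' nearest background (`FALSE`) voxel centre. Background voxels get 0. The
#' image border is not treated as background; a mask with no background
#' voxel returns `Inf` everywhere.
#'
#' @param mask A 3D logical array (foreground = `TRUE`).
#' @return A 3D numeric array of squared distances (voxel units).
#' @export
sqedt <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  sqedt_cpp(as.logical(mask), as.integer(dim(mask)))
}

# dilation by a digitized Euclidean ball: voxel included iff its centre is
# within distance r of a foreground voxel centre
dilate_ball <- function(mask, radius_vx) {
  if (radius_vx <= 0) return(mask)
  d2 <- sqedt_cpp(as.logical(!mask), as.integer(dim(mask)))
  array(d2 <= radius_vx^2, dim(mask))
}

erode_ball <- function(mask, radius_vx) {
  if (radius_vx <= 0) return(mask)
  !dilate_ball(!mask, radius_vx)
}

pad_array <- function(a, r, value) {
  d <- dim(a)
  out <- array(value, d + 2L * r)
  out[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- a
  out
}

unpad_array <- function(a, r, d) {
  a[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3]), drop = FALSE]
}

# central-difference gradient magnitude with edge clamping (one-sided at
# the faces), so plane interfaces integrate to their exact area
grad_mag <- function(phi) {
  d <- dim(phi)
  shift <- function(axis, by) {
    idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
    switch(axis, phi[idx, , , drop = FALSE], phi[, idx, , drop = FALSE],
           phi[, , idx, drop = FALSE])
  }
  g2 <- array(0, d)
  for (a in 1:3) g2 <- g2 + ((shift(a, 1L) - shift(a, -1L)) / 2)^2
  sqrt(g2)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Mirror boundary conditions; `sigma_vx <= 0` returns the input unchanged.
#'
#' @param x A 3D numeric array.
#' @param sigma_vx Gaussian standard deviation in voxels.
#' @return A smoothed array of the same dimensions.
#' @export
gaussian_blur <- function(x, sigma_vx) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (sigma_vx <= 0) return(x)
  gauss3_cpp(as.numeric(x), as.integer(dim(x)), sigma_vx)
}
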