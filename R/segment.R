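#' Estimate the two grey-level thresholds separating air, ice and starch
#'
#' Builds a 256-bin histogram and exhaustively searches all threshold
#' pairs for the three-class split minimizing the within-class grey-level
#' variance (three-class Otsu). Before thresholding, the histogram is
#' checked for three detectable modes (local maxima of the smoothed
#' histogram with prominence at least 5% of the tallest peak); volumes
#' with fewer modes (e.g. an unfrozen air/starch scan) raise a
#' degenerate-histogram error advising manual thresholds.
#'
#' @param grey A [grey_volume()].
#' @param n_bins Number of histogram bins (default 256).
#' @return A named numeric vector `c(t_air_ice, t_ice_starch)`; voxels
#'   below `t_air_ice` are air, in `[t_air_ice, t_ice_starch)` ice, and at
#'   or above `t_ice_starch` starch.
#' @export
estimate_thresholds <- function(grey, n_bins = 256L) {
  stopifnot(inherits(grey, "grey_volume"))
  v <- as.vector(grey$data)
  rng <- range(v)
  if (diff(rng) == 0)
    abort("degenerate histogram: constant volume; supply manual thresholds",
          class = "icemorph_degenerate_histogram")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  if (count_modes(counts) < 3L)
    abort("degenerate histogram: fewer than three detectable grey-level modes; supply manual thresholds",
          class = "icemorph_degenerate_histogram")
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  ks <- otsu3(counts, mids)
  c(t_air_ice = edges[ks[1] + 1L], t_ice_starch = edges[ks[2] + 1L])
}

# number of modes: local maxima of the lightly smoothed histogram with
# prominence >= 5% of the global maximum
count_modes <- function(counts, window = 2L, prominence = 0.05) {
  k <- 2L * window + 1L
  sm <- as.numeric(stats::filter(c(rep(counts[1], window), counts,
                                   rep(counts[length(counts)], window)),
                                 rep(1 / k, k), sides = 2))
  sm <- sm[window + seq_along(counts)]
  n <- length(sm)
  peaks <- integer(0)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window); hi <- min(n, i + window)
    if (sm[i] >= max(sm[lo:hi]) && sm[i] > 0) {
      if (!length(peaks) || i - tail(peaks, 1) > window) peaks <- c(peaks, i)
    }
  }
  thr <- prominence * max(sm)
  # prominence: drop from the peak to the highest valley separating it
  # from a higher peak
  keep <- vapply(peaks, function(p) {
    higher <- peaks[sm[peaks] > sm[p]]
    if (!length(higher)) return(TRUE)
    nearest <- higher[which.min(abs(higher - p))]
    valley <- min(sm[seq(min(p, nearest), max(p, nearest))])
    (sm[p] - valley) >= thr
  }, logical(1))
  sum(keep)
}

# exhaustive three-class Otsu on binned data; returns the two cut bin
# indices (air = bins 1..k1, ice = k1+1..k2, starch = k2+1..n)
otsu3 <- function(counts, mids) {
  n <- length(counts)
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  csum <- function(a, b) if (a > b) 0 else w[b] - if (a > 1) w[a - 1] else 0
  msum <- function(a, b) if (a > b) 0 else m[b] - if (a > 1) m[a - 1] else 0
  best <- -Inf; bk <- c(1L, 2L)
  for (k1 in 1:(n - 2L)) {
    w1 <- csum(1L, k1)
    if (w1 == 0) next
    mu1 <- msum(1L, k1) / w1
    for (k2 in (k1 + 1L):(n - 1L)) {
      w2 <- csum(k1 + 1L, k2)
      w3 <- csum(k2 + 1L, n)
      if (w2 == 0 || w3 == 0) next
      mu2 <- msum(k1 + 1L, k2) / w2
      mu3 <- msum(k2 + 1L, n) / w3
      crit <- w1 * mu1^2 + w2 * mu2^2 + w3 * mu3^2
      if (crit > best) { best <- crit; bk <- c(k1, k2) }
    }
  }
  bk
}

#' Threshold a grey volume into air, ice and starch
#'
#' Boundary convention (lower-inclusive on the brighter class): voxels
#' with grey `< t_air_ice` are air, `[t_air_ice, t_ice_starch)` ice, and
#' `>= t_ice_starch` starch. Ice is not yet localized: all ice voxels
#' receive the ice-outside code until [partition_ice()] runs.
#'
#' @param grey A [grey_volume()].
#' @param thresholds Numeric `c(t_air_ice, t_ice_starch)`, increasing. A
#'   single threshold segments an unfrozen (two-phase) volume into air
#'   and starch with no ice.
#' @return A [label_volume()] with codes air/ice_outside/starch.
#' @export
segment_phases <- function(grey, thresholds) {
  stopifnot(inherits(grey, "grey_volume"), length(thresholds) %in% 1:2)
  codes <- phase_codes()
  lab <- array(codes[["air"]], dim(grey$data))
  if (length(thresholds) == 1L) {
    lab[grey$data >= thresholds[1]] <- codes[["starch"]]
    return(label_volume(lab, grey$voxel_size))
  }
  if (!(thresholds[1] < thresholds[2]))
    abort("thresholds must satisfy t_air_ice < t_ice_starch",
          class = "icemorph_error")
  lab[grey$data >= thresholds[1]] <- codes[["ice_outside"]]
  lab[grey$data >= thresholds[2]] <- codes[["starch"]]
  label_volume(lab, grey$voxel_size)
}

#' Close the starch phase into the matrix mask
#'
#' 3D morphological closing (dilation then erosion) with a digitized
#' Euclidean ball of radius `radius_vx` voxels (a voxel belongs to the
#' ball iff its centre lies within the radius). The volume is padded with
#' `radius_vx` background voxels before dilation and cropped after
#' erosion, so no artificial matrix forms at the faces. Closing is
#' extensive (output contains the input), increasing in the radius, and
#' idempotent; gaps and embedded cavities narrower than the ball are
#' filled. The default radius of 16 voxels connects starch walls across
#' embedded ice crystals.
#'
#' @param starch_mask 3D logical array of the starch phase.
#' @param radius_vx Ball radius in voxels (>= 0; 0 is the identity).
#' @return A 3D logical array: the closed starch matrix.
#' @export
close_matrix <- function(starch_mask, radius_vx = 16L) {
  stopifnot(is.array(starch_mask), radius_vx >= 0)
  if (radius_vx == 0) return(array(as.logical(starch_mask), dim(starch_mask)))
  d <- dim(starch_mask)
  padded <- pad_array(starch_mask, radius_vx, FALSE)
  closed <- erode_ball(dilate_ball(padded, radius_vx), radius_vx)
  unpad_array(closed, radius_vx, d)
}

#' Split ice into inside- and outside-matrix components
#'
#' Logical (not/and) partition: `ice_inside = ice & matrix`,
#' `ice_outside = ice & !matrix`. The two are disjoint and their union is
#' the ice mask.
#'
#' @param ice_mask 3D logical array of all ice voxels.
#' @param matrix_mask 3D logical array of the closed starch matrix.
#' @return A list with logical arrays `inside` and `outside`.
#' @export
partition_ice <- function(ice_mask, matrix_mask) {
  stopifnot(identical(dim(ice_mask), dim(matrix_mask)))
  list(inside = ice_mask & matrix_mask,
       outside = ice_mask & !matrix_mask)
}

#' Full three-phase segmentation with ice localization
#'
#' Runs the complete procedure: grey-level thresholding into air, ice and
#' starch ([estimate_thresholds()] unless manual thresholds are given),
#' 3D closing of the starch phase into the matrix ([close_matrix()]), and
#' the ice inside/outside partition ([partition_ice()]).
#'
#' @param grey A [grey_volume()].
#' @param thresholds `"auto"` (default) or numeric
#'   `c(t_air_ice, t_ice_starch)`.
#' @param closing_radius Ball radius in voxels for matrix closing.
#' @return A `segmentation_result`: list with `labels` (a
#'   [label_volume()], 4-phase codes), `thresholds`, `closing_radius` and
#'   `matrix` (logical array of the closed matrix).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_preset("fast", shape = c(48, 48, 48), pore_scale = 30))
#' seg <- segment(ph$grey, closing_radius = 8)
#' glance(seg)
segment <- function(grey, thresholds = "auto", closing_radius = 16L) {
  stopifnot(inherits(grey, "grey_volume"))
  if (identical(thresholds, "auto")) thresholds <- estimate_thresholds(grey)
  lab3 <- segment_phases(grey, thresholds)
  codes <- phase_codes()
  starch <- lab3$data == codes[["starch"]]
  ice <- lab3$data == codes[["ice_outside"]]
  matrix_mask <- close_matrix(starch, closing_radius)
  parts <- partition_ice(ice, matrix_mask)
  lab <- lab3$data
  lab[parts$inside] <- codes[["ice_inside"]]
  structure(list(labels = label_volume(lab, grey$voxel_size),
                 thresholds = setNames(as.numeric(thresholds),
                                       if (length(thresholds) == 2L)
                                         c("t_air_ice", "t_ice_starch")
                                       else "t_air_starch"),
                 closing_radius = as.integer(closing_radius),
                 matrix = matrix_mask),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> thresholds = (%s), closing radius = %d vx\n",
              paste(signif(x$thresholds, 4), collapse = ", "),
              x$closing_radius))
  print(x$labels)
  invisible(x)
}

#' @rdname segment
#' @param x A `segmentation_result`.
#' @param ... Unused.
#' @export
tidy.segmentation_result <- function(x, ...) {
  volume_fractions(x$labels)
}

#' @rdname segment
#' @export
glance.segmentation_result <- function(x, ...) {
  tibble(t_air_ice = unname(x$thresholds[1]),
         t_ice_starch = unname(x$thresholds[2]),
         closing_radius_vx = x$closing_radius,
         matrix_fraction = mean(x$matrix),
         n_voxels = length(x$labels$data))
}
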