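#' Representative elementary volume (REV) convergence curve
#'
#' For each requested cube size, crops a sub-volume from every label
#' volume (centred by default, or averaged over random placements),
#' computes the selected phase fraction, and averages across volumes. The
#' reference level is the mean +/- sd of the fraction over the full
#' volumes, mirroring the shaded reference band of sub-volume convergence
#' plots.
#'
#' @param volumes A [label_volume()] or list of them (replicate scans).
#' @param phase Phase selector (see [specific_surface_area()]), default
#'   `"air"` for porosity convergence.
#' @param sizes Cube edge lengths in voxels, increasing. Sizes that do not
#'   fit in a volume are skipped for that volume with a message.
#' @param placement `"center"` (one cube per size per volume) or
#'   `"random"` (`n_random` uniformly placed cubes, averaged).
#' @param n_random Number of random placements when `placement="random"`.
#' @return A tibble (class `rev_curve`) with `size_vx`, `size_um`,
#'   `mean_fraction`, `sd_fraction`, `n`; attributes `ref_mean`, `ref_sd`.
#' @export
rev_curve <- function(volumes, phase = "air", sizes,
                      placement = c("center", "random"), n_random = 5L) {
  placement <- match.arg(placement)
  if (inherits(volumes, "label_volume")) volumes <- list(volumes)
  if (!length(volumes))
    abort("at least one volume is required", class = "icemorph_error")
  sizes <- sort(unique(as.integer(sizes)))
  codes <- resolve_phase(phase)
  frac <- function(arr) mean(arr %in% codes)
  vs <- volumes[[1]]$voxel_size
  rows <- list()
  for (s in sizes) {
    vals <- numeric(0)
    for (v in volumes) {
      d <- dim(v$data)
      if (s > min(d)) {
        message(sprintf("size %d exceeds volume %s: skipped", s,
                        paste(d, collapse = "x")))
        next
      }
      if (placement == "center") {
        vals <- c(vals, frac(crop_subvolume(v, s)$data))
      } else {
        for (r in seq_len(n_random)) {
          lo <- vapply(d, function(n) sample.int(n - s + 1L, 1L), integer(1))
          vals <- c(vals, frac(v$data[lo[1]:(lo[1] + s - 1L),
                                      lo[2]:(lo[2] + s - 1L),
                                      lo[3]:(lo[3] + s - 1L)]))
        }
      }
    }
    if (length(vals))
      rows[[length(rows) + 1L]] <-
        tibble(size_vx = s, size_um = s * vs,
               mean_fraction = mean(vals),
               sd_fraction = if (length(vals) > 1L) sd(vals) else NA_real_,
               n = length(vals))
  }
  if (!length(rows))
    abort("no admissible sub-volume size", class = "icemorph_parameterization_error")
  out <- bind_rows(rows)
  full <- vapply(volumes, function(v) frac(v$data), numeric(1))
  attr(out, "ref_mean") <- mean(full)
  attr(out, "ref_sd") <- if (length(full) > 1L) sd(full) else 0
  attr(out, "phase") <- paste(phase, collapse = "+")
  class(out) <- c("rev_curve", class(out))
  out
}

#' Smallest representative sub-volume size
#'
#' The smallest size on a [rev_curve()] whose fraction, and the fractions
#' at all larger sizes, stay within `tolerance` of the reference mean.
#' `tolerance = "std"` uses the reference +/- sd band (the shaded band of
#' the convergence plot); a numeric tolerance is an absolute fraction.
#' Returns `NA` when no size qualifies.
#'
#' @param curve A [rev_curve()].
#' @param tolerance `"std"` or a positive number (absolute fraction).
#' @return The representative edge length in voxels, or `NA`.
#' @export
smallest_representative_size <- function(curve, tolerance = "std") {
  stopifnot(inherits(curve, "rev_curve"), nrow(curve) > 0)
  ref <- attr(curve, "ref_mean")
  tol <- if (identical(tolerance, "std")) attr(curve, "ref_sd")
         else as.numeric(tolerance)
  dev <- abs(curve$mean_fraction - ref)
  ok <- rev(cumall(rev(dev <= tol)))
  if (!any(ok)) return(NA_integer_)
  curve$size_vx[which(ok)[1]]
}

cumall <- function(x) cumprod(as.logical(x)) > 0
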