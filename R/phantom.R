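#' Specification of a synthetic frozen porous phantom
#'
#' Parameterizes a synthetic grey-level tomogram of a frozen porous cake
#' with exact ground-truth phase labels. The pore space is a thresholded
#' Gaussian random field (stationary, controllable correlation length);
#' wall ice is a conformal shell deposited on the air side of every pore
#' wall; internal ice crystals are axis-aligned cuboids embedded in the
#' solid matrix, mirroring the prismatic crystals (20-100 um) seen in
#' frozen sponge cake.
#'
#' @param shape Integer vector of voxel counts `(y, x, z)`.
#' @param voxel_size Voxel edge in micrometres (isotropic).
#' @param target_porosity Air volume fraction in (0, 1).
#' @param pore_scale Correlation length of the pore space in micrometres
#'   (the Gaussian field is smoothed with sigma = pore_scale / 2).
#' @param wall_ice_thickness Conformal wall-ice layer thickness in
#'   micrometres (0 = none; 20-30 um emulates slow freezing).
#' @param n_crystals Number of embedded cuboid ice crystals.
#' @param crystal_size_range Min/max crystal edge lengths in micrometres.
#' @param grey_means Grey-level means `(air, ice, starch)`, strictly
#'   increasing (air darkest, starch brightest).
#' @param noise_sigma Standard deviation of additive Gaussian grey noise.
#' @param blur_sigma Gaussian blur of the rendered volume, micrometres.
#' @param seed RNG seed (integer).
#' @return A `phantom_spec` object (validated list).
#' @seealso [generate_phantom()], [phantom_preset()]
#' @export
phantom_spec <- function(shape = c(112L, 112L, 112L),
                         voxel_size = 2,
                         target_porosity = 0.6,
                         pore_scale = 80,
                         wall_ice_thickness = 0,
                         n_crystals = 0L,
                         crystal_size_range = c(20, 100),
                         grey_means = c(air = 50, ice = 120, starch = 200),
                         noise_sigma = 10,
                         blur_sigma = 1.4,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    abort("shape must be three positive voxel counts", class = "icemorph_error")
  if (!(target_porosity > 0 && target_porosity < 1))
    abort("target_porosity must lie strictly in (0, 1)", class = "icemorph_error")
  if (voxel_size <= 0 || pore_scale <= 0)
    abort("voxel_size and pore_scale must be > 0", class = "icemorph_error")
  if (wall_ice_thickness < 0)
    abort("wall_ice_thickness must be >= 0", class = "icemorph_error")
  if (n_crystals < 0) abort("n_crystals must be >= 0", class = "icemorph_error")
  if (length(crystal_size_range) != 2L || any(crystal_size_range <= 0) ||
      crystal_size_range[1] > crystal_size_range[2])
    abort("crystal_size_range must be positive (min, max)", class = "icemorph_error")
  if (length(grey_means) != 3L || !all(diff(unname(grey_means)) > 0))
    abort("grey_means must be strictly increasing: air < ice < starch",
          class = "icemorph_error")
  if (noise_sigma < 0 || blur_sigma < 0)
    abort("noise_sigma and blur_sigma must be >= 0", class = "icemorph_error")
  structure(list(shape = shape, voxel_size = voxel_size,
                 target_porosity = target_porosity, pore_scale = pore_scale,
                 wall_ice_thickness = wall_ice_thickness,
                 n_crystals = as.integer(n_crystals),
                 crystal_size_range = as.numeric(crystal_size_range),
                 grey_means = setNames(as.numeric(grey_means),
                                       c("air", "ice", "starch")),
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Phantom presets emulating fast and slow freezing
#'
#' `"fast"` combines a thin (2 um) wall-ice layer with many small (8-20
#' um) crystals embedded in the matrix, so most ice forms inside the
#' matrix. `"slow"` combines a thick (24 um) wall-ice layer with fewer,
#' larger (20-45 um) crystals, so most ice sits at the air-matrix
#' interface. The crystal sizes mirror the characteristic ice thicknesses
#' of the two freezing regimes. `"unfrozen"` contains only air and starch.
#'
#' @param condition `"fast"`, `"slow"` or `"unfrozen"`.
#' @param shape,voxel_size,seed Passed to [phantom_spec()].
#' @param ... Further overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(condition = c("fast", "slow", "unfrozen"),
                           shape = c(112L, 112L, 112L), voxel_size = 2,
                           seed = 1L, ...) {
  condition <- match.arg(condition)
  args <- switch(condition,
    fast = list(wall_ice_thickness = 2, n_crystals = 400L,
                crystal_size_range = c(8, 20)),
    slow = list(wall_ice_thickness = 24, n_crystals = 40L,
                crystal_size_range = c(20, 45)),
    unfrozen = list(wall_ice_thickness = 0, n_crystals = 0L))
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, c(list(shape = shape, voxel_size = voxel_size,
                               seed = seed), args))
}

# pore space without seeding (caller controls the RNG)
gen_pore_space_ <- function(spec) {
  sigma_vx <- spec$pore_scale / spec$voxel_size / 2
  if (4 * sigma_vx >= min(spec$shape))
    abort("pore_scale too large for the requested shape: porosity target unattainable",
          class = "icemorph_parameterization_error")
  field <- array(rnorm(prod(spec$shape)), spec$shape)
  field <- gaussian_blur(field, sigma_vx)
  thr <- quantile(field, spec$target_porosity, names = FALSE)
  solid <- array(field > thr, spec$shape)
  solid
}

#' Generate the solid/air pore structure of a phantom
#'
#' Thresholded Gaussian random field: white noise smoothed at the pore
#' correlation length, thresholded at the porosity quantile so the air
#' fraction matches `target_porosity` (well within +/- 0.02). Deterministic
#' given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A 3D logical array, `TRUE` = solid matrix, `FALSE` = air.
#' @export
generate_pore_space <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, gen_pore_space_(spec))
}

#' Deposit a conformal wall-ice shell on pore walls
#'
#' Marks as ice every air voxel whose centre lies within
#' `round(thickness_um / voxel_size)` voxels of the solid phase, i.e. the
#' Euclidean dilation of the solid into the air, labelled ice. The shell is
#' disjoint from the solid by construction. A warning is emitted when the
#' shell reaches the deepest pore radius (pores close completely).
#'
#' @param solid_mask 3D logical array of the solid phase.
#' @param thickness_um Shell thickness in micrometres (>= 0).
#' @param voxel_size Voxel size in micrometres.
#' @return A 3D logical array of wall-ice (ice outside the matrix) voxels.
#' @export
deposit_wall_ice <- function(solid_mask, thickness_um, voxel_size) {
  stopifnot(is.array(solid_mask), thickness_um >= 0, voxel_size > 0)
  t_vx <- round(thickness_um / voxel_size)
  out <- array(FALSE, dim(solid_mask))
  if (t_vx < 1) return(out)
  air <- !solid_mask
  d2 <- sqedt(air)  # distance of air voxels to the solid phase
  if (any(air) && t_vx >= sqrt(max(d2[air])))
    warn("wall-ice thickness reaches the deepest pore radius: pores close completely")
  array(air & d2 <= t_vx^2, dim(solid_mask))
}

# crystal seeding without RNG control (caller seeds); centers may be given
seed_internal_crystals_ <- function(solid_mask, n, size_range, voxel_size,
                                    centers = NULL) {
  d <- dim(solid_mask)
  out <- array(FALSE, d)
  if (n == 0L) return(out)
  if (is.null(centers)) {
    idx <- which(solid_mask)
    if (!length(idx)) return(out)
    centers <- arrayInd(idx[sample.int(length(idx), n, replace = TRUE)], d)
  } else {
    centers <- matrix(as.integer(centers), ncol = 3L)
    if (nrow(centers) != n)
      abort("centers must have one row per crystal", class = "icemorph_error")
  }
  for (i in seq_len(n)) {
    edges_um <- runif(3, size_range[1], size_range[2])
    half <- pmax(1L, round(edges_um / voxel_size)) %/% 2L
    lo <- pmax(centers[i, ] - half, 1L)
    hi <- pmin(centers[i, ] + half, d)
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  out & solid_mask
}

#' Seed cuboid ice crystals inside the solid matrix
#'
#' Places `n` axis-aligned cuboids with edge lengths drawn uniformly from
#' `size_range` (micrometres), centred at uniformly sampled solid voxels
#' (or at user-supplied `centers`), and clips them to the solid mask. Uses
#' the current RNG state; seed beforehand for reproducibility.
#'
#' @param solid_mask 3D logical array of the solid phase.
#' @param n Number of crystals (>= 0).
#' @param size_range Min/max cuboid edge lengths, micrometres.
#' @param voxel_size Voxel size in micrometres.
#' @param centers Optional integer matrix (n x 3) of `(y, x, z)` centres.
#' @return A 3D logical array, a subset of `solid_mask`.
#' @export
seed_internal_crystals <- function(solid_mask, n, size_range, voxel_size,
                                   centers = NULL) {
  stopifnot(is.array(solid_mask), n >= 0, voxel_size > 0)
  seed_internal_crystals_(solid_mask, as.integer(n), size_range, voxel_size,
                          centers)
}

#' Render a grey-level volume from ground-truth labels
#'
#' Each voxel receives the grey mean of its phase (both ice phases share
#' the ice mean), plus i.i.d. Gaussian noise, followed by a Gaussian blur.
#' Uses the current RNG state.
#'
#' @param truth A [label_volume()] of ground-truth phases.
#' @param grey_means Means `(air, ice, starch)`, strictly increasing.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param blur_sigma Gaussian blur in micrometres.
#' @return A [grey_volume()].
#' @export
render_greyscale <- function(truth, grey_means, noise_sigma = 0,
                             blur_sigma = 0) {
  stopifnot(inherits(truth, "label_volume"))
  if (!all(diff(unname(grey_means)) > 0))
    abort("grey_means must be strictly increasing: air < ice < starch",
          class = "icemorph_error")
  lut <- c(grey_means[1], grey_means[2], grey_means[2], grey_means[3])
  g <- array(lut[truth$data + 1L], dim(truth$data))
  if (noise_sigma > 0)
    g <- g + array(rnorm(length(g), 0, noise_sigma), dim(g))
  g <- gaussian_blur(g, blur_sigma / truth$voxel_size)
  grey_volume(g, truth$voxel_size)
}

#' Generate a complete synthetic phantom
#'
#' Composes pore-space generation, wall-ice deposition, internal crystal
#' seeding and grey-level rendering. A single RNG seed (`spec$seed`) is set
#' once; sub-steps draw in a fixed order, so identical specs give
#' bit-identical phantoms.
#'
#' @param spec A [phantom_spec()] (see also [phantom_preset()]).
#' @return A `phantom_volume`: list with elements `grey` ([grey_volume()]),
#'   `truth` ([label_volume()], codes per [phase_codes()]) and `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_preset("fast", shape = c(48, 48, 48), pore_scale = 30))
#' ph$truth
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    solid <- gen_pore_space_(spec)
    ice_out <- deposit_wall_ice(solid, spec$wall_ice_thickness, spec$voxel_size)
    ice_in <- seed_internal_crystals_(solid, spec$n_crystals,
                                      spec$crystal_size_range, spec$voxel_size)
    codes <- phase_codes()
    lab <- array(codes[["air"]], spec$shape)
    lab[solid] <- codes[["starch"]]
    lab[ice_in] <- codes[["ice_inside"]]
    lab[ice_out] <- codes[["ice_outside"]]
    truth <- label_volume(lab, spec$voxel_size)
    grey <- render_greyscale(truth, spec$grey_means, spec$noise_sigma,
                             spec$blur_sigma)
    structure(list(grey = grey, truth = truth, spec = spec),
              class = "phantom_volume")
  })
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat("<phantom_volume>\n")
  print(x$truth)
  invisible(x)
}
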