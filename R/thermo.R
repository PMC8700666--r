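#' Water content from wet and dried masses
#'
#' `Xw = (m0 - mf) / m0 * 100`, the oven-drying water content in percent
#' of wet mass.
#'
#' @param m0 Wet mass (kg, or any unit; only the ratio matters).
#' @param mf Dried mass, same unit; `0 < mf <= m0`.
#' @return Water content in percent, in `[0, 100]`. Vectorized.
#' @export
#' @examples
#' water_content(10, 4)  # 60
water_content <- function(m0, mf) {
  if (any(mf <= 0) || any(m0 < mf))
    abort("masses must satisfy m0 >= mf > 0", class = "icemorph_validation_error")
  (m0 - mf) / m0 * 100
}

#' Freezable water content from DSC melting enthalpy
#'
#' `Fw = dHw / (dHi * Tw) * 100`: the mass fraction of total water that
#' crystallizes on freezing, from the measured ice-melting enthalpy
#' relative to the latent heat of pure ice scaled by the water content.
#' `Tw` must be entered as a mass *fraction* (e.g. 0.60 for 60% water):
#' only the fraction form is dimensionally consistent with the latent
#' heat in J/g. Results above 100% are physically impossible and raise a
#' validation error.
#'
#' @param dHw Measured transition enthalpy of ice fusion, J/g.
#' @param dHi Specific latent heat of fusion of ice, J/g (default 334).
#' @param Tw Total water content as a mass fraction in (0, 1].
#' @return Freezable water in percent of total water. Vectorized.
#' @export
#' @examples
#' freezable_water(124, 334, 0.60)  # ~61.9
freezable_water <- function(dHw, dHi = 334, Tw) {
  if (any(dHw <= 0) || any(dHi <= 0))
    abort("enthalpies must be positive", class = "icemorph_validation_error")
  if (any(Tw <= 0) || any(Tw > 1))
    abort("Tw must be a mass fraction in (0, 1]", class = "icemorph_validation_error")
  fw <- dHw / (dHi * Tw) * 100
  if (any(fw > 100 + 1e-9))
    abort("freezable water above 100% is physically impossible; check inputs",
          class = "icemorph_validation_error")
  fw
}

#' Theoretical density of a formulation by harmonic mass-fraction mixing
#'
#' `rho = sum(w_i) / sum(w_i / rho_i)` over the included components
#' (mass-weighted harmonic mean, i.e. additive specific volumes).
#' Components without a density (e.g. stabilizers at trace level) are
#' excluded from both sums.
#'
#' @param formulation A data frame with columns `component`,
#'   `mass_fraction` (percent or fraction, > 0) and `density` (kg/m^3, or
#'   `NA` to exclude).
#' @return Mixture density in kg/m^3.
#' @export
#' @examples
#' mixture_density(sponge_cake_formulation())  # ~899
mixture_density <- function(formulation) {
  stopifnot(is.data.frame(formulation),
            all(c("mass_fraction", "density") %in% names(formulation)))
  if (any(formulation$mass_fraction <= 0))
    abort("mass fractions must be positive", class = "icemorph_validation_error")
  inc <- !is.na(formulation$density)
  if (!any(inc))
    abort("no component with a density to include", class = "icemorph_validation_error")
  if (any(formulation$density[inc] <= 0))
    abort("densities must be positive", class = "icemorph_validation_error")
  w <- formulation$mass_fraction[inc]
  rho <- formulation$density[inc]
  sum(w) / sum(w / rho)
}

#' Model sponge cake formulation
#'
#' The water/starch/stabilizer formulation of the model sponge cake used
#' in the examples, with ingredient densities where applicable
#' (stabilizers carry no density and are excluded from the theoretical
#' batter density).
#'
#' @return A tibble with `component`, `mass_fraction` (% w/w) and
#'   `density` (kg/m^3).
#' @export
sponge_cake_formulation <- function() {
  tibble(component = c("HPMC", "MC", "water", "starch"),
         mass_fraction = c(0.35, 0.46, 62.64, 36.55),
         density = c(NA, NA, 1000, 766))
}

#' Porosity from apparent and theoretical densities
#'
#' `porosity = (1 - rho_apparent / rho_theoretical) * 100`: the air
#' fraction implied by comparing the apparent density of the porous cake
#' with the air-free theoretical density of its batter.
#'
#' @param rho_apparent Apparent density (with air), kg/m^3.
#' @param rho_theoretical Theoretical air-free density, kg/m^3.
#' @return Porosity in percent, in `[0, 100]`. Vectorized.
#' @export
#' @examples
#' porosity_from_densities(392, 899)  # ~56.4
porosity_from_densities <- function(rho_apparent, rho_theoretical) {
  if (any(rho_apparent <= 0) || any(rho_theoretical <= 0))
    abort("densities must be positive", class = "icemorph_validation_error")
  if (any(rho_apparent > rho_theoretical))
    abort("apparent density cannot exceed the air-free theoretical density",
          class = "icemorph_validation_error")
  (1 - rho_apparent / rho_theoretical) * 100
}
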