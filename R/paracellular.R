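#' Hydrodynamic radius of a solute
#'
#' Combines the Sutherland-Stokes-Einstein correction for small
#' spherical particles with the Stokes-Einstein relation:
#' `r_hydr = (0.92 + 21.8/MW) * k_B T / (6 pi eta D_aq)`, evaluated in
#' CGS units (dynamic viscosity in poise) and returned in Angstrom.
#' In the large-MW limit this tends to 0.92 times the bare
#' Stokes-Einstein radius.
#'
#' @param mw molecular weight, g/mol; vectorized.
#' @param d_aq_37 aqueous diffusion coefficient at 37 degrees C, cm^2/s.
#' @param params a [model_parameters()] object (supplies eta and T).
#' @return Hydrodynamic radius in Angstrom.
#' @examples
#' hydrodynamic_radius(300, 1e-5) # ~3.26 A
#' @export
hydrodynamic_radius <- function(mw, d_aq_37, params = model_parameters()) {
  stopifnot(all(mw > 0), all(d_aq_37 > 0))
  eta_poise <- params$eta * 10  # N s/m^2 -> poise (g/(cm s))
  r_cm <- (0.92 + 21.8 / mw) * .kB_erg * params$temperature /
    (6 * pi * eta_poise * d_aq_37)
  r_cm * 1e8
}

#' Renkin hindrance function for cylindrical pores
#'
#' Size-sieving factor for diffusion of a solute of hydrodynamic radius
#' `r_hydr` through a water-filled cylindrical pore of radius `r_pore`:
#' `F(rho) = (1 - rho)^2 (1 - 2.104 rho + 2.09 rho^3 - 0.95 rho^5)`
#' with `rho = r_hydr / r_pore`. F decreases from 1 (point solute) to 0
#' (full occlusion); for `rho >= 1` the polynomial is non-physical and
#' the factor is clamped to 0.
#'
#' @param r_hydr solute hydrodynamic radius; same length unit as
#'   `r_pore` (the ratio is what matters); vectorized.
#' @param r_pore pore radius.
#' @return Dimensionless factor in [0, 1].
#' @examples
#' renkin_sieving(0, 12.9)    # 1
#' renkin_sieving(6.45, 12.9) # ~0.0449
#' @export
renkin_sieving <- function(r_hydr, r_pore) {
  stopifnot(all(r_hydr >= 0), all(r_pore > 0))
  rho <- r_hydr / r_pore
  f <- (1 - rho)^2 *
    (1 - 2.104 * rho + 2.09 * rho^3 - 0.95 * rho^5)
  ifelse(rho >= 1, 0, f)
}

#' Electric-field speciation factor for the paracellular pore
#'
#' The tight-junction pore carries a potential drop of magnitude
#' `delta_phi` (negative residues line the channel), which accelerates
#' cations and retards anions. With `x = kappa * |delta_phi|`:
#' neutral and zwitterionic fractions weigh 1; monovalent cations weigh
#' `x / (1 - exp(-x))`, monovalent anions `x / (exp(x) - 1)`; divalent
#' species use the same expressions with `2x`. The factor tends to 1
#' for any speciation as `delta_phi -> 0`.
#'
#' @param s speciation data.frame (see [speciation_profile()]); any
#'   number of rows.
#' @param delta_phi potential drop magnitude, mV.
#' @param kappa electric-field constant, 1/mV.
#' @return Dimensionless weighting factor (vector, one per row).
#' @examples
#' efield_factor(speciation_profile(f_cation = 1)) # ~1.664 at defaults
#' efield_factor(speciation_profile(f_anion = 1))  # ~0.542
#' @export
efield_factor <- function(s, delta_phi = 30, kappa = 0.037414) {
  s <- validate_speciation(s)
  stopifnot(delta_phi >= 0, kappa > 0)
  x <- kappa * abs(delta_phi)
  # x/(1 - e^-x) and x/(e^x - 1) both -> 1 as x -> 0; expm1 keeps the
  # small-x limit accurate to machine precision
  wplus <- function(x) if (x == 0) 1 else x / (-expm1(-x))
  wminus <- function(x) if (x == 0) 1 else x / expm1(x)
  s$f_neutral + s$f_zwitterion +
    s$f_cation * wplus(x) +
    s$f_anion * wminus(x) +
    s$f_dication * wplus(2 * x) +
    s$f_dianion * wminus(2 * x)
}

#' Paracellular pathway resistance
#'
#' Diffusion through the water-filled tight-junction pores between
#' cells. The primary pore population (porosity/path-length ratio
#' `eps_over_delta`) is size-sieved by the Renkin function and weighted
#' by the electric-field factor; a secondary population
#' (`eps_over_delta2`) is neither size- nor charge-restricted:
#' `P_para = (eps/delta) D_aq F(r_hydr/r_pore) E(delta_phi)
#'           + (eps/delta_2) D_aq`, and `R_para = 1/P_para`.
#'
#' @param mw molecular weight, g/mol; vectorized.
#' @param d_aq_37 aqueous diffusion coefficient at 37 degrees C, cm^2/s.
#' @param s speciation data.frame (same number of rows).
#' @param params a [model_parameters()] object.
#' @return Resistance in s/cm (`Inf` when both pore terms vanish).
#' @examples
#' paracellular_resistance(300, 1e-5, speciation_profile(f_neutral = 1))
#' @export
paracellular_resistance <- function(mw, d_aq_37, s,
                                    params = model_parameters()) {
  r_hydr <- hydrodynamic_radius(mw, d_aq_37, params)
  f <- renkin_sieving(r_hydr * 1e-8, params$r_pore)
  e <- efield_factor(s, params$delta_phi, params$kappa)
  p <- params$eps_over_delta * d_aq_37 * f * e +
    params$eps_over_delta2 * d_aq_37
  ifelse(p > 0, 1 / p, Inf)
}
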