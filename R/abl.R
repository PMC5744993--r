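#' Unstirred water layer resistance
#'
#' Combined apical plus basal resistance of the unstirred water layers
#' from a hydrodynamic stirring model: `R_UWL = 1 / (chi_uwl * nu^alpha)`
#' with `nu` the effective stirring speed in rpm. Missing or sub-default
#' speeds are raised to the 150 rpm default (see [effective_rpm()]).
#' The apical and basal layers are kept lumped, as the model never uses
#' them separately. Speciation does not enter: neutral and ionic species
#' cross stagnant water at the same velocity.
#'
#' @param stirring_rpm reported stirring speed (rpm), `NA` or `NULL` if
#'   unreported; vectorized.
#' @param params a [model_parameters()] object.
#' @return Resistance in s/cm.
#' @examples
#' uwl_resistance(NA)          # default 150 rpm, ~2.5e4 s/cm
#' uwl_resistance(600)         # stronger stirring, smaller resistance
#' @export
uwl_resistance <- function(stirring_rpm = NA, params = model_parameters()) {
  nu <- effective_rpm(stirring_rpm, params)
  1 / (params$chi_uwl * nu^params$alpha)
}

#' Cytosol resistance
#'
#' The cytosol is modeled as a crowded aqueous compartment of thickness
#' `h_cytosol` in which solutes diffuse at a fraction
#' (`cytosol_d_factor`, default 0.25) of their pure-water diffusivity:
#' `R_cytosol = h_cytosol / (cytosol_d_factor * D_aq)`.
#'
#' @param d_aq_37 aqueous diffusion coefficient at 37 degrees C, cm^2/s;
#'   vectorized.
#' @param params a [model_parameters()] object.
#' @return Resistance in s/cm.
#' @examples
#' cytosol_resistance(1e-5) # 600 s/cm at defaults
#' @export
cytosol_resistance <- function(d_aq_37, params = model_parameters()) {
  stopifnot(all(d_aq_37 > 0))
  params$h_cytosol / (params$cytosol_d_factor * d_aq_37)
}

#' Filter support resistance
#'
#' Resistance of the stagnant water inside the pores of the
#' polycarbonate filter supporting the monolayer:
#' `R_filter = h_filter / (eps_filter * D_aq)`, with pore length
#' `h_filter` (10 um) and porosity `eps_filter` (0.13 for a
#' "translucent" filter; "clear" filters are about 0.05).
#'
#' @inheritParams cytosol_resistance
#' @return Resistance in s/cm.
#' @examples
#' filter_resistance(1e-5) # ~769 s/cm at defaults
#' @export
filter_resistance <- function(d_aq_37, params = model_parameters()) {
  stopifnot(all(d_aq_37 > 0))
  params$h_filter / (params$eps_filter * d_aq_37)
}
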