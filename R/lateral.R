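#' Space-restriction factor for lateral membrane diffusion
#'
#' Viewed from above, a cell of diameter `h_cytosol` offers only the
#' thin membrane annulus around its perimeter for lateral diffusion.
#' The restriction factor is the ratio of the cytosol cross-section to
#' the membrane annulus:
#' `phi = r^2 / ((r + h_membrane)^2 - r^2)` with `r = 0.5 h_cytosol`.
#' At the defaults (15 um cell, 55 Angstrom membrane) phi is about 682;
#' it multiplies the lateral resistance as the inverse of a porosity.
#'
#' @param h_cytosol cell (cytosol) diameter, cm.
#' @param h_membrane membrane height, cm.
#' @return Dimensionless factor (> 0).
#' @examples
#' phi_factor(15e-4, 55e-8) # ~682
#' @export
phi_factor <- function(h_cytosol, h_membrane) {
  stopifnot(all(h_cytosol > 0), all(h_membrane > 0))
  r <- 0.5 * h_cytosol
  r^2 / ((r + h_membrane)^2 - r^2)
}

#' Lateral diffusion path length
#'
#' Half the circumference of a spherical cell: a solute sorbing at the
#' centre of the apical surface and desorbing at the centre of the
#' basolateral surface travels `h_lateral = 0.5 pi h_cytosol`
#' (about 24 um for a 15 um cell).
#'
#' @param h_cytosol cell diameter, cm.
#' @return Path length in cm.
#' @examples
#' lateral_path_length(15e-4) * 1e4 # ~24 um
#' @export
lateral_path_length <- function(h_cytosol) {
  stopifnot(all(h_cytosol >= 0))
  0.5 * pi * h_cytosol
}

#' Lateral pathway resistance
#'
#' Diffusion of the neutral species along the membrane plane around the
#' cell, from apical to basolateral surface:
#' `R_lateral = h_lateral * phi / (f_neutral * K_lipw * D_lateral)`.
#' The liposome-water partition coefficient `K_lipw` (whole-membrane
#' partitioning, headgroup-dominated for polar solutes) drives sorption
#' into the membrane; only the non-zwitterionic neutral fraction
#' permeates, so `f_neutral = 0` gives infinite resistance. When the
#' lateral pathway is disabled in the parameters the resistance is
#' `Inf` for every chemical.
#'
#' @param log_klipw log10 liposome-water partition coefficient of the
#'   neutral species; vectorized.
#' @param d_lateral lateral membrane diffusion coefficient, cm^2/s.
#' @param f_neutral non-zwitterionic neutral fraction at pH 7.4.
#' @param params a [model_parameters()] object.
#' @return Resistance in s/cm, possibly `Inf`.
#' @examples
#' lateral_resistance(4, 1e-8, 1) # ~1.6e4 s/cm
#' @export
lateral_resistance <- function(log_klipw, d_lateral, f_neutral,
                               params = model_parameters()) {
  stopifnot(all(d_lateral > 0), all(f_neutral >= 0), all(f_neutral <= 1))
  if (!params$lateral_enabled)
    return(rep(Inf, max(length(log_klipw), length(f_neutral))))
  h_lat <- lateral_path_length(params$h_cytosol)
  phi <- phi_factor(params$h_cytosol, params$h_membrane)
  g <- f_neutral * 10^log_klipw * d_lateral
  ifelse(g == 0, Inf, h_lat * phi / g)
}
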