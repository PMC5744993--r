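#' Monolayer model parameters
#'
#' Constructs the full set of geometric and physical constants of the
#' monolayer resistance network, with defaults for a combined
#' Caco-2/MDCK assay at 37 degrees C and pH 7.4. Any subset of fields
#' may be overridden; the rest keep their defaults.
#'
#' Lengths given in non-CGS units at the interface (Angstrom for
#' membrane thicknesses, the cytosol and filter heights in cm) are
#' stored in cm; conversions happen here, at the boundary, so the rest
#' of the package is purely CGS.
#'
#' @param chi_uwl unstirred-water-layer hydrodynamic constant, cm/s.
#' @param alpha empirical stirring-speed exponent, in (0, 1].
#' @param default_rpm stirring speed (rpm) assumed when none is
#'   reported; reported speeds below this value are raised to it, since
#'   UWL permeabilities under mild agitation are indistinguishable.
#' @param eps_over_delta porosity/path-length ratio of the primary
#'   tight-junction pore population, 1/cm.
#' @param eps_over_delta2 same ratio for the secondary (size- and
#'   charge-unrestricted) pore population, 1/cm; must be smaller than
#'   `eps_over_delta`.
#' @param delta_phi magnitude of the electrical potential drop along
#'   the paracellular pore, mV.
#' @param r_pore paracellular pore radius, Angstrom.
#' @param eta dynamic viscosity of water at 37 degrees C, N s/m^2
#'   (converted internally to poise).
#' @param h_cytosol diffusional path length through the cytosol, cm
#'   (default 15 um, from averaged Caco-2/MDCK cell volumes assuming
#'   spherical cells).
#' @param cytosol_d_factor retardation of aqueous diffusivity in the
#'   crowded cytosol (default 0.25).
#' @param h_filter filter (pore) thickness, cm (default 10 um).
#' @param eps_filter filter porosity in (0, 1] (default 0.13, a
#'   "translucent" polycarbonate filter).
#' @param h_membrane full membrane height, Angstrom.
#' @param h_hexlike thickness of the rate-limiting hexadecane-like
#'   membrane interior, Angstrom.
#' @param microvilli_factor apical surface-area amplification by
#'   microvilli (default 24).
#' @param temperature absolute temperature, K.
#' @param kappa electric-field constant e/(k_B T) expressed per mV;
#'   see [derive_kappa()] for the value computed from physical
#'   constants.
#' @param ionized_cutoff neutral-fraction threshold below which a
#'   chemical is treated as fully ionized (default 1e-4, i.e. 0.01%).
#' @param d_lateral_default lateral membrane diffusion coefficient used
#'   when a table provides none, cm^2/s.
#' @param lateral_enabled logical; set `FALSE` to remove the lateral
#'   pathway from the network entirely.
#'
#' @return An object of class `papp_parameters`: a named list with all
#'   fields above, lengths in cm.
#' @seealso [derive_kappa()], [read_parameters()]
#' @examples
#' p <- model_parameters()
#' p$r_pore # 12.9 Angstrom stored as cm
#' model_parameters(eps_filter = 0.05) # "clear" filter
#' @export
model_parameters <- function(chi_uwl = 2e-6,
                             alpha = 0.6,
                             default_rpm = 150,
                             eps_over_delta = 0.78,
                             eps_over_delta2 = 0.05,
                             delta_phi = 30,
                             r_pore = 12.9,
                             eta = 0.6913e-3,
                             h_cytosol = 15e-4,
                             cytosol_d_factor = 0.25,
                             h_filter = 10e-4,
                             eps_filter = 0.13,
                             h_membrane = 55,
                             h_hexlike = 15,
                             microvilli_factor = 24,
                             temperature = 310,
                             kappa = 0.037414,
                             ionized_cutoff = 1e-4,
                             d_lateral_default = 1e-8,
                             lateral_enabled = TRUE) {
  p <- list(
    chi_uwl = chi_uwl,
    alpha = alpha,
    default_rpm = default_rpm,
    eps_over_delta = eps_over_delta,
    eps_over_delta2 = eps_over_delta2,
    delta_phi = delta_phi,
    r_pore = r_pore * 1e-8,          # Angstrom -> cm
    eta = eta,
    h_cytosol = h_cytosol,
    cytosol_d_factor = cytosol_d_factor,
    h_filter = h_filter,
    eps_filter = eps_filter,
    h_membrane = h_membrane * 1e-8,  # Angstrom -> cm
    h_hexlike = h_hexlike * 1e-8,    # Angstrom -> cm
    microvilli_factor = microvilli_factor,
    temperature = temperature,
    kappa = kappa,
    ionized_cutoff = ionized_cutoff,
    d_lateral_default = d_lateral_default,
    lateral_enabled = isTRUE(lateral_enabled)
  )
  class(p) <- "papp_parameters"
  validate_parameters(p)
}

validate_parameters <- function(p) {
  stopifnot(inherits(p, "papp_parameters"))
  pos <- c("chi_uwl", "default_rpm", "eps_over_delta",
           "r_pore", "eta", "h_cytosol", "cytosol_d_factor", "h_filter",
           "h_membrane", "h_hexlike", "microvilli_factor", "temperature",
           "kappa", "ionized_cutoff", "d_lateral_default")
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", f, "' must be a single positive number", call. = FALSE)
  }
  if (p$alpha <= 0 || p$alpha > 1)
    stop("parameter 'alpha' must lie in (0, 1]", call. = FALSE)
  if (p$eps_filter <= 0 || p$eps_filter > 1)
    stop("parameter 'eps_filter' must lie in (0, 1]", call. = FALSE)
  if (p$delta_phi < 0)
    stop("parameter 'delta_phi' must be non-negative", call. = FALSE)
  if (p$eps_over_delta2 < 0)
    stop("parameter 'eps_over_delta2' must be non-negative", call. = FALSE)
  if (p$eps_over_delta <= p$eps_over_delta2)
    stop("primary pore ratio 'eps_over_delta' must exceed 'eps_over_delta2'",
         call. = FALSE)
  p
}

#' @export
print.papp_parameters <- function(x, ...) {
  cat("Monolayer resistance-network parameters (CGS units)\n")
  show <- x
  show$r_pore <- paste0(format(x$r_pore * 1e8), " A")
  show$h_membrane <- paste0(format(x$h_membrane * 1e8), " A")
  show$h_hexlike <- paste0(format(x$h_hexlike * 1e8), " A")
  for (nm in names(show))
    cat(sprintf("  %-18s %s\n", nm, format(show[[nm]])))
  invisible(x)
}

#' Electric-field constant from physical constants
#'
#' Computes kappa = F / (N_A k_B T) = e / (k_B T), expressed per mV,
#' the constant weighting monovalent ions in the paracellular
#' electric-field factor. At 310 K this evaluates to about 0.0374 / mV.
#'
#' @param temperature absolute temperature, K.
#' @return kappa in 1/mV.
#' @examples
#' derive_kappa(310)
#' @export
derive_kappa <- function(temperature = 310) {
  # F/(R*T) is in 1/V; 1e-3 converts to 1/mV
  .faraday_C / (.gas_constant_J * temperature) * 1e-3
}

#' Read model parameters from a config file
#'
#' Reads a YAML or JSON key-value file whose keys are
#' [model_parameters()] argument names and returns the parameter set
#' with those fields overridden. Unknown keys are an error, so typos in
#' sensitivity-run configs fail loudly.
#'
#' @param path path to a `.yml`/`.yaml` or `.json` file.
#' @return A `papp_parameters` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(model_parameters))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(model_parameters, cfg)
}
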