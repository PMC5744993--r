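#' Intrinsic membrane permeability of the neutral species
#'
#' Solubility-diffusion model of the rate-limiting hexadecane-like
#' membrane interior (thickness `h_hexlike`, default 15 Angstrom):
#' `P_m = K_hexw * D_hex / h_hexlike`. This is the permeability a
#' neutral solute shows across a single phospholipid bilayer, the
#' quantity measured in black-lipid-membrane (BLM) experiments.
#' In log form, `log10 P_m = log_khexw + log10 D_hex - log10 h_hexlike`.
#'
#' @param log_khexw log10 hexadecane-water partition coefficient of the
#'   neutral species; vectorized.
#' @param d_hex diffusion coefficient in hexadecane, cm^2/s.
#' @param params a [model_parameters()] object.
#' @return Permeability in cm/s.
#' @examples
#' intrinsic_membrane_permeability(-4, 1e-5) # ~6.7e-3 cm/s
#' @export
intrinsic_membrane_permeability <- function(log_khexw, d_hex,
                                            params = model_parameters()) {
  stopifnot(all(d_hex > 0))
  10^log_khexw * d_hex / params$h_hexlike
}

#' Basolateral membrane resistance
#'
#' Only the non-zwitterionic neutral fraction crosses the bilayer
#' (pH partition hypothesis): `R_m(basal) = 1 / (f_neutral * P_m)`.
#' Fully ionized chemicals (`f_neutral = 0`) get an infinite membrane
#' resistance and are thereby confined to the paracellular route.
#' Zwitterionic chemicals (the zwitterion is the dominant
#' neutral-charge species, `f_zwitterion > f_neutral`) are assigned a
#' negligibly small membrane permeability, i.e. infinite resistance:
#' zwitterions cross bilayers at ion-like rates despite their zero net
#' charge.
#'
#' @param pm intrinsic membrane permeability of the neutral species,
#'   cm/s (see [intrinsic_membrane_permeability()]); vectorized.
#' @param f_neutral non-zwitterionic neutral fraction at pH 7.4.
#' @param f_zwitterion zwitterionic fraction at pH 7.4.
#' @return Resistance in s/cm, possibly `Inf`.
#' @examples
#' basal_membrane_resistance(6.7e-3, f_neutral = 1)
#' basal_membrane_resistance(6.7e-3, f_neutral = 0)      # Inf
#' @export
basal_membrane_resistance <- function(pm, f_neutral, f_zwitterion = 0) {
  stopifnot(all(pm > 0), all(f_neutral >= 0), all(f_neutral <= 1),
            all(f_zwitterion >= 0), all(f_zwitterion <= 1))
  g <- f_neutral * pm
  ifelse(f_zwitterion > f_neutral | g == 0, Inf, 1 / g)
}

#' Apical membrane resistance
#'
#' Identical to the basolateral membrane except that microvilli
#' amplify the apical surface area by `microvilli_factor` (default 24),
#' dividing the resistance: `R_m(apical) = R_m(basal) / 24`. The factor
#' is applied to all chemicals; for lipophilic solutes any resulting
#' P_m overestimate is immaterial because their transport is
#' ABL-limited.
#'
#' @inheritParams basal_membrane_resistance
#' @param params a [model_parameters()] object.
#' @return Resistance in s/cm, possibly `Inf`.
#' @export
apical_membrane_resistance <- function(pm, f_neutral, f_zwitterion = 0,
                                       params = model_parameters()) {
  basal_membrane_resistance(pm, f_neutral, f_zwitterion) /
    params$microvilli_factor
}

#' Read a black-lipid-membrane (BLM) dataset
#'
#' Reads a delimited table of intrinsic membrane permeability
#' measurements with columns `name`, `mw`, `log_khexw`, `d_hex` and
#' `log_pm_exp` (experimental log10 P_m, cm/s).
#'
#' @param path file path (CSV, or TSV for `.tsv`/`.txt`).
#' @return A data.frame.
#' @seealso [blm_evaluate()]
#' @export
read_blm_table <- function(path) {
  d <- read_delim_auto(path)
  need <- c("name", "mw", "log_khexw", "d_hex", "log_pm_exp")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing BLM column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(d$mw <= 0)) stop("BLM 'mw' must be positive", call. = FALSE)
  if (any(d$d_hex <= 0)) stop("BLM 'd_hex' must be positive", call. = FALSE)
  d
}
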