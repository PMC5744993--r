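species_cols <- c("f_neutral", "f_cation", "f_anion",
                  "f_dication", "f_dianion", "f_zwitterion")

descriptor_cols <- c("name", "mw", "log_khexw", "log_klipw",
                     "d_aq_37", "d_hex", "d_lateral")

#' Build a speciation profile
#'
#' A speciation profile holds the fractions of a chemical present as
#' each of six species at pH 7.4: neutral, (di)cation, (di)anion and
#' zwitterion. Fractions must lie in [0, 1] and sum to 1.
#'
#' @param f_neutral,f_cation,f_anion,f_dication,f_dianion,f_zwitterion
#'   species fractions, each in [0, 1].
#' @return A one-row data.frame with the six fraction columns.
#' @examples
#' speciation_profile(f_neutral = 0.2, f_cation = 0.8)
#' @export
speciation_profile <- function(f_neutral = 0, f_cation = 0, f_anion = 0,
                               f_dication = 0, f_dianion = 0,
                               f_zwitterion = 0) {
  s <- data.frame(f_neutral = f_neutral, f_cation = f_cation,
                  f_anion = f_anion, f_dication = f_dication,
                  f_dianion = f_dianion, f_zwitterion = f_zwitterion)
  validate_speciation(s)
}

#' Validate speciation fractions
#'
#' Checks that every fraction lies in [0, 1], that no profile is
#' all-zero, and that each row sums to 1 within 1e-9.
#'
#' @param s a data.frame with the six `f_*` fraction columns (any
#'   number of rows).
#' @return `s`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_speciation <- function(s) {
  miss <- setdiff(species_cols, names(s))
  if (length(miss))
    stop("missing speciation column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(s[species_cols])
  if (!is.numeric(m) || anyNA(m))
    stop("speciation fractions must be numeric and non-missing", call. = FALSE)
  if (any(m < 0) || any(m > 1))
    stop("speciation fractions must lie in [0, 1]", call. = FALSE)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("all-zero speciation profile (fractions must sum to 1)", call. = FALSE)
  if (any(abs(tot - 1) > 1e-9))
    stop("speciation fractions must sum to 1 (worst deviation ",
         format(max(abs(tot - 1))), ")", call. = FALSE)
  s
}

#' Clamp sub-threshold neutral fractions to zero
#'
#' Chemicals whose neutral fraction at pH 7.4 falls below `cutoff`
#' (default 0.01%) are treated as fully ionized: the neutral fraction
#' is set to 0 and its mass is redistributed proportionally over the
#' nonzero remaining fractions so each row still sums to 1. Profiles
#' at or above the cutoff pass through unchanged; the operation is
#' idempotent.
#'
#' @param s speciation data.frame (any number of rows).
#' @param cutoff neutral-fraction threshold, default `1e-4`.
#' @return The clamped speciation data.frame.
#' @examples
#' clamp_speciation(speciation_profile(f_neutral = 5e-5, f_cation = 1 - 5e-5))
#' @export
clamp_speciation <- function(s, cutoff = 1e-4) {
  s <- validate_speciation(s)
  hit <- s$f_neutral > 0 & s$f_neutral < cutoff
  if (any(hit)) {
    other <- as.matrix(s[species_cols[-1L]])
    rest <- rowSums(other)[hit]
    if (any(rest == 0))
      stop("cannot clamp: profile has no non-neutral mass to renormalize",
           call. = FALSE)
    other[hit, ] <- other[hit, , drop = FALSE] / rest
    s[species_cols[-1L]] <- other
    s$f_neutral[hit] <- 0
  }
  validate_speciation(s)
}

#' Validate a chemical descriptor table
#'
#' Checks the physicochemical descriptor columns of one or more
#' chemicals: molecular weight, log10 hexadecane-water and
#' liposome-water partition coefficients of the neutral species, and
#' the aqueous (37 degrees C), hexadecane and lateral-membrane
#' diffusion coefficients (cm^2/s). Errors name the offending field.
#'
#' A missing `d_lateral` column is allowed (a model default is
#' substituted downstream); all present diffusion coefficients must be
#' positive and below 1e-3 cm^2/s, a sanity bound well above any
#' small-molecule diffusivity in water or oil.
#'
#' @param d data.frame with columns `name`, `mw`, `log_khexw`,
#'   `log_klipw`, `d_aq_37`, `d_hex` and optionally `d_lateral`.
#' @return `d`, unchanged, if valid.
#' @export
validate_descriptors <- function(d) {
  need <- setdiff(descriptor_cols, c("d_lateral"))
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing descriptor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  chk_pos <- function(field) {
    v <- d[[field]]
    if (!is.numeric(v) || anyNA(v) || any(v <= 0))
      stop("descriptor '", field, "' must be positive and non-missing",
           call. = FALSE)
    v
  }
  chk_pos("mw")
  for (f in intersect(c("d_aq_37", "d_hex", "d_lateral"), names(d))) {
    chk_pos(f)
    if (any(d[[f]] >= 1e-3))
      stop("descriptor '", f, "' exceeds 1e-3 cm^2/s sanity bound",
           call. = FALSE)
  }
  for (f in c("log_khexw", "log_klipw")) {
    v <- d[[f]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop("descriptor '", f, "' must be finite and non-missing",
           call. = FALSE)
  }
  d
}

#' Effective stirring speed
#'
#' Missing stirring speeds and speeds below the default are replaced by
#' the default (150 rpm): under mild or absent agitation the UWL
#' permeability cannot be distinguished experimentally, so all such
#' assays are modeled at one nominal speed.
#'
#' @param stirring_rpm numeric vector of reported stirring speeds (rpm),
#'   `NA` where unreported.
#' @param params a [model_parameters()] object.
#' @return Numeric vector of effective speeds, all `>= params$default_rpm`.
#' @export
effective_rpm <- function(stirring_rpm, params = model_parameters()) {
  if (is.null(stirring_rpm)) return(params$default_rpm)
  if (any(!is.na(stirring_rpm) & stirring_rpm < 0))
    stop("stirring_rpm must be non-negative", call. = FALSE)
  out <- ifelse(is.na(stirring_rpm), params$default_rpm, stirring_rpm)
  pmax(out, params$default_rpm)
}

#' Read a chemical descriptor table
#'
#' Reads a delimited text file (CSV, or TSV for `.tsv`/`.txt`) with one
#' row per chemical. Required columns: `name`, `mw`, `log_khexw`,
#' `log_klipw`, `d_aq_37`, `d_hex`, and the six speciation fractions
#' `f_neutral`, `f_cation`, `f_anion`, `f_dication`, `f_dianion`,
#' `f_zwitterion`. Optional: `d_lateral`, `stirring_rpm`, `cell_line`.
#'
#' Speciation is validated and clamped at the fully-ionized cutoff on
#' the way in; descriptors are validated.
#'
#' @param path file path.
#' @param params a [model_parameters()] object (supplies the ionized
#'   cutoff).
#' @return A validated data.frame.
#' @seealso [predict_papp()], [generate_chemicals()]
#' @export
read_descriptors <- function(path, params = model_parameters()) {
  d <- read_delim_auto(path)
  validate_descriptors(d)
  validate_speciation(d)
  d[species_cols] <- clamp_speciation(d[species_cols], params$ionized_cutoff)
  d
}

read_delim_auto <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE)
}
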