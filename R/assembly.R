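component_cols <- c("r_uwl", "r_m_apical", "r_cytosol", "r_m_basal",
                    "r_filter", "r_para", "r_lateral")
total_cols <- c("r_para_total", "r_lateral_total", "r_cytosol_total")

#' Serial pathway totals from component resistances
#'
#' Sums the serial resistances of each parallel pathway:
#' \itemize{
#'   \item paracellular: `r_uwl + r_para + r_filter`
#'   \item lateral: `r_uwl + r_lateral + r_filter`
#'   \item cytosolic: `r_uwl + r_m_apical + r_cytosol + r_m_basal + r_filter`
#' }
#' `r_uwl` is the lumped apical+basal unstirred water layer. Infinite
#' components (excluded pathways) propagate to an infinite total.
#'
#' @param components data.frame (any number of rows) with columns
#'   `r_uwl`, `r_m_apical`, `r_cytosol`, `r_m_basal`, `r_filter`,
#'   `r_para`, `r_lateral`, all in s/cm.
#' @return The input with columns `r_para_total`, `r_lateral_total`,
#'   `r_cytosol_total` appended; class `papp_breakdown`.
#' @examples
#' pathway_totals(data.frame(r_uwl = 2.5e4, r_m_apical = 10,
#'   r_cytosol = 600, r_m_basal = 240, r_filter = 770,
#'   r_para = 4e5, r_lateral = 1.6e4))
#' @export
pathway_totals <- function(components) {
  miss <- setdiff(component_cols, names(components))
  if (length(miss))
    stop("missing resistance column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in component_cols)
    if (any(components[[f]] <= 0, na.rm = TRUE))
      stop("resistance '", f, "' must be positive", call. = FALSE)
  b <- as.data.frame(components)
  b$r_para_total <- b$r_uwl + b$r_para + b$r_filter
  b$r_lateral_total <- b$r_uwl + b$r_lateral + b$r_filter
  b$r_cytosol_total <- b$r_uwl + b$r_m_apical + b$r_cytosol +
    b$r_m_basal + b$r_filter
  class(b) <- c("papp_breakdown", "data.frame")
  b
}

#' Apparent permeability from pathway totals
#'
#' The three pathways act in parallel, so their permeabilities
#' (reciprocal resistances) add:
#' `P_app = 1/r_para_total + 1/r_lateral_total + 1/r_cytosol_total`,
#' with `1/Inf = 0` for excluded pathways.
#'
#' @param breakdown a `papp_breakdown` (see [pathway_totals()]) or any
#'   data.frame with the three `*_total` columns.
#' @return Apparent permeability, cm/s (vector, one per row).
#' @examples
#' # Table-style inputs: log totals 6.34 / 4.44 / 4.42 give log P_app -4.13
#' log10(total_papp(data.frame(r_para_total = 10^6.34,
#'   r_cytosol_total = 10^4.44, r_lateral_total = 10^4.42)))
#' @export
total_papp <- function(breakdown) {
  miss <- setdiff(total_cols, names(breakdown))
  if (length(miss))
    stop("missing pathway total(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  inv <- function(r) ifelse(is.infinite(r), 0, 1 / r)
  p <- inv(breakdown$r_para_total) + inv(breakdown$r_lateral_total) +
    inv(breakdown$r_cytosol_total)
  if (any(p == 0))
    stop("no transport path: all three pathway resistances are infinite",
         call. = FALSE)
  p
}

#' Dominant-route and main-barrier classification
#'
#' Labels each chemical by the most permeable pathway (the one with the
#' lowest total resistance). Ties are broken deterministically in the
#' order cytosolic, paracellular, lateral. For cytosolic-dominant
#' chemicals the main barrier within the route is the largest of the
#' UWL, the two membranes summed (apical + basolateral), the cytosol
#' and the filter; for the other routes it is `"n/a"`.
#'
#' @param breakdown a `papp_breakdown` from [pathway_totals()].
#' @return data.frame with columns `dominant_route` (one of
#'   `"cytosolic"`, `"paracellular"`, `"lateral"`) and
#'   `cytosolic_main_barrier` (one of `"UWL"`, `"membranes"`,
#'   `"cytosol"`, `"filter"`, `"n/a"`).
#' @export
classify_routes <- function(breakdown) {
  miss <- setdiff(c(total_cols, component_cols), names(breakdown))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  # tie-break order is the column order here
  totals <- cbind(cytosolic = breakdown$r_cytosol_total,
                  paracellular = breakdown$r_para_total,
                  lateral = breakdown$r_lateral_total)
  route <- colnames(totals)[apply(totals, 1L, which.min)]
  barriers <- cbind(UWL = breakdown$r_uwl,
                    membranes = breakdown$r_m_apical + breakdown$r_m_basal,
                    cytosol = breakdown$r_cytosol,
                    filter = breakdown$r_filter)
  barrier <- colnames(barriers)[apply(barriers, 1L, which.max)]
  barrier[route != "cytosolic"] <- "n/a"
  data.frame(dominant_route = route, cytosolic_main_barrier = barrier,
             stringsAsFactors = FALSE)
}

#' Full resistance breakdown for a descriptor table
#'
#' Evaluates every serial resistance of the network for each chemical
#' in a validated descriptor table: UWL (from the stirring speed),
#' apical and basolateral membranes (hexadecane-slab model with the
#' microvilli factor and pH-partition speciation weighting), cytosol,
#' filter, paracellular pore (Renkin sieving and electric-field factor)
#' and lateral route; then the three pathway totals and P_app.
#'
#' @param tbl data.frame with the descriptor columns of
#'   [validate_descriptors()], the six speciation fractions, and
#'   optionally `stirring_rpm` and `d_lateral`.
#' @param params a [model_parameters()] object.
#' @return A `papp_breakdown` data.frame with, per chemical: all
#'   component resistances (s/cm), the three pathway totals, `p_app`
#'   (cm/s) and `log_papp`.
#' @seealso [predict_papp()] for the full report including route
#'   classification.
#' @export
resistance_breakdown <- function(tbl, params = model_parameters()) {
  tbl <- validate_descriptors(tbl)
  s <- clamp_speciation(validate_speciation(tbl[species_cols]),
                        params$ionized_cutoff)
  d_lat <- if ("d_lateral" %in% names(tbl)) tbl$d_lateral
           else rep(params$d_lateral_default, nrow(tbl))
  rpm <- if ("stirring_rpm" %in% names(tbl)) tbl$stirring_rpm
         else rep(NA_real_, nrow(tbl))

  pm <- intrinsic_membrane_permeability(tbl$log_khexw, tbl$d_hex, params)
  comp <- data.frame(
    r_uwl = uwl_resistance(rpm, params),
    r_m_apical = apical_membrane_resistance(pm, s$f_neutral,
                                            s$f_zwitterion, params),
    r_cytosol = cytosol_resistance(tbl$d_aq_37, params),
    r_m_basal = basal_membrane_resistance(pm, s$f_neutral, s$f_zwitterion),
    r_filter = filter_resistance(tbl$d_aq_37, params),
    r_para = paracellular_resistance(tbl$mw, tbl$d_aq_37, s, params),
    r_lateral = lateral_resistance(tbl$log_klipw, d_lat, s$f_neutral, params)
  )
  b <- pathway_totals(comp)
  b$p_app <- total_papp(b)
  b$log_papp <- log10(b$p_app)
  if ("name" %in% names(tbl))
    b <- cbind(name = tbl$name, b, stringsAsFactors = FALSE)
  class(b) <- c("papp_breakdown", "data.frame")
  b
}

#' Predict apparent permeability for a table of chemicals
#'
#' End-to-end forward model: validates descriptors and speciation,
#' computes the full resistance breakdown, P_app, and the
#' route/barrier classification.
#'
#' @inheritParams resistance_breakdown
#' @return data.frame: `name`, every component resistance and pathway
#'   total (s/cm), `p_app` (cm/s), `log_papp`, `dominant_route`,
#'   `cytosolic_main_barrier`.
#' @examples
#' tbl <- generate_chemicals(5, seed = 1)
#' predict_papp(tbl)[, c("name", "log_papp", "dominant_route")]
#' @export
predict_papp <- function(tbl, params = model_parameters()) {
  b <- resistance_breakdown(tbl, params)
  cbind(b, classify_routes(b))
}

#' Write a per-chemical prediction report
#'
#' Writes the [predict_papp()] table as delimited text and, optionally,
#' a JSON version carrying the same per-chemical records.
#'
#' @param report data.frame from [predict_papp()].
#' @param path output file; `.json` writes JSON, anything else
#'   tab-separated text.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, auto_unbox = FALSE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
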