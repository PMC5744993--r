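#' Read an experimental P_app record table
#'
#' Reads delimited experimental apparent-permeability records with
#' columns `name`, `log_papp_exp` (log10 cm/s) and optionally
#' `cell_line`, `efflux_ratio`, `stirring_rpm`, `source`.
#'
#' @param path file path (CSV, or TSV for `.tsv`/`.txt`).
#' @return A data.frame.
#' @export
read_experiments <- function(path) {
  d <- read_delim_auto(path)
  need <- c("name", "log_papp_exp")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing experiment column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(d$log_papp_exp < -9 | d$log_papp_exp > -2, na.rm = TRUE))
    stop("log_papp_exp outside plausible range (-9, -2)", call. = FALSE)
  d
}

#' Curate experimental P_app records
#'
#' Applies the passive-transport curation rules to raw literature
#' records:
#' \enumerate{
#'   \item records with efflux ratio >= 2 are dropped (active
#'     transport);
#'   \item remaining replicates are averaged on the linear P_app scale
#'     (arithmetic mean), first within a source (both transport
#'     directions count as replicates), then across sources and cell
#'     lines;
#'   \item records stirred at or above 150 rpm keep their reported
#'     speed and are modeled separately per distinct speed; unstirred,
#'     unreported or mildly stirred records are pooled at the 150 rpm
#'     default.
#' }
#' A chemical measured at two qualifying stirring speeds therefore
#' yields two curated entries. The operation is idempotent.
#'
#' @param records data.frame with columns `name`, `log_papp_exp` and
#'   optionally `efflux_ratio`, `stirring_rpm`, `source`, `cell_line`.
#' @param efflux_cutoff efflux-ratio threshold, default 2.
#' @param params a [model_parameters()] object (supplies the default
#'   stirring speed).
#' @return data.frame with one row per (chemical, effective stirring
#'   speed): `name`, `stirring_rpm`, `log_papp_exp`, `n_records`.
#' @export
curate_records <- function(records, efflux_cutoff = 2,
                           params = model_parameters()) {
  if (nrow(records) == 0)
    return(data.frame(name = character(), stirring_rpm = numeric(),
                      log_papp_exp = numeric(), n_records = integer(),
                      stringsAsFactors = FALSE))
  r <- as.data.frame(records)
  if ("efflux_ratio" %in% names(r))
    r <- r[is.na(r$efflux_ratio) | r$efflux_ratio < efflux_cutoff, ,
           drop = FALSE]
  if (nrow(r) == 0)
    return(curate_records(r[0, , drop = FALSE], efflux_cutoff, params))
  if (!"stirring_rpm" %in% names(r)) r$stirring_rpm <- NA_real_
  if (!"source" %in% names(r)) r$source <- "unknown"
  r$.rpm_eff <- effective_rpm(r$stirring_rpm, params)
  r$.papp <- 10^r$log_papp_exp

  # stage 1: arithmetic mean of linear P_app within a source
  key1 <- interaction(r$name, r$source, r$.rpm_eff, drop = TRUE)
  s1 <- data.frame(
    name = tapply(r$name, key1, `[`, 1L),
    .rpm_eff = as.numeric(tapply(r$.rpm_eff, key1, `[`, 1L)),
    .papp = as.numeric(tapply(r$.papp, key1, mean)),
    .n = as.integer(tapply(r$.papp, key1, length)),
    stringsAsFactors = FALSE
  )
  # stage 2: mean across sources (and cell lines) per stirring condition
  key2 <- interaction(s1$name, s1$.rpm_eff, drop = TRUE)
  out <- data.frame(
    name = as.character(tapply(s1$name, key2, `[`, 1L)),
    stirring_rpm = as.numeric(tapply(s1$.rpm_eff, key2, `[`, 1L)),
    log_papp_exp = log10(as.numeric(tapply(s1$.papp, key2, mean))),
    n_records = as.integer(tapply(s1$.n, key2, sum)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$name, out$stirring_rpm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prediction-vs-experiment fit statistics
#'
#' Root-mean-square error and R-squared between predicted and
#' experimental log10 values. By default R-squared is the squared
#' Pearson correlation; `method = "cod"` gives the coefficient of
#' determination `1 - SS_res/SS_tot` instead (which, unlike the
#' correlation, penalizes systematic offsets and can be negative).
#'
#' @param pred,obs numeric vectors of log10 values, equal length.
#' @param method `"pearson"` (default) or `"cod"`.
#' @return Named list: `n`, `rmse`, `r2`.
#' @examples
#' fit_metrics(c(-4, -5, -6), c(-4.5, -5, -5.5)) # rmse ~0.408, r2 = 1
#' @export
fit_metrics <- function(pred, obs, method = c("pearson", "cod")) {
  method <- match.arg(method)
  if (length(pred) != length(obs))
    stop("pred and obs must have equal length", call. = FALSE)
  keep <- is.finite(pred) & is.finite(obs)
  pred <- pred[keep]; obs <- obs[keep]
  n <- length(pred)
  if (n < 2)
    stop("need at least 2 paired finite values for fit metrics",
         call. = FALSE)
  rmse <- sqrt(mean((pred - obs)^2))
  r2 <- if (method == "pearson") {
    if (sd(pred) == 0 && sd(obs) == 0 && rmse == 0) 1
    else cor(pred, obs)^2
  } else {
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
  list(n = n, rmse = rmse, r2 = r2)
}

#' Evaluate model predictions against curated experiments
#'
#' Joins a descriptor table with curated experimental records by
#' chemical name (and, when the curation produced several stirring
#' conditions, models each condition at its own speed), runs the
#' forward model, and reports fit statistics plus the per-chemical
#' comparison.
#'
#' @param descriptors validated descriptor table (see
#'   [read_descriptors()]).
#' @param experiments raw experimental records (see
#'   [read_experiments()]); curated internally.
#' @param params a [model_parameters()] object.
#' @param exclude character vector of chemical names to drop before
#'   fitting (e.g. chemicals with unreliable speciation predictions).
#' @param r2_method passed to [fit_metrics()].
#' @return Object of class `papp_evaluation`: list with `n`, `rmse`,
#'   `r2`, and `per_chemical` (name, stirring_rpm, log_pred, log_exp,
#'   dominant_route, cytosolic_main_barrier).
#' @export
evaluate_dataset <- function(descriptors, experiments,
                             params = model_parameters(),
                             exclude = character(),
                             r2_method = "pearson") {
  cur <- curate_records(experiments, params = params)
  cur <- cur[!cur$name %in% exclude, , drop = FALSE]
  idx <- match(cur$name, descriptors$name)
  if (all(is.na(idx)))
    stop("no overlap between experiment and descriptor chemicals",
         call. = FALSE)
  cur <- cur[!is.na(idx), , drop = FALSE]
  d <- descriptors[idx[!is.na(idx)], , drop = FALSE]
  d$stirring_rpm <- cur$stirring_rpm  # model each stirring condition
  pred <- predict_papp(d, params)
  m <- fit_metrics(pred$log_papp, cur$log_papp_exp, method = r2_method)
  out <- list(
    n = m$n, rmse = m$rmse, r2 = m$r2,
    per_chemical = data.frame(
      name = cur$name,
      stirring_rpm = cur$stirring_rpm,
      log_pred = pred$log_papp,
      log_exp = cur$log_papp_exp,
      dominant_route = pred$dominant_route,
      cytosolic_main_barrier = pred$cytosolic_main_barrier,
      stringsAsFactors = FALSE
    )
  )
  class(out) <- "papp_evaluation"
  out
}

#' Evaluate the intrinsic-membrane (BLM) submodel
#'
#' Black-lipid-membrane measurements probe the bare bilayer resistance
#' of neutral species, free of cellular artifacts. Molecules with
#' MW < `mw_min` are excluded: such small solutes cross faster than the
#' homogeneous solubility-diffusion model predicts (polymer-like rather
#' than liquid-hydrocarbon membrane behaviour). Remaining records are
#' predicted as `log10 P_m = log_khexw + log10 d_hex - log10 h_hexlike`
#' and compared with the experimental values.
#'
#' @param records data.frame with `name`, `mw`, `log_khexw`, `d_hex`,
#'   `log_pm_exp` (see [read_blm_table()]).
#' @param params a [model_parameters()] object.
#' @param mw_min molecular-weight exclusion threshold, default 50.
#' @param r2_method passed to [fit_metrics()].
#' @return Object of class `papp_evaluation`: list with `n`, `rmse`,
#'   `r2`, `per_chemical` (name, mw, log_pred, log_exp).
#' @export
blm_evaluate <- function(records, params = model_parameters(),
                         mw_min = 50, r2_method = "pearson") {
  need <- c("name", "mw", "log_khexw", "d_hex", "log_pm_exp")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing BLM column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- records[records$mw >= mw_min, , drop = FALSE]
  if (nrow(keep) == 0)
    stop("no BLM records left after the MW filter", call. = FALSE)
  log_pred <- log10(intrinsic_membrane_permeability(keep$log_khexw,
                                                    keep$d_hex, params))
  m <- fit_metrics(log_pred, keep$log_pm_exp, method = r2_method)
  out <- list(
    n = m$n, rmse = m$rmse, r2 = m$r2,
    per_chemical = data.frame(
      name = keep$name, mw = keep$mw,
      log_pred = log_pred, log_exp = keep$log_pm_exp,
      stringsAsFactors = FALSE
    )
  )
  class(out) <- "papp_evaluation"
  out
}

#' @export
print.papp_evaluation <- function(x, ...) {
  cat(sprintf("Permeability evaluation: n = %d, RMSE = %.3f, R2 = %.3f\n",
              x$n, x$rmse, x$r2))
  if (!is.null(x$per_chemical$dominant_route)) {
    tb <- table(x$per_chemical$dominant_route)
    cat("Dominant routes:",
        paste(sprintf("%s = %d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}
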