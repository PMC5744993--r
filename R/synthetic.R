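# Runs code under a temporary RNG state so generators are deterministic
# in `seed` without disturbing the caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Dirichlet sample via normalized gammas; rows sum to 1 exactly enough
# for the speciation validator after an explicit renormalization.
rdirichlet <- function(n, alpha) {
  m <- matrix(rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  m / rowSums(m)
}

#' Generate a synthetic chemical descriptor table
#'
#' Draws `n` chemicals whose descriptors span the ranges the monolayer
#' model is exercised over: MW in [50, 800] g/mol, log K_hexw in
#' [-8, 4], log K_lipw in [-1, 6]; aqueous diffusivity follows a
#' log-linear MW scaling with mild scatter, D_hex stays within a
#' factor ~4 of D_aq, and D_lateral scatters around the lateral-route
#' default. Speciation profiles are drawn per chemical class (neutral,
#' acid, base, zwitterionic, permanently ionized, diprotic) so that
#' every route-classification branch is exercised; when `n >= 6` the
#' first six rows are fixed archetypes (neutral lipophile, neutral
#' hydrophile, pure cation, pure anion, pure zwitterion, dication) so
#' corner behaviour is always present. Stirring speeds mix unreported
#' (`NA`), mild and strong agitation.
#'
#' The generator is deterministic in `seed` and every row passes
#' [validate_descriptors()] and [validate_speciation()].
#'
#' @param n number of chemicals, >= 1.
#' @param seed integer RNG seed.
#' @return data.frame with the descriptor, speciation and
#'   `stirring_rpm` columns consumed by [predict_papp()].
#' @examples
#' generate_chemicals(6, seed = 1)$name
#' @export
generate_chemicals <- function(n, seed = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    mw <- runif(n, 50, 800)
    log_khexw <- runif(n, -8, 4)
    log_klipw <- runif(n, -1, 6)
    # log10 D_aq(37C) ~ -4.06 - 0.453 log10 MW, with 0.05-log scatter
    d_aq_37 <- 10^(-4.06 - 0.453 * log10(mw) + rnorm(n, 0, 0.05))
    d_hex <- d_aq_37 * runif(n, 0.5, 2)
    d_lateral <- 10^(-8 + rnorm(n, 0, 0.3))

    cls <- sample(c("neutral", "acid", "base", "zwitterion",
                    "permanent_ion", "diprotic"),
                  n, replace = TRUE,
                  prob = c(0.30, 0.20, 0.20, 0.10, 0.12, 0.08))
    spec <- matrix(0, n, 6,
                   dimnames = list(NULL, species_cols))
    for (i in seq_len(n)) {
      spec[i, ] <- switch(
        cls[i],
        neutral = c(1, 0, 0, 0, 0, 0),
        acid = {
          fa <- runif(1, 0, 0.999)
          c(1 - fa, 0, fa, 0, 0, 0)
        },
        base = {
          fc <- runif(1, 0, 0.999)
          c(1 - fc, fc, 0, 0, 0, 0)
        },
        zwitterion = {
          w <- rdirichlet(1, c(0.2, 0.5, 0.5, 0, 0, 8) + 1e-3)
          w
        },
        permanent_ion = {
          # no neutral species at all; mono- or divalent
          w <- rdirichlet(1, c(0, 3, 3, 0.3, 0.3, 0) + 1e-6)
          w[1] <- 0; w / sum(w)
        },
        diprotic = {
          w <- rdirichlet(1, c(1, 1, 1, 0.7, 0.7, 0.2))
          w
        }
      )
    }
    if (n >= 6L) {
      spec[1L, ] <- c(1, 0, 0, 0, 0, 0)   # neutral lipophile
      spec[2L, ] <- c(1, 0, 0, 0, 0, 0)   # neutral hydrophile
      spec[3L, ] <- c(0, 1, 0, 0, 0, 0)   # permanent cation
      spec[4L, ] <- c(0, 0, 1, 0, 0, 0)   # permanent anion
      spec[5L, ] <- c(0, 0, 0, 0, 0, 1)   # pure zwitterion
      spec[6L, ] <- c(0, 0, 0, 1, 0, 0)   # dication
      log_khexw[1L] <- 2;  log_klipw[1L] <- 3   # lipophilic, UWL-limited
      log_khexw[2L] <- -7; log_klipw[2L] <- 0   # polar, membrane-limited
      cls[1:6] <- c("neutral", "neutral", "permanent_ion",
                    "permanent_ion", "zwitterion", "permanent_ion")
    }
    spec <- spec / rowSums(spec)

    stirring_rpm <- sample(c(NA, NA, 25, 150, 500, 600), n, replace = TRUE)
    tbl <- data.frame(
      name = sprintf("syn%04d", seq_len(n)),
      mw = mw, log_khexw = log_khexw, log_klipw = log_klipw,
      d_aq_37 = d_aq_37, d_hex = d_hex, d_lateral = d_lateral,
      stirring_rpm = stirring_rpm,
      chemical_class = cls,
      stringsAsFactors = FALSE
    )
    tbl <- cbind(tbl, as.data.frame(spec))
    validate_descriptors(tbl)
    validate_speciation(tbl)
    tbl
  })
}

#' Generate pseudo-experimental P_app records from a descriptor table
#'
#' Runs the forward model on `tbl` and perturbs the predicted log10
#' P_app with Gaussian noise of standard deviation `noise_sd` (log10
#' units), emitting experimental-style records (efflux ratio 1, source
#' `"synthetic"`). With `noise_sd = 0` the evaluation pipeline must
#' recover the predictions exactly (RMSE 0, R2 1), which makes this the
#' package's end-to-end closure fixture.
#'
#' @param tbl descriptor table (see [generate_chemicals()]).
#' @param noise_sd experimental noise in log10 units, >= 0.
#' @param seed integer RNG seed.
#' @param params a [model_parameters()] object.
#' @return data.frame with columns `name`, `cell_line`,
#'   `log_papp_exp`, `efflux_ratio`, `stirring_rpm`, `source`.
#' @examples
#' tbl <- generate_chemicals(8, seed = 2)
#' generate_pseudo_experiment(tbl, noise_sd = 0, seed = 3)
#' @export
generate_pseudo_experiment <- function(tbl, noise_sd = 0.3, seed = 1,
                                       params = model_parameters()) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  pred <- predict_papp(tbl, params)
  with_seed(seed, {
    log_exp <- pred$log_papp + rnorm(nrow(pred), 0, noise_sd)
    data.frame(
      name = tbl$name,
      cell_line = sample(c("Caco-2", "MDCK"), nrow(tbl), replace = TRUE),
      log_papp_exp = log_exp,
      efflux_ratio = 1,
      stirring_rpm = if ("stirring_rpm" %in% names(tbl)) tbl$stirring_rpm
                     else NA_real_,
      source = "synthetic",
      stringsAsFactors = FALSE
    )
  })
}
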