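# Independent resistor-network oracle: computes the current through a
# series chain of resistances between a unit-potential donor node and a
# grounded acceptor node by solving the Kirchhoff node equations, not by
# summing resistances. Used to cross-check the pathway-total algebra.
solve_series_current <- function(r, v = 1) {
  g <- 1 / r
  k <- length(r)
  if (k == 1L) return(g * v)
  n <- k - 1L  # internal nodes
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, i] <- g[i] + g[i + 1L]
    if (i > 1L) A[i, i - 1L] <- -g[i]
    if (i < n) A[i, i + 1L] <- -g[i + 1L]
  }
  b <- c(g[1L] * v, rep(0, n - 1L))
  vv <- solve(A, b)
  g[1L] * (v - vv[1L])
}

# Oracle P_app for one row of component resistances: three independent
# series chains in parallel (each pathway carries its own UWL + filter).
oracle_network_papp <- function(comp) {
  chains <- list(
    c(comp$r_uwl, comp$r_para, comp$r_filter),
    c(comp$r_uwl, comp$r_lateral, comp$r_filter),
    c(comp$r_uwl, comp$r_m_apical, comp$r_cytosol, comp$r_m_basal,
      comp$r_filter)
  )
  sum(vapply(chains, solve_series_current, numeric(1)))
}

# One-row descriptor table with sensible defaults, overridable per test.
make_chemical <- function(name = "x", mw = 300, log_khexw = -2,
                          log_klipw = 2, d_aq_37 = 8e-6, d_hex = 8e-6,
                          d_lateral = 1e-8, stirring_rpm = NA,
                          f_neutral = 1, f_cation = 0, f_anion = 0,
                          f_dication = 0, f_dianion = 0,
                          f_zwitterion = 0) {
  data.frame(name = name, mw = mw, log_khexw = log_khexw,
             log_klipw = log_klipw, d_aq_37 = d_aq_37, d_hex = d_hex,
             d_lateral = d_lateral, stirring_rpm = stirring_rpm,
             f_neutral = f_neutral, f_cation = f_cation,
             f_anion = f_anion, f_dication = f_dication,
             f_dianion = f_dianion, f_zwitterion = f_zwitterion,
             stringsAsFactors = FALSE)
}
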