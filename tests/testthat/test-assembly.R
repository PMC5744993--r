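test_that("pathway totals are exact serial sums and propagate exclusions", {
  comp <- data.frame(r_uwl = 2.5e4, r_m_apical = 10, r_cytosol = 600,
                     r_m_basal = 240, r_filter = 770, r_para = 4e5,
                     r_lateral = 1.6e4)
  b <- pathway_totals(comp)
  expect_equal(b$r_para_total, comp$r_uwl + comp$r_para + comp$r_filter,
               tolerance = 1e-12)
  expect_equal(b$r_lateral_total,
               comp$r_uwl + comp$r_lateral + comp$r_filter,
               tolerance = 1e-12)
  expect_equal(b$r_cytosol_total,
               comp$r_uwl + comp$r_m_apical + comp$r_cytosol +
                 comp$r_m_basal + comp$r_filter, tolerance = 1e-12)

  comp$r_m_basal <- Inf
  b2 <- pathway_totals(comp)
  expect_identical(b2$r_cytosol_total, Inf)
  expect_true(is.finite(b2$r_para_total) && is.finite(b2$r_lateral_total))
})

test_that("parallel permeabilities add, with excluded pathways contributing zero", {
  b <- data.frame(r_para_total = 1e5, r_lateral_total = Inf,
                  r_cytosol_total = Inf)
  expect_equal(total_papp(b), 1e-5)
  b3 <- data.frame(r_para_total = 3e4, r_lateral_total = 3e4,
                   r_cytosol_total = 3e4)
  expect_equal(total_papp(b3), 3 / 3e4)
  expect_error(total_papp(data.frame(r_para_total = Inf,
                                     r_lateral_total = Inf,
                                     r_cytosol_total = Inf)),
               "no transport path")
})

test_that("printed ritonavir pathway totals reproduce the tabulated P_app", {
  # log totals 6.34 / 4.44 / 4.42 (para / cytosol / lateral)
  b <- data.frame(r_para_total = 10^6.34, r_cytosol_total = 10^4.44,
                  r_lateral_total = 10^4.42)
  expect_equal(log10(total_papp(b)), -4.13, tolerance = 0.002)
})

test_that("pathway algebra agrees with a Kirchhoff network oracle", {
  set.seed(99)
  for (i in 1:40) {
    comp <- data.frame(
      r_uwl = 10^runif(1, 3, 5), r_m_apical = 10^runif(1, 0, 7),
      r_cytosol = 10^runif(1, 2, 4), r_m_basal = 10^runif(1, 0, 7),
      r_filter = 10^runif(1, 2, 4), r_para = 10^runif(1, 4, 8),
      r_lateral = 10^runif(1, 3, 8))
    b <- pathway_totals(comp)
    expect_equal(total_papp(b), oracle_network_papp(comp),
                 tolerance = 1e-10)
  }
})

test_that("route classification finds the least-resistive pathway and its barrier", {
  p <- model_parameters()

  # fully ionized non-zwitterion: paracellular only
  ion <- predict_papp(make_chemical(f_neutral = 0, f_cation = 1), p)
  expect_identical(ion$dominant_route, "paracellular")
  expect_identical(ion$cytosolic_main_barrier, "n/a")
  expect_identical(ion$r_cytosol_total, Inf)

  # very polar neutral chemical: cytosolic route, membranes limiting
  polar <- predict_papp(make_chemical(log_khexw = -6.5, log_klipw = 0,
                                      mw = 60, d_aq_37 = 1.3e-5,
                                      d_hex = 1.3e-5), p)
  expect_identical(polar$dominant_route, "cytosolic")
  expect_identical(polar$cytosolic_main_barrier, "membranes")

  # lipophilic neutral chemical: cytosolic route, UWL limiting
  lipo <- predict_papp(make_chemical(log_khexw = 2, log_klipw = 3), p)
  expect_identical(lipo$dominant_route, "cytosolic")
  expect_identical(lipo$cytosolic_main_barrier, "UWL")

  # zwitterion: membranes shut, paracellular wins over lateral
  zwit <- predict_papp(make_chemical(f_neutral = 0, f_zwitterion = 1), p)
  expect_identical(zwit$dominant_route, "paracellular")
})

test_that("route ties break deterministically: cytosolic, paracellular, lateral", {
  comp <- data.frame(r_uwl = 1e4, r_m_apical = 1, r_cytosol = 1,
                     r_m_basal = 1, r_filter = 1, r_para = 3, r_lateral = 3)
  b <- pathway_totals(comp)  # all three totals equal
  expect_identical(classify_routes(b)$dominant_route, "cytosolic")
  comp$r_m_basal <- 1e6
  b2 <- pathway_totals(comp)  # paracellular and lateral tie
  expect_identical(classify_routes(b2)$dominant_route, "paracellular")
})

test_that("P_app is monotone in partitioning, speciation, stirring and diffusivity", {
  p <- model_parameters()
  papp_of <- function(...) predict_papp(make_chemical(...), p)$p_app

  # hexadecane partitioning opens the transcellular membranes
  lk <- seq(-8, 3, by = 1)
  v <- vapply(lk, function(k) papp_of(log_khexw = k), numeric(1))
  expect_true(all(diff(v) >= 0))

  # neutral fraction (traded against anion) opens membranes, lateral
  # route and the paracellular field factor together
  fn <- c(0, 0.001, 0.01, 0.1, 0.5, 1)
  v <- vapply(fn, function(f) papp_of(f_neutral = f, f_anion = 1 - f),
              numeric(1))
  expect_true(all(diff(v) >= 0))

  # stirring thins the UWL
  rpm <- c(150, 300, 600, 1200)
  v <- vapply(rpm, function(s) papp_of(stirring_rpm = s), numeric(1))
  expect_true(all(diff(v) >= 0))

  # aqueous diffusivity speeds every ABL term
  d <- c(3e-6, 6e-6, 1.2e-5)
  v <- vapply(d, function(x) papp_of(d_aq_37 = x), numeric(1))
  expect_true(all(diff(v) >= 0))

  # liposome partitioning opens the lateral route
  klip <- c(0, 2, 4, 6)
  v <- vapply(klip, function(k) papp_of(log_klipw = k), numeric(1))
  expect_true(all(diff(v) >= 0))
})

test_that("the shared UWL caps P_app at three parallel UWL conductances", {
  p <- model_parameters()
  set.seed(17)
  tbl <- generate_chemicals(200, seed = 17)
  pr <- predict_papp(tbl, p)
  cap <- 3 / uwl_resistance(tbl$stirring_rpm, p)
  expect_true(all(pr$p_app <= cap + 1e-15))
  # each pathway alone never exceeds the total
  for (tot in c("r_para_total", "r_lateral_total", "r_cytosol_total")) {
    pathway_perm <- ifelse(is.infinite(pr[[tot]]), 0, 1 / pr[[tot]])
    expect_true(all(pr$p_app >= pathway_perm - 1e-18))
  }
  # with default stirring the cap pins log P_app near -4
  mild <- is.na(tbl$stirring_rpm) | tbl$stirring_rpm <= 150
  expect_lte(max(pr$log_papp[mild]), log10(3 / uwl_resistance(NA, p)))
  expect_lt(log10(3 / uwl_resistance(NA, p)), -3.8)
})

test_that("removing a pathway never increases P_app", {
  p_on <- model_parameters()
  p_off <- model_parameters(lateral_enabled = FALSE)
  tbl <- generate_chemicals(50, seed = 23)
  expect_true(all(predict_papp(tbl, p_off)$p_app <=
                    predict_papp(tbl, p_on)$p_app + 1e-18))
})
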