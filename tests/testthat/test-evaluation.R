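test_that("curation drops efflux substrates and averages replicates", {
  rec <- data.frame(
    name = "drugA",
    log_papp_exp = c(-5, -5.2, -5.4),
    efflux_ratio = c(1.5, 2.0, 3.0),
    source = "s1",
    stringsAsFactors = FALSE
  )
  out <- curate_records(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$log_papp_exp, -5)  # only the efflux-ratio-1.5 record

  # within-source replicates (both directions) average on the linear scale
  rec2 <- data.frame(name = "drugB", log_papp_exp = c(-5, -6),
                     source = "s1", stringsAsFactors = FALSE)
  out2 <- curate_records(rec2)
  expect_equal(out2$log_papp_exp, log10(mean(c(1e-5, 1e-6))))

  # two-stage averaging: within source first, then across sources
  rec3 <- data.frame(name = "drugC",
                     log_papp_exp = c(-5, -6, -5.5),
                     source = c("s1", "s1", "s2"),
                     stringsAsFactors = FALSE)
  out3 <- curate_records(rec3)
  expect_equal(out3$log_papp_exp,
               log10(mean(c(mean(c(1e-5, 1e-6)), 10^-5.5))))
})

test_that("reported fast-stirring conditions stay separate entries", {
  rec <- data.frame(
    name = "drugS",
    log_papp_exp = c(-4.8, -4.5, -4.9),
    stirring_rpm = c(150, 600, NA),
    source = c("s1", "s2", "s3"),
    stringsAsFactors = FALSE
  )
  out <- curate_records(rec)
  expect_equal(nrow(out), 2)  # 150-rpm pool (incl. unreported) + 600 rpm
  expect_setequal(out$stirring_rpm, c(150, 600))
  pooled <- out$log_papp_exp[out$stirring_rpm == 150]
  expect_equal(pooled, log10(mean(c(10^-4.8, 10^-4.9))))
})

test_that("curation is idempotent and handles empty input", {
  expect_equal(nrow(curate_records(data.frame())), 0)
  rec <- generate_pseudo_experiment(generate_chemicals(10, 5), 0.2, 6)
  once <- curate_records(rec)
  twice <- curate_records(once)
  expect_equal(twice[c("name", "stirring_rpm", "log_papp_exp")],
               once[c("name", "stirring_rpm", "log_papp_exp")],
               tolerance = 1e-12)
  # all efflux substrates -> empty output, not an error
  allefflux <- data.frame(name = "x", log_papp_exp = -5, efflux_ratio = 4)
  expect_equal(nrow(curate_records(allefflux)), 0)
})

test_that("fit metrics recover identity, offsets and hand-computed cases", {
  m <- fit_metrics(c(-4, -5, -6), c(-4, -5, -6))
  expect_equal(m$rmse, 0)
  expect_equal(m$r2, 1)
  m2 <- fit_metrics(c(-4, -5, -6) + 0.3, c(-4, -5, -6))
  expect_equal(m2$rmse, 0.3)
  expect_equal(m2$r2, 1)
  m3 <- fit_metrics(c(-4, -5, -6), c(-4.5, -5, -5.5))
  expect_equal(m3$rmse, sqrt(mean(c(0.5, 0, 0.5)^2)), tolerance = 1e-12)
  expect_equal(m3$rmse, 0.408, tolerance = 1e-3)
  expect_equal(m3$r2, 1)
  expect_error(fit_metrics(-4, -4), "at least 2")
})

test_that("fit metrics are shift-invariant and rmse is symmetric", {
  set.seed(31)
  a <- rnorm(20, -5, 0.8); b <- a + rnorm(20, 0, 0.4)
  m <- fit_metrics(a, b)
  ms <- fit_metrics(a + 1.7, b + 1.7)
  expect_equal(m$rmse, ms$rmse, tolerance = 1e-12)
  expect_equal(m$r2, ms$r2, tolerance = 1e-12)
  expect_equal(fit_metrics(b, a)$rmse, m$rmse, tolerance = 1e-12)
  # coefficient-of-determination variant penalizes offsets
  off <- fit_metrics(a + 1, a, method = "cod")
  expect_lt(off$r2, 1)
  expect_equal(fit_metrics(a + 1, a)$r2, 1, tolerance = 1e-12)
})

test_that("BLM evaluation excludes sub-50-Da molecules and fits the rest", {
  p <- model_parameters()
  blm <- data.frame(
    name = c("water-like", paste0("c", 1:6)),
    mw = c(18, 80, 150, 250, 320, 410, 500),
    log_khexw = c(-4, -6, -4.5, -3, -1.5, 0.5, 2),
    d_hex = rep(8e-6, 7),
    stringsAsFactors = FALSE
  )
  blm$log_pm_exp <- blm$log_khexw + log10(blm$d_hex) - log10(p$h_hexlike)
  ev <- blm_evaluate(blm, p)
  expect_equal(ev$n, 6)          # the 18-Da molecule is excluded
  expect_false("water-like" %in% ev$per_chemical$name)
  expect_equal(ev$rmse, 0, tolerance = 1e-12)
  expect_equal(ev$r2, 1, tolerance = 1e-12)
  # perturbed observations give a positive rmse of the injected size
  blm$log_pm_exp <- blm$log_pm_exp + c(0, 0.5, -0.5, 0.5, -0.5, 0.5, -0.5)
  expect_equal(blm_evaluate(blm, p)$rmse, 0.5, tolerance = 1e-12)
  expect_error(blm_evaluate(blm[blm$mw < 50, , drop = FALSE], p),
               "MW filter")
})

test_that("dataset evaluation joins, curates and reports per-chemical routes", {
  tbl <- generate_chemicals(40, seed = 41)
  rec <- generate_pseudo_experiment(tbl, noise_sd = 0, seed = 42)
  ev <- evaluate_dataset(tbl, rec)
  expect_equal(ev$rmse, 0, tolerance = 1e-10)
  expect_equal(ev$r2, 1, tolerance = 1e-10)
  expect_true(all(c("dominant_route", "cytosolic_main_barrier") %in%
                    names(ev$per_chemical)))
  # exclusion list removes chemicals before fitting
  ev2 <- evaluate_dataset(tbl, rec, exclude = tbl$name[1:5])
  expect_equal(ev2$n, ev$n - 5)
  expect_error(evaluate_dataset(tbl, transform(rec, name = "nope")),
               "no overlap")
})

test_that("shipped synthetic fixtures load and evaluate", {
  dfile <- system.file("extdata", "synthetic_chemicals.csv",
                       package = "pappnet")
  efile <- system.file("extdata", "synthetic_experiments.csv",
                       package = "pappnet")
  bfile <- system.file("extdata", "synthetic_blm.csv", package = "pappnet")
  ev <- evaluate_dataset(read_descriptors(dfile), read_experiments(efile))
  expect_equal(ev$n, 12)
  expect_lt(ev$rmse, 1)
  blm <- blm_evaluate(read_blm_table(bfile))
  expect_gt(blm$r2, 0.5)
})
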