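mk_rate <- function(value, se = 0, process = "AO", below = FALSE) {
  rate_estimate(value, se, p_slope = if (below) 0.5 else 1e-6,
                below_detection = below, process = process)
}

test_that("n2o_yield is the percent ratio with delta-method error", {
  y <- n2o_yield(mk_rate(0.05, process = "N2O-NH4"), mk_rate(100, process = "AO"))
  expect_equal(y$yield_pct, 0.05)
  expect_true(y$defined)
  expect_equal(n2o_yield(mk_rate(0), mk_rate(10))$yield_pct, 0)
  # undefined (missing, not zero) for flagged or non-positive denominator
  expect_false(n2o_yield(mk_rate(1), mk_rate(10, below = TRUE))$defined)
  expect_true(is.na(n2o_yield(mk_rate(1), mk_rate(0))$yield_pct))
  # unit invariance under joint rescaling
  y1 <- n2o_yield(mk_rate(2, 0.2), mk_rate(900, 50))
  y2 <- n2o_yield(mk_rate(2000, 200), mk_rate(9e5, 5e4))
  expect_equal(y1$yield_pct, y2$yield_pct)
  expect_equal(y1$se_pct, y2$se_pct)
  # propagation closed form
  expect_equal(y1$se_pct,
               100 * sqrt(0.2^2 / 900^2 + 2^2 * 50^2 / 900^4), tolerance = 1e-12)
})

test_that("fractional contributions sum to 1 with delta sd matching Monte-Carlo", {
  fc <- fractional_contributions(c("N2O-NH4" = 1, "N2O-NO2" = 1, "N2O-NO3" = 2))
  expect_equal(fc$f_ao, 0.25)
  expect_equal(fc$f_red, 0.75)
  expect_equal(fractional_contributions(
    c("N2O-NH4" = 3, "N2O-NO2" = 0, "N2O-NO3" = 0))$f_ao, 1)
  # f_ao + f_red = 1 exactly wherever defined; both within [0,1]
  set.seed(5)
  for (i in 1:25) {
    r <- runif(3, 0, 10)
    fc <- fractional_contributions(setNames(r, c("N2O-NH4", "N2O-NO2", "N2O-NO3")),
                                   se = runif(3, 0, 1))
    expect_equal(fc$f_ao + fc$f_red, 1, tolerance = 1e-15)
    expect_true(fc$f_ao >= 0 && fc$f_ao <= 1)
  }
  # degenerate total
  fc0 <- fractional_contributions(c("N2O-NH4" = 0, "N2O-NO2" = 0, "N2O-NO3" = 0))
  expect_true(is.na(fc0$f_ao))
  # delta sd vs 10^4-draw Monte-Carlo at <20% relative errors
  r <- c("N2O-NH4" = 4, "N2O-NO2" = 2, "N2O-NO3" = 6)
  s <- 0.15 * r
  d <- fractional_contributions(r, se = s, method = "delta")
  set.seed(99)
  m <- fractional_contributions(r, se = s, method = "mc", n_draws = 1e4)
  expect_lt(abs(d$sd_f_ao - m$sd_f_ao) / m$sd_f_ao, 0.10)
})

test_that("PN normalization divides by mass and skips zero-PN classes", {
  f1 <- size_fraction_set("0.2-3", c(AO = 10), pn_mass = 5)
  f2 <- size_fraction_set("3-20", c(AO = 10), pn_mass = 10)
  out <- pn_normalized_rates(list(f1, f2))
  expect_equal(out$rate_per_pn, c(2, 1))   # doubling PN halves normalized rate
  f3 <- size_fraction_set("20-160", c(AO = 1), pn_mass = 0)
  expect_warning(out3 <- pn_normalized_rates(list(f1, f3)), "skipped")
  expect_equal(nrow(out3), 1)
})

test_that("size spectrum with per-PN reductive enrichment reproduces ordering", {
  # construct a spectrum where large particles have 3x the per-PN reductive
  # rate: the normalized ordering must reflect it even though absolute rates
  # peak on the (mass-dominant) fine particles
  pn <- c(8, 4, 1)                         # fine particles dominate mass
  per_pn_red <- c(0.5, 0.8, 1.5)           # rises with size (3x overall)
  frs <- lapply(1:3, function(i) {
    size_fraction_set(c("0.2-3", "3-20", "20-160")[i],
                      c("N2O-NO3" = per_pn_red[i] * pn[i]), pn_mass = pn[i])
  })
  out <- pn_normalized_rates(frs)
  expect_true(all(diff(out$rate_per_pn) > 0))
  expect_gt(which.max(out$rate), 0)        # absolute peak need not be large size
})

test_that("nir:amoA ratio handles components and undefined denominator", {
  fr <- size_fraction_set("3-20", c(AO = 1), 1,
                          gene_copies = c(amoA_archaeal = 50, amoA_bacterial = 50,
                                          nirS = 60, nirK = 40))
  expect_equal(nir_amoa_ratio(fr), 1.0)
  fr2 <- size_fraction_set("3-20", c(AO = 1), 1,
                           gene_copies = c(amoA_archaeal = 25, amoA_bacterial = 25,
                                           nirS = 100, nirK = 0))
  expect_equal(nir_amoa_ratio(fr2), 2.0)
  fr0 <- size_fraction_set("3-20", c(AO = 1), 1,
                           gene_copies = c(amoA_archaeal = 0, amoA_bacterial = 0,
                                           nirS = 10, nirK = 0))
  expect_message(out <- nir_amoa_ratio(fr0), "undefined")
  expect_true(is.na(out))
})

test_that("nir:amoA correlates with reductive fraction in a constructed spectrum", {
  # 12 synthetic fractions where both the gene ratio and the reductive share
  # increase along the size spectrum (with mild noise)
  set.seed(21)
  ratio <- seq(0.5, 4, length.out = 12) * exp(rnorm(12, 0, 0.1))
  f_red <- plogis(seq(-1, 1.5, length.out = 12) + rnorm(12, 0, 0.2))
  ct <- cor.test(ratio, f_red)
  expect_gt(unname(ct$estimate), 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("pearson_screen masks by p-value and handles degenerate columns", {
  x <- data.frame(a = 1:10)
  y <- data.frame(b = 2 * (1:10), c = 10:1, d = rep(1, 10))
  out <- pearson_screen(x, y)
  expect_equal(out$r["a", "b"], 1)
  expect_equal(out$r["a", "c"], -1)
  expect_false(is.na(out$r_masked["a", "b"]))
  expect_true(is.na(out$r["a", "d"]))      # constant column undefined
  expect_true(is.na(out$r_masked["a", "d"]))
  # non-significant cell is masked but keeps its r
  set.seed(8)
  x2 <- data.frame(a = rnorm(10))
  y2 <- data.frame(b = rnorm(10))
  o2 <- pearson_screen(x2, y2)
  if (o2$p["a", "b"] >= 0.05) expect_true(is.na(o2$r_masked["a", "b"]))
  # pairwise-complete handling
  x3 <- data.frame(a = c(1:9, NA))
  o3 <- pearson_screen(x3, y)
  expect_equal(o3$n["a", "b"], 9)
})

test_that("t-test comparison matches closed form and degenerate rules", {
  expect_equal(compare_rates_ttest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_lt(compare_rates_ttest(c(1, 1.1, 0.9), c(5, 5.1, 4.9))$p, 0.05)
  # closed-form pooled t for that comparison
  ht <- t.test(c(1, 1.1, 0.9), c(5, 5.1, 4.9), var.equal = TRUE)
  expect_equal(compare_rates_ttest(c(1, 1.1, 0.9), c(5, 5.1, 4.9))$p, ht$p.value)
  expect_equal(compare_rates_ttest(c(2, 2), c(2, 2))$p, 1)
  expect_equal(compare_rates_ttest(c(2, 2), c(3, 3))$p, 0)
  expect_error(compare_rates_ttest(1, c(1, 2)), "2 replicates")
})

test_that("depth integration matches closed forms and flux ratio conventions", {
  # uniform rate 1 nmol N L-1 d-1 over 10 m -> 10 umol m-2 d-1
  expect_equal(depth_integrated_production(c(2, 8), c(1, 1), depth_limit = 10), 10)
  # trapezoid equals closed form for a linear profile (no end extension)
  z <- c(0, 5, 10); r <- 2 * z + 1
  expect_equal(depth_integrated_production(z, r, depth_limit = 10),
               0.5 * (1 + 21) * 10)
  # areal production equal to flux -> 100%
  expect_equal(depth_integrated_ratio(c(2, 8), c(1, 1), flux = 10,
                                      depth_limit = 10), 100)
  expect_true(is.na(depth_integrated_ratio(c(2, 8), c(1, 1), flux = -5)))
  expect_error(depth_integrated_production(c(5, 2), c(1, 1)), "increasing")
  # synthetic profile + flux at the field scale: production ~7% of flux
  # (CJE average): uniform 0.14 nmol L-1 d-1 over 15 m against 30 umol m-2 d-1
  expect_equal(depth_integrated_ratio(c(3, 12), c(0.14, 0.14), flux = 30,
                                      depth_limit = 15), 7, tolerance = 1e-9)
})
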