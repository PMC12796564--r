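make_scan_series <- function(abundance,
                             condition = seq_along(abundance)) {
  structure(data.frame(condition = condition, mean_area = abundance,
                       abundance = abundance,
                       in_band = abundance >= 0.7 & abundance <= 1.3),
            class = c("scan_series", "data.frame"))
}

test_that("scan normalisation fixes the reference at 1 and flags the band", {
  cfg <- exact_config()
  tab <- simulate_fet_scan("time", c(5, 10, 20, 30), 2, cfg, seed = 4)
  s <- normalize_scan(tab, "limonene", "time", 20, sample_type = "standard")
  expect_equal(s$abundance[s$condition == 20], 1)
  # rescaling all areas by a common factor leaves the series unchanged
  tab2 <- tab
  tab2$area_target <- tab2$area_target * 37.5
  s2 <- normalize_scan(tab2, "limonene", "time", 20,
                       sample_type = "standard")
  expect_equal(s2$abundance, s$abundance)
  expect_error(normalize_scan(tab, "limonene", "time", 12.5,
                              sample_type = "standard"), "reference")
})

test_that("degradation pushes high-temperature abundance out of band", {
  cfg <- exact_config()
  i <- cfg$species$name == "limonene"
  cfg$species$degradation_onset[i] <- 110
  cfg$species$degradation_rate[i] <- 0.2
  cfg$species$evap_rate_ref[i] <- 0.5   # evaporation complete at 100 degC
  tab <- simulate_fet_scan("temperature", seq(70, 170, 10), 2, cfg,
                           seed = 8, sample_types = "standard")
  s <- normalize_scan(tab, "limonene", "temperature", 100,
                      sample_type = "standard")
  sp <- species_param(cfg, "limonene")
  e <- function(temp) {
    k <- sp$evap_rate_ref * sp$evap_temp_coeff^(temp - 100)
    (1 - exp(-k * 10)) * ifelse(temp > 110, exp(-0.2 * 10), 1)
  }
  expect_equal(s$abundance, e(s$condition) / e(100), tolerance = 1e-9)
  expect_lt(s$abundance[s$condition == 170], 0.7)
  expect_false(s$in_band[s$condition == 170])
})

test_that("plateau onset follows the definition and the evaporation law", {
  expect_equal(find_plateau(make_scan_series(c(1, 1, 1, 1))), 1)
  # first condition from which everything stays within 30% of the final
  expect_equal(find_plateau(make_scan_series(c(0.4, 0.65, 1.0, 1.0, 1.0))), 3)
  expect_equal(find_plateau(make_scan_series(c(0.4, 0.8, 1.0, 1.0, 1.0))), 2)
  expect_true(is.na(find_plateau(make_scan_series(c(1, 0.2, 1, 0.2, 1)))))
  expect_error(find_plateau(make_scan_series(c(1, 1))), "at least 3")

  # simulated time scan: with k in the window where the 20-min point is
  # the first within 30% of the 40-min value, the plateau lands at 20 min
  grid <- c(2.5, 5, 10, 15, 20, 25, 30, 35, 40)
  cfg <- exact_config()
  for (a in c("alpha-pinene", "beta-eudesmol")) {
    k <- species_param(cfg, a)$evap_rate_ref
    frac <- (1 - exp(-k * grid)) / (1 - exp(-k * 40))
    expect_equal(grid[which(frac >= 0.7)[1]], 20)  # closed-form inversion
  }
  tab <- simulate_fet_scan("time", grid, 2, cfg, seed = 4)
  for (a in c("alpha-pinene", "beta-eudesmol")) {
    s <- normalize_scan(tab, a, "time", 20, sample_type = "flower")
    expect_equal(find_plateau(s), 20)
  }
})

test_that("tightening the plateau tolerance never gives an earlier onset", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      ab <- cumsum(stats::runif(8, -0.2, 0.4))
      ab <- ab - min(ab) + 0.1
      s <- make_scan_series(ab / ab[8])
      onsets <- vapply(c(0.5, 0.3, 0.2, 0.1, 0.05), function(tol) {
        p <- find_plateau(s, tol)
        if (is.na(p)) Inf else p
      }, numeric(1))
      expect_true(all(diff(onsets) >= 0, na.rm = TRUE))  # Inf-Inf is NaN
    }
  })
})

test_that("sample-size linearity detects proportionality and saturation", {
  w <- rep(c(2.5, 5, 7.5, 10, 12.5, 15), each = 2)
  exact <- size_linearity(w, 3.2 * w)
  expect_equal(exact$r_squared, 1)
  expect_false(exact$saturation_flag)
  capped <- size_linearity(w, pmin(3.2 * w, 3.2 * 7.5))
  expect_true(capped$saturation_flag)
  expect_equal(capped$linear_up_to, 7.5)
  expect_error(size_linearity(c(1, 1, 2), c(1, 1, 2)), "3 distinct")
  # agrees with an independent OLS on pure noise (slope-zero truth)
  withr::with_seed(31, {
    y <- stats::rnorm(length(w))
    res <- size_linearity(w, y)
    expect_equal(res$r_squared, summary(stats::lm(y ~ w))$r.squared)
    expect_lt(res$r_squared, 0.5)
  })
})

test_that("MHE fit recovers exact geometric depletion to machine precision", {
  f <- mhe_fit(c(1000, 500, 250, 125, 62.5))
  expect_equal(f$slope, log(0.5), tolerance = 1e-12)
  expect_equal(f$q_hat, 0.5, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$total_area, 2000, tolerance = 1e-9)
  # random geometric series
  withr::with_seed(41, {
    for (rep in 1:25) {
      q <- stats::runif(1, 0.05, 0.95)
      a1 <- stats::runif(1, 10, 1e6)
      f <- mhe_fit(a1 * (1 - q)^(0:4))
      expect_equal(f$q_hat, q, tolerance = 1e-9)
      expect_equal(f$r_squared, 1, tolerance = 1e-9)
    }
  })
  flat <- mhe_fit(c(10, 10, 10))
  expect_false(flat$q_valid)
  expect_true(is.na(flat$q_hat))
  expect_error(mhe_fit(c(10, 5)), "at least 3")
  expect_error(mhe_fit(c(10, 0, 5)), "positive")
})

test_that("MHE slope comparison applies the strict 30% criterion", {
  # hand-built fits give exact slopes, so the boundary case is exact
  mk <- function(slope) {
    structure(list(slope = slope, q_valid = TRUE), class = "mhe_fit")
  }
  same <- compare_mhe(mk(-0.5), mk(-0.5))
  expect_equal(same$deviation_percent, 0)
  expect_true(same$pass)
  edge <- compare_mhe(mk(-0.7), mk(-1.0))
  expect_equal(edge$deviation_percent, 30)
  expect_false(edge$pass)   # strict inequality at the boundary
  expect_error(compare_mhe(mhe_fit(c(1, 1, 1)), mk(-0.5)), "negative")
})

test_that("adsorption shifts the flower MHE slope by the closed-form amount", {
  cfg <- exact_config(extraction_fraction = 0.5, adsorption_excess = 0.2)
  std <- simulate_mhe(c(limonene = 1), 5, cfg, seed = 1)
  flo <- simulate_mhe(c(limonene = 1), 5, cfg, seed = 1,
                      sample_type = "flower")
  f_std <- mhe_fit(std$area_target[order(std$injection_index)])
  f_flo <- mhe_fit(flo$area_target[order(flo$injection_index)])
  cmp <- compare_mhe(f_flo, f_std)
  expect_equal(cmp$deviation_percent,
               abs(log(0.4) - log(0.5)) / abs(log(0.5)) * 100,
               tolerance = 1e-9)
  expect_false(cmp$pass)  # about 32.2% > 30%
})

test_that("slope deviation is invariant to the logarithm base", {
  a_s <- 1000 * 0.45^(0:4)
  a_f <- 800 * 0.36^(0:4)
  pkg <- compare_mhe(mhe_fit(a_f), mhe_fit(a_s))$deviation_percent
  s10 <- unname(stats::coef(stats::lm(log10(a_f) ~ I(0:4)))[2])
  t10 <- unname(stats::coef(stats::lm(log10(a_s) ~ I(0:4)))[2])
  expect_equal(pkg, abs(s10 - t10) / abs(t10) * 100, tolerance = 1e-9)
})

test_that("the verification report combines all checks per analyte", {
  cfg <- synthetic_config(panel, noise_rsd = 0.01,
                          suppression_rel_sd = 0)
  grid_t <- c(2.5, 5, 10, 15, 20, 25, 30, 35, 40)
  time_scan <- simulate_fet_scan("time", grid_t, 2, cfg, seed = 11)
  weight_scan <- simulate_fet_scan("weight", c(2.5, 5, 7.5), 2, cfg,
                                   seed = 12, sample_types = "flower")
  mhe_f <- simulate_mhe(NULL, 5, cfg, seed = 13, sample_type = "flower")
  mhe_s <- simulate_mhe(NULL, 5, cfg, seed = 14)
  rep <- verify_fet(time_scan, weight_scan, mhe_f, mhe_s,
                    analytes = c("alpha-pinene", "beta-caryophyllene"))
  expect_equal(nrow(rep), 2)
  expect_true(all(rep$mhe_pass))          # ideal evaporation, no adsorption
  expect_true(all(rep$size_r_squared > 0.99))
  expect_true(all(rep$plateau_time <= 20))
})
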