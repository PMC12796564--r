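test_that("fit_line reproduces exact lines and the DIN quantities", {
  d <- ladder_responses(slope = 2, intercept = 0)
  f <- fit_line(d$x, d$y)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$s_yx, 0, tolerance = 1e-10)
  expect_equal(f$r, 1, tolerance = 1e-12)
  expect_equal(f$n, 33)
  expect_equal(f$x_mean, mean(d$x))
  expect_equal(f$q_x, sum((d$x - mean(d$x))^2))
  expect_error(fit_line(c(1, 2, 3, 4), c(1, 2, 3, 4)), "at least 5")
  expect_error(fit_line(rep(1, 6), 1:6), "at least 5")
})

test_that("fit_line matches the brute-force normal equations", {
  withr::with_seed(51, {
    for (rep in 1:1000) {
      x <- rep(sort(stats::runif(7, 0, 10)), each = 2)
      y <- 0.3 + 1.7 * x + stats::rnorm(length(x), 0, 0.5)
      f <- fit_line(x, y)
      # independent oracle: solve X'X beta = X'y explicitly
      xtx <- matrix(c(length(x), sum(x), sum(x), sum(x^2)), 2)
      beta <- solve(xtx, c(sum(y), sum(x * y)))
      expect_equal(f$intercept, beta[1], tolerance = 1e-9)
      expect_equal(f$slope, beta[2], tolerance = 1e-9)
      resid <- y - beta[1] - beta[2] * x
      expect_equal(f$s_yx, sqrt(sum(resid^2) / (length(x) - 2)),
                   tolerance = 1e-9)
    }
  })
})

test_that("Cochran statistic and degenerate cases behave as defined", {
  groups <- lapply(1:11, function(i) c(-1, 0, 1) * 2 + i)  # equal variances
  res <- cochran_test(groups)
  expect_equal(res$statistic, 1 / 11, tolerance = 1e-12)
  expect_true(res$passed)
  # one dominating variance fails at the 99% level
  groups[[4]] <- c(-100, 0, 100)
  expect_false(cochran_test(groups)$passed)
  # all-zero variances pass trivially with the defined statistic
  flat <- cochran_test(lapply(1:6, function(i) rep(i, 3)))
  expect_true(flat$passed)
  expect_equal(flat$statistic, 1 / 6)
  expect_error(cochran_test(list(1:3)), "at least 2")
  expect_error(cochran_test(list(1:3, 5)), "2 replicates")
  expect_error(cochran_test(list(1:3, 1:4)), "balanced")
})

test_that("Cochran critical value agrees with an independent Monte Carlo", {
  crit <- cochran_critical(11, 2, alpha = 0.01)
  ind <- withr::with_seed(61, {
    c_stat <- replicate(4e4, {
      s2 <- apply(matrix(stats::rnorm(33), nrow = 3), 2, stats::var)
      max(s2) / sum(s2)
    })
    stats::quantile(c_stat, 0.99, names = FALSE)
  })
  expect_equal(crit, ind, tolerance = 0.01)
})

test_that("Mandel test separates straight lines from curvature", {
  d <- ladder_responses(slope = 1.2)
  line <- mandel_test(d$x, d$y)
  expect_equal(line$statistic, 0)
  expect_true(line$passed)
  # an exact parabola is fit perfectly by the quadratic: infinite statistic
  x <- rep(1:6, each = 2)
  par <- mandel_test(x, x^2)
  expect_false(par$passed)
  expect_true(is.infinite(par$statistic))
  expect_error(mandel_test(1:5, 1:5), "at least 6")
  # critical value is the F(1, n-3) upper quantile
  expect_equal(line$critical_value, stats::qf(0.99, 1, 33 - 3))
})

test_that("Mandel flags the saturating response only over the full ladder", {
  cfg <- exact_config()
  cfg$species$saturation_amount[cfg$species$name == "limonene"] <- 2
  resp <- function(levels) {
    vapply(levels, function(a) {
      simulate_injection(c(limonene = a), list(), cfg)$area_target
    }, numeric(1))
  }
  lv <- c(0.050, 0.0750, 0.125, 0.375, 0.500, 1.00, 1.75, 2.50, 5.00,
          7.50, 10.0)
  expect_false(mandel_test(lv, resp(lv))$passed)       # full 11 levels
  expect_true(mandel_test(lv[1:7], resp(lv[1:7]))$passed)  # below the cap
})

test_that("Cochran and Mandel hold their nominal type-I error", {
  # moderate-size null check; the full-scale calibration study lives in
  # the acceptance suite
  n_sim <- 5000
  x <- rep(c(0.05, 0.075, 0.125, 0.375, 0.5, 1, 1.75, 2.5, 5, 7.5, 10),
           each = 3)
  rej <- withr::with_seed(71, {
    cochran_rej <- 0
    mandel_rej <- 0
    for (i in seq_len(n_sim)) {
      y <- 2 * x + stats::rnorm(length(x))
      if (!cochran_test(split(y, x))$passed) cochran_rej <- cochran_rej + 1
      if (!mandel_test(x, y)$passed) mandel_rej <- mandel_rej + 1
    }
    c(cochran_rej, mandel_rej) / n_sim
  })
  expect_equal(rej[1], 0.01, tolerance = 0.6)  # within MC scatter at 5e3
  expect_equal(rej[2], 0.01, tolerance = 0.6)
  expect_lt(rej[1], 0.025)
  expect_lt(rej[2], 0.025)
})

test_that("model selection keeps the entire range for linear truth", {
  d <- ladder_responses(slope = 0.8, intercept = 0.01)
  sel <- select_model(d$x, d$y)
  expect_equal(sel$kind, "entire")
  expect_equal(sel$dropped_top_levels, 0L)
  expect_equal(sel$fits$full$slope, 0.8, tolerance = 1e-9)
  expect_true(sel$cochran$passed)
})

test_that("saturation forces a restricted range dropping the top levels", {
  cfg <- synthetic_config(panel, noise_rsd = 0.01, suppression_rel_sd = 0)
  cfg$species$saturation_amount[cfg$species$name == "fenchone"] <- 6
  lv <- rep(c(0.050, 0.0750, 0.125, 0.375, 0.500, 1.00, 1.75, 2.50,
              5.00, 7.50, 10.0), each = 3)
  resp <- withr::with_seed(81, {
    vapply(lv, function(a) {
      simulate_injection(c(fenchone = a), list(), cfg)$area_target
    }, numeric(1))
  })
  sel <- select_model(lv, resp)
  expect_equal(sel$kind, "restricted")
  expect_equal(sel$dropped_top_levels, 2L)   # 7.50 and 10.0 dropped
  expect_equal(max(sel$fits$full$range), 5.00)
  # and never "entire" whenever the cap sits below the top calibrator
  for (sat in c(4, 8)) {
    cfg$species$saturation_amount[cfg$species$name == "fenchone"] <- sat
    r2 <- withr::with_seed(82, vapply(lv, function(a) {
      simulate_injection(c(fenchone = a), list(), cfg)$area_target
    }, numeric(1)))
    expect_false(select_model(lv, r2)$kind == "entire")
  }
})

test_that("a two-regime response splits at the 1.00 ug boundary", {
  lv <- rep(c(0.050, 0.0750, 0.125, 0.375, 0.500, 1.00, 1.75, 2.50,
              5.00, 7.50, 10.0), each = 3)
  y <- ifelse(lv <= 1, lv, 1 + 0.45 * (lv - 1))
  sel <- select_model(lv, y)
  expect_equal(sel$kind, "split")
  expect_equal(sel$split_point, 1.00)
  expect_equal(sel$fits$low$slope, 1, tolerance = 1e-9)
  expect_equal(sel$fits$high$slope, 0.45, tolerance = 1e-9)
})

test_that("inverse prediction is the identity on noiseless calibrations", {
  lv <- rep(c(0.050, 0.0750, 0.125, 0.375, 0.500, 1.00, 1.75, 2.50,
              5.00, 7.50, 10.0), each = 3)
  models <- list(
    entire = select_model(lv, 0.7 * lv + 0.02),
    split = select_model(lv, ifelse(lv <= 1, lv, 1 + 0.45 * (lv - 1)))
  )
  for (sel in models) {
    for (a in unique(lv)) {
      pred <- predict_amount(sel, predict_response(sel, a))
      expect_equal(pred$amount, a, tolerance = 1e-9)
      expect_false(pred$below_range || pred$above_range)
    }
  }
})

test_that("prediction flags range and transition-zone responses", {
  lv <- rep(c(0.050, 0.0750, 0.125, 0.375, 0.500, 1.00, 1.75, 2.50,
              5.00, 7.50, 10.0), each = 3)
  sel <- select_model(lv, ifelse(lv <= 1, lv, 1 + 0.45 * (lv - 1)))
  boundary_y <- predict_response(sel, 1.00)
  at <- predict_amount(sel, boundary_y)
  expect_true(at$transition_zone)
  expect_equal(at$amount, 1.00, tolerance = 1e-9)  # low range owns it
  hi <- predict_amount(sel, predict_response(sel, 10) * 1.2)
  expect_true(hi$above_range)
  lo <- predict_amount(sel, predict_response(sel, 0.05) * 0.5)
  expect_true(lo$below_range)
  far <- predict_amount(sel, predict_response(sel, 5))
  expect_false(far$transition_zone)
  expect_error(predict_amount(select_model(lv, rep(c(1, 2, 3), 11)),
                              0.5), "admissible|slope")
})

test_that("panel calibration assigns Table-style model kinds per analyte", {
  cfg <- synthetic_config(panel, noise_rsd = 0.02, suppression_rel_sd = 0)
  cal <- simulate_calibration(cfg, panel, n_rep = 3, seed = 91)
  models <- calibrate_panel(cal$peaks, cal$amounts, panel)
  expect_setequal(names(models), panel$analytes$name)
  kinds <- vapply(models, function(m) m$kind, character(1))
  expect_false(any(kinds == "failed"))
  # ratio responses recover the designed amounts through the model
  m <- models[["alpha-pinene"]]
  pred <- predict_amount(m, predict_response(m, 2.5))
  expect_equal(pred$amount, 2.5, tolerance = 1e-9)
})
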