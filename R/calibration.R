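#' Unweighted linear calibration fit
#'
#' Ordinary least squares of response on amount over all replicate points
#' (replicates are pooled, not averaged). Reports the quantities needed by
#' the DIN 32645 limit formulas: residual SD `s_yx = sqrt(RSS / (n - 2))`,
#' mean calibration amount and its centred sum of squares `Q_x`.
#'
#' @param levels Amounts in the vial (ug), one per measured point.
#' @param responses ISTD-normalised responses, same length.
#' @param min_levels Minimum number of distinct calibrator levels.
#' @return A list of class `"calibration_fit"`: `slope`, `intercept`,
#'   `s_yx`, `r` (signed correlation), `n`, `x_mean`, `q_x`, `range`.
#' @export
fit_line <- function(levels, responses, min_levels = 5) {
  stopifnot(length(levels) == length(responses), is.numeric(levels),
            is.numeric(responses))
  if (length(unique(levels)) < min_levels) {
    stop("calibration needs at least ", min_levels, " distinct levels")
  }
  if (stats::var(levels) == 0) stop("zero variance in calibration amounts")
  n <- length(levels)
  fit <- stats::lm.fit(cbind(1, levels), responses)
  rss <- sum(fit$residuals^2)
  structure(list(
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    s_yx = sqrt(rss / (n - 2)),
    r = if (stats::var(responses) == 0) 0 else stats::cor(levels, responses),
    n = n,
    x_mean = mean(levels),
    q_x = sum((levels - mean(levels))^2),
    range = range(levels)
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("calibration fit: y = %.5g + %.5g x, s_yx = %.4g, r = %.5f, n = %d\n",
              x$intercept, x$slope, x$s_yx, x$r, x$n))
  invisible(x)
}

# Predicted response at given amounts.
.fit_predict <- function(fit, x) fit$intercept + fit$slope * x

# Cache of Monte-Carlo Cochran critical values, keyed by (k, nu, alpha).
.fetterp_cache <- new.env(parent = emptyenv())

#' Critical value of Cochran's variance-outlier statistic
#'
#' Upper quantile of `C = max(s_i^2) / sum(s_i^2)` for `k` groups of
#' normal samples with `nu` degrees of freedom each. Printed Cochran
#' tables differ between sources, so the critical value is computed once
#' per design by Monte Carlo from chi-square draws (fixed internal seed)
#' and cached.
#'
#' @param k Number of variance groups.
#' @param nu Degrees of freedom per group (replicates - 1).
#' @param alpha Significance level (upper tail).
#' @param n_draws Monte-Carlo sample size.
#' @return The critical value (scalar).
#' @export
cochran_critical <- function(k, nu, alpha = 0.01, n_draws = 2e5) {
  stopifnot(k >= 2, nu >= 1)
  key <- sprintf("k%d_nu%d_a%g_n%g", k, nu, alpha, n_draws)
  if (!is.null(.fetterp_cache[[key]])) return(.fetterp_cache[[key]])
  crit <- withr::with_seed(190301, {
    s2 <- matrix(stats::rchisq(k * n_draws, df = nu), nrow = k)
    c_stat <- matrixStats_colMaxs(s2) / colSums(s2)
    stats::quantile(c_stat, probs = 1 - alpha, names = FALSE, type = 7)
  })
  .fetterp_cache[[key]] <- crit
  crit
}

# Column maxima without extra dependencies.
matrixStats_colMaxs <- function(m) do.call(pmax, asplit(m, 1))

#' Cochran test for variance homogeneity across calibration levels
#'
#' Tests whether the largest within-level replicate variance is an outlier
#' among all levels: `C = s2_max / sum(s2_i)`, compared to the Monte-Carlo
#' critical value at the 99% significance level. Homogeneous variances
#' justify the unweighted calibration model.
#'
#' @param replicate_groups List of numeric replicate vectors (one per
#'   level) or a matrix with one row per level.
#' @param alpha Significance level (default 0.01, i.e. 99%).
#' @return A list of class `"range_test"`: `statistic`, `critical_value`,
#'   `significance`, `passed`.
#' @export
cochran_test <- function(replicate_groups, alpha = 0.01) {
  if (is.matrix(replicate_groups)) {
    replicate_groups <- asplit(replicate_groups, 1)
  }
  k <- length(replicate_groups)
  if (k < 2) stop("Cochran test needs at least 2 groups")
  sizes <- lengths(replicate_groups)
  if (any(sizes < 2)) stop("every group needs at least 2 replicates")
  if (length(unique(sizes)) != 1) {
    stop("Cochran test requires balanced replicate groups")
  }
  s2 <- vapply(replicate_groups, stats::var, numeric(1))
  if (all(s2 == 0)) {
    # no variance anywhere: homogeneity trivially holds
    stat <- 1 / k
    crit <- cochran_critical(k, sizes[1] - 1, alpha)
    return(structure(list(statistic = stat, critical_value = crit,
                          significance = 1 - alpha, passed = TRUE),
                     class = "range_test"))
  }
  stat <- max(s2) / sum(s2)
  crit <- cochran_critical(k, sizes[1] - 1, alpha)
  structure(list(statistic = stat, critical_value = crit,
                 significance = 1 - alpha, passed = stat <= crit),
            class = "range_test")
}

#' Mandel linearity test
#'
#' Compares the linear calibration fit against a quadratic alternative:
#' `DS2 = (n - 2) s1^2 - (n - 3) s2^2` (the residual sum of squares freed
#' by the quadratic term) is tested as `F = DS2 / s2^2` against
#' `F(1, n - 3)` at the 99% level. A significant statistic means the
#' linear model is inadequate over the tested range.
#'
#' @param levels Amounts (ug), length >= 6.
#' @param responses Responses, same length.
#' @param alpha Significance level.
#' @return A `"range_test"` list: `statistic`, `critical_value`,
#'   `significance`, `passed` (TRUE = linear model adequate).
#' @export
mandel_test <- function(levels, responses, alpha = 0.01) {
  n <- length(levels)
  stopifnot(length(responses) == n)
  if (n < 6) stop("Mandel test needs at least 6 points")
  rss1 <- sum(stats::lm.fit(cbind(1, levels), responses)$residuals^2)
  rss2 <- sum(stats::lm.fit(cbind(1, levels, levels^2),
                            responses)$residuals^2)
  # residual sums at rounding-error scale are exact fits
  num_tol <- 1e-20 * (sum(responses^2) + .Machine$double.xmin)
  if (rss1 <= num_tol) rss1 <- 0
  if (rss2 <= num_tol) rss2 <- 0
  s2_sq <- rss2 / (n - 3)
  ds2 <- max(0, rss1 - rss2)
  crit <- stats::qf(1 - alpha, 1, n - 3)
  stat <- if (s2_sq == 0) {
    if (ds2 > 0) Inf else 0
  } else {
    ds2 / s2_sq
  }
  structure(list(statistic = stat, critical_value = crit,
                 significance = 1 - alpha, passed = stat <= crit),
            class = "range_test")
}

# Admissibility of one candidate range: Mandel passes and |r| > threshold.
.range_ok <- function(x, y, r_threshold, alpha) {
  fit <- fit_line(x, y)
  mandel <- mandel_test(x, y, alpha)
  list(fit = fit, mandel = mandel,
       ok = mandel$passed && abs(fit$r) > r_threshold)
}

#' Select the calibration model for one analyte
#'
#' Codifies the guideline-driven range decisions: (1) keep the entire
#' range when the Mandel test passes and r > 0.99; (2) otherwise drop up
#' to two top calibrators (saturation restriction); (3) otherwise split the
#' range at one of the boundaries used in practice (0.500, 1.00 or 1.75 ug,
#' scaled by the analyte's isomer fraction), chosen to minimise the summed
#' residual variance subject to at least 5 calibrators per side (the
#' boundary level belongs to both sides), the high side again allowed to
#' drop up to two top levels (`split_restricted`).
#'
#' @param levels Amounts (ug) per measured point (replicates pooled).
#' @param responses Responses, same length.
#' @param split_candidates Candidate split boundaries (ug, same scale as
#'   `levels`).
#' @param r_threshold Correlation requirement.
#' @param alpha Significance level for the Mandel test.
#' @param max_drop Maximum number of top levels a restriction may drop.
#' @param min_levels Minimum distinct calibrators per (sub-)range.
#' @return A list of class `"model_selection"`: `kind` (`"entire"`,
#'   `"restricted"`, `"split"`, `"split_restricted"` or `"failed"`),
#'   `fits` (named list; `low`/`high` for split kinds, `full` otherwise),
#'   `split_point`, `dropped_top_levels`, `tests`, and `cochran` (variance
#'   homogeneity over the full replicate set, when balanced).
#' @export
select_model <- function(levels, responses,
                         split_candidates = c(0.500, 1.00, 1.75),
                         r_threshold = 0.99, alpha = 0.01,
                         max_drop = 2, min_levels = 5) {
  stopifnot(length(levels) == length(responses))
  ulev <- sort(unique(levels))
  cochran <- tryCatch({
    groups <- split(responses, factor(levels, levels = ulev))
    if (length(unique(lengths(groups))) == 1 && all(lengths(groups) >= 2)) {
      cochran_test(groups, alpha)
    } else NULL
  }, error = function(e) NULL)

  finish <- function(kind, fits, split_point, dropped, tests) {
    structure(list(kind = kind, fits = fits, split_point = split_point,
                   dropped_top_levels = dropped, tests = tests,
                   cochran = cochran), class = "model_selection")
  }

  # (1) entire range
  entire <- .range_ok(levels, responses, r_threshold, alpha)
  if (entire$ok) {
    return(finish("entire", list(full = entire$fit), NULL, 0L,
                  list(full = entire$mandel)))
  }

  # (2) top-level restriction
  for (drop_n in seq_len(max_drop)) {
    if (length(ulev) - drop_n < min_levels) break
    top <- ulev[length(ulev) - drop_n]
    keep <- levels <= top
    res <- .range_ok(levels[keep], responses[keep], r_threshold, alpha)
    if (res$ok) {
      return(finish("restricted", list(full = res$fit), NULL, drop_n,
                    list(full = res$mandel)))
    }
  }

  # (3) split range, boundaries ordered by summed residual variance
  cands <- split_candidates[vapply(split_candidates, function(b) {
    any(abs(ulev - b) < 1e-9 * max(b, 1))
  }, logical(1))]
  cands <- cands[vapply(cands, function(b) {
    sum(ulev <= b + 1e-12) >= min_levels && sum(ulev >= b - 1e-12) >= min_levels
  }, logical(1))]
  if (length(cands)) {
    resid_var <- vapply(cands, function(b) {
      lo <- fit_line(levels[levels <= b + 1e-12],
                     responses[levels <= b + 1e-12])
      hi <- fit_line(levels[levels >= b - 1e-12],
                     responses[levels >= b - 1e-12])
      lo$s_yx^2 + hi$s_yx^2
    }, numeric(1))
    for (b in cands[order(resid_var)]) {
      lo_keep <- levels <= b + 1e-12
      hi_keep <- levels >= b - 1e-12
      lo <- .range_ok(levels[lo_keep], responses[lo_keep], r_threshold, alpha)
      if (!lo$ok) next
      hi <- .range_ok(levels[hi_keep], responses[hi_keep], r_threshold, alpha)
      if (hi$ok) {
        return(finish("split", list(low = lo$fit, high = hi$fit), b, 0L,
                      list(low = lo$mandel, high = hi$mandel)))
      }
      hi_lev <- sort(unique(levels[hi_keep]))
      for (drop_n in seq_len(max_drop)) {
        if (length(hi_lev) - drop_n < min_levels) break
        top <- hi_lev[length(hi_lev) - drop_n]
        keep <- hi_keep & levels <= top
        hi2 <- .range_ok(levels[keep], responses[keep], r_threshold, alpha)
        if (hi2$ok) {
          return(finish("split_restricted",
                        list(low = lo$fit, high = hi2$fit), b, drop_n,
                        list(low = lo$mandel, high = hi2$mandel)))
        }
      }
    }
  }
  finish("failed", list(), NULL, 0L,
         list(full = entire$mandel, entire_fit = entire$fit))
}

#' @export
print.model_selection <- function(x, ...) {
  cat("calibration model:", x$kind)
  if (!is.null(x$split_point)) cat(", split at", x$split_point, "ug")
  if (x$dropped_top_levels > 0) {
    cat(",", x$dropped_top_levels, "top level(s) dropped")
  }
  cat("\n")
  invisible(x)
}

#' Inverse prediction of the vial amount from a response
#'
#' Inverts the selected calibration: `x = (y - a) / b` using the sub-range
#' whose fitted response interval contains the observation. For split
#' models the boundary level belongs to the low range, and responses
#' within +/-10% of the boundary response are flagged `transition_zone`
#' (values there may carry larger errors). Out-of-range responses are
#' still inverted (with the nearest range) but flagged.
#'
#' @param selection A `"model_selection"` (kind other than `"failed"`).
#' @param response Numeric vector of ISTD-normalised responses.
#' @param transition_width Relative half-width of the transition flag
#'   around the boundary response.
#' @return Data frame with `amount` (ug) and logical flag columns
#'   `below_range`, `above_range`, `transition_zone`.
#' @export
predict_amount <- function(selection, response, transition_width = 0.10) {
  stopifnot(inherits(selection, "model_selection"))
  if (selection$kind == "failed") {
    stop("no admissible calibration model was selected")
  }
  split_kind <- selection$kind %in% c("split", "split_restricted")
  fits <- selection$fits
  for (f in fits) if (f$slope == 0) stop("calibration slope is zero")
  invert <- function(fit, y) (y - fit$intercept) / fit$slope
  if (!split_kind) {
    fit <- fits$full
    y_ends <- sort(.fit_predict(fit, fit$range))
    amount <- invert(fit, response)
    data.frame(amount = amount,
               below_range = response < y_ends[1],
               above_range = response > y_ends[2],
               transition_zone = FALSE)
  } else {
    lo <- fits$low
    hi <- fits$high
    boundary_y <- .fit_predict(lo, selection$split_point)
    use_low <- response <= boundary_y    # boundary belongs to the low range
    amount <- ifelse(use_low, invert(lo, response), invert(hi, response))
    y_lo <- sort(.fit_predict(lo, lo$range))
    y_hi <- sort(.fit_predict(hi, hi$range))
    data.frame(
      amount = amount,
      below_range = response < y_lo[1],
      above_range = response > y_hi[2],
      transition_zone = abs(response - boundary_y) <=
        transition_width * abs(boundary_y)
    )
  }
}

#' Predicted response at a given amount (forward calibration)
#'
#' @param selection A `"model_selection"`.
#' @param amount Amounts (ug); for split models the boundary belongs to
#'   the low range.
#' @return Predicted responses.
#' @export
predict_response <- function(selection, amount) {
  stopifnot(inherits(selection, "model_selection"))
  if (selection$kind == "failed") stop("no admissible calibration model")
  if (selection$kind %in% c("split", "split_restricted")) {
    ifelse(amount <= selection$split_point,
           .fit_predict(selection$fits$low, amount),
           .fit_predict(selection$fits$high, amount))
  } else {
    .fit_predict(selection$fits$full, amount)
  }
}

#' ISTD-normalised response ratios from a peak table
#'
#' For every sample and analyte, the quantification response is the
#' analyte target area divided by the target area of its assigned ISTD
#' alkane in the same injection.
#'
#' @param peaks Peak-table data frame containing analyte and alkane rows.
#' @param panel A `"terpene_panel"`.
#' @return Data frame `sample_id`, `injection_index`, `analyte`, `ratio`.
#' @export
response_ratios <- function(peaks, panel) {
  an <- panel$analytes
  is_alkane <- peaks$analyte %in% panel$alkanes$name
  istd <- peaks[is_alkane, c("sample_id", "injection_index", "analyte",
                             "area_target")]
  names(istd)[3:4] <- c("istd", "istd_area")
  obs <- peaks[!is_alkane & peaks$analyte %in% an$name, , drop = FALSE]
  obs$istd <- an$assigned_istd[match(obs$analyte, an$name)]
  merged <- merge(obs, istd,
                  by = c("sample_id", "injection_index", "istd"),
                  all.x = TRUE)
  missing <- is.na(merged$istd_area)
  if (any(missing)) {
    bad <- unique(merged$istd[missing])
    stop("missing ISTD peak(s) for assigned alkane(s): ",
         paste(bad, collapse = ", "))
  }
  out <- merged[, c("sample_id", "injection_index", "analyte")]
  out$ratio <- merged$area_target / merged$istd_area
  out[order(out$sample_id, out$analyte), , drop = FALSE]
}

#' Calibrate every panel analyte from a calibration peak table
#'
#' Computes ISTD-normalised responses, joins them to the true vial
#' amounts, and runs [select_model()] per analyte with the split-boundary
#' candidates scaled by the analyte's isomer fraction.
#'
#' @param peaks Calibration peak table (e.g. from
#'   [simulate_calibration()]).
#' @param amounts Long data frame `sample_id`, `analyte`, `amount_ug` of
#'   the true purity-adjusted vial amounts.
#' @param panel A `"terpene_panel"`.
#' @param ... Passed to [select_model()].
#' @return Named list of `"model_selection"` objects, one per analyte.
#' @export
calibrate_panel <- function(peaks, amounts, panel, ...) {
  ratios <- response_ratios(peaks, panel)
  merged <- merge(ratios, amounts[, c("sample_id", "analyte", "amount_ug")],
                  by = c("sample_id", "analyte"))
  an <- panel$analytes
  models <- lapply(an$name, function(a) {
    d <- merged[merged$analyte == a, , drop = FALSE]
    frac <- an$isomer_fraction[an$name == a]
    select_model(d$amount_ug, d$ratio,
                 split_candidates = c(0.500, 1.00, 1.75) * frac, ...)
  })
  names(models) <- an$name
  models
}
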