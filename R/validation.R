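#' DIN 32645 analytical limits from a low-range calibration line
#'
#' Calibration-curve method: from the unweighted line over calibrators
#' placed around the expected detection limit (`b`, `s_yx`, `x_mean`,
#' `Q_x`, `n`), the detection limit is
#' `x_LOD = (s_yx / b) t(n-2; alpha) sqrt(1/m + 1/n + x_mean^2 / Q_x)` and
#' the quantification limit solves the fixed-point equation
#' `x_LOQ = k (s_yx / b) t(n-2; alpha) sqrt(1/m + 1/n + (x_LOQ - x_mean)^2 / Q_x)`.
#'
#' @param levels Calibrator amounts (ug) near the expected limit (the
#'   study design used six: 0.001-0.075 ug).
#' @param responses Responses, same length.
#' @param alpha One-sided significance level (standard default 0.01).
#' @param k Relative result uncertainty factor for the quantification
#'   limit (standard default 3).
#' @param m Number of future replicate determinations (default 1).
#' @param tol Relative fixed-point convergence tolerance.
#' @return List with `lod`, `loq` (ug) and the underlying
#'   `"calibration_fit"`.
#' @export
din32645_limits <- function(levels, responses, alpha = 0.01, k = 3, m = 1,
                            tol = 1e-9) {
  fit <- fit_line(levels, responses, min_levels = min(5, length(unique(levels))))
  if (length(unique(levels)) < 6) {
    stop("DIN 32645 calibration-curve method needs at least 6 calibrators")
  }
  if (fit$slope <= 0) stop("calibration slope must be positive")
  t_crit <- stats::qt(1 - alpha, df = fit$n - 2)
  sx0 <- fit$s_yx / fit$slope
  lod <- sx0 * t_crit * sqrt(1 / m + 1 / fit$n + fit$x_mean^2 / fit$q_x)
  if (fit$s_yx == 0) {
    return(list(lod = 0, loq = 0, fit = fit))
  }
  loq <- k * lod
  for (i in 1:1000) {
    new <- k * sx0 * t_crit *
      sqrt(1 / m + 1 / fit$n + (loq - fit$x_mean)^2 / fit$q_x)
    if (abs(new - loq) <= tol * abs(new)) {
      return(list(lod = lod, loq = new, fit = fit))
    }
    loq <- new
  }
  stop("LOQ fixed-point iteration did not converge")
}

#' Accuracy (bias) of QC measurements
#'
#' Relative deviation of the mean measured value from the nominal value,
#' in percent. The acceptance criterion is +/-15% (+/-20% near the limit
#' of quantification).
#'
#' @param measured Measured values (>= 1).
#' @param nominal Nominal (true) value, > 0.
#' @return Bias in percent.
#' @export
bias <- function(measured, nominal) {
  if (length(nominal) != 1 || nominal <= 0) stop("nominal must be a single positive value")
  if (length(measured) < 1) stop("at least one measurement required")
  100 * (mean(measured) - nominal) / nominal
}

#' Intra- and inter-day precision from a days x replicates design
#'
#' Balanced one-way ANOVA with day as the grouping factor (the validation
#' design measured QCs in duplicate on eight days). The within-day mean
#' square estimates the repeatability variance; the between-day variance
#' component is `max(0, (MS_between - MS_within) / n_rep)` and the
#' intermediate (inter-day) precision combines both:
#' `intra = 100 sqrt(MS_w) / mean`,
#' `inter = 100 sqrt(MS_w + s2_between) / mean`.
#'
#' @param values Measured values, or a days x replicates matrix.
#' @param day Day labels (ignored when `values` is a matrix).
#' @return List with `intra_rsd`, `inter_rsd` (percent), `ms_within`,
#'   `s2_between`, `grand_mean`, `n_days`, `n_rep`.
#' @export
precision_anova <- function(values, day = NULL) {
  if (is.matrix(values)) {
    day <- rep(seq_len(nrow(values)), times = ncol(values))
    values <- as.vector(values)
  }
  stopifnot(length(values) == length(day))
  groups <- split(values, day)
  n_days <- length(groups)
  sizes <- lengths(groups)
  if (n_days < 2 || any(sizes < 2)) {
    stop("need at least 2 days with at least 2 replicates each")
  }
  if (length(unique(sizes)) != 1) stop("unbalanced design: equal replicates per day required")
  n_rep <- sizes[[1]]
  grand <- mean(values)
  if (grand <= 0) stop("grand mean must be positive for a relative SD")
  day_means <- vapply(groups, mean, numeric(1))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  ms_within <- ss_within / (n_days * (n_rep - 1))
  ms_between <- n_rep * sum((day_means - grand)^2) / (n_days - 1)
  s2_between <- max(0, (ms_between - ms_within) / n_rep)
  list(intra_rsd = 100 * sqrt(ms_within) / grand,
       inter_rsd = 100 * sqrt(ms_within + s2_between) / grand,
       ms_within = ms_within,
       s2_between = s2_between,
       grand_mean = grand,
       n_days = n_days,
       n_rep = n_rep)
}

#' Spike-recovery check for matrix-induced systematic error
#'
#' Flowers with known baseline content are spiked with standard; the
#' target vial amount is the baseline content scaled to the exact weighed
#' sample (rule of three) plus the spiked amount. Recovery deviations
#' within +/-30% (the QC acceptance interval) show that reduced ISTD
#' areas on flower matrix do not bias quantification.
#'
#' @param flower_baseline Baseline content of the flower, ug/g.
#' @param flower_weight Weighed sample, mg.
#' @param spike_amount Spiked standard amount, ug.
#' @param measured Measured vial amount, ug.
#' @param limit Acceptance limit, percent.
#' @return List with `target` (ug), `deviation_percent`, `pass`.
#' @export
spike_recovery <- function(flower_baseline, flower_weight, spike_amount,
                           measured, limit = 30) {
  stopifnot(flower_baseline >= 0, flower_weight >= 0, spike_amount >= 0,
            measured >= 0)
  target <- flower_baseline * flower_weight / 1000 + spike_amount
  if (target == 0) stop("spike-recovery target is zero")
  dev <- 100 * (measured - target) / target
  list(target = target, deviation_percent = dev, pass = abs(dev) <= limit)
}

#' Assemble a per-analyte validation report
#'
#' Combines DIN 32645 limits with QC bias and intra-/inter-day precision
#' and applies the guideline acceptance bounds: bias within +/-15%
#' (+/-20% near the LOQ, taken as the low QC) and RSDs at most 15%
#' (20% near the LOQ).
#'
#' @param limits Named list (per analyte) of [din32645_limits()] results.
#' @param qc Data frame with columns `analyte`, `qc_level` ("low"/"high"),
#'   `day`, `measured` (amount, ug), `nominal` (amount, ug).
#' @param bias_limit,bias_limit_loq,rsd_limit,rsd_limit_loq Acceptance
#'   bounds in percent; the `_loq` bounds apply to the low QC.
#' @return Data frame of class `"validation_report"`, one row per analyte:
#'   LOD/LOQ, bias and RSDs at both QC levels, and per-criterion pass
#'   flags.
#' @export
validation_report <- function(limits, qc, bias_limit = 15,
                              bias_limit_loq = 20, rsd_limit = 15,
                              rsd_limit_loq = 20) {
  analytes <- unique(qc$analyte)
  rows <- lapply(analytes, function(a) {
    d <- qc[qc$analyte == a, , drop = FALSE]
    one_level <- function(lev) {
      dl <- d[d$qc_level == lev, , drop = FALSE]
      prec <- precision_anova(dl$measured, dl$day)
      list(bias = bias(dl$measured, dl$nominal[1]),
           intra = prec$intra_rsd, inter = prec$inter_rsd)
    }
    lo <- one_level("low")
    hi <- one_level("high")
    lim <- limits[[a]]
    data.frame(
      analyte = a,
      lod = if (is.null(lim)) NA_real_ else lim$lod,
      loq = if (is.null(lim)) NA_real_ else lim$loq,
      bias_low = lo$bias, bias_high = hi$bias,
      intra_rsd_low = lo$intra, intra_rsd_high = hi$intra,
      inter_rsd_low = lo$inter, inter_rsd_high = hi$inter,
      bias_pass = abs(lo$bias) <= bias_limit_loq &
        abs(hi$bias) <= bias_limit,
      precision_pass = lo$intra <= rsd_limit_loq & lo$inter <= rsd_limit_loq &
        hi$intra <= rsd_limit & hi$inter <= rsd_limit,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("validation_report", "data.frame")
  out
}
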