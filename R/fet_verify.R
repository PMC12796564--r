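#' Normalise a verification scan for one analyte
#'
#' Aggregates a scan peak table to one point per condition: the arithmetic
#' mean of replicate target areas, weight-normalised for flower samples
#' (rule of three to a common weight, i.e. area per mg), then divided by
#' the value at the reference condition so the reference point is exactly
#' 1. Points outside the forensic +/-30% band (0.7-1.3) are flagged.
#'
#' @param table Peak-table data frame from [simulate_fet_scan()] or
#'   [read_peak_table()].
#' @param analyte Species name to extract.
#' @param axis `"temperature"`, `"time"` or `"weight"` (selects the
#'   condition column).
#' @param reference_condition Condition whose mean defines abundance 1
#'   (e.g. 100 degC or 20 min).
#' @param sample_type Which sample type to profile.
#' @param band Acceptance band on normalised abundance.
#' @return A data frame of class `"scan_series"` with columns `condition`,
#'   `mean_area`, `abundance`, `in_band`; attributes `axis`,
#'   `reference_condition`, `band`.
#' @export
normalize_scan <- function(table, analyte, axis = c("temperature", "time",
                                                    "weight"),
                           reference_condition, sample_type = "flower",
                           band = c(0.7, 1.3)) {
  axis <- match.arg(axis)
  col <- switch(axis, temperature = "thermostat_temp",
                time = "thermostat_time", weight = "sample_weight")
  rows <- table[table$analyte == analyte & table$sample_type == sample_type, ,
                drop = FALSE]
  if (nrow(rows) == 0) stop("no records for analyte: ", analyte)
  area <- rows$area_target
  if (identical(sample_type, "flower")) {
    area <- area / rows$sample_weight   # rule of three to a common weight
  }
  cond <- rows[[col]]
  agg <- stats::aggregate(list(mean_area = area), list(condition = cond),
                          mean)
  agg <- agg[order(agg$condition), , drop = FALSE]
  ref <- agg$mean_area[agg$condition == reference_condition]
  if (length(ref) != 1L) {
    stop("reference condition ", reference_condition, " not present in scan")
  }
  if (ref == 0) stop("zero area at the reference condition")
  agg$abundance <- agg$mean_area / ref
  agg$in_band <- agg$abundance >= band[1] & agg$abundance <= band[2]
  rownames(agg) <- NULL
  structure(agg, class = c("scan_series", "data.frame"), axis = axis,
            reference_condition = reference_condition, band = band)
}

#' Find the plateau onset of a scan series
#'
#' Returns the smallest condition value from which every later normalised
#' abundance stays within `[1 - tolerance, 1 + tolerance]` times the final
#' grid value, mirroring the visual "constant response" reading with the
#' +/-30% measurement-uncertainty band.
#'
#' @param series A `"scan_series"` (or data frame with `condition` and
#'   `abundance`).
#' @param tolerance Relative band half-width around the final value.
#' @return The plateau-onset condition, or `NA` if the series never
#'   stabilises.
#' @export
find_plateau <- function(series, tolerance = 0.30) {
  stopifnot(tolerance >= 0)
  ab <- series$abundance
  cond <- series$condition
  if (length(ab) < 3) stop("plateau detection needs at least 3 points")
  final <- ab[length(ab)]
  ok <- ab >= final * (1 - tolerance) & ab <= final * (1 + tolerance)
  # smallest index from which all later points are in band; the final
  # point alone is not a plateau (it trivially matches itself)
  from <- which(rev(cumprod(rev(ok))) == 1)
  if (length(from) == 0 || min(from) >= length(ab)) return(NA_real_)
  cond[min(from)]
}

#' Sample-size linearity check
#'
#' Ordinary least squares of area on sample weight. Full evaporation
#' predicts proportional response (r^2 > 0.99 over 2.5-7.5 mg in the
#' study); a drop in r^2 that is cured by removing the largest weight(s)
#' indicates saturation at high sample loads.
#'
#' @param weights Sample weights (mg), at least 3 distinct values.
#' @param areas Peak areas (same length).
#' @param r2_threshold Linearity threshold on r^2.
#' @param max_drop Largest number of top weights to drop when probing for
#'   saturation; default drops as long as 3 distinct weights remain.
#' @return List with `r_squared`, `slope`, `intercept`,
#'   `saturation_flag` (TRUE when the full range fails the threshold but a
#'   top-trimmed range passes) and `linear_up_to` (largest weight of the
#'   passing range, or `NA`).
#' @export
size_linearity <- function(weights, areas, r2_threshold = 0.99,
                           max_drop = NULL) {
  stopifnot(length(weights) == length(areas))
  if (length(unique(weights)) < 3) stop("need at least 3 distinct weights")
  if (is.null(max_drop)) max_drop <- length(unique(weights)) - 3L
  r2_of <- function(w, a) {
    rss <- sum(stats::lm.fit(cbind(1, w), a)$residuals^2)
    tss <- sum((a - mean(a))^2)
    if (tss == 0) 1 else 1 - rss / tss
  }
  fit <- stats::lm(areas ~ weights)
  r2 <- r2_of(weights, areas)
  saturation <- FALSE
  linear_up_to <- if (r2 > r2_threshold) max(weights) else NA_real_
  if (r2 <= r2_threshold) {
    uw <- sort(unique(weights), decreasing = TRUE)
    for (drop_n in seq_len(min(max_drop, length(uw) - 3))) {
      keep <- !(weights %in% uw[seq_len(drop_n)])
      if (length(unique(weights[keep])) < 3) break
      if (r2_of(weights[keep], areas[keep]) > r2_threshold) {
        saturation <- TRUE
        linear_up_to <- max(weights[keep])
        break
      }
    }
  }
  list(r_squared = r2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       saturation_flag = saturation,
       linear_up_to = linear_up_to)
}

#' Fit a multiple-headspace-extraction depletion line
#'
#' Under full evaporation, sequential injections of one vial deplete the
#' analyte geometrically, so log area falls linearly with injection
#' number. The fit is natural-log OLS of area on `injection_index - 1`;
#' the recovered per-injection extraction fraction is
#' `q_hat = 1 - exp(slope)` and the total recoverable area follows from
#' the geometric series as `first_area / (1 - exp(slope))`.
#'
#' @param areas Peak areas ordered by injection index (>= 3, all > 0).
#' @return A list of class `"mhe_fit"`: `slope`, `intercept`, `r_squared`,
#'   `q_hat` (`NA` with `q_valid = FALSE` for non-negative slopes),
#'   `total_area`, `n_points`.
#' @export
mhe_fit <- function(areas) {
  if (length(areas) < 3) stop("MHE fit needs at least 3 injections")
  if (any(areas <= 0)) stop("MHE areas must all be positive")
  x <- seq_along(areas) - 1
  y <- log(areas)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  # a numerically zero slope (constant series) carries no depletion signal
  q_valid <- slope < -1e-12
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    q_hat = if (q_valid) 1 - exp(slope) else NA_real_,
    q_valid = q_valid,
    total_area = if (q_valid) areas[1] / (1 - exp(slope)) else NA_real_,
    n_points = length(areas)
  ), class = "mhe_fit")
}

#' Compare MHE depletion slopes between sample and standard
#'
#' Matrix adsorption slows the apparent depletion of a flower sample
#' relative to a standard solution; the relative slope deviation is the
#' magnitude of the matrix effect. The method accepts deviations below 30%
#' (the forensic QC acceptance interval).
#'
#' @param sample_fit,standard_fit `"mhe_fit"` objects with negative slopes.
#' @param limit Acceptance limit in percent (strict inequality).
#' @return List with `deviation_percent` and `pass`.
#' @export
compare_mhe <- function(sample_fit, standard_fit, limit = 30) {
  stopifnot(inherits(sample_fit, "mhe_fit"),
            inherits(standard_fit, "mhe_fit"))
  if (!isTRUE(sample_fit$q_valid) || !isTRUE(standard_fit$q_valid)) {
    stop("both MHE fits must have negative depletion slopes")
  }
  dev <- abs(sample_fit$slope - standard_fit$slope) /
    abs(standard_fit$slope) * 100
  list(deviation_percent = dev, pass = dev < limit)
}

#' Per-analyte full-evaporation verification report
#'
#' Convenience wrapper running the complete verification workflow on
#' simulated (or imported) scan and MHE tables: time-scan plateau onset,
#' sample-size linearity with saturation probe, and MHE slope comparison
#' between flower and standard.
#'
#' @param time_scan Peak table from a thermostatting-time scan.
#' @param weight_scan Peak table from a sample-size scan (flower).
#' @param mhe_sample,mhe_standard Peak tables from MHE runs of a flower
#'   sample and a standard vial.
#' @param analytes Analyte names to report (default: all in `time_scan`).
#' @param reference_time Reference condition for the time scan (min).
#' @return Data frame, one row per analyte, with plateau onset, r^2,
#'   saturation flag, MHE slopes, deviation and pass flags.
#' @export
verify_fet <- function(time_scan, weight_scan, mhe_sample, mhe_standard,
                       analytes = NULL, reference_time = 20) {
  if (is.null(analytes)) analytes <- unique(time_scan$analyte)
  rows <- lapply(analytes, function(a) {
    ts <- normalize_scan(time_scan, a, "time", reference_time,
                         sample_type = "flower")
    ws <- weight_scan[weight_scan$analyte == a &
                        weight_scan$sample_type == "flower", , drop = FALSE]
    sl <- size_linearity(ws$sample_weight, ws$area_target)
    ms <- mhe_sample[mhe_sample$analyte == a, , drop = FALSE]
    mt <- mhe_standard[mhe_standard$analyte == a, , drop = FALSE]
    fit_s <- mhe_fit(ms$area_target[order(ms$injection_index)])
    fit_t <- mhe_fit(mt$area_target[order(mt$injection_index)])
    cmp <- compare_mhe(fit_s, fit_t)
    data.frame(
      analyte = a,
      plateau_time = find_plateau(ts),
      size_r_squared = sl$r_squared,
      saturation_flag = sl$saturation_flag,
      mhe_slope_sample = fit_s$slope,
      mhe_slope_standard = fit_t$slope,
      mhe_deviation_percent = cmp$deviation_percent,
      mhe_pass = cmp$pass,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
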