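#' Quantify samples from a peak table
#'
#' Converts identified peaks into per-sample terpene contents: the
#' ISTD-normalised response (duplicate injections of a sample averaged) is
#' inverted through the analyte's selected calibration model and scaled by
#' the actual sample weight. Analytical-limit and range flags are carried
#' along: amounts below the LOD/LOQ are flagged (and excluded from profile
#' totals downstream), out-of-range responses are still quantified but
#' flagged.
#'
#' @param peaks Peak table containing analyte and ISTD alkane rows for one
#'   or more samples.
#' @param models Named list of `"model_selection"` objects per analyte
#'   (from [calibrate_panel()]).
#' @param panel A `"terpene_panel"`.
#' @param limits Optional data frame `analyte`, `lod`, `loq` (ug in vial);
#'   defaults to the packaged validation fixture values.
#' @return Data frame of class `"quant_result"`: `sample_id`, `analyte`,
#'   `amount_ug`, `content` (ug/g), `sample_weight`, and logical flags
#'   `below_lod`, `below_loq`, `above_range`, `below_range`,
#'   `transition_zone`.
#' @export
quantify_sample <- function(peaks, models, panel, limits = NULL) {
  if (is.null(limits)) {
    limits <- data.frame(analyte = panel$analytes$name,
                         lod = panel$analytes$lod_ug,
                         loq = panel$analytes$loq_ug,
                         stringsAsFactors = FALSE)
  }
  ratios <- response_ratios(peaks, panel)
  # duplicate injections of one sample averaged before quantification
  agg <- stats::aggregate(list(ratio = ratios$ratio),
                          list(sample_id = ratios$sample_id,
                               analyte = ratios$analyte), mean)
  weights <- peaks[!duplicated(peaks$sample_id),
                   c("sample_id", "sample_weight")]
  rows <- lapply(seq_len(nrow(agg)), function(i) {
    a <- agg$analyte[i]
    model <- models[[a]]
    if (is.null(model) || model$kind == "failed") return(NULL)
    pred <- predict_amount(model, agg$ratio[i])
    w <- weights$sample_weight[weights$sample_id == agg$sample_id[i]][1]
    lim <- limits[limits$analyte == a, , drop = FALSE]
    lod <- if (nrow(lim)) lim$lod[1] else NA_real_
    loq <- if (nrow(lim)) lim$loq[1] else NA_real_
    data.frame(
      sample_id = agg$sample_id[i],
      analyte = a,
      amount_ug = pred$amount,
      content = amount_to_content(pred$amount, w),
      sample_weight = w,
      below_lod = !is.na(lod) & pred$amount < lod,
      below_loq = !is.na(loq) & pred$amount < loq,
      above_range = pred$above_range,
      below_range = pred$below_range,
      transition_zone = pred$transition_zone,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id,
                   match(out$analyte, panel$analytes$name)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("quant_result", "data.frame")
  out
}

#' Verify an above-range quantification by re-weighing
#'
#' Values above the calibration range at the standard 5 mg weight are
#' verified by re-analysing a smaller sample weight (FET allows weight
#' changes without re-calibration). The deviation of the original content
#' from the re-weighed content beyond +30% marks a suspected saturation
#' effect in the extrapolated original value; deviations within +/-30%
#' verify the original result.
#'
#' @param original Quantification at the original (larger) weight: a
#'   one-row `"quant_result"` or a numeric content (ug/g).
#' @param reweighed Quantification at the smaller weight, same analyte and
#'   sample.
#' @param limit Acceptance half-width, percent.
#' @return List with `deviation_percent`, `saturation_suspect`,
#'   `reweigh_verified`.
#' @export
reweigh_check <- function(original, reweighed, limit = 30) {
  val <- function(x) if (is.data.frame(x)) x$content[1] else x[1]
  orig <- val(original)
  rw <- val(reweighed)
  if (is.data.frame(original) && is.data.frame(reweighed) &&
      original$analyte[1] != reweighed$analyte[1]) {
    stop("re-weigh comparison requires the same analyte")
  }
  if (rw == 0) stop("re-weighed content is zero")
  dev <- 100 * (orig - rw) / rw
  list(deviation_percent = dev,
       saturation_suspect = dev > limit,
       reweigh_verified = abs(dev) <= limit)
}

#' Build strain profile summaries from quantification results
#'
#' Assembles the samples x analytes content matrix, per-class sums, total
#' terpene content in weight percent, and the radar-chart subset (analytes
#' detected above a threshold content in at least one sample). Contents
#' flagged below the LOQ enter as zero (conservative totals) unless
#' `include_below_loq` is set.
#'
#' @param results A `"quant_result"` data frame covering one or more
#'   samples.
#' @param panel A `"terpene_panel"` (for compound classes and ordering).
#' @param radar_threshold Detection threshold for the radar subset, ug/g.
#' @param include_below_loq Keep raw below-LOQ values in the matrix and
#'   totals instead of zeroing them.
#' @return A list of class `"terpene_profile"`: `contents` (matrix,
#'   samples x analytes, ug/g), `class_sums` (samples x classes),
#'   `total_wt_percent` (named vector), `radar_analytes` (character),
#'   `long` (tidy data frame with class and share columns).
#' @export
build_profiles <- function(results, panel, radar_threshold = 100,
                           include_below_loq = FALSE) {
  stopifnot(nrow(results) >= 1)
  res <- results
  if (!include_below_loq) {
    res$content[res$below_loq] <- 0
  }
  samples <- unique(res$sample_id)
  analytes <- panel$analytes$name[panel$analytes$name %in% res$analyte]
  contents <- matrix(0, nrow = length(samples), ncol = length(analytes),
                     dimnames = list(samples, analytes))
  idx <- cbind(match(res$sample_id, samples), match(res$analyte, analytes))
  contents[idx] <- res$content
  classes <- factor(
    panel$analytes$compound_class[match(analytes, panel$analytes$name)],
    levels = unique(panel$analytes$compound_class))
  class_sums <- t(apply(contents, 1, function(r) {
    tapply(r, classes, sum, default = 0)
  }))
  total_wt <- rowSums(contents) / 1e4   # ug/g -> wt-%
  radar <- analytes[apply(contents > radar_threshold, 2, any)]
  long <- data.frame(
    sample_id = rep(samples, times = length(analytes)),
    analyte = rep(analytes, each = length(samples)),
    compound_class = rep(classes, each = length(samples)),
    content = as.vector(contents),
    stringsAsFactors = FALSE
  )
  cls_tot <- class_sums[cbind(match(long$sample_id, rownames(class_sums)),
                              match(long$compound_class,
                                    colnames(class_sums)))]
  long$class_share <- ifelse(cls_tot > 0, long$content / cls_tot, 0)
  structure(list(contents = contents, class_sums = class_sums,
                 total_wt_percent = total_wt, radar_analytes = radar,
                 long = long), class = "terpene_profile")
}

#' @export
print.terpene_profile <- function(x, ...) {
  cat("Terpene profiles:", nrow(x$contents), "sample(s),",
      ncol(x$contents), "analytes\n")
  cat("Total terpene content (wt-%):\n")
  print(round(x$total_wt_percent, 3))
  cat("Radar subset (>",
      paste0(attr(x, "radar_threshold", exact = TRUE), ""),
      "ug/g in >= 1 sample):",
      length(x$radar_analytes), "analytes\n")
  invisible(x)
}
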