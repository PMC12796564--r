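#' Retention index from the alkane ladder
#'
#' Linear (temperature-programmed, van den Dool-Kratz style) retention
#' index: `RI = 100 * (n + (rt - rt_n) / (rt_(n+1) - rt_n))` with the
#' bracketing ladder alkanes of carbon numbers n and n+1. Retention times
#' outside the ladder are extrapolated linearly from the nearest alkane
#' pair and flagged.
#'
#' @param rt Retention time(s), minutes (vectorised).
#' @param ladder Alkane ladder data frame with `carbon_number` and
#'   `reference_rt` (at least 2 entries, strictly increasing RT).
#' @return Data frame with `rt`, `lower_carbon`, `upper_carbon`,
#'   `retention_index`, `extrapolated`.
#' @examples
#' panel <- load_panel()
#' retention_index(24.5, panel$alkanes)  # limonene, between C10 and C11
#' @export
retention_index <- function(rt, ladder) {
  stopifnot(is.numeric(rt), nrow(ladder) >= 2)
  ord <- order(ladder$reference_rt)
  rts <- ladder$reference_rt[ord]
  cn <- ladder$carbon_number[ord]
  if (any(diff(rts) <= 0)) stop("degenerate ladder: retention times must be strictly increasing")
  # bracketing pair index; clamp to nearest pair outside the ladder
  i <- findInterval(rt, rts, rightmost.closed = FALSE)
  extrapolated <- rt < rts[1] | rt > rts[length(rts)]
  i <- pmin(pmax(i, 1L), length(rts) - 1L)
  frac <- (rt - rts[i]) / (rts[i + 1L] - rts[i])
  ri <- 100 * (cn[i] + frac * (cn[i + 1L] - cn[i]))
  data.frame(rt = rt, lower_carbon = cn[i], upper_carbon = cn[i + 1L],
             retention_index = ri, extrapolated = extrapolated)
}

#' Confirm peak identity from qualifier-ion ratios
#'
#' A peak is identified only when both qualifier areas are present and the
#' qualifier/target area ratios lie within a relative tolerance of the
#' reference ratios; deviating ratios or missing qualifiers mark a
#' negative finding, as used to reject interfering matrix signals.
#'
#' @param record One peak record (list or one-row data frame with
#'   `area_target`, `area_q1`, `area_q2`).
#' @param reference_ratios Length-2 positive vector: expected q1/target and
#'   q2/target area ratios.
#' @param tolerance Relative tolerance on each ratio (default +/-30%).
#' @return List with `identified` (logical) and `reason`, one of `"ok"`,
#'   `"missing_target"`, `"missing_qualifier"`, `"ratio_deviation"`.
#' @export
qualifier_check <- function(record, reference_ratios, tolerance = 0.30) {
  stopifnot(length(reference_ratios) == 2, all(reference_ratios > 0),
            tolerance >= 0)
  at <- record$area_target
  if (is.null(at) || is.na(at) || at <= 0) {
    return(list(identified = FALSE, reason = "missing_target"))
  }
  q <- c(record$area_q1, record$area_q2)
  if (any(is.na(q)) || any(q <= 0)) {
    return(list(identified = FALSE, reason = "missing_qualifier"))
  }
  ratios <- q / at
  rel_dev <- abs(ratios - reference_ratios) / reference_ratios
  if (all(rel_dev <= tolerance)) {
    list(identified = TRUE, reason = "ok")
  } else {
    list(identified = FALSE, reason = "ratio_deviation")
  }
}

#' Match a retention time to a panel analyte
#'
#' Nearest-neighbour assignment within a retention-time window; ties are
#' broken towards the smaller panel index. Co-eluting panel pairs with the
#' same printed retention time (isoborneol / terpinene-4-ol at 37.8 min)
#' cannot be separated by RT alone and must be resolved by their distinct
#' target masses.
#'
#' @param rt Retention time, minutes (scalar).
#' @param panel A `"terpene_panel"`.
#' @param rt_window Maximum absolute RT deviation, minutes.
#' @return One-row data frame of the matched analyte, or `NULL` when no
#'   panel member lies within the window.
#' @export
match_peak <- function(rt, panel, rt_window = 0.15) {
  stopifnot(rt_window > 0, length(rt) == 1L)
  an <- panel$analytes
  d <- abs(an$reference_rt - rt)
  ok <- which(d <= rt_window)
  if (length(ok) == 0) return(NULL)
  best <- ok[order(d[ok], an$index[ok])][1]
  an[best, , drop = FALSE]
}

#' Annotate a peak table with retention indices and identifications
#'
#' Adds to every record: the retention index from the ladder, the matched
#' panel analyte by retention time, and the qualifier-ratio identification
#' flag (using the configured reference qualifier ratios).
#'
#' @param table Peak-table data frame.
#' @param panel A `"terpene_panel"`.
#' @param reference_ratios Expected qualifier/target ratios.
#' @param tolerance Relative ratio tolerance.
#' @param rt_window RT matching window, minutes.
#' @return The table with columns `retention_index`, `matched_analyte`,
#'   `identified`, `reason` appended.
#' @export
identify_peaks <- function(table, panel, reference_ratios = c(0.6, 0.3),
                           tolerance = 0.30, rt_window = 0.15) {
  ri <- retention_index(table$rt, panel$alkanes)
  table$retention_index <- ri$retention_index
  matched <- character(nrow(table))
  identified <- logical(nrow(table))
  reason <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    m <- match_peak(table$rt[i], panel, rt_window)
    matched[i] <- if (is.null(m)) NA_character_ else m$name
    chk <- qualifier_check(table[i, ], reference_ratios, tolerance)
    identified[i] <- chk$identified && !is.null(m)
    reason[i] <- if (is.null(m)) "no_rt_match" else chk$reason
  }
  table$matched_analyte <- matched
  table$identified <- identified
  table$reason <- reason
  table
}
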