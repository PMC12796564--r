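#' Load the packaged terpene panel and alkane ladder
#'
#' Reads the packaged analyte registry: 45 cannabis terpenes (16
#' monoterpenes, 16 monoterpenoids, 7 sesquiterpenes, 6 sesquiterpenoids)
#' with SIM target/qualifier masses, calibration-mix membership, isomer
#' fractions, reference retention times, assigned internal-standard alkanes
#' and calibration model kinds, together with the n-alkane retention-index
#' ladder (C10-C17) used as internal standard.
#'
#' @param panel_file,ladder_file Paths to the delimited fixture tables.
#'   Defaults are the files shipped with the package.
#' @return A list of class `"terpene_panel"` with elements `analytes`
#'   (data frame, one row per analyte, ordered by `index`) and `alkanes`
#'   (data frame, one row per alkane, ordered by `carbon_number`).
#' @examples
#' panel <- load_panel()
#' table(panel$analytes$compound_class)
#' @export
load_panel <- function(panel_file = system.file("extdata", "terpene_panel.tsv",
                                                package = "fetterp"),
                       ladder_file = system.file("extdata", "alkane_ladder.tsv",
                                                 package = "fetterp")) {
  if (!nzchar(panel_file) || !file.exists(panel_file)) {
    stop("panel fixture not found: ", panel_file)
  }
  if (!nzchar(ladder_file) || !file.exists(ladder_file)) {
    stop("alkane ladder fixture not found: ", ladder_file)
  }
  analytes <- utils::read.delim(panel_file, stringsAsFactors = FALSE)
  alkanes <- utils::read.delim(ladder_file, stringsAsFactors = FALSE)

  required <- c("index", "name", "compound_class", "target_mz",
                "qualifier_mz1", "qualifier_mz2", "calibration_mix",
                "isomer_fraction", "reference_rt", "assigned_istd",
                "model_kind", "split_point", "top_level", "lod_ug", "loq_ug")
  missing <- setdiff(required, names(analytes))
  if (length(missing)) {
    stop("panel fixture is missing field(s): ", paste(missing, collapse = ", "))
  }
  ladder_required <- c("carbon_number", "name", "reference_rt",
                       "vial_amount_ug", "target_mz")
  missing <- setdiff(ladder_required, names(alkanes))
  if (length(missing)) {
    stop("alkane ladder fixture is missing field(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyNA(analytes[required[required != "split_point"]])) {
    bad <- required[vapply(analytes[required], anyNA, logical(1))]
    bad <- setdiff(bad, "split_point")
    if (length(bad)) {
      stop("panel fixture has missing values in field(s): ",
           paste(bad, collapse = ", "))
    }
  }
  analytes <- analytes[order(analytes$index), , drop = FALSE]
  alkanes <- alkanes[order(alkanes$carbon_number), , drop = FALSE]
  rownames(analytes) <- NULL
  rownames(alkanes) <- NULL

  stopifnot(
    all(analytes$isomer_fraction > 0 & analytes$isomer_fraction <= 1),
    all(analytes$reference_rt > 0),
    all(analytes$target_mz != analytes$qualifier_mz1),
    all(analytes$target_mz != analytes$qualifier_mz2),
    !is.unsorted(alkanes$reference_rt, strictly = TRUE)
  )
  structure(list(analytes = analytes, alkanes = alkanes),
            class = "terpene_panel")
}

#' @export
print.terpene_panel <- function(x, ...) {
  cat(sprintf("Terpene panel: %d analytes; %d alkane ISTDs (C%d-C%d)\n",
              nrow(x$analytes), nrow(x$alkanes),
              min(x$alkanes$carbon_number), max(x$alkanes$carbon_number)))
  print(table(x$analytes$compound_class))
  invisible(x)
}

#' Assign the internal-standard alkane for a retention time
#'
#' Applies the rule used for novel analytes: the internal standard is the
#' alkane that elutes closest before (or exactly at) the analyte retention
#' time. Analytes eluting before the first ladder alkane fall back to that
#' first alkane. For panel members the packaged `assigned_istd` fixture
#' value is authoritative; this rule serves analytes outside the panel.
#'
#' @param analyte_rt Retention time in minutes (vectorised).
#' @param ladder Alkane ladder data frame (`alkanes` element of
#'   [load_panel()]), with `name` and `reference_rt` columns.
#' @return Character vector of alkane names.
#' @export
assign_istd <- function(analyte_rt, ladder) {
  if (is.null(ladder) || nrow(ladder) == 0L) stop("alkane ladder is empty")
  stopifnot(is.numeric(analyte_rt))
  ord <- order(ladder$reference_rt)
  rts <- ladder$reference_rt[ord]
  nms <- ladder$name[ord]
  idx <- findInterval(analyte_rt, rts)   # latest alkane with rt <= analyte_rt
  idx[idx == 0L] <- 1L                   # pre-ladder fallback: first alkane
  nms[idx]
}

#' Convert an absolute vial amount to a sample content
#'
#' FET methods are calibrated to the absolute amount of analyte in the
#' vial; content in the flower is the derived view
#' `content = amount / (sample_weight / 1000)` (micrograms per gram).
#'
#' @param amount Amount in the vial, micrograms (vectorised).
#' @param sample_weight Sample weight in milligrams (vectorised).
#' @return Content in micrograms per gram.
#' @seealso [content_to_amount()] for the exact inverse.
#' @export
amount_to_content <- function(amount, sample_weight) {
  stopifnot(is.numeric(amount), is.numeric(sample_weight))
  if (any(sample_weight <= 0)) stop("sample_weight must be positive")
  amount / (sample_weight / 1000)
}

#' @rdname amount_to_content
#' @param content Content in micrograms per gram.
#' @export
content_to_amount <- function(content, sample_weight) {
  stopifnot(is.numeric(content), is.numeric(sample_weight))
  if (any(sample_weight <= 0)) stop("sample_weight must be positive")
  content * (sample_weight / 1000)
}

#' Eleven-level calibration ladder (amounts in the vial, micrograms)
#'
#' The nominal design covers 0.050-10.0 ug in the vial (10-2000 ug/g at the
#' 5 mg reference sample weight), with QC levels at 0.0625 and 3.75 ug.
#' @keywords internal
.cal_levels <- function() {
  c(0.050, 0.0750, 0.125, 0.375, 0.500, 1.00, 1.75, 2.50, 5.00, 7.50, 10.0)
}

#' Build the calibration design for one panel analyte
#'
#' Returns the 11-level nominal ladder plus low/high QC levels and the
#' purity-adjusted levels: reference substances supplied as defined isomer
#' mixtures (cis/trans-beta-ocimene, beta-cedrene) contribute only their
#' certified isomer fraction, so the actual calibrated amount is
#' `nominal * isomer_fraction`.
#'
#' @param analyte A single analyte: either a one-row data frame from the
#'   panel's `analytes` table, or an analyte name looked up in `panel`.
#' @param panel A `"terpene_panel"` (needed only when `analyte` is a name).
#' @return A list of class `"calibration_design"` with `nominal_levels`,
#'   `qc_low`, `qc_high`, `adjusted_levels`, `adjusted_qc_low`,
#'   `adjusted_qc_high`, `isomer_fraction` and `sample_weight_ref` (mg).
#' @examples
#' panel <- load_panel()
#' build_calibration_design("cis-beta-ocimene", panel)$adjusted_levels[1]
#' @export
build_calibration_design <- function(analyte, panel = NULL) {
  if (is.character(analyte)) {
    if (is.null(panel)) stop("panel required to look up analyte by name")
    row <- panel$analytes[panel$analytes$name == analyte, , drop = FALSE]
    if (nrow(row) != 1L) stop("analyte not in panel: ", analyte)
    analyte <- row
  }
  frac <- analyte$isomer_fraction
  stopifnot(is.numeric(frac), length(frac) == 1L, frac > 0, frac <= 1)
  nominal <- .cal_levels()
  structure(list(
    analyte = analyte$name,
    nominal_levels = nominal,
    qc_low = 0.0625,
    qc_high = 3.75,
    isomer_fraction = frac,
    adjusted_levels = nominal * frac,
    adjusted_qc_low = 0.0625 * frac,
    adjusted_qc_high = 3.75 * frac,
    sample_weight_ref = 5
  ), class = "calibration_design")
}
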