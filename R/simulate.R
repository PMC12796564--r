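#' Default per-class simulator parameters
#'
#' Evaporation and degradation defaults are package defaults chosen so the
#' qualitative behaviour of FET sampling holds on the study grids: at
#' 100 degC the time scan plateaus at 20 min for every class, the
#' optimum-temperature ordering follows boiling class (monoterpenes peak at
#' lower thermostatting temperatures than sesquiterpenoids), and thermal
#' degradation sets in sharply above a class-specific onset. They are
#' illustrative, not measured constants.
#' @keywords internal
.class_defaults <- function() {
  data.frame(
    compound_class = c("monoterpene", "monoterpenoid", "sesquiterpene",
                       "sesquiterpenoid", "alkane"),
    evap_rate_ref = c(0.070, 0.060, 0.055, 0.045, 0.060),   # 1/min at 100 degC
    evap_temp_coeff = c(1.12, 1.10, 1.09, 1.08, 1.09),       # per degC
    degradation_onset = c(105, 115, 125, 135, 140),          # degC
    degradation_rate = c(0.18, 0.15, 0.13, 0.11, 0.08),      # 1/min above onset
    saturation_amount = c(20, 18, 15, 15, Inf),              # ug in vial
    stringsAsFactors = FALSE
  )
}

#' Default flower terpene contents (ug/g) used by the generator
#'
#' A realistic single-strain profile: a few dominant monoterpenes and
#' sesquiterpenes above 1000 ug/g, mid-range terpenoids, traces, and a set
#' of panel members absent from flower material. Totals about 1.0 wt-%.
#' @keywords internal
.default_flower_content <- function(analytes) {
  profile <- c(
    "alpha-pinene" = 1200, "camphene" = 150, "sabinene" = 8,
    "beta-myrcene" = 1800, "beta-pinene" = 350, "alpha-phellandrene" = 40,
    "3-carene" = 30, "alpha-terpinene" = 60, "cis-beta-ocimene" = 9,
    "m-cymene" = 0, "limonene" = 1600, "p-cymene" = 25,
    "trans-beta-ocimene" = 80, "eucalyptol" = 35, "o-cymene" = 0,
    "gamma-terpinene" = 45, "terpinolene" = 900,
    "trans-sabinene-hydrate" = 45, "linalool" = 300, "fenchone" = 60,
    "endo-fenchol" = 120, "isopulegol" = 0, "camphor" = 9,
    "isoborneol" = 8, "terpinene-4-ol" = 70, "menthol" = 0,
    "borneol" = 140, "alpha-terpineol" = 220, "pulegone" = 0,
    "thymol" = 0, "carvacrol" = 0, "geranyl-acetate" = 0,
    "trans-beta-farnesene" = 130, "alpha-cedrene" = 0,
    "beta-caryophyllene" = 1600, "beta-cedrene" = 0,
    "alpha-humulene" = 500, "valencene" = 0, "cis-nerolidol" = 0,
    "selina-3,7-(11)-diene" = 400, "guaiol" = 60,
    "caryophyllene-oxide" = 120, "alpha-cedrol" = 0,
    "alpha-bisabolol" = 90, "beta-eudesmol" = 70
  )
  out <- profile[analytes]
  out[is.na(out)] <- 0
  names(out) <- analytes
  out
}

#' Build a synthetic GC-MS configuration for the panel
#'
#' Assembles the per-species parameter table (analytes plus ISTD alkanes)
#' and global sampling parameters driving [simulate_injection()],
#' [simulate_fet_scan()] and [simulate_mhe()]. The detector response for a
#' species is
#' `area = rf * cap(amount) * E(T, t) * S * q * D(i) * noise` with
#' evaporated-and-surviving fraction
#' `E(T, t) = (1 - exp(-k(T) t)) * exp(-d t [T > onset])`,
#' temperature-scaled evaporation rate `k(T) = k_ref * c^(T - 100)`,
#' per-sample flower matrix suppression `S`, per-injection extraction
#' fraction `q`, multiple-headspace depletion
#' `D(i) = ((1 - q)(1 - adsorption_excess))^(i - 1)` and multiplicative
#' lognormal noise. `cap()` is exactly linear up to `saturation_amount` and
#' compresses the excess smoothly above it (scale `saturation_amount / 2`),
#' emulating detector/vial overload.
#'
#' Flower-matrix suppression means are set per alkane (declining with
#' carbon number down to 0.218 for heptadecane); analytes default to the
#' mean of their assigned alkane and share its per-sample draw, so the
#' analyte/ISTD ratio is matrix-robust, matching the behaviour of the real
#' method.
#'
#' @param panel A `"terpene_panel"` from [load_panel()].
#' @param extraction_fraction Per-injection headspace extraction fraction
#'   `q` in (0, 1).
#' @param adsorption_excess Extra per-injection retention fraction for
#'   flower samples (0 = ideal full evaporation).
#' @param noise_rsd Relative SD of the multiplicative lognormal area noise.
#' @param suppression_rel_sd Relative SD of the per-sample flower
#'   suppression draw.
#' @param response_factor Detector response, area counts per ug.
#' @param qualifier_ratios Reference qualifier/target area ratios (length 2).
#' @param flower_content Named vector of flower contents (ug/g) overriding
#'   the packaged default profile.
#' @param istd_suppression Named vector (by alkane name) overriding the
#'   default suppression means.
#' @return A list of class `"synthetic_config"` with elements `species`
#'   (per-species parameter data frame) and the global scalars. Per-species
#'   parameters can be edited directly in `config$species` before use.
#' @export
synthetic_config <- function(panel = load_panel(),
                             extraction_fraction = 0.3,
                             adsorption_excess = 0,
                             noise_rsd = 0.03,
                             suppression_rel_sd = 0.02,
                             response_factor = 5e6,
                             qualifier_ratios = c(0.6, 0.3),
                             flower_content = NULL,
                             istd_suppression = NULL) {
  stopifnot(extraction_fraction > 0, extraction_fraction < 1,
            adsorption_excess >= 0, adsorption_excess < 1,
            noise_rsd >= 0, suppression_rel_sd >= 0,
            response_factor > 0, length(qualifier_ratios) == 2)
  an <- panel$analytes
  al <- panel$alkanes
  cls <- .class_defaults()

  suppression_default <- c(decane = 1.0, undecane = 0.95, dodecane = 0.90,
                           tridecane = 0.80, tetradecane = 0.65,
                           pentadecane = 0.50, hexadecane = 0.35,
                           heptadecane = 0.218)
  supp <- suppression_default[al$name]
  supp[is.na(supp)] <- 1
  if (!is.null(istd_suppression)) {
    supp[names(istd_suppression)] <- istd_suppression
  }

  content <- .default_flower_content(an$name)
  if (!is.null(flower_content)) content[names(flower_content)] <- flower_content

  species_a <- data.frame(
    name = an$name,
    kind = "analyte",
    compound_class = an$compound_class,
    rt = an$reference_rt,
    suppression_group = an$assigned_istd,
    standard_amount = 1.0 * an$isomer_fraction,  # 10 uL of 100 ug/mL mix
    flower_content = unname(content),
    stringsAsFactors = FALSE
  )
  species_b <- data.frame(
    name = al$name,
    kind = "alkane",
    compound_class = "alkane",
    rt = al$reference_rt,
    suppression_group = al$name,
    standard_amount = al$vial_amount_ug,  # ISTD spiked on every vial
    flower_content = 0,
    stringsAsFactors = FALSE
  )
  species <- rbind(species_a, species_b)
  species <- merge(species, cls, by = "compound_class", sort = FALSE)
  species <- species[order(species$rt), , drop = FALSE]
  species$response_factor <- response_factor
  species$suppression_mean <- unname(supp[species$suppression_group])
  species$q1_ratio <- qualifier_ratios[1]
  species$q2_ratio <- ifelse(species$kind == "alkane",
                             qualifier_ratios[2] / 2, qualifier_ratios[2])
  rownames(species) <- NULL

  structure(list(
    species = species,
    extraction_fraction = extraction_fraction,
    adsorption_excess = adsorption_excess,
    noise_rsd = noise_rsd,
    suppression_rel_sd = suppression_rel_sd,
    ref_temp = 100
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic GC-MS config:", nrow(x$species), "species; q =",
      x$extraction_fraction, "; noise RSD =", x$noise_rsd, "\n")
  invisible(x)
}

# Evaporated-and-surviving fraction E(T, t); closed form shared with tests.
.evap_survive <- function(temp, time, evap_rate_ref, evap_temp_coeff,
                          degradation_onset, degradation_rate,
                          ref_temp = 100) {
  k <- evap_rate_ref * evap_temp_coeff^(temp - ref_temp)
  evap <- 1 - exp(-k * time)
  deg <- ifelse(temp > degradation_onset,
                exp(-pmax(0, degradation_rate * time)), 1)
  evap * deg
}

# Shifted soft cap: linear up to `sat`, smooth compression of the excess.
.soft_cap <- function(amount, sat) {
  ifelse(is.finite(sat) & amount > sat,
         sat + (sat / 2) * (1 - exp(-(amount - sat) / (sat / 2))),
         amount)
}

# Multiplicative lognormal noise factors with mean 1.
.noise_factor <- function(n, rsd) {
  if (rsd <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rsd^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# Per-sample suppression draw, one deviate per alkane group (consumes RNG).
.draw_suppression <- function(config, sample_type) {
  groups <- unique(config$species$suppression_group)
  if (!identical(sample_type, "flower")) {
    return(stats::setNames(rep(1, length(groups)), groups))
  }
  dev <- .noise_factor(length(groups), config$suppression_rel_sd)
  stats::setNames(dev, groups)
}

# Core area model for one injection of one vial. `suppression` is the
# named per-group deviate from .draw_suppression(); consumes RNG for noise.
.injection_areas <- function(amounts, meta, config, suppression) {
  sp <- config$species
  unknown <- setdiff(names(amounts), sp$name)
  if (length(unknown)) {
    stop("unknown analyte name(s): ", paste(unknown, collapse = ", "))
  }
  sp <- sp[match(names(amounts), sp$name), , drop = FALSE]
  e <- .evap_survive(meta$thermostat_temp, meta$thermostat_time,
                     sp$evap_rate_ref, sp$evap_temp_coeff,
                     sp$degradation_onset, sp$degradation_rate,
                     config$ref_temp)
  s <- if (identical(meta$sample_type, "flower")) {
    pmin(1, sp$suppression_mean * suppression[sp$suppression_group])
  } else rep(1, nrow(sp))
  q <- config$extraction_fraction
  retain <- 1 - q
  if (identical(meta$sample_type, "flower")) {
    retain <- retain * (1 - config$adsorption_excess)
  }
  depl <- retain^(meta$injection_index - 1)
  lin <- sp$response_factor * .soft_cap(amounts, sp$saturation_amount) *
    e * s * q * depl
  n <- length(lin)
  data.frame(
    sample_id = meta$sample_id,
    analyte = sp$name,
    rt = sp$rt,
    area_target = lin * .noise_factor(n, config$noise_rsd),
    area_q1 = lin * sp$q1_ratio * .noise_factor(n, config$noise_rsd),
    area_q2 = lin * sp$q2_ratio * .noise_factor(n, config$noise_rsd),
    sample_weight = meta$sample_weight,
    thermostat_temp = meta$thermostat_temp,
    thermostat_time = meta$thermostat_time,
    injection_index = meta$injection_index,
    sample_type = meta$sample_type,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

.default_meta <- function(meta = list()) {
  base <- list(sample_id = "sample1", sample_weight = 5,
               thermostat_temp = 100, thermostat_time = 20,
               injection_index = 1L, sample_type = "standard")
  base[names(meta)] <- meta
  stopifnot(base$injection_index >= 1, base$sample_weight > 0,
            base$sample_type %in% c("standard", "flower"))
  base
}

#' Simulate one headspace injection
#'
#' Generates the peak records for a single FET injection of one vial, using
#' the forward model described in [synthetic_config()]. Areas are zero-mean
#' unbiased under the lognormal noise (noise factors have mean 1).
#'
#' @param amounts Named numeric vector: absolute amount (ug) of each
#'   species in the vial. Names must be panel analyte or alkane names.
#' @param meta List overriding injection metadata: `sample_id`,
#'   `sample_weight` (mg), `thermostat_temp` (degC), `thermostat_time`
#'   (min), `injection_index`, `sample_type` ("standard" or "flower").
#' @param config A `"synthetic_config"`.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   stream so the function can be composed inside larger seeded designs.
#' @return Data frame of peak records (one row per species).
#' @export
simulate_injection <- function(amounts, meta = list(), config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"), all(amounts >= 0))
  meta <- .default_meta(meta)
  run <- function() {
    supp <- .draw_suppression(config, meta$sample_type)
    .injection_areas(amounts, meta, config, supp)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Standard-vial amounts: 10 uL of 100 ug/mL mix plus the ISTD spike.
.standard_amounts <- function(config) {
  stats::setNames(config$species$standard_amount, config$species$name)
}

# Flower-vial amounts at a given weight plus the ISTD spike.
.flower_amounts <- function(config, weight) {
  sp <- config$species
  amt <- ifelse(sp$kind == "alkane", sp$standard_amount,
                sp$flower_content * weight / 1000)
  stats::setNames(amt, sp$name)
}

#' Simulate a full-evaporation verification scan
#'
#' Reproduces the scan designs used to verify full evaporation: a
#' thermostatting-temperature scan (10 min holds), a thermostatting-time
#' scan (at 100 degC) or a sample-size scan (at 100 degC / 20 min), each
#' run for both a standard vial and a flower vial with replicates.
#'
#' @param axis One of `"temperature"`, `"time"`, `"weight"`.
#' @param grid Sorted vector of conditions (degC, min or mg).
#' @param n_rep Replicates per condition (the study design used n = 2).
#' @param config A `"synthetic_config"`.
#' @param seed Integer seed (or `NULL` for the ambient RNG stream).
#' @param sample_types Which sample types to include.
#' @return A peak-table data frame covering grid x replicates x types.
#' @export
simulate_fet_scan <- function(axis = c("temperature", "time", "weight"),
                              grid, n_rep = 2, config, seed = NULL,
                              sample_types = c("standard", "flower")) {
  axis <- match.arg(axis)
  if (length(grid) == 0) stop("empty condition grid")
  stopifnot(!is.unsorted(grid), n_rep >= 1,
            inherits(config, "synthetic_config"))
  run <- function() {
    out <- vector("list", length(grid) * n_rep * length(sample_types))
    j <- 0L
    for (type in sample_types) {
      for (cond in grid) {
        for (rep_i in seq_len(n_rep)) {
          meta <- list(
            sample_id = sprintf("%s_%s%g_r%d", type, axis, cond, rep_i),
            sample_type = type,
            thermostat_temp = if (axis == "temperature") cond else 100,
            thermostat_time = switch(axis, temperature = 10, time = cond,
                                     weight = 20),
            sample_weight = if (axis == "weight" && type == "flower") cond
                            else 5
          )
          amounts <- if (type == "flower") {
            .flower_amounts(config, meta$sample_weight)
          } else {
            .standard_amounts(config)
          }
          j <- j + 1L
          out[[j]] <- simulate_injection(amounts, meta, config)
        }
      }
    }
    do.call(rbind, out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a multiple headspace extraction series
#'
#' Repeatedly injects a single vial: areas deplete geometrically with the
#' per-injection extraction fraction `q`; flower vials are additionally
#' attenuated by `adsorption_excess` per injection. The flower matrix
#' suppression factor is drawn once for the vial and held across
#' injections.
#'
#' @param amounts Named species amounts in the vial (ug); defaults to the
#'   standard mix or the flower profile depending on `sample_type`.
#' @param n_injections Number of sequential injections (>= 2; the study
#'   design used 5).
#' @param config A `"synthetic_config"`.
#' @param seed Integer seed (or `NULL`).
#' @param sample_type `"standard"` or `"flower"`.
#' @param meta Extra metadata overrides (e.g. `sample_id`).
#' @return Peak-table data frame with `injection_index` 1..n per species.
#' @export
simulate_mhe <- function(amounts = NULL, n_injections = 5, config,
                         seed = NULL, sample_type = "standard",
                         meta = list()) {
  if (n_injections < 2) stop("MHE needs at least 2 injections")
  stopifnot(inherits(config, "synthetic_config"))
  meta$sample_type <- sample_type
  meta0 <- .default_meta(meta)
  if (is.null(amounts)) {
    amounts <- if (sample_type == "flower") {
      .flower_amounts(config, meta0$sample_weight)
    } else {
      .standard_amounts(config)
    }
  }
  run <- function() {
    supp <- .draw_suppression(config, sample_type)
    out <- lapply(seq_len(n_injections), function(i) {
      m <- meta0
      m$injection_index <- i
      .injection_areas(amounts, m, config, supp)
    })
    do.call(rbind, out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a replicated calibration series over the 11-level ladder
#'
#' One standard vial per level and replicate, each carrying every analyte
#' at its purity-adjusted amount plus the ISTD spike, measured under final
#' method conditions (100 degC, 20 min).
#'
#' @param config A `"synthetic_config"`.
#' @param panel The panel the design is built from.
#' @param n_rep Replicate measurements per level (the guideline-driven
#'   design uses 3).
#' @param levels Nominal vial amounts (ug); defaults to the 11-level ladder.
#' @param seed Integer seed (or `NULL`).
#' @return List with `peaks` (peak table) and `amounts` (long data frame
#'   `sample_id`, `analyte`, `amount_ug`, `nominal_ug`, `replicate` of the
#'   true purity-adjusted amounts in each vial).
#' @export
simulate_calibration <- function(config, panel = load_panel(), n_rep = 3,
                                 levels = .cal_levels(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"), n_rep >= 1)
  an <- panel$analytes
  run <- function() {
    peaks <- vector("list", length(levels) * n_rep)
    amounts <- vector("list", length(levels) * n_rep)
    j <- 0L
    for (li in seq_along(levels)) {
      for (rep_i in seq_len(n_rep)) {
        id <- sprintf("cal_L%02d_r%d", li, rep_i)
        amt_an <- stats::setNames(levels[li] * an$isomer_fraction, an$name)
        amt_al <- stats::setNames(panel$alkanes$vial_amount_ug,
                                  panel$alkanes$name)
        meta <- list(sample_id = id, sample_type = "standard")
        j <- j + 1L
        peaks[[j]] <- simulate_injection(c(amt_an, amt_al), meta, config)
        amounts[[j]] <- data.frame(sample_id = id, analyte = an$name,
                                   amount_ug = unname(amt_an),
                                   nominal_ug = levels[li],
                                   replicate = rep_i,
                                   stringsAsFactors = FALSE)
      }
    }
    list(peaks = do.call(rbind, peaks), amounts = do.call(rbind, amounts))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
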