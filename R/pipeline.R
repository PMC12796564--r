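#' Simulate the DIN 32645 low-level calibrator series
#'
#' Six evenly distributed calibrators around the expected detection limit
#' (0.001-0.075 ug absolute amount in the vial), one injection each.
#'
#' @param config A `"synthetic_config"`.
#' @param panel The analyte panel.
#' @param levels Calibrator amounts (ug).
#' @param seed Integer seed (or `NULL`).
#' @return List with `peaks` and `amounts` (as in
#'   [simulate_calibration()]).
#' @export
simulate_limit_series <- function(config, panel = load_panel(),
                                  levels = c(0.001, 0.005, 0.01, 0.02,
                                             0.04, 0.075),
                                  seed = NULL) {
  simulate_calibration(config, panel, n_rep = 1, levels = levels,
                       seed = seed)
}

#' Simulate a QC series over several days
#'
#' QC standards at the low and high level measured in replicate on
#' several days. Day-to-day instrument drift is emulated by a per-day,
#' per-analyte multiplicative factor on the analyte areas (source-state
#' drift that the ISTD ratio does not fully cancel), giving inter-day
#' variability above the within-day repeatability.
#'
#' @param config A `"synthetic_config"`.
#' @param panel The analyte panel.
#' @param n_days Number of measurement days (study design: 8).
#' @param n_rep Replicates per day (study design: 2).
#' @param day_rsd Relative SD of the per-day drift factor.
#' @param qc_levels Named nominal QC amounts (ug in vial).
#' @param seed Integer seed (or `NULL`).
#' @return List with `peaks` and `amounts` (long, with `qc_level` and
#'   `day` columns).
#' @export
simulate_qc_series <- function(config, panel = load_panel(), n_days = 8,
                               n_rep = 2, day_rsd = 0.04,
                               qc_levels = c(low = 0.0625, high = 3.75),
                               seed = NULL) {
  an <- panel$analytes
  run <- function() {
    peaks <- list()
    amounts <- list()
    for (d in seq_len(n_days)) {
      drift <- stats::setNames(.noise_factor(nrow(an), day_rsd), an$name)
      for (lev_name in names(qc_levels)) {
        for (r in seq_len(n_rep)) {
          id <- sprintf("qc_%s_d%d_r%d", lev_name, d, r)
          amt_an <- stats::setNames(qc_levels[[lev_name]] *
                                      an$isomer_fraction, an$name)
          amt_al <- stats::setNames(panel$alkanes$vial_amount_ug,
                                    panel$alkanes$name)
          p <- simulate_injection(c(amt_an, amt_al), list(sample_id = id),
                                  config)
          is_an <- p$analyte %in% an$name
          mult <- drift[p$analyte[is_an]]
          p$area_target[is_an] <- p$area_target[is_an] * mult
          p$area_q1[is_an] <- p$area_q1[is_an] * mult
          p$area_q2[is_an] <- p$area_q2[is_an] * mult
          peaks[[length(peaks) + 1L]] <- p
          amounts[[length(amounts) + 1L]] <- data.frame(
            sample_id = id, analyte = an$name,
            amount_ug = unname(amt_an), qc_level = lev_name, day = d,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(peaks = do.call(rbind, peaks), amounts = do.call(rbind, amounts))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate flower samples for quantification
#'
#' Each sample is weighed (around the 5 mg target with realistic
#' weighing scatter), spiked with ISTD and measured in duplicate
#' injections of separately prepared vials under final method conditions.
#'
#' @param config A `"synthetic_config"`.
#' @param panel The analyte panel.
#' @param contents Named list: per sample, a named vector of true flower
#'   contents (ug/g). Defaults to one sample with the generator's default
#'   profile.
#' @param target_weight Target sample weight, mg.
#' @param weight_rsd Relative SD of the actual weighed amount.
#' @param n_injections Injections per sample (averaged at quantification).
#' @param seed Integer seed (or `NULL`).
#' @return List with `peaks` and `truth` (long data frame of true
#'   contents).
#' @export
simulate_flower_samples <- function(config, panel = load_panel(),
                                    contents = NULL, target_weight = 5,
                                    weight_rsd = 0.02, n_injections = 2,
                                    seed = NULL) {
  sp <- config$species
  if (is.null(contents)) {
    prof <- stats::setNames(sp$flower_content[sp$kind == "analyte"],
                            sp$name[sp$kind == "analyte"])
    contents <- list(sample1 = prof)
  }
  run <- function() {
    peaks <- list()
    truth <- list()
    for (sid in names(contents)) {
      prof <- contents[[sid]]
      w <- target_weight * .noise_factor(1, weight_rsd)
      cfg <- config
      cfg$species$flower_content <- ifelse(
        cfg$species$kind == "analyte",
        ifelse(is.na(prof[cfg$species$name]), 0, prof[cfg$species$name]),
        0)
      amounts <- .flower_amounts(cfg, w)
      supp <- .draw_suppression(cfg, "flower")  # one matrix draw per sample
      for (inj in seq_len(n_injections)) {
        meta <- .default_meta(list(sample_id = sid, sample_weight = w,
                                   sample_type = "flower",
                                   injection_index = 1L))
        meta$sample_id <- sprintf("%s", sid)
        p <- .injection_areas(amounts, meta, cfg, supp)
        p$injection_index <- inj   # separately prepared duplicate vials
        peaks[[length(peaks) + 1L]] <- p
      }
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = sid, analyte = names(prof),
        true_content = unname(prof), sample_weight = w,
        stringsAsFactors = FALSE)
    }
    list(peaks = do.call(rbind, peaks), truth = do.call(rbind, truth))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Pipeline run configuration
#'
#' Bundles the stage parameters of [run_pipeline()] with their defaults
#' (all tolerances and significance levels at the method's stated
#' values).
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Master seed; every stochastic stage derives from it.
#' @param n_flower_samples Number of unknown flower samples to simulate
#'   and profile.
#' @param noise_rsd Measurement noise RSD for the generator.
#' @param alpha Significance level for Cochran/Mandel/DIN 32645.
#' @param din_k DIN 32645 `k` factor.
#' @param radar_threshold Radar-subset threshold, ug/g.
#' @param n_cal_rep Calibration replicates per level.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(out_dir = tempfile("fetterp_run_"), seed = 1L,
                       n_flower_samples = 2, noise_rsd = 0.03,
                       alpha = 0.01, din_k = 3, radar_threshold = 100,
                       n_cal_rep = 3) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_flower_samples = n_flower_samples,
                 noise_rsd = noise_rsd, alpha = alpha, din_k = din_k,
                 radar_threshold = radar_threshold,
                 n_cal_rep = n_cal_rep), class = "run_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages end to end: calibration simulation and model
#' selection, DIN 32645 limits, flower-sample quantification and profile
#' summaries, writing CSV artifacts plus a JSON run summary carrying the
#' seed and configuration for reproducibility. Identical configuration
#' and seed give identical outputs.
#'
#' @param config A `"run_config"`.
#' @param panel The analyte panel.
#' @return Invisible list with the in-memory stage results (`models`,
#'   `limits`, `quant`, `profiles`, `paths`).
#' @export
run_pipeline <- function(config = run_config(), panel = load_panel()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- synthetic_config(panel, noise_rsd = config$noise_rsd)

  cal <- simulate_calibration(scfg, panel, n_rep = config$n_cal_rep,
                              seed = config$seed)
  models <- calibrate_panel(cal$peaks, cal$amounts, panel,
                            alpha = config$alpha)

  lim_series <- simulate_limit_series(scfg, panel, seed = config$seed + 1L)
  lim_ratios <- response_ratios(lim_series$peaks, panel)
  lim_merged <- merge(lim_ratios, lim_series$amounts,
                      by = c("sample_id", "analyte"))
  limits <- lapply(stats::setNames(panel$analytes$name,
                                   panel$analytes$name), function(a) {
    d <- lim_merged[lim_merged$analyte == a, , drop = FALSE]
    tryCatch(din32645_limits(d$amount_ug, d$ratio, alpha = config$alpha,
                             k = config$din_k),
             error = function(e) NULL)
  })
  limit_df <- data.frame(
    analyte = names(limits),
    lod = vapply(limits, function(l) if (is.null(l)) NA_real_ else l$lod,
                 numeric(1)),
    loq = vapply(limits, function(l) if (is.null(l)) NA_real_ else l$loq,
                 numeric(1)),
    stringsAsFactors = FALSE)

  base_prof <- stats::setNames(
    scfg$species$flower_content[scfg$species$kind == "analyte"],
    scfg$species$name[scfg$species$kind == "analyte"])
  contents <- lapply(seq_len(config$n_flower_samples), function(i) {
    base_prof * (0.6 + 0.3 * i)   # strains differ by overall richness
  })
  names(contents) <- sprintf("strain%02d", seq_along(contents))
  flowers <- simulate_flower_samples(scfg, panel, contents,
                                     seed = config$seed + 2L)
  quant <- quantify_sample(flowers$peaks, models, panel, limits = limit_df)
  profiles <- build_profiles(quant, panel,
                             radar_threshold = config$radar_threshold)

  model_df <- data.frame(
    analyte = names(models),
    kind = vapply(models, function(m) m$kind, character(1)),
    split_point = vapply(models, function(m)
      if (is.null(m$split_point)) NA_real_ else m$split_point, numeric(1)),
    dropped_top_levels = vapply(models, function(m)
      m$dropped_top_levels, integer(1)),
    stringsAsFactors = FALSE)

  paths <- list(
    models = file.path(config$out_dir, "calibration_models.csv"),
    limits = file.path(config$out_dir, "analytical_limits.csv"),
    quant = file.path(config$out_dir, "quantification.csv"),
    profile_long = file.path(config$out_dir, "profile_long.csv"),
    profile_wide = file.path(config$out_dir, "profile_wide.csv"),
    summary = file.path(config$out_dir, "run_summary.json"))
  utils::write.csv(model_df, paths$models, row.names = FALSE)
  utils::write.csv(limit_df, paths$limits, row.names = FALSE)
  utils::write.csv(quant, paths$quant, row.names = FALSE)
  utils::write.csv(profiles$long, paths$profile_long, row.names = FALSE)
  wide <- data.frame(sample_id = rownames(profiles$contents),
                     profiles$contents, check.names = FALSE)
  utils::write.csv(wide, paths$profile_wide, row.names = FALSE)
  summary <- list(
    seed = config$seed,
    config = unclass(config),
    total_wt_percent = as.list(profiles$total_wt_percent),
    radar_analytes = profiles$radar_analytes,
    model_kinds = as.list(table(model_df$kind)))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(models = models, limits = limits, quant = quant,
                 profiles = profiles, paths = paths))
}
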