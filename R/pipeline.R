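#' Orchestrated condensation-flux analysis
#'
#' [run_c1_analysis()] executes the full inference chain in one call:
#' model curation, phenotypic phase planes for the thymidine and
#' thymidine+methionine media, intersection with the measured growth rates
#' to obtain the condensation flux, the serine-cycle phase plane on
#' formaldehyde as sole carbon source, the maximal-growth-rate bound and
#' its doubling time, and the comparison against the in vitro rate law.
#'
#' @name pipeline
NULL

#' Default analysis configuration
#'
#' Defaults mirror the measured study conditions: growth rates
#' 0.036 +/- 0.006 h^-1 (n = 18, thymidine) and 0.047 +/- 0.004 h^-1
#' (n = 18, thymidine + methionine), with per-condition pantothenate
#' comparisons; toy models whose analytic slopes equal the genome-scale
#' phase-plane slopes (0.7 and 0.54 mmol gCDW^-1 via `b = 0.7`,
#' `met_share = 0.16/0.7`; serine-cycle slope `b_serine = 20.8`); and the
#' printed cellular constants. Pass `model_path`/`model_dialect` to run the
#' same chain on a user-supplied genome-scale model instead of the toy
#' oracle.
#'
#' @param model_path Optional path to a genome-scale model (e.g. iML1515).
#' @param model_dialect `"bigg_json"` or `"sbml"`.
#' @param b,met_share,b_serine Toy-model parameters (ignored when
#'   `model_path` is given).
#' @param growth_thy,growth_thy_met [growth_measurement()]s for the two
#'   scenarios.
#' @param thf_pool THF pool, pmol mL^-1 OD600^-1.
#' @param formaldehyde_uM Formaldehyde concentration sustained during
#'   growth, uM.
#' @param consts [cell_constants()].
#' @param n_grid Phase-plane grid size.
#' @param seed Integer seed (toy-model decoys).
#' @param out_dir Optional output directory for report files.
#' @return A named list (the run configuration).
#' @export
c1_config <- function(model_path = NULL, model_dialect = "bigg_json",
                      b = 0.7, met_share = 0.16 / 0.7, b_serine = 20.8,
                      growth_thy = growth_measurement(0.036, 0.006, 18),
                      growth_thy_met = growth_measurement(0.047, 0.004, 18),
                      thf_pool = 23, formaldehyde_uM = 100,
                      consts = cell_constants(), n_grid = 30, seed = 1,
                      out_dir = NULL) {
  if (!is.null(model_path) && !file.exists(model_path)) {
    stop("config error: model file not found: ", model_path,
         "\nSupply a local copy of a genome-scale model (e.g. iML1515 ",
         "JSON from the BiGG database) or omit model_path to use the toy ",
         "oracle.", call. = FALSE)
  }
  list(model_path = model_path, model_dialect = model_dialect,
       b = b, met_share = met_share, b_serine = b_serine,
       growth_thy = growth_thy, growth_thy_met = growth_thy_met,
       thf_pool = thf_pool, formaldehyde_uM = formaldehyde_uM,
       consts = consts, n_grid = n_grid, seed = seed, out_dir = out_dir)
}

#' Run the full condensation-flux analysis
#'
#' @param config A [c1_config()].
#' @return A `c1_report` list: `slopes` (per-scenario slope/intercept),
#'   `flux_thy`, `flux_thy_met` ([derive_flux()] estimates),
#'   `flux_consistency` (absolute difference vs combined SD), `max_growth`
#'   (serine-cycle bound, h^-1), `doubling_time_h`, `in_vitro` (rate-law
#'   block: THF concentration, rate, fold difference),
#'   `direct_estimate` (biomass-fraction growth estimate), `config`.
#' @export
run_c1_analysis <- function(config = c1_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.null(config$model_path)) {
    aux <- stage("toy model (auxotroph)",
                 gen_toy_model(config$b, "auxotroph",
                               met_share = config$met_share,
                               seed = config$seed))
    ser <- stage("toy model (serine)",
                 gen_toy_model(config$b_serine, "serine", seed = config$seed))
  } else {
    raw <- stage("read model",
                 read_model(config$model_path, config$model_dialect))
    aux <- stage("base curation", apply_curation(raw, base_curation_recipe()))
    ser <- stage("serine-cycle curation",
                 apply_curation(aux, serine_cycle_recipe()))
  }
  pp_thy <- stage("phase plane (thy)",
                  phase_plane(aux, build_medium("thy"),
                              n_grid = config$n_grid))
  pp_met <- stage("phase plane (thy_met)",
                  phase_plane(aux, build_medium("thy_met"),
                              n_grid = config$n_grid))
  pp_ser <- stage("phase plane (formaldehyde_only)",
                  phase_plane(ser, build_medium("formaldehyde_only"),
                              n_grid = config$n_grid))
  f_thy <- stage("derive flux (thy)", derive_flux(pp_thy, config$growth_thy))
  f_met <- stage("derive flux (thy_met)",
                 derive_flux(pp_met, config$growth_thy_met))
  mg <- stage("derive max growth", derive_max_growth(pp_ser, f_thy))
  dt <- doubling_time(mg$mean_mu)

  consts <- config$consts
  thf_uM <- pool_to_intracellular(config$thf_pool, consts)
  ivr <- in_vitro_rate(config$formaldehyde_uM * 1e-6, thf_uM * 1e-6,
                       consts = consts)
  report <- structure(list(
    slopes = data.frame(
      scenario = c("thy", "thy_met", "formaldehyde_only"),
      slope = c(pp_thy$slope, pp_met$slope, pp_ser$slope),
      intercept = c(pp_thy$intercept, pp_met$intercept, pp_ser$intercept),
      mu_max = c(pp_thy$mu_max, pp_met$mu_max, pp_ser$mu_max)),
    phase_planes = list(thy = pp_thy, thy_met = pp_met,
                        formaldehyde_only = pp_ser),
    flux_thy = f_thy,
    flux_thy_met = f_met,
    flux_consistency = list(
      difference = abs(f_thy$flux - f_met$flux),
      combined_sd = f_thy$sd + f_met$sd,
      consistent = abs(f_thy$flux - f_met$flux) <= f_thy$sd + f_met$sd),
    max_growth = mg,
    doubling_time_h = dt,
    in_vitro = list(thf_uM = thf_uM,
                    formaldehyde_uM = config$formaldehyde_uM,
                    rate_mmol_gcdw_h = ivr$biomass_mmol_gcdw_h,
                    rate_M_s = ivr$volumetric_M_s,
                    fold_difference = fold_difference(
                      f_thy$flux, ivr$biomass_mmol_gcdw_h)),
    direct_estimate = direct_growth_estimate(
      config$growth_thy$mean_mu, consts$carbon_fraction_c1),
    config = config), class = "c1_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.c1_report <- function(x, ...) {
  s2 <- function(v) format(signif(v, 2))
  cat("Spontaneous formaldehyde-THF condensation: derived rates\n",
      "--------------------------------------------------------\n", sep = "")
  cat(sprintf("  phase-plane slope (thy):      %s mmol gCDW^-1\n",
              s2(x$slopes$slope[1])))
  cat(sprintf("  phase-plane slope (thy+met):  %s mmol gCDW^-1\n",
              s2(x$slopes$slope[2])))
  cat(sprintf("  condensation flux (thy):      %s +/- %s mmol gCDW^-1 h^-1\n",
              s2(x$flux_thy$flux), s2(x$flux_thy$sd)))
  cat(sprintf("  condensation flux (thy+met):  %s +/- %s mmol gCDW^-1 h^-1\n",
              s2(x$flux_thy_met$flux), s2(x$flux_thy_met$sd)))
  cat(sprintf("  scenarios consistent:         %s\n",
              x$flux_consistency$consistent))
  cat(sprintf("  serine-cycle slope:           %s mmol gCDW^-1\n",
              s2(x$slopes$slope[3])))
  cat(sprintf("  maximal growth on HCHO:       %s +/- %s h^-1\n",
              s2(x$max_growth$mean_mu), s2(x$max_growth$sd)))
  cat(sprintf("  doubling time:                %s h (%s days)\n",
              s2(x$doubling_time_h), s2(x$doubling_time_h / 24)))
  cat(sprintf("  direct biomass-fraction est.: %s h^-1\n",
              s2(x$direct_estimate)))
  cat(sprintf("  in vitro rate law:            %s mmol gCDW^-1 h^-1\n",
              s2(x$in_vitro$rate_mmol_gcdw_h)))
  cat(sprintf("  in vivo / in vitro:           %s-fold\n",
              s2(x$in_vitro$fold_difference)))
  invisible(x)
}

#' Write a report to disk (JSON summary + TSV phase planes)
#'
#' @param report A `c1_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(report$phase_planes)) {
    p <- file.path(out_dir, paste0("phase_plane_", nm, ".tsv"))
    write_phase_plane(report$phase_planes[[nm]], tsv_path = p)
    paths <- c(paths, p)
  }
  summary_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(
    slopes = report$slopes,
    flux_thy = list(value = report$flux_thy$flux, sd = report$flux_thy$sd),
    flux_thy_met = list(value = report$flux_thy_met$flux,
                        sd = report$flux_thy_met$sd),
    flux_consistency = report$flux_consistency,
    max_growth = list(value = report$max_growth$mean_mu,
                      sd = report$max_growth$sd),
    doubling_time_h = report$doubling_time_h,
    in_vitro = report$in_vitro,
    direct_estimate = report$direct_estimate,
    provenance = list(
      package = "c1flux",
      version = as.character(utils::packageVersion("c1flux")),
      model = if (is.null(report$config$model_path)) "toy oracle"
              else report$config$model_path,
      seed = report$config$seed)),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, summary_path))
}
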