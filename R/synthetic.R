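#' Seeded synthetic-data generators
#'
#' Generators emulating every input of the analysis so that the whole chain
#' is testable without downloads: growth curves (lag, exponential phase,
#' logistic saturation, multiplicative lognormal noise), formaldehyde time
#' series in the two regimes seen experimentally (monotone accumulation
#' towards ~1000 uM in non-growing cultures; rise to a ~100 uM plateau then
#' decline in growing cultures) with matching Nash-assay absorbances, and a
#' toy stoichiometric model whose phenotypic phase plane has a known
#' analytic slope. All generators are bit-reproducible given their seed;
#' the caller's RNG state is left untouched.
#'
#' @name synthetic_data
NULL

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic growth curve
#'
#' The noiseless trajectory is piecewise: flat at `n0` during the lag,
#' exact exponential growth at rate `mu` up to half the carrying capacity,
#' then a logistic approach to `capacity`. Multiplicative lognormal noise
#' of coefficient of variation `noise_cv` is applied pointwise.
#'
#' @param mu Growth rate, h^-1 (default 0.036, the rate observed with
#'   thymidine supplementation).
#' @param n0 Inoculation density, OD600 (default 0.02).
#' @param lag Lag phase, h.
#' @param capacity Carrying capacity, OD600.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (< 0.5; 0 disables noise).
#' @param times Sampling times, h; default covers lag through saturation.
#' @param seed Integer seed.
#' @return A [growth_curve()]; the generating parameters are stored in
#'   `attr(, "meta")`.
#' @export
gen_growth_curve <- function(mu = 0.036, n0 = 0.02, lag = 5, capacity = 0.9,
                             noise_cv = 0.03,
                             times = NULL, seed = 1) {
  stopifnot(mu > 0, n0 > 0, lag >= 0, capacity > n0, noise_cv >= 0,
            noise_cv < 0.5)
  if (is.null(times)) {
    # reach saturation: time to capacity plus margin
    t_end <- lag + log(capacity / n0) / mu * 1.3
    times <- seq(0, t_end, length.out = 49)
  }
  s <- pmax(0, times - lag)
  n_exp <- n0 * exp(mu * s)
  half <- capacity / 2
  od <- ifelse(n_exp <= half, n_exp, {
    # logistic continuation matched at half capacity
    t_half <- (log(half / n0)) / mu
    capacity / (1 + exp(-mu * (s - t_half)))
  })
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    od <- with_seed(seed, od * exp(stats::rnorm(length(od), 0, sdlog)))
  }
  growth_curve(times, od,
               meta = list(mu = mu, n0 = n0, lag = lag, capacity = capacity,
                           noise_cv = noise_cv, seed = seed))
}

#' Generate a synthetic formaldehyde time series with Nash absorbances
#'
#' Phenomenological shapes: `non_growing_accumulation` rises monotonically,
#' saturating towards `ceiling_uM` (~1000 uM) as sarcosine oxidation by the
#' inoculum proceeds; `growing_plateau` rises to `plateau_uM` (~100 uM),
#' holds during exponential growth, then declines exponentially after
#' `decline_onset` as the culture enters stationary phase. Absorbances are
#' produced through a linear Nash calibration with additive Gaussian noise
#' truncated at zero.
#'
#' @param mode `"non_growing_accumulation"` or `"growing_plateau"`.
#' @param production_rate Initial formaldehyde production rate, uM h^-1.
#' @param plateau_uM Plateau concentration for growing cultures, uM.
#' @param ceiling_uM Saturation level for non-growing cultures, uM.
#' @param decline_onset Start of the stationary-phase decline, h.
#' @param noise_sd Additive noise on concentrations, uM.
#' @param cal_slope,cal_intercept Nash calibration used to synthesize
#'   absorbances (absorbance per mM, blank absorbance).
#' @param times Sampling times, h.
#' @param seed Integer seed.
#' @return data.frame with `time_h`, `conc_uM` (noisy), `conc_true_uM`,
#'   `absorbance`.
#' @export
gen_formaldehyde_series <- function(mode = c("non_growing_accumulation",
                                             "growing_plateau"),
                                    production_rate = 25, plateau_uM = 100,
                                    ceiling_uM = 1000, decline_onset = 60,
                                    noise_sd = 3, cal_slope = 1.2,
                                    cal_intercept = 0.05,
                                    times = seq(0, 100, by = 4), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(production_rate > 0, plateau_uM > 0, ceiling_uM > 0,
            noise_sd >= 0)
  conc <- if (mode == "non_growing_accumulation") {
    ceiling_uM * (1 - exp(-production_rate * times / ceiling_uM))
  } else {
    rise <- pmin(plateau_uM, production_rate * times)
    decay <- ifelse(times > decline_onset,
                    exp(-0.05 * (times - decline_onset)), 1)
    rise * decay
  }
  out <- with_seed(seed, {
    noisy <- pmax(0, conc + stats::rnorm(length(conc), 0, noise_sd))
    absorb <- pmax(0, cal_slope * noisy / 1000 + cal_intercept +
                     stats::rnorm(length(conc), 0, 0.005))
    data.frame(time_h = times, conc_uM = noisy, conc_true_uM = conc,
               absorbance = absorb)
  })
  attr(out, "meta") <- list(mode = mode, production_rate = production_rate,
                            plateau_uM = plateau_uM, ceiling_uM = ceiling_uM,
                            decline_onset = decline_onset,
                            noise_sd = noise_sd, cal_slope = cal_slope,
                            cal_intercept = cal_intercept, seed = seed)
  out
}

#' Generate Nash-assay calibration standards
#'
#' @param conc_mM Standard concentrations, mM (default an even grid on the
#'   assay's linear range 0-1 mM).
#' @param slope,intercept True calibration line (absorbance per mM, blank).
#' @param noise_sd Additive absorbance noise.
#' @param seed Integer seed.
#' @return data.frame with columns `mM`, `absorbance`.
#' @export
gen_nash_standards <- function(conc_mM = seq(0, 1, by = 0.125), slope = 1.2,
                               intercept = 0.05, noise_sd = 0.01, seed = 1) {
  ab <- slope * conc_mM + intercept
  if (noise_sd > 0) {
    ab <- with_seed(seed, pmax(0, ab + stats::rnorm(length(ab), 0, noise_sd)))
  }
  out <- data.frame(mM = conc_mM, absorbance = ab)
  attr(out, "meta") <- list(slope = slope, intercept = intercept,
                            noise_sd = noise_sd, seed = seed)
  out
}

# --- toy stoichiometric model ------------------------------------------------

# dead-end decoy reaction: two private metabolites, no other producer or
# consumer, so the reaction can never carry steady-state flux
decoy_reaction <- function(id) {
  reaction(id, stats::setNames(c(-1, 1), paste0("x_", tolower(id),
                                                c("_a_c", "_b_c"))))
}

#' Generate a toy stoichiometric model with a known phase-plane slope
#'
#' Builds a small BiGG-dialect model that mirrors, at toy scale, the
#' metabolic logic of the curated genome-scale reconstruction, and whose
#' phenotypic phase plane for the condensation reaction THFSPONT has the
#' analytic lower-envelope slope `b` (mmol gCDW^-1).
#'
#' Two scenarios are available. `"auxotroph"`: glucose fuels a linear
#' pathway to a biomass precursor; the biomass reaction additionally
#' requires `b` one-carbon units per unit growth, of which a fraction
#' `met_share` are methyl groups that methionine (when its exchange is
#' open) can supply directly, so the slope is `b` on thymidine medium and
#' `b * (1 - met_share)` with methionine. `"serine"`: biomass is built
#' from acetyl-CoA produced by a miniature serine cycle (SHMT, the
#' SGAT aminotransferase couple, a lumped hydroxypyruvate-to-malate leg,
#' malate thiokinase, malyl-CoA lyase), so every unit of biomass requires
#' `b` condensation events and formaldehyde is the sole carbon source.
#'
#' By default the returned model is uncurated: it contains every target of
#' [base_curation_recipe()] (and of [serine_cycle_recipe()] for the serine
#' scenario) -- as faithful mini-versions where the reaction is mechanistic
#' (GLYCL, GHMT2r, THD2pp, THYMt3pp) and as dead-end decoys otherwise --
#' and lacks THFSPONT, which the recipe adds. With `curated = TRUE` the
#' appropriate recipe(s) are applied before returning. Additional seeded
#' filler pathways are dead-end decoys that cannot carry steady-state flux
#' and therefore never affect the phase-plane envelope.
#'
#' @param b Biomass demand for 5,10-methylene-THF, mmol gCDW^-1 (> 0); the
#'   analytic phase-plane slope.
#' @param scenario `"auxotroph"` or `"serine"`.
#' @param met_share Fraction of the C1 demand substitutable by methionine
#'   (auxotroph scenario; default 0.16/0.7, reproducing the 0.7 -> 0.54
#'   slope drop of the genome-scale model).
#' @param n_filler Number of random dead-end decoy pathways.
#' @param curated Apply the curation recipe(s) before returning
#'   (default TRUE).
#' @param seed Integer seed (names of the filler pathways).
#' @return A [stoich_model()] with attributes `slope` (analytic lower-bound
#'   slope under the scenario's reference medium), `slope_met` (auxotroph
#'   only: slope with methionine open) and `mu_max` (maximal growth under
#'   the reference medium with default uptake bounds).
#' @export
gen_toy_model <- function(b, scenario = c("auxotroph", "serine"),
                          met_share = 0.16 / 0.7, n_filler = 3,
                          curated = TRUE, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(b > 0, met_share >= 0, met_share < 1, n_filler >= 0)
  rev_rxn <- function(id, st, name = id) {
    reaction(id, st, lower_bound = -1000, upper_bound = 1000, name = name)
  }
  ex <- function(met) reaction(paste0("EX_", met),
                               stats::setNames(-1, met),
                               lower_bound = -1000, upper_bound = 1000)
  # shared skeleton: boundary, transport, base-recipe targets
  rxns <- list(
    ex("fald_e"), ex("co2_e"), ex("h2o_e"), ex("o2_e"), ex("for_e"),
    rev_rxn("FALDt", c(fald_e = -1, fald_c = 1)),
    rev_rxn("CO2t", c(co2_e = -1, co2_c = 1)),
    rev_rxn("H2Ot", c(h2o_e = -1, h2o_c = 1)),
    reaction("FORt", c(for_c = -1, for_e = 1)),
    # C1 wastage: 5,10-methylene-THF hydrolysed to formate; makes the upper
    # envelope of the phase plane exceed the lower one
    reaction("C1WASTE", c(mlthf_c = -1, thf_c = 1, for_c = 1)),
    # mechanistic curation targets
    reaction("GLYCL", c(gly_c = -1, thf_c = -1, mlthf_c = 1, co2_c = 1),
             name = "glycine cleavage (lumped)"),
    rev_rxn("GHMT2r", c(ser__L_c = -1, thf_c = -1,
                        gly_c = 1, mlthf_c = 1, h2o_c = 1),
            name = "serine hydroxymethyltransferase"),
    reaction("THD2pp", c(h_p = -2, nadh_c = -1, nadp_c = -1,
                         h_c = 2, nad_c = 1, nadph_c = 1),
             name = "transhydrogenase (uncorrected)"),
    # decoy curation targets (dead ends; removal/redirection cannot change
    # the envelope)
    decoy_reaction("POR5"), decoy_reaction("GLYCK"), decoy_reaction("PFL"),
    decoy_reaction("OBTFL"), decoy_reaction("FTHFLi"),
    rev_rxn("FTHFD", stats::setNames(c(-1, 1), c("x_fthfd_a_c", "x_fthfd_b_c"))),
    rev_rxn("GARFT", stats::setNames(c(-1, 1), c("x_garft_a_c", "x_garft_b_c"))),
    rev_rxn("AICART", stats::setNames(c(-1, 1), c("x_aicart_a_c", "x_aicart_b_c"))),
    # periplasmic symporter: secretion-only until curation reverses it
    reaction("THYMt3pp", c(thymd_c = -1, thymd_e = 1),
             name = "thymidine periplasmic symporter"),
    # serine-recipe removal targets
    reaction("GLXCL", c(glx_c = -1, co2_c = 2)),
    reaction("THRD", c(thr__L_c = -1, x_thrd_b_c = 1)),
    reaction("THRA", c(thr__L_c = -1, acald_c = 1, gly_c = 1)),
    reaction("THRA2", c(thr__L_c = -1, acald_c = 1, gly_c = 1),
             name = "threonine aldolase (isozyme)"),
    reaction("SERD_L", c(ser__L_c = -1, pyr_c = 1)),
    rev_rxn("MMM", c(succoa_c = -1, mmcoa__S_c = 1))
  )
  if (scenario == "auxotroph") {
    stopifnot(b * (1 - met_share) > 0)
    b_met <- b * met_share
    rxns <- c(rxns, list(
      ex("glc__D_e"), ex("gly_e"), ex("thymd_e"), ex("met__L_e"),
      ex("pnto__R_e"),
      reaction("GLCt", c(glc__D_e = -1, glc__D_c = 1)),
      reaction("GLYt", c(gly_e = -1, gly_c = 1)),
      reaction("METt", c(met__L_e = -1, met__L_c = 1)),
      reaction("PANt", c(pnto__R_e = -1, pnto__R_c = 1)),
      reaction("PREC_SYN", c(glc__D_c = -1, prec_c = 1)),
      reaction("MLTHF2ME", c(mlthf_c = -1, me1_c = 1, thf_c = 1),
               name = "methyl-group synthesis from 5,10-methylene-THF"),
      reaction("MET2ME", c(met__L_c = -1, me1_c = 1),
               name = "methyl-group salvage from methionine"),
      reaction("BIOMASS_toy",
               stats::setNames(
                 c(-10, -(b - b_met), -b_met, -0.05, (b - b_met)),
                 c("prec_c", "mlthf_c", "me1_c", "thymd_c", "thf_c")),
               name = "biomass")
    ))
    objective <- "BIOMASS_toy"
  } else {
    rxns <- c(rxns, list(
      # lumped glycerate leg of the serine cycle: hydroxypyruvate ->
      # glycerate -> 2PG -> PEP -> oxaloacetate -> malate, carboxylation
      # included
      reaction("HPYRMAL", c(hpyr_c = -1, co2_c = -1, mal__L_c = 1),
               name = "hydroxypyruvate to malate (lumped)"),
      # unlimited ATP regeneration: energy metabolism is outside this toy
      reaction("ATPREG", c(adp_c = -1, pi_c = -1, atp_c = 1),
               name = "ATP regeneration (toy closure)"),
      reaction("BIOMASS_toy",
               stats::setNames(c(-b, b), c("accoa_c", "coa_c")),
               name = "biomass from acetyl-CoA")
    ))
    objective <- "BIOMASS_toy"
  }
  filler <- if (n_filler > 0) {
    tags <- with_seed(seed, {
      paste0("FILLER", sample(100:999, n_filler))
    })
    lapply(tags, decoy_reaction)
  } else list()
  rxns <- c(rxns, filler)

  met_ids <- sort(unique(unlist(lapply(rxns, function(r)
    names(r$stoichiometry)))))
  mets <- lapply(met_ids, metabolite)
  model <- stoich_model(paste0("toy_", scenario, "_b", b), mets, rxns,
                        objective)
  if (curated) {
    model <- apply_curation(model, base_curation_recipe())
    if (scenario == "serine") {
      model <- apply_curation(model, serine_cycle_recipe())
    }
  }
  attr(model, "slope") <- b
  attr(model, "slope_met") <- if (scenario == "auxotroph") b * (1 - met_share)
                              else NA_real_
  attr(model, "mu_max") <- if (scenario == "auxotroph") 1 else 1000 / b
  attr(model, "b") <- b
  model
}
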