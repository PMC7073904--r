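#' Growth media as exchange-bound specifications
#'
#' A `medium_spec` maps exchange-reaction ids to a maximal uptake rate and a
#' maximal secretion rate (both >= 0, mmol gCDW^-1 h^-1). When applied to a
#' model, listed exchanges are opened accordingly; exchanges of inorganic
#' (carbon-free or freely available) species stay fully open; every other
#' exchange is closed for uptake but left open for secretion.
#'
#' @name medium
NULL

# extracellular species whose exchange stays open in every scenario:
# gases, water, protons and the standard minimal-medium inorganic salts.
INORGANIC_EXCHANGE_METS <- c(
  "o2_e", "co2_e", "h2o_e", "h_e", "nh4_e", "pi_e", "so4_e", "k_e", "na1_e",
  "cl_e", "mg2_e", "ca2_e", "fe2_e", "fe3_e", "cu2_e", "mn2_e", "zn2_e",
  "ni2_e", "cobalt2_e", "mobd_e", "tungs_e", "sel_e", "slnt_e", "cbl1_e")

#' Create a medium specification
#'
#' @param uptake Named numeric vector: exchange reaction id -> maximal
#'   uptake rate (>= 0).
#' @param secretion Named numeric vector of maximal secretion rates for the
#'   same exchanges; defaults to 1000 for each.
#' @return A `medium_spec`.
#' @export
medium_spec <- function(uptake, secretion = NULL) {
  stopifnot(is.numeric(uptake), !is.null(names(uptake)), all(uptake >= 0))
  if (is.null(secretion)) {
    secretion <- stats::setNames(rep(1000, length(uptake)), names(uptake))
  }
  stopifnot(all(secretion >= 0))
  structure(list(uptake = uptake, secretion = secretion),
            class = "medium_spec")
}

#' Build the medium for a growth scenario
#'
#' Scenarios mirror the cultivation conditions of the C1-auxotroph
#' experiments: glucose is the main carbon source, glycine relieves the
#' glycine auxotrophy, formaldehyde (generated in situ from sarcosine) feeds
#' the spontaneous condensation, and thymidine is the obligatory C1
#' supplement. `thy_met` additionally supplies methionine, lowering the
#' biosynthetic demand for 5,10-methylene-THF; `*_pan` variants add
#' pantothenate. `formaldehyde_only` opens formaldehyde as the sole carbon
#' source, the medium of the hypothetical serine-cycle methylotroph.
#'
#' @param scenario One of `"thy"`, `"thy_met"`, `"thy_pan"`,
#'   `"thy_met_pan"`, `"formaldehyde_only"`.
#' @param glc_uptake Glucose uptake bound, mmol gCDW^-1 h^-1 (default the
#'   conventional 10).
#' @param supplement_uptake Uptake bound for supplements and formaldehyde
#'   (default effectively unlimited, 1000).
#' @return A [medium_spec()].
#' @export
build_medium <- function(scenario = c("thy", "thy_met", "thy_pan",
                                      "thy_met_pan", "formaldehyde_only"),
                         glc_uptake = 10, supplement_uptake = 1000) {
  scenario <- match.arg(scenario)
  s <- supplement_uptake
  uptake <- switch(scenario,
    thy = c(EX_glc__D_e = glc_uptake, EX_gly_e = s, EX_fald_e = s,
            EX_thymd_e = s),
    thy_met = c(EX_glc__D_e = glc_uptake, EX_gly_e = s, EX_fald_e = s,
                EX_thymd_e = s, EX_met__L_e = s),
    thy_pan = c(EX_glc__D_e = glc_uptake, EX_gly_e = s, EX_fald_e = s,
                EX_thymd_e = s, EX_pnto__R_e = s),
    thy_met_pan = c(EX_glc__D_e = glc_uptake, EX_gly_e = s, EX_fald_e = s,
                    EX_thymd_e = s, EX_met__L_e = s, EX_pnto__R_e = s),
    formaldehyde_only = c(EX_fald_e = s))
  m <- medium_spec(uptake)
  attr(m, "scenario") <- scenario
  m
}

#' Apply a medium to a model
#'
#' Listed exchanges get bounds `[-uptake, secretion]`; exchanges of
#' inorganic species (see `INORGANIC_EXCHANGE_METS`) are fully opened
#' `[-1000, 1000]`; all remaining exchanges are closed for uptake
#' (`[0, 1000]`). Errors if the medium references an exchange the model
#' lacks.
#'
#' @param model A [stoich_model()] (curated).
#' @param medium A [medium_spec()].
#' @return The model with exchange bounds set.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(medium, "medium_spec"))
  ex <- exchange_reactions(model)
  missing <- setdiff(names(medium$uptake), ex)
  if (length(missing)) {
    stop("medium references exchange(s) absent from model '", model$id,
         "': ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (id in ex) {
    met <- names(model$reactions[[id]]$stoichiometry)
    if (id %in% names(medium$uptake)) {
      model$reactions[[id]]$lower_bound <- -medium$uptake[[id]]
      model$reactions[[id]]$upper_bound <- medium$secretion[[id]]
    } else if (met %in% INORGANIC_EXCHANGE_METS) {
      model$reactions[[id]]$lower_bound <- -1000
      model$reactions[[id]]$upper_bound <- 1000
    } else {
      model$reactions[[id]]$lower_bound <- 0
      model$reactions[[id]]$upper_bound <- 1000
    }
  }
  model
}
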