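#' Stoichiometric metabolic models
#'
#' A `stoich_model` is a plain-list representation of a constraint-based
#' metabolic model: metabolites, reactions with bounds and signed
#' stoichiometries (negative = consumed), and a biomass objective reaction.
#' Identifiers follow the BiGG dialect (compartment-suffixed, e.g. `thf_c`,
#' `EX_glc__D_e`), so curation recipes written against genome-scale
#' reconstructions apply unchanged to the bundled toy models.
#'
#' @name stoich_model
NULL

#' Create a metabolite record
#'
#' @param id BiGG-style identifier with compartment suffix (e.g. `"thf_c"`).
#' @param name Free-text name; defaults to the id.
#' @param compartment Compartment identifier; inferred from the id suffix
#'   when missing.
#' @return A named list of class `metabolite`.
#' @export
metabolite <- function(id, name = id, compartment = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  suffix <- sub("^.*_", "", id)
  if (is.null(compartment)) compartment <- suffix
  if (!identical(compartment, suffix)) {
    stop("metabolite '", id, "': compartment '", compartment,
         "' does not match id suffix '", suffix, "'", call. = FALSE)
  }
  structure(list(id = id, name = name, compartment = compartment),
            class = "metabolite")
}

#' Create a reaction record
#'
#' @param id Reaction identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed). Must be non-empty.
#' @param lower_bound,upper_bound Flux bounds in mmol gCDW^-1 h^-1.
#' @param name Free-text name.
#' @return A named list of class `reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     name = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop("reaction '", id, "': stoichiometry must be a non-empty named vector",
         call. = FALSE)
  }
  storage.mode(stoichiometry) <- "double"
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (length(stoichiometry) == 0L) {
    stop("reaction '", id, "': stoichiometry has no nonzero coefficients",
         call. = FALSE)
  }
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound > upper_bound", call. = FALSE)
  }
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound)),
            class = "reaction")
}

#' Assemble a stoichiometric model
#'
#' @param id Model identifier.
#' @param metabolites List of [metabolite()] records.
#' @param reactions List of [reaction()] records.
#' @param objective Id of the biomass (objective) reaction.
#' @return An object of class `stoich_model`.
#' @export
stoich_model <- function(id, metabolites, reactions, objective) {
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  model <- structure(list(id = id, metabolites = metabolites,
                          reactions = reactions, objective = objective),
                     class = "stoich_model")
  validate_model(model)
  model
}

#' Validate a stoichiometric model
#'
#' Checks the structural invariants: every metabolite referenced by a
#' reaction is declared, bounds are ordered, and the objective reaction
#' exists.
#'
#' @param model A `stoich_model`.
#' @return The model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "stoich_model"))
  met_ids <- names(model$metabolites)
  for (rxn in model$reactions) {
    missing <- setdiff(names(rxn$stoichiometry), met_ids)
    if (length(missing)) {
      stop("reaction '", rxn$id, "' references undeclared metabolite(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (rxn$lower_bound > rxn$upper_bound) {
      stop("reaction '", rxn$id, "': lower_bound > upper_bound", call. = FALSE)
    }
  }
  if (!model$objective %in% names(model$reactions)) {
    stop("objective reaction '", model$objective, "' not in model",
         call. = FALSE)
  }
  invisible(model)
}

#' Steady-state stoichiometric matrix
#'
#' @param model A `stoich_model`.
#' @return Dense numeric matrix S with one row per metabolite and one column
#'   per reaction.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' Reaction bounds as a two-column matrix
#' @param model A `stoich_model`.
#' @return Numeric matrix with columns `lower`, `upper`, rownames = reaction ids.
#' @export
reaction_bounds <- function(model) {
  cbind(lower = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
        upper = vapply(model$reactions, `[[`, numeric(1), "upper_bound"))
}

#' Identify exchange reactions
#'
#' Exchange reactions move a single extracellular metabolite across the
#' model boundary (stoichiometry `{met_e: -1}`); by convention a negative
#' flux is uptake and a positive flux is secretion.
#'
#' @param model A `stoich_model`.
#' @return Character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  is_ex <- vapply(model$reactions, function(r) {
    length(r$stoichiometry) == 1L && r$stoichiometry[[1]] < 0
  }, logical(1))
  names(model$reactions)[is_ex]
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("<stoich_model> ", x$id, "\n",
      "  metabolites: ", length(x$metabolites), "\n",
      "  reactions:   ", length(x$reactions),
      " (", length(exchange_reactions(x)), " exchanges)\n",
      "  objective:   ", x$objective, "\n", sep = "")
  invisible(x)
}

# internal: fetch a reaction or fail with a named error
get_reaction <- function(model, id, context = "lookup") {
  if (!id %in% names(model$reactions)) {
    stop(context, ": reaction '", id, "' not in model '", model$id, "'",
         call. = FALSE)
  }
  model$reactions[[id]]
}
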