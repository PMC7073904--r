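#' Read a stoichiometric model from disk
#'
#' Supports BiGG-style JSON (the format of the BiGG model repository, e.g.
#' iML1515.json) and SBML Level 3 with the FBC package. Flux bounds larger in
#' magnitude than `cap` are truncated to `±cap`, the conventional COBRA
#' "unbounded" sentinel.
#'
#' @param path Path to the model file.
#' @param dialect One of `"bigg_json"`, `"sbml"`.
#' @param cap Magnitude at which bounds are capped (default 1000).
#' @return A [stoich_model()].
#' @export
read_model <- function(path, dialect = c("bigg_json", "sbml"), cap = 1000) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  switch(dialect,
         bigg_json = read_model_bigg_json(path, cap),
         sbml = read_model_sbml(path, cap))
}

#' Write a stoichiometric model to disk
#'
#' @param model A [stoich_model()].
#' @param path Output path.
#' @param dialect One of `"bigg_json"`, `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("bigg_json", "sbml")) {
  dialect <- match.arg(dialect)
  validate_model(model)
  switch(dialect,
         bigg_json = write_model_bigg_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

clamp_bound <- function(x, cap) max(-cap, min(cap, x))

read_model_bigg_json <- function(path, cap) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("malformed BiGG JSON '", path,
         "': missing 'metabolites' or 'reactions' element", call. = FALSE)
  }
  mets <- lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("malformed BiGG JSON: metabolite without id",
                            call. = FALSE)
    metabolite(m$id, name = if (is.null(m$name)) m$id else m$name)
  })
  objective <- NULL
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("malformed BiGG JSON: reaction without id",
                            call. = FALSE)
    if (is.null(r$metabolites) || length(r$metabolites) == 0L) {
      stop("malformed BiGG JSON: reaction '", r$id, "' has no metabolites",
           call. = FALSE)
    }
    st <- unlist(r$metabolites)
    lb <- if (is.null(r$lower_bound)) 0 else r$lower_bound
    ub <- if (is.null(r$upper_bound)) 1000 else r$upper_bound
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      objective <<- r$id
    }
    reaction(r$id, st, clamp_bound(lb, cap), clamp_bound(ub, cap),
             name = if (is.null(r$name)) r$id else r$name)
  })
  met_ids <- vapply(mets, `[[`, character(1), "id")
  for (r in rxns) {
    bad <- setdiff(names(r$stoichiometry), met_ids)
    if (length(bad)) {
      stop("malformed BiGG JSON '", path, "': reaction '", r$id,
           "' references undeclared metabolite(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(objective)) {
    # fall back on the conventional BiGG biomass naming
    ids <- vapply(rxns, `[[`, character(1), "id")
    hit <- grep("^BIOMASS", ids, value = TRUE)
    if (length(hit)) objective <- hit[[1]] else
      stop("BiGG JSON '", path, "': no objective reaction declared",
           call. = FALSE)
  }
  model_id <- if (is.null(doc$id)) basename(path) else doc$id
  stoich_model(model_id, mets, rxns, objective)
}

write_model_bigg_json <- function(model, path) {
  doc <- list(
    id = model$id,
    metabolites = unname(lapply(model$metabolites, function(m) {
      list(id = m$id, name = m$name, compartment = m$compartment)
    })),
    reactions = unname(lapply(model$reactions, function(r) {
      list(id = r$id, name = r$name,
           metabolites = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           objective_coefficient = if (identical(r$id, model$objective)) 1 else 0)
    })),
    genes = list(),
    compartments = as.list(stats::setNames(
      unique(vapply(model$metabolites, `[[`, character(1), "compartment")),
      unique(vapply(model$metabolites, `[[`, character(1), "compartment")))),
    version = "1"
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
}

# --- SBML L3 / FBC -----------------------------------------------------------

# SBML prefixes species/reaction ids with "M_"/"R_"; strip on read, add on write.
strip_sbml_prefix <- function(id, prefix) sub(paste0("^", prefix), "", id)

read_model_sbml <- function(path, cap) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  find <- function(node, what) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  }
  model_node <- find(doc, "model")
  if (length(model_node) == 0L) {
    stop("malformed SBML '", path, "': no <model> element", call. = FALSE)
  }
  model_node <- model_node[[1]]
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- basename(path)

  params <- find(model_node, "parameter")
  param_vals <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  species <- find(model_node, "species")
  if (length(species) == 0L) {
    stop("malformed SBML '", path, "': no species declared", call. = FALSE)
  }
  mets <- lapply(species, function(s) {
    id <- xml2::xml_attr(s, "id")
    if (is.na(id)) stop("malformed SBML: species without id", call. = FALSE)
    nm <- xml2::xml_attr(s, "name")
    metabolite(strip_sbml_prefix(id, "M_"),
               name = if (is.na(nm)) strip_sbml_prefix(id, "M_") else nm)
  })

  rxn_nodes <- find(model_node, "reaction")
  objective <- NULL
  flux_obj <- find(model_node, "fluxObjective")
  if (length(flux_obj)) {
    objective <- strip_sbml_prefix(
      xml2::xml_attr(flux_obj[[1]], "reaction"), "R_")
  }
  bound_of <- function(node, attr, default) {
    ref <- xml2::xml_attr(node, attr)
    if (!is.na(ref) && ref %in% names(param_vals)) return(param_vals[[ref]])
    default
  }
  rxns <- lapply(rxn_nodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    if (is.na(id)) stop("malformed SBML: reaction without id", call. = FALSE)
    sid <- strip_sbml_prefix(id, "R_")
    refs <- function(kind, sign) {
      lst <- xml2::xml_find_all(rn, sprintf(
        ".//*[local-name()='%s']/*[local-name()='speciesReference']", kind))
      if (length(lst) == 0L) return(numeric(0))
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(lst, "stoichiometry")),
        strip_sbml_prefix(xml2::xml_attr(lst, "species"), "M_"))
    }
    st <- c(refs("listOfReactants", -1), refs("listOfProducts", +1))
    if (length(st) == 0L) {
      stop("malformed SBML: reaction '", sid, "' has no participants",
           call. = FALSE)
    }
    # merge duplicated species (legal in SBML)
    st <- tapply(st, names(st), sum)
    reversible <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lb <- bound_of(rn, "lowerFluxBound", if (reversible) -1000 else 0)
    ub <- bound_of(rn, "upperFluxBound", 1000)
    nm <- xml2::xml_attr(rn, "name")
    reaction(sid, stats::setNames(as.numeric(st), names(st)),
             clamp_bound(lb, cap), clamp_bound(ub, cap),
             name = if (is.na(nm)) sid else nm)
  })
  if (is.null(objective)) {
    ids <- vapply(rxns, `[[`, character(1), "id")
    hit <- grep("^BIOMASS", ids, value = TRUE)
    if (length(hit)) objective <- hit[[1]] else
      stop("SBML '", path, "': no active flux objective found", call. = FALSE)
  }
  stoich_model(strip_sbml_prefix(model_id, "^"), mets, rxns, objective)
}

write_model_sbml <- function(model, path) {
  bnds <- reaction_bounds(model)
  uniq <- sort(unique(c(bnds)))
  pid <- function(v) sprintf("bnd_%d", match(v, uniq))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w(sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)))
  comps <- unique(vapply(model$metabolites, `[[`, character(1), "compartment"))
  w("    <listOfCompartments>")
  for (cp in comps) {
    w(sprintf('      <compartment id="%s" constant="true"/>', esc(cp)))
  }
  w("    </listOfCompartments>")
  w("    <listOfSpecies>")
  for (m in model$metabolites) {
    w(sprintf(paste0('      <species id="M_%s" name="%s" compartment="%s" ',
                     'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                     'constant="false"/>'),
              esc(m$id), esc(m$name), esc(m$compartment)))
  }
  w("    </listOfSpecies>")
  w("    <listOfParameters>")
  for (i in seq_along(uniq)) {
    w(sprintf('      <parameter id="bnd_%d" value="%s" constant="true"/>',
              i, format(uniq[i], digits = 17)))
  }
  w("    </listOfParameters>")
  w("    <listOfReactions>")
  for (r in model$reactions) {
    rev <- if (r$lower_bound < 0) "true" else "false"
    w(sprintf(paste0('      <reaction id="R_%s" name="%s" reversible="%s" ',
                     'fast="false" fbc:lowerFluxBound="%s" ',
                     'fbc:upperFluxBound="%s">'),
              esc(r$id), esc(r$name), rev,
              pid(r$lower_bound), pid(r$upper_bound)))
    st <- r$stoichiometry
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      w("        <listOfReactants>")
      for (k in seq_along(reac)) {
        w(sprintf(paste0('          <speciesReference species="M_%s" ',
                         'stoichiometry="%s" constant="true"/>'),
                  esc(names(reac)[k]), format(-reac[[k]], digits = 17)))
      }
      w("        </listOfReactants>")
    }
    if (length(prod)) {
      w("        <listOfProducts>")
      for (k in seq_along(prod)) {
        w(sprintf(paste0('          <speciesReference species="M_%s" ',
                         'stoichiometry="%s" constant="true"/>'),
                  esc(names(prod)[k]), format(prod[[k]], digits = 17)))
      }
      w("        </listOfProducts>")
    }
    w("      </reaction>")
  }
  w("    </listOfReactions>")
  w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  w("        <fbc:listOfFluxObjectives>")
  w(sprintf(paste0('          <fbc:fluxObjective fbc:reaction="R_%s" ',
                   'fbc:coefficient="1"/>'), esc(model$objective)))
  w("        </fbc:listOfFluxObjectives>")
  w("      </fbc:objective>")
  w("    </fbc:listOfObjectives>")
  w("  </model>")
  w("</sbml>")
}
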