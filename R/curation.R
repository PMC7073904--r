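#' Declarative model curation
#'
#' Curation recipes are ordered lists of small declarative edits
#' (`curation_edit`) applied to a [stoich_model()] by [apply_curation()].
#' The two shipped recipes, [base_curation_recipe()] and
#' [serine_cycle_recipe()], encode the adjustments that turn the iML1515
#' reconstruction of *E. coli* into (i) the C1-auxotroph model in which
#' 5,10-methylene-THF can only be formed by the spontaneous condensation of
#' formaldehyde with THF, and (ii) the hypothetical serine-cycle
#' methylotroph growing on formaldehyde as sole carbon source.
#'
#' @name curation
NULL

CURATION_ACTIONS <- c("remove_reaction", "add_reaction", "set_bounds",
                      "make_irreversible", "make_reversible",
                      "replace_stoichiometry", "knockout")

#' Create a single curation edit
#'
#' @param action One of `r paste0('"', CURATION_ACTIONS, '"', collapse = ", ")`.
#' @param target Reaction id the edit applies to.
#' @param payload For `add_reaction` a [reaction()]; for
#'   `replace_stoichiometry` a named stoichiometry vector; for `set_bounds`
#'   a numeric `c(lower, upper)`; otherwise `NULL`.
#' @param note Free-text rationale carried into the edit log.
#' @return A list of class `curation_edit`.
#' @export
curation_edit <- function(action, target, payload = NULL, note = "") {
  action <- match.arg(action, CURATION_ACTIONS)
  if (action == "add_reaction" && !inherits(payload, "reaction")) {
    stop("add_reaction edit needs a reaction() payload", call. = FALSE)
  }
  if (action == "replace_stoichiometry" &&
      (is.null(names(payload)) || !is.numeric(payload))) {
    stop("replace_stoichiometry edit needs a named numeric payload",
         call. = FALSE)
  }
  if (action == "set_bounds" && (!is.numeric(payload) || length(payload) != 2L)) {
    stop("set_bounds edit needs a numeric c(lower, upper) payload",
         call. = FALSE)
  }
  structure(list(action = action, target = target, payload = payload,
                 note = note), class = "curation_edit")
}

#' Apply a curation recipe to a model
#'
#' Returns a new model; the input model is never modified. Each edit is
#' checked against its preconditions: removal/modification targets must
#' exist, added reactions must not. `add_reaction` creates any referenced
#' metabolites that the model lacks (compartment inferred from the id
#' suffix), recording them in the edit log.
#'
#' @param model A [stoich_model()].
#' @param recipe List of [curation_edit()]s.
#' @return The curated model, with the cumulative edit log in
#'   `attr(, "edit_log")` (a data.frame: step, action, target, before, after).
#' @export
apply_curation <- function(model, recipe) {
  validate_model(model)
  log <- attr(model, "edit_log")
  if (is.null(log)) {
    log <- data.frame(step = integer(), action = character(),
                      target = character(), before = character(),
                      after = character(), stringsAsFactors = FALSE)
  }
  fmt_rxn <- function(r) {
    sprintf("%s [%g, %g]",
            paste(sprintf("%g %s", r$stoichiometry, names(r$stoichiometry)),
                  collapse = " + "),
            r$lower_bound, r$upper_bound)
  }
  for (edit in recipe) {
    if (!inherits(edit, "curation_edit")) {
      stop("recipe elements must be curation_edit objects", call. = FALSE)
    }
    a <- edit$action; tgt <- edit$target
    before <- if (tgt %in% names(model$reactions)) {
      fmt_rxn(model$reactions[[tgt]])
    } else "<absent>"
    if (a == "add_reaction") {
      if (tgt %in% names(model$reactions)) {
        stop("curation error: add_reaction '", tgt, "' already in model",
             call. = FALSE)
      }
      new_mets <- setdiff(names(edit$payload$stoichiometry),
                          names(model$metabolites))
      for (m in new_mets) {
        model$metabolites[[m]] <- metabolite(m)
      }
      model$reactions[[tgt]] <- edit$payload
      after <- fmt_rxn(edit$payload)
      if (length(new_mets)) {
        after <- paste0(after, " (+metabolites: ",
                        paste(new_mets, collapse = ", "), ")")
      }
    } else {
      if (!tgt %in% names(model$reactions)) {
        stop("curation error: ", a, " target '", tgt, "' not in model",
             call. = FALSE)
      }
      r <- model$reactions[[tgt]]
      if (a == "remove_reaction") {
        model$reactions[[tgt]] <- NULL
        after <- "<removed>"
      } else if (a == "set_bounds") {
        r$lower_bound <- as.numeric(edit$payload[[1]])
        r$upper_bound <- as.numeric(edit$payload[[2]])
        model$reactions[[tgt]] <- r
        after <- fmt_rxn(r)
      } else if (a == "make_irreversible") {
        r$lower_bound <- max(0, r$lower_bound)
        model$reactions[[tgt]] <- r
        after <- fmt_rxn(r)
      } else if (a == "make_reversible") {
        r$lower_bound <- min(r$lower_bound, -1000)
        model$reactions[[tgt]] <- r
        after <- fmt_rxn(r)
      } else if (a == "replace_stoichiometry") {
        pay <- edit$payload
        storage.mode(pay) <- "double"
        r$stoichiometry <- pay[pay != 0]
        model$reactions[[tgt]] <- r
        after <- fmt_rxn(r)
      } else if (a == "knockout") {
        r$lower_bound <- 0
        r$upper_bound <- 0
        model$reactions[[tgt]] <- r
        after <- fmt_rxn(r)
      }
    }
    log <- rbind(log, data.frame(step = nrow(log) + 1L, action = a,
                                 target = tgt, before = before, after = after,
                                 stringsAsFactors = FALSE))
  }
  validate_model(model)
  attr(model, "edit_log") <- log
  model
}

#' Write a curation edit log as TSV
#' @param model A curated model (output of [apply_curation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edit_log <- function(model, path) {
  log <- attr(model, "edit_log")
  if (is.null(log)) stop("model carries no edit log", call. = FALSE)
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Curation recipe for the C1-auxotroph model
#'
#' Encodes the adjustments that convert iML1515 into the model of the
#' engineered C1 auxotroph: reactions absent from *E. coli* in vivo (POR5,
#' GLYCK) are removed; the transhydrogenase THD2pp is corrected to
#' translocate one proton; oxygen-sensitive formate lyases (PFL, OBTFL) are
#' removed; FTHFLi is removed so THF cannot be charged directly with
#' formate; FTHFD, GARFT and AICART are made irreversible so nucleotide
#' degradation cannot charge THF; the thymidine periplasmic symporter
#' THYMt3pp is made reversible (thymidine supplementation rescues growth);
#' the glycine cleavage system (GLYCL) and serine hydroxymethyltransferase
#' (GHMT2r) are knocked out, mirroring the gcvTHP and glyA deletions; and
#' the spontaneous condensation THFSPONT (thf_c + fald_c -> mlthf_c +
#' h2o_c) is added, irreversibly -- its flux is interpreted as the net
#' condensation rate (condensation minus 5,10-methylene-THF dissociation).
#'
#' @return Ordered list of [curation_edit()]s.
#' @export
base_curation_recipe <- function() {
  list(
    curation_edit("remove_reaction", "POR5", note = "not present in E. coli cells"),
    curation_edit("remove_reaction", "GLYCK", note = "not present in E. coli cells"),
    curation_edit("replace_stoichiometry", "THD2pp",
                  payload = c(h_p = -1, nadh_c = -1, nadp_c = -1,
                              h_c = 1, nad_c = 1, nadph_c = 1),
                  note = "transhydrogenase translocates one proton, not two"),
    curation_edit("remove_reaction", "PFL", note = "oxygen-sensitive enzyme"),
    curation_edit("remove_reaction", "OBTFL", note = "oxygen-sensitive enzyme"),
    curation_edit("remove_reaction", "FTHFLi",
                  note = "would charge THF directly with formate"),
    curation_edit("make_irreversible", "FTHFD",
                  note = "block THF charging via nucleotide degradation"),
    curation_edit("make_irreversible", "GARFT",
                  note = "block THF charging via nucleotide degradation"),
    curation_edit("make_irreversible", "AICART",
                  note = "block THF charging via nucleotide degradation"),
    curation_edit("make_reversible", "THYMt3pp",
                  note = "thymidine supplementation rescues growth"),
    curation_edit("knockout", "GLYCL", note = "gcvTHP deletion"),
    curation_edit("knockout", "GHMT2r", note = "glyA deletion"),
    curation_edit("add_reaction", "THFSPONT",
                  payload = reaction(
                    "THFSPONT",
                    c(thf_c = -1, fald_c = -1, mlthf_c = 1, h2o_c = 1),
                    lower_bound = 0, upper_bound = 1000,
                    name = "spontaneous formaldehyde-THF condensation (net)"),
                  note = "spontaneous formaldehyde-THF condensation")
  )
}

#' Curation recipe for the serine-cycle methylotroph model
#'
#' Applied on top of [base_curation_recipe()], this recipe equips the model
#' to grow on formaldehyde as sole carbon source via the serine cycle and
#' the ethylmalonyl-CoA cycle: potential carbon-fixation shortcuts are
#' removed (GLXCL, GLYCL, THRD, THRA2, THRA, SERD_L); an NAD-dependent
#' formate dehydrogenase (FDH) provides reducing power from formate;
#' crotonyl-CoA carboxylase/reductase (EtMaCoA) and propionyl-CoA
#' carboxylase (MMCDr) implement the ethylmalonyl-CoA cycle, with
#' methylmalonyl-CoA mutase (MMM) made reversible for recycling; and the
#' serine-cycle reactions SGAT1, SGAT2, MTK and MCL are added. Serine
#' hydroxymethyltransferase (GHMT2r, knocked out in the auxotroph recipe to
#' model the glyA deletion) is restored to reversibility: the hypothetical
#' serine-cycle organism requires it to condense glycine with
#' 5,10-methylene-THF, the cycle's carbon-entry step. The two
#' aminotransferases SGAT1/SGAT2 are added reversible; in the assimilatory
#' direction SGAT2 runs glyoxylate + glutamate -> glycine + 2-oxoglutarate.
#'
#' FDH stoichiometry (not fixed by the reconstruction) is the standard
#' cytosolic NAD-dependent formate dehydrogenase,
#' `for_c + nad_c -> co2_c + nadh_c`.
#'
#' @return Ordered list of [curation_edit()]s.
#' @export
serine_cycle_recipe <- function() {
  rxn <- function(id, st, rev = FALSE, name = id) {
    reaction(id, st, lower_bound = if (rev) -1000 else 0,
             upper_bound = 1000, name = name)
  }
  list(
    curation_edit("remove_reaction", "GLXCL", note = "avoid carbon-fixation cycles"),
    curation_edit("remove_reaction", "GLYCL", note = "avoid carbon-fixation cycles"),
    curation_edit("remove_reaction", "THRD", note = "avoid carbon-fixation cycles"),
    curation_edit("remove_reaction", "THRA2", note = "avoid carbon-fixation cycles"),
    curation_edit("remove_reaction", "THRA", note = "avoid carbon-fixation cycles"),
    curation_edit("remove_reaction", "SERD_L", note = "avoid carbon-fixation cycles"),
    curation_edit("add_reaction", "FDH",
                  payload = rxn("FDH", c(for_c = -1, nad_c = -1,
                                         co2_c = 1, nadh_c = 1),
                                name = "NAD-dependent formate dehydrogenase"),
                  note = "reducing power from formate"),
    curation_edit("add_reaction", "EtMaCoA",
                  payload = rxn("EtMaCoA",
                                c(b2coa_c = -1, nadph_c = -1, co2_c = -1,
                                  q8_c = -1, h2o_c = -1,
                                  glx_c = 1, ppcoa_c = 1, nadp_c = 1,
                                  q8h2_c = 1),
                                name = "crotonyl-CoA carboxylase (lumped)"),
                  note = "ethylmalonyl-CoA cycle"),
    curation_edit("add_reaction", "MMCDr",
                  payload = rxn("MMCDr",
                                c(ppcoa_c = -1, atp_c = -1, hco3_c = -1,
                                  mmcoa__S_c = 1, adp_c = 1, h_c = 1,
                                  pi_c = 1),
                                name = "propionyl-CoA carboxylase"),
                  note = "recycle propionyl-CoA"),
    curation_edit("make_reversible", "MMM",
                  note = "allow methylmalonyl-CoA recycling"),
    curation_edit("add_reaction", "SGAT1",
                  payload = rxn("SGAT1",
                                c(ser__L_c = -1, akg_c = -1,
                                  glu__L_c = 1, hpyr_c = 1), rev = TRUE,
                                name = "serine-hydroxypyruvate aminotransferase"),
                  note = "serine cycle"),
    curation_edit("add_reaction", "SGAT2",
                  payload = rxn("SGAT2",
                                c(gly_c = -1, akg_c = -1,
                                  glx_c = 1, glu__L_c = 1), rev = TRUE,
                                name = "glycine-glyoxylate aminotransferase"),
                  note = "serine cycle"),
    curation_edit("add_reaction", "MTK",
                  payload = rxn("MTK",
                                c(mal__L_c = -1, atp_c = -1, coa_c = -1,
                                  malylcoa_c = 1, adp_c = 1, pi_c = 1),
                                name = "malate thiokinase"),
                  note = "serine cycle"),
    curation_edit("add_reaction", "MCL",
                  payload = rxn("MCL",
                                c(malylcoa_c = -1, accoa_c = 1, glx_c = 1),
                                name = "malyl-CoA lyase"),
                  note = "serine cycle"),
    curation_edit("set_bounds", "GHMT2r", payload = c(-1000, 1000),
                  note = "restore SHMT: carbon entry of the serine cycle")
  )
}

#' Serialize / deserialize a curation recipe as JSON
#'
#' @param recipe List of [curation_edit()]s.
#' @param path Output (or input) path.
#' @return `write_recipe_json` returns `path` invisibly;
#'   `read_recipe_json` returns the recipe.
#' @export
write_recipe_json <- function(recipe, path) {
  doc <- lapply(recipe, function(e) {
    p <- e$payload
    payload <- if (inherits(p, "reaction")) {
      list(kind = "reaction", id = p$id, name = p$name,
           stoichiometry = as.list(p$stoichiometry),
           lower_bound = p$lower_bound, upper_bound = p$upper_bound)
    } else if (is.numeric(p) && !is.null(names(p))) {
      list(kind = "stoichiometry", coefficients = as.list(p))
    } else if (is.numeric(p)) {
      list(kind = "bounds", lower = p[[1]], upper = p[[2]])
    } else NULL
    list(action = e$action, target = e$target, payload = payload,
         note = e$note)
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_recipe_json
#' @export
read_recipe_json <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc, function(e) {
    payload <- NULL
    if (length(e$payload) && !is.null(e$payload$kind)) {
      p <- e$payload
      payload <- switch(p$kind,
        reaction = reaction(p$id, unlist(p$stoichiometry),
                            p$lower_bound, p$upper_bound, name = p$name),
        stoichiometry = unlist(p$coefficients),
        bounds = c(p$lower, p$upper))
    }
    curation_edit(e$action, e$target, payload,
                  note = if (is.null(e$note)) "" else e$note)
  })
}
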