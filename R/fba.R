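#' Flux balance analysis and phenotypic phase planes
#'
#' FBA solves the linear program max c'v subject to S v = 0 and
#' lb <= v <= ub, using the package's deterministic two-phase simplex
#' kernel; every reported optimum is re-checked against the steady-state
#' condition independently of the solver's own status. Model bounds are
#' finite by construction (capped at +/-1000 on input).
#'
#' @name fba
NULL

LP_RESIDUAL_TOL <- 1e-9

#' Flux balance analysis
#'
#' Maximizes the model's biomass objective under a medium.
#'
#' @param model A curated [stoich_model()].
#' @param medium Optional [medium_spec()]; applied before solving.
#' @return A `flux_solution`: list with `objective` (h^-1 for biomass),
#'   `fluxes` (named vector, mmol gCDW^-1 h^-1), `status` (`"optimal"`,
#'   `"infeasible"`, or `"solver_failure"`) and `residual` (max |S v|).
#' @export
fba <- function(model, medium = NULL) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  validate_model(model)
  S <- stoichiometric_matrix(model)
  bd <- reaction_bounds(model)
  obj <- as.numeric(names(model$reactions) == model$objective)
  sol <- solve_lp(S, bd[, "lower"], bd[, "upper"], obj, maximize = TRUE)
  fluxes <- if (is.null(sol$x)) NULL else
    stats::setNames(sol$x, names(model$reactions))
  structure(list(objective = sol$objective, fluxes = fluxes,
                 status = sol$status,
                 residual = if (is.null(sol$residual)) NA_real_ else sol$residual,
                 model_id = model$id,
                 scenario = attr(medium, "scenario")),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> model ", x$model_id,
      if (!is.null(x$scenario)) paste0(" [", x$scenario, "]"), "\n",
      "  status:    ", x$status, "\n",
      "  objective: ", format(x$objective), " h^-1\n", sep = "")
  invisible(x)
}

#' Phenotypic phase plane of a reaction against growth
#'
#' For each growth rate on a grid, the biomass flux is fixed and the target
#' reaction's flux is minimized and maximized, tracing the feasible
#' envelope. The slope and intercept of the lower envelope are obtained by
#' ordinary least squares over the feasible grid points; the slope of this
#' lower bound is the stoichiometric demand for the target flux per unit
#' growth (mmol gCDW^-1). The intercept is flagged when it exceeds 1% of
#' slope x max feasible growth, signalling a nonlinear envelope for which
#' the fitted line is a poor summary.
#'
#' @param model A curated [stoich_model()].
#' @param medium A [medium_spec()].
#' @param reaction_id Target reaction (default `"THFSPONT"`).
#' @param growth_grid Strictly increasing numeric grid of growth rates
#'   (h^-1), >= 3 points. Default: 30 evenly spaced points from 0 to the
#'   FBA maximum.
#' @param n_grid Number of grid points for the default grid.
#' @return A `phase_plane`: list with `grid` (data.frame: mu, min_flux,
#'   max_flux, feasible), `slope`, `intercept`, `intercept_flagged`,
#'   `mu_max`, `reaction_id`, `scenario`.
#' @export
phase_plane <- function(model, medium, reaction_id = "THFSPONT",
                        growth_grid = NULL, n_grid = 30) {
  model <- apply_medium(model, medium)
  get_reaction(model, reaction_id, context = "phase_plane")
  S <- stoichiometric_matrix(model)
  bd <- reaction_bounds(model)
  rxn_ids <- names(model$reactions)
  j_bio <- match(model$objective, rxn_ids)
  j_tgt <- match(reaction_id, rxn_ids)

  if (is.null(growth_grid)) {
    top <- fba(model)
    if (top$status != "optimal") {
      stop("phase_plane: model infeasible under this medium; cannot build ",
           "default grid", call. = FALSE)
    }
    growth_grid <- seq(0, top$objective, length.out = n_grid)
  }
  if (length(growth_grid) < 3L || any(diff(growth_grid) <= 0)) {
    stop("growth_grid must be strictly increasing with >= 3 points",
         call. = FALSE)
  }

  obj <- as.numeric(seq_along(rxn_ids) == j_tgt)
  lo <- hi <- rep(NA_real_, length(growth_grid))
  feasible <- logical(length(growth_grid))
  for (k in seq_along(growth_grid)) {
    lb <- bd[, "lower"]; ub <- bd[, "upper"]
    lb[j_bio] <- ub[j_bio] <- growth_grid[k]
    smin <- solve_lp(S, lb, ub, obj, maximize = FALSE)
    if (smin$status != "optimal") next
    smax <- solve_lp(S, lb, ub, obj, maximize = TRUE)
    if (smax$status != "optimal") next
    feasible[k] <- TRUE
    lo[k] <- smin$objective
    hi[k] <- smax$objective
  }
  if (!any(feasible)) {
    stop("phase_plane: no feasible point on the growth grid; shrink the ",
         "grid towards lower growth rates", call. = FALSE)
  }
  grid <- data.frame(mu = growth_grid, min_flux = lo, max_flux = hi,
                     feasible = feasible)
  fit_df <- grid[grid$feasible, , drop = FALSE]
  if (nrow(fit_df) >= 2L) {
    fit <- stats::lm(min_flux ~ mu, data = fit_df)
    slope <- unname(stats::coef(fit)[["mu"]])
    intercept <- unname(stats::coef(fit)[["(Intercept)"]])
    # envelopes are often exactly linear; summary.lm warns on perfect fits
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
  }
  mu_max <- max(fit_df$mu)
  flagged <- is.finite(intercept) && is.finite(slope) &&
    abs(intercept) > 0.01 * abs(slope) * mu_max
  structure(list(grid = grid, slope = slope, intercept = intercept,
                 r_squared = r2, intercept_flagged = flagged,
                 mu_max = mu_max, reaction_id = reaction_id,
                 model_id = model$id, scenario = attr(medium, "scenario")),
            class = "phase_plane")
}

#' @export
print.phase_plane <- function(x, ...) {
  cat("<phase_plane> ", x$reaction_id, " vs growth, model ", x$model_id,
      if (!is.null(x$scenario)) paste0(" [", x$scenario, "]"), "\n",
      "  slope:     ", format(x$slope), " mmol gCDW^-1\n",
      "  intercept: ", format(x$intercept), " mmol gCDW^-1 h^-1",
      if (isTRUE(x$intercept_flagged)) "  ** flagged **", "\n",
      "  feasible growth up to ", format(x$mu_max), " h^-1 (",
      sum(x$grid$feasible), "/", nrow(x$grid), " grid points)\n", sep = "")
  invisible(x)
}

#' Export a phase plane as TSV (grid) and JSON (fit summary)
#' @param pp A [phase_plane()].
#' @param tsv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, a list of the written paths.
#' @export
write_phase_plane <- function(pp, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(pp$grid, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(reaction_id = pp$reaction_id, model_id = pp$model_id,
           scenario = pp$scenario, slope = pp$slope,
           intercept = pp$intercept, r_squared = pp$r_squared,
           intercept_flagged = pp$intercept_flagged, mu_max = pp$mu_max),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}

#' Growth-rate measurement summary
#'
#' @param mean_mu Mean growth rate, h^-1.
#' @param sd Standard deviation, h^-1 (>= 0).
#' @param n Number of replicates (>= 1).
#' @return A `growth_measurement`.
#' @export
growth_measurement <- function(mean_mu, sd, n) {
  stopifnot(sd >= 0, n >= 1)
  structure(list(mean_mu = mean_mu, sd = sd, n = as.integer(n)),
            class = "growth_measurement")
}

#' Derive the condensation flux from a measured growth rate
#'
#' Intersects the lower envelope of the phase plane with the measured
#' growth rate: flux = slope * mu + intercept, with the SD propagated
#' linearly (sd_flux = slope * sd_mu).
#'
#' @param pp A [phase_plane()].
#' @param g A [growth_measurement()].
#' @return A `flux_estimate`: list with `flux`, `sd` (mmol gCDW^-1 h^-1)
#'   and provenance (`scenario`, `slope`, `intercept`, `growth`).
#' @export
derive_flux <- function(pp, g) {
  stopifnot(inherits(pp, "phase_plane"), inherits(g, "growth_measurement"))
  if (g$mean_mu < min(pp$grid$mu[pp$grid$feasible]) ||
      g$mean_mu > pp$mu_max) {
    stop("measured growth rate ", g$mean_mu,
         " h^-1 outside the feasible range of the phase plane [",
         format(min(pp$grid$mu[pp$grid$feasible])), ", ",
         format(pp$mu_max), "]", call. = FALSE)
  }
  structure(list(flux = pp$slope * g$mean_mu + pp$intercept,
                 sd = abs(pp$slope) * g$sd,
                 scenario = pp$scenario, slope = pp$slope,
                 intercept = pp$intercept, growth = g),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat("<flux_estimate> ", format(signif(x$flux, 2)), " +/- ",
      format(signif(x$sd, 2)), " mmol gCDW^-1 h^-1",
      if (!is.null(x$scenario)) paste0(" [", x$scenario, "]"), "\n", sep = "")
  invisible(x)
}

#' Maximal growth rate supported by a condensation flux
#'
#' Inverts the lower envelope of a phase plane (computed for the
#' serine-cycle model on formaldehyde as sole carbon source):
#' mu = (flux - intercept) / slope, sd_mu = sd_flux / slope.
#'
#' @param pp A [phase_plane()] with positive slope.
#' @param fe A [derive_flux()] estimate.
#' @return A [growth_measurement()]-like list (`mean_mu`, `sd`, `n`) with
#'   provenance attributes.
#' @export
derive_max_growth <- function(pp, fe) {
  stopifnot(inherits(pp, "phase_plane"), inherits(fe, "flux_estimate"))
  if (!is.finite(pp$slope) || pp$slope <= 0) {
    stop("phase-plane slope must be positive to invert; got ",
         format(pp$slope), call. = FALSE)
  }
  out <- growth_measurement((fe$flux - pp$intercept) / pp$slope,
                            fe$sd / pp$slope, fe$growth$n)
  attr(out, "slope") <- pp$slope
  attr(out, "scenario") <- pp$scenario
  out
}
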