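#' Growth curves and exponential fitting
#'
#' Cell densities in exponential phase follow N = N0 * exp(mu * t). Fitting
#' is done by ordinary least squares of log(OD) against time over an
#' automatically selected window, which under multiplicative (lognormal)
#' measurement noise is the maximum-likelihood fit of the stated model.
#'
#' @name growth
NULL

#' Create a growth curve
#'
#' @param times Strictly increasing times, h.
#' @param od Positive OD600 readings, same length.
#' @param meta Optional named list of labels (strain, scenario, replicate).
#' @return A `growth_curve` (data.frame with columns `time_h`, `od600`).
#' @export
growth_curve <- function(times, od, meta = list()) {
  stopifnot(length(times) == length(od))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  if (any(od <= 0)) stop("od must be positive", call. = FALSE)
  structure(data.frame(time_h = times, od600 = od),
            meta = meta, class = c("growth_curve", "data.frame"))
}

#' Fit an exponential growth model to a curve
#'
#' Scans all contiguous windows of at least `min_points` readings whose OD
#' lies inside `od_range` (the photometer's reliable operating range and
#' the usual exponential regime), fits log(OD) ~ time by OLS in each, and
#' keeps the window with the highest r-squared, preferring the longest
#' among near-ties. If no reading falls in `od_range` the whole curve is
#' used as the candidate window.
#'
#' @param curve A [growth_curve()].
#' @param od_range OD600 window considered exponential (default 0.04-0.5).
#' @param min_points Minimum window length (default 4).
#' @param r2_threshold Minimum acceptable r-squared (default 0.95).
#' @return An `exp_fit`: list with `mu` (h^-1), `mu_sd`, `n0`, `window`
#'   (start/end indices into the curve), `r2`.
#' @export
fit_exponential <- function(curve, od_range = c(0.04, 0.5), min_points = 4,
                            r2_threshold = 0.95) {
  stopifnot(inherits(curve, "growth_curve"))
  if (nrow(curve) < 6L) stop("need at least 6 readings", call. = FALSE)
  in_range <- which(curve$od600 >= od_range[1] & curve$od600 <= od_range[2])
  idx <- if (length(in_range) >= min_points) {
    seq(min(in_range), max(in_range))
  } else {
    seq_len(nrow(curve))
  }
  tt <- curve$time_h
  yy <- log(curve$od600)
  best <- NULL
  # closed-form OLS per window keeps the O(n^2) scan cheap
  for (i in idx) {
    for (j in idx[idx >= i + min_points - 1L]) {
      win <- seq(i, j)
      t <- tt[win]; y <- yy[win]
      vt <- stats::var(t); vy <- stats::var(y); cv <- stats::cov(t, y)
      r2 <- if (vy <= 0) 1 else min(1, cv^2 / (vt * vy))
      # prefer higher r2; among near-ties (within 1e-9), the longer window
      if (is.null(best) || r2 > best$r2 + 1e-9 ||
          (r2 > best$r2 - 1e-9 && length(win) > length(best$win))) {
        best <- list(win = win, r2 = r2)
      }
    }
  }
  win <- best$win
  fit <- stats::lm(yy[win] ~ tt[win])
  mu <- unname(stats::coef(fit)[[2]])
  r2 <- best$r2
  if (r2 < r2_threshold || mu <= 0) {
    stop("exponential fit failed: best window [",
         win[1], ", ", win[length(win)], "] has r2 = ",
         format(r2), " and mu = ", format(mu),
         " h^-1 (need r2 >= ", r2_threshold, " and mu > 0)", call. = FALSE)
  }
  mu_sd <- suppressWarnings(summary(fit)$coefficients[2, "Std. Error"])
  structure(list(mu = mu, mu_sd = mu_sd,
                 n0 = exp(unname(stats::coef(fit)[[1]])),
                 window = c(start = win[1], end = win[length(win)]),
                 r2 = r2),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("<exp_fit> mu = ", format(signif(x$mu, 4)), " +/- ",
      format(signif(x$mu_sd, 2)), " h^-1, N0 = ", format(signif(x$n0, 3)),
      ", window [", x$window[1], ", ", x$window[2], "], r2 = ",
      format(round(x$r2, 4)), "\n", sep = "")
  invisible(x)
}

#' Doubling time from a growth rate
#'
#' @param mu Growth rate, h^-1 (> 0).
#' @return ln(2) / mu, h.
#' @export
doubling_time <- function(mu) {
  if (any(mu <= 0)) stop("doubling time undefined for mu <= 0", call. = FALSE)
  log(2) / mu
}

#' Welch two-sample t-test from summary statistics
#'
#' Two-sided test on two groups given (mean, sd, n). The unequal-variance
#' (Welch) form is used since the groups' variances are not assumed equal;
#' setting `pooled = TRUE` gives the classical equal-variance Student form.
#'
#' @param a,b Numeric vectors `c(mean, sd, n)` or lists with those names.
#' @param pooled Use the pooled-variance Student test instead of Welch.
#' @return Two-sided p-value.
#' @export
compare_groups <- function(a, b, pooled = FALSE) {
  pick <- function(g) {
    if (is.list(g)) c(g$mean, g$sd, g$n) else as.numeric(g)
  }
  a <- pick(a); b <- pick(b)
  stopifnot(length(a) == 3L, length(b) == 3L, a[2] >= 0, b[2] >= 0,
            a[3] >= 2, b[3] >= 2)
  if (a[2] == 0 && b[2] == 0) {
    return(if (isTRUE(all.equal(a[1], b[1]))) 1 else 0)
  }
  if (pooled) {
    sp2 <- ((a[3] - 1) * a[2]^2 + (b[3] - 1) * b[2]^2) / (a[3] + b[3] - 2)
    se <- sqrt(sp2 * (1 / a[3] + 1 / b[3]))
    df <- a[3] + b[3] - 2
  } else {
    va <- a[2]^2 / a[3]; vb <- b[2]^2 / b[3]
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a[3] - 1) + vb^2 / (b[3] - 1))
  }
  tstat <- (a[1] - b[1]) / se
  2 * stats::pt(-abs(tstat), df)
}

#' Calibrate the Nash formaldehyde assay
#'
#' Fits the linear standard curve absorbance = slope * conc + intercept by
#' OLS. The intercept is estimated (not forced through the origin) because
#' reagent blanks are nonzero in practice. The assay is linear between 0
#' and 1 mM; inversions outside that range are flagged.
#'
#' @param standards data.frame with columns `mM` and `absorbance`
#'   (>= 3 rows spanning the valid range).
#' @param valid_range Concentration range over which the calibration is
#'   trusted, mM.
#' @return An `assay_calibration`: list with `slope` (absorbance per mM),
#'   `intercept`, `r2`, `valid_range`.
#' @export
calibrate_nash <- function(standards, valid_range = c(0, 1)) {
  stopifnot(is.data.frame(standards),
            all(c("mM", "absorbance") %in% names(standards)))
  if (nrow(standards) < 3L) stop("need >= 3 standards", call. = FALSE)
  o <- order(standards$mM)
  standards <- standards[o, ]
  fit <- stats::lm(absorbance ~ mM, data = standards)
  slope <- unname(stats::coef(fit)[["mM"]])
  if (slope <= 0 ||
      stats::cor(standards$mM, standards$absorbance,
                 method = "spearman") <= 0) {
    stop("calibration error: standards are not monotonically increasing ",
         "in concentration", call. = FALSE)
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 valid_range = valid_range),
            class = "assay_calibration")
}

#' Invert a Nash calibration
#'
#' @param cal An [calibrate_nash()] calibration.
#' @param absorbance Absorbance reading(s) at 412 nm.
#' @return Numeric concentration(s) in mM, with attribute `out_of_range`
#'   (logical vector) marking values outside the calibration's valid range.
#' @export
nash_invert <- function(cal, absorbance) {
  stopifnot(inherits(cal, "assay_calibration"))
  conc <- (absorbance - cal$intercept) / cal$slope
  oor <- conc < cal$valid_range[1] | conc > cal$valid_range[2]
  attr(conc, "out_of_range") <- oor
  conc
}
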