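# Default molar absorptivity of uric acid at 292 nm, 1/(M cm). Standard
# literature value for the alkaline/neutral urate chromophore; configurable
# everywhere it is used, and it cancels exactly in generator -> fit round
# trips because both sides share it.
EPSILON292_DEFAULT <- 12300

#' Substrate dilution series
#'
#' Successive 1:`factor` dilutions starting at `start` until the next value
#' would fall below `floor`; endpoints included. The assay convention is
#' 400 uM diluted 1:1.6 down to 23.8 uM, giving 7 levels.
#'
#' @param start Top concentration, uM.
#' @param factor Dilution factor (> 1).
#' @param floor Lowest concentration retained, uM.
#' @return Numeric vector of concentrations, uM, descending.
#' @export
dilution_series <- function(start = 400, factor = 1.6, floor = 23.8) {
  stopifnot(start > 0, floor > 0, start >= floor)
  if (factor <= 1) stop("dilution factor must be > 1")
  out <- start
  repeat {
    nxt <- out[length(out)] / factor
    if (nxt < floor) break
    out <- c(out, nxt)
  }
  out
}

#' Construct a progress curve
#'
#' Timestamped absorbance trace at 292 nm for one substrate concentration.
#'
#' @param times Seconds, strictly increasing, >= 3 points.
#' @param a292 Absorbance units at 292 nm.
#' @param s0 Initial substrate (uric acid), uM.
#' @param e0 Enzyme concentration (monomer-equivalent), uM.
#' @param path_length Cuvette path, cm.
#' @return Object of class `uox_curve`.
#' @export
progress_curve <- function(times, a292, s0, e0, path_length = 1) {
  stopifnot(length(times) == length(a292), length(times) >= 3,
            all(diff(times) > 0), s0 > 0, e0 > 0, path_length > 0)
  structure(list(times = as.numeric(times), a292 = as.numeric(a292),
                 s0 = s0, e0 = e0, path_length = path_length),
            class = "uox_curve")
}

#' Initial rate from a substrate-depletion trace
#'
#' Converts absorbance to substrate concentration (`[UA] = A / (eps * path)`,
#' scaled to uM) and takes minus the ordinary-least-squares slope over the
#' initial window: points up to `window_s` seconds or until 10% of the
#' substrate is consumed, whichever comes first, with a minimum of
#' `min_points` points. A rising trend is clamped to rate 0 with a warning.
#'
#' @param curve A [progress_curve()].
#' @param epsilon292 Molar absorptivity, 1/(M cm).
#' @param window_s Maximum window, seconds.
#' @param depletion_frac Fractional substrate depletion ending the window.
#' @param min_points Minimum points in the regression.
#' @return List: `rate` (uM/s), `specific_activity` (uM UA / s / uM enzyme),
#'   `n_points`, `window_s`.
#' @export
initial_rate <- function(curve, epsilon292 = EPSILON292_DEFAULT,
                         window_s = 120, depletion_frac = 0.10,
                         min_points = 4) {
  stopifnot(inherits(curve, "uox_curve"), epsilon292 > 0)
  conc <- curve$a292 / (epsilon292 * curve$path_length) * 1e6  # uM
  n <- length(conc)
  in_window <- curve$times <= window_s
  depleted <- (conc[1] - conc) / curve$s0 > depletion_frac
  last <- if (any(depleted)) min(which(depleted)) else n
  use <- which(in_window & seq_len(n) <= last)
  if (length(use) < min_points) use <- seq_len(min(min_points, n))
  if (length(use) < min_points) {
    stop("fewer than ", min_points, " usable points in the initial window")
  }
  fit <- stats::lm(conc[use] ~ curve$times[use])
  slope <- unname(stats::coef(fit)[2])
  rate <- -slope
  if (rate < 0) {
    # warn only for a genuine rising trend, not numerical noise on a flat one
    if (rate < -1e-12 * max(abs(conc), 1)) {
      warning("increasing absorbance trend; rate clamped at 0")
    }
    rate <- 0
  }
  list(rate = rate, specific_activity = rate / curve$e0,
       n_points = length(use), window_s = max(curve$times[use]))
}

#' Michaelis-Menten fit of initial rates
#'
#' Nonlinear least squares of `v = kcat * e0 * s / (km + s)` (Levenberg-
#' Marquardt), started from `kcat0 = max(v)/e0` and `km0 = median(s)`.
#'
#' @param rates Initial rates, uM/s, one per concentration.
#' @param concentrations Substrate concentrations, uM (>= 4 distinct).
#' @param e0 Enzyme concentration (monomer-equivalent), uM.
#' @param weights Optional weights for the residuals (default unweighted).
#' @return Object of class `uox_mm_fit`: list with `kcat` (uM UA/s/uM
#'   enzyme), `km` (uM), `se` (named vector), `converged`, `rates`,
#'   `concentrations`, `e0`.
#' @export
mm_fit <- function(rates, concentrations, e0, weights = NULL) {
  stopifnot(length(rates) == length(concentrations),
            length(unique(concentrations)) >= 4, e0 > 0)
  df <- data.frame(s = concentrations, v = rates)
  start <- list(kcat = max(rates) / e0, km = stats::median(concentrations))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ kcat * e0 * s / (km + s), data = df, start = start,
                      weights = if (is.null(weights)) rep(1, nrow(df)) else weights,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                             conditionMessage(e))
  )
  co <- stats::coef(fit)
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
    error = function(e) c(kcat = NA_real_, km = NA_real_))
  structure(list(kcat = unname(co["kcat"]), km = unname(co["km"]),
                 se = se, converged = fit$convInfo$isConv %||% TRUE,
                 rates = rates, concentrations = concentrations, e0 = e0),
            class = "uox_mm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rates from quench-mode (stopped) assays
#'
#' For serum assays the reaction is stopped at a few timepoints (minutes) and
#' absorbance read after deproteinization, so each concentration yields a
#' handful of quenched readings rather than a continuous trace. The rate is
#' minus the OLS slope of the absorbance-derived substrate concentration
#' against time, per concentration; results feed [mm_fit()] unchanged.
#'
#' @param timepoints_min Quench times in minutes (>= 3).
#' @param a292_matrix Matrix of absorbances: rows = timepoints, columns =
#'   substrate concentrations.
#' @param epsilon292 Molar absorptivity, 1/(M cm).
#' @param path_length Path, cm.
#' @return Numeric vector of rates (uM/min), one per column, clamped at 0
#'   with a warning when rising.
#' @export
quench_rates <- function(timepoints_min, a292_matrix,
                         epsilon292 = EPSILON292_DEFAULT, path_length = 1) {
  a292_matrix <- as.matrix(a292_matrix)
  if (length(timepoints_min) < 3) {
    stop("need at least 3 quenched timepoints per concentration")
  }
  stopifnot(nrow(a292_matrix) == length(timepoints_min))
  apply(a292_matrix, 2, function(col) {
    conc <- col / (epsilon292 * path_length) * 1e6
    slope <- unname(stats::coef(stats::lm(conc ~ timepoints_min))[2])
    r <- -slope
    if (r < 0) {
      if (r < -1e-12 * max(abs(conc), 1)) {
        warning("increasing absorbance trend; rate clamped at 0")
      }
      r <- 0
    }
    r
  })
}
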