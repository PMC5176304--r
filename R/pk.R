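#' Construct a serum concentration-time profile
#'
#' @param times Hours post dose, increasing.
#' @param conc Active-enzyme serum concentration; any consistent unit. For
#'   volume-of-distribution and clearance the convention is mg/L (numerically
#'   identical to ug/mL) against a dose in mg/kg.
#' @param dose Dose, mg/kg.
#' @param route `"IV"` or `"SC"`.
#' @return Object of class `uox_pk_profile`.
#' @export
pk_profile <- function(times, conc, dose, route = c("IV", "SC")) {
  route <- match.arg(route)
  stopifnot(length(times) == length(conc), all(diff(times) > 0),
            all(conc >= 0), dose > 0)
  structure(list(times = as.numeric(times), conc = as.numeric(conc),
                 dose = dose, route = route),
            class = "uox_pk_profile")
}

#' Mono-exponential IV elimination fit
#'
#' Ordinary least squares of log concentration against time over ALL
#' positive-concentration points - the profile is assumed monophasic, so no
#' terminal-phase selection is applied. Returns the elimination rate
#' constant, half-life, back-extrapolated c0, volume of distribution
#' (dose / c0) and clearance (lambda_z * Vd). A profile that is not
#' log-linear (r^2 below `r2_warn`) triggers a lack-of-fit warning: biphasic
#' or atypical elimination should not be summarized by this model.
#'
#' @param profile An IV [pk_profile()]; concentrations in mg/L if Vd in L/kg
#'   is wanted.
#' @param r2_warn r-squared threshold below which a lack-of-fit warning is
#'   raised (default 0.95).
#' @return Object of class `uox_pk_fit`: `lambda_z` (1/hr), `half_life`
#'   (hr), `c0`, `vd` (L/kg), `cl` (L/hr/kg), `r_squared`, `n_points_used`.
#' @export
fit_iv_monophasic <- function(profile, r2_warn = 0.95) {
  stopifnot(inherits(profile, "uox_pk_profile"))
  if (profile$route != "IV") stop("fit_iv_monophasic requires an IV profile")
  pos <- profile$conc > 0
  # two exact points already determine the line (the closed-form case);
  # anything less is underdetermined
  if (sum(pos) < 2) stop("need at least 2 positive concentrations")
  t <- profile$times[pos]
  y <- log(profile$conc[pos])
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("no elimination phase: log-concentration slope is non-negative")
  r2 <- r_squared(y, stats::fitted(fit))
  if (is.finite(r2) && r2 < r2_warn) {
    warning(sprintf("lack of fit (r^2 = %.3f): elimination may not be monophasic", r2))
  }
  lambda_z <- -slope
  c0 <- exp(unname(stats::coef(fit)[1]))
  vd <- profile$dose / c0
  structure(list(lambda_z = lambda_z, half_life = log(2) / lambda_z,
                 c0 = c0, vd = vd, cl = lambda_z * vd, r_squared = r2,
                 n_points_used = sum(pos)),
            class = "uox_pk_fit")
}

#' Terminal half-life from a subcutaneous profile
#'
#' Identifies tmax and regresses log concentration on the last
#' `terminal_points` post-peak samples. Only the half-life is returned:
#' volume of distribution and clearance are absorption-confounded after SC
#' dosing and are deliberately omitted.
#'
#' @param profile An SC [pk_profile()].
#' @param terminal_points Number of terminal samples to regress (>= 3).
#' @return Object of class `uox_pk_fit` with `lambda_z`, `half_life`,
#'   `r_squared`, `n_points_used`; `c0`, `vd`, `cl` are `NA`.
#' @export
fit_sc_terminal <- function(profile, terminal_points = 3) {
  stopifnot(inherits(profile, "uox_pk_profile"), terminal_points >= 3)
  if (profile$route != "SC") stop("fit_sc_terminal requires an SC profile")
  pos <- which(profile$conc > 0)
  if (length(pos) < 3) stop("need at least 3 positive concentrations")
  t <- profile$times[pos]
  c <- profile$conc[pos]
  imax <- which.max(c)
  post <- seq_along(t) > imax
  if (sum(post) < terminal_points) {
    stop("no post-peak decline: fewer than ", terminal_points,
         " samples after tmax")
  }
  idx <- utils::tail(which(post), terminal_points)
  fit <- stats::lm(log(c[idx]) ~ t[idx])
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("no post-peak decline in the terminal samples")
  lambda_z <- -slope
  structure(list(lambda_z = lambda_z, half_life = log(2) / lambda_z,
                 c0 = NA_real_, vd = NA_real_, cl = NA_real_,
                 r_squared = r_squared(log(c[idx]), stats::fitted(fit)),
                 n_points_used = length(idx)),
            class = "uox_pk_fit")
}

# coefficient of determination without summary.lm's perfect-fit warning
r_squared <- function(y, yhat) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  1 - sum((y - yhat)^2) / tss
}
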