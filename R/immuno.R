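#' Replicate well counts for one donor and condition
#'
#' @param donor_id Donor identifier.
#' @param condition One of `"blank"`, `"buffer"`, `"test"`, `"positive"`.
#' @param counts Non-negative integer replicate counts of proliferating
#'   CD3+CD4+ cells per well (typically 8 replicates).
#' @return Object of class `uox_wells`.
#' @export
donor_wells <- function(donor_id, condition, counts) {
  condition <- match.arg(condition, c("blank", "buffer", "test", "positive"))
  stopifnot(length(counts) >= 2, all(counts >= 0),
            all(abs(counts - round(counts)) < 1e-8))
  structure(list(donor_id = donor_id, condition = condition,
                 counts = as.numeric(counts)),
            class = "uox_wells")
}

#' Stimulation index for one donor
#'
#' Fits condition means by an ordinary-least-squares linear model on the
#' replicate counts and forms the treated/reference contrast as a ratio: the
#' stimulation index (SI). The SI standard error comes from the delta method
#' on the two estimated means (pooled residual variance); the two-sided
#' p-value tests SI = 1 on a t reference distribution with the model's
#' residual degrees of freedom, and a 95% confidence interval is reported on
#' the same scale. With zero residual variance the p-value degenerates to 1
#' (SI exactly 1) or 0 (otherwise).
#'
#' @param treated `uox_wells` for the antigen-treated condition.
#' @param reference `uox_wells` for the untreated/buffer reference wells of
#'   the same donor.
#' @param si_threshold,alpha Responder rule: SI >= `si_threshold` supported
#'   by p < `alpha`.
#' @return Object of class `uox_si`: `donor_id`, `si`, `se`, `ci95`
#'   (length-2), `p_value`, `responder`.
#' @export
donor_si <- function(treated, reference, si_threshold = 2, alpha = 0.05) {
  stopifnot(inherits(treated, "uox_wells"), inherits(reference, "uox_wells"))
  if (!identical(treated$donor_id, reference$donor_id)) {
    stop("treated and reference wells must come from the same donor")
  }
  df <- data.frame(
    count = c(reference$counts, treated$counts),
    cond = factor(rep(c("ref", "trt"), c(length(reference$counts),
                                         length(treated$counts))),
                  levels = c("ref", "trt"))
  )
  fit <- stats::lm(count ~ cond, data = df)
  mu <- stats::coef(fit)
  m_ref <- unname(mu[1])
  m_trt <- unname(mu[1] + mu[2])
  if (m_ref <= 0) stop("reference mean is not positive: SI undefined")
  sigma2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  n_ref <- length(reference$counts)
  n_trt <- length(treated$counts)
  si <- m_trt / m_ref
  # delta method for the ratio of two independent means
  se <- sqrt(sigma2 * (1 / (n_trt * m_ref^2) + m_trt^2 / (n_ref * m_ref^4)))
  if (se == 0) {
    p <- if (si == 1) 1 else 0
    ci <- c(si, si)
  } else {
    tstat <- (si - 1) / se
    p <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
    ci <- si + c(-1, 1) * stats::qt(0.975, df = fit$df.residual) * se
  }
  structure(list(donor_id = treated$donor_id, si = si, se = se, ci95 = ci,
                 p_value = p,
                 responder = si >= si_threshold && p < alpha),
            class = "uox_si")
}

#' Responder call from a stimulation-index result
#'
#' A donor responds to an antigen when the stimulation index is at least
#' `si_threshold` AND the SI = 1 test gives p below `alpha`.
#'
#' @param result A `uox_si`.
#' @param si_threshold SI cut-off (default 2).
#' @param alpha Significance level (default 0.05).
#' @return Logical.
#' @export
call_responder <- function(result, si_threshold = 2, alpha = 0.05) {
  stopifnot(inherits(result, "uox_si"))
  result$si >= si_threshold && result$p_value < alpha
}

#' Summarize a donor population
#'
#' Arithmetic mean SI across donors plus responder count and (unrounded)
#' fraction. No multiple-testing correction is applied across donors: the
#' responder definition is a fixed per-donor rule.
#'
#' @param results List of `uox_si` objects (>= 1).
#' @return List: `n_donors`, `mean_si`, `n_responders`,
#'   `responder_fraction`.
#' @export
population_summary <- function(results) {
  if (!length(results)) stop("no donor results")
  stopifnot(all(vapply(results, inherits, logical(1), "uox_si")))
  si <- vapply(results, `[[`, numeric(1), "si")
  resp <- vapply(results, `[[`, logical(1), "responder")
  list(n_donors = length(results), mean_si = mean(si),
       n_responders = sum(resp), responder_fraction = mean(resp))
}
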