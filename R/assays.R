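#' Adsorption rate from an unadsorbed-phage decay series
#'
#' In the tube assay, free phage mixed with adsorbing bacteria at density
#' `B` (per ml) decay as `N_t = N0 * exp(-B a t)`. The rate is recovered by
#' ordinary least squares of `ln(N_t)` on `t`: `a = -slope / B`, with the
#' standard error propagated from the slope. Note the units: this assay
#' yields a rate per millilitre of culture; the in-vivo model constant is
#' per gram of feces and the two are never interconverted here.
#'
#' @param data An `assay_dataset` of kind `"adsorption_decay"` (see
#'   [assay_dataset()]), or a data.frame with columns `time_h` and `value`
#'   plus a bacterial density supplied via `B`.
#' @param B Adsorbing bacterial density per ml; taken from the dataset if
#'   present.
#' @return List with `a` (ml h^-1), `se`, `slope`, `n`.
#' @examples
#' d <- generate_adsorption_assay(a = 3e-7, B = 6e8, N0 = 500,
#'                                times = seq(0, 0.02, by = 0.0025))
#' adsorption_rate_from_decay(d)$a
#' @export
adsorption_rate_from_decay <- function(data, B = NULL) {
  d <- as_assay(data, "adsorption_decay")
  B <- B %||% d$B
  if (is.null(B) || !is.finite(B) || B <= 0) {
    stop("adsorbing bacterial density B (> 0, per ml) is required", call. = FALSE)
  }
  t <- d$data$time_h
  n <- d$data$value
  if (any(n == 0)) {
    warning("zero PFU count(s) treated as censored at 1")
    n[n == 0] <- 1
  }
  if (sum(n > 0) < 3) stop("need at least 3 positive PFU counts", call. = FALSE)
  fit <- stats::lm(log(n) ~ t)
  slope <- unname(stats::coef(fit)[2])
  se_slope <- suppressWarnings(summary(fit)$coefficients[2, 2])
  list(a = -slope / B, se = se_slope / B, slope = slope, n = length(n))
}

#' Burst size from a single-burst PFU series
#'
#' The burst size is the factor between the maximum and the initial PFU
#' counts of a one-step growth experiment.
#'
#' @param data An `assay_dataset` of kind `"single_burst"` or a data.frame
#'   with `time_h`, `value`.
#' @return Burst size `y` (dimensionless).
#' @export
burst_size <- function(data) {
  d <- as_assay(data, "single_burst")
  v <- d$data$value
  if (length(v) < 2) stop("need at least 2 time points", call. = FALSE)
  if (v[1] <= 0) stop("initial PFU count must be positive", call. = FALSE)
  max(v) / v[1]
}

#' Bacterial generations elapsed under the two-phase gut growth schedule
#'
#' Colonizing bacteria grow at the maximal rate `r` during the first day
#' and thereafter merely balance washout, so net turnover proceeds at the
#' excretion rate `d`. Generations are the accumulated rate divided by
#' ln 2.
#'
#' @param t Time in hours (vectorized).
#' @param r Growth rate during the initial phase, h^-1.
#' @param d Turnover rate after `phase_switch`, h^-1.
#' @param phase_switch Hour at which growth slows; default 24.
#' @return Generation count(s).
#' @examples
#' generations_elapsed(24)  # ~38 generations in the first day
#' @export
generations_elapsed <- function(t, r = 1.1, d = 0.25, phase_switch = 24) {
  stopifnot(all(t >= 0))
  (r * pmin(t, phase_switch) + d * pmax(t - phase_switch, 0)) / log(2)
}

#' Model-independent induction rate from the decline of the L/S ratio
#'
#' In receptor-deletion competitions the only process distinguishing the
#' lysogenic and susceptible lineages is induction, which removes lysogens.
#' The induction rate per generation is the negative slope of `ln(L/S)`
#' against the number of generations (two-phase schedule of
#' [generations_elapsed()]). For rates of this magnitude the linear-slope
#' estimate and `1 - exp(slope)` differ by under 1%.
#'
#' @param data An `assay_dataset` of kind `"ratio_series"`, or a data.frame
#'   with columns `time_h`, `value` (the L/S ratio) and optionally
#'   `mouse_id`; with several mice the regression uses mouse-mean log
#'   ratios per time point.
#' @param r,d,phase_switch Growth schedule, as in [generations_elapsed()].
#' @return List with `x` (per generation), `se`, `slope`, `generations`.
#' @export
induction_rate_regression <- function(data, r = 1.1, d = 0.25,
                                      phase_switch = 24) {
  dd <- as_assay(data, "ratio_series")
  df <- dd$data
  if (any(df$value <= 0)) {
    stop("L/S ratios must be positive (both counts observed)", call. = FALSE)
  }
  lr <- log(df$value)
  if (!is.null(df$mouse_id)) {
    means <- tapply(lr, df$time_h, mean)
    tt <- as.numeric(names(means))
    lr <- as.numeric(means)
  } else {
    tt <- df$time_h
  }
  if (length(tt) < 3) stop("need at least 3 ratio observations", call. = FALSE)
  gen <- generations_elapsed(tt, r = r, d = d, phase_switch = phase_switch)
  fit <- stats::lm(lr ~ gen)
  slope <- unname(stats::coef(fit)[2])
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  list(x = -slope, se = se, slope = slope, generations = gen)
}

#' Induction rate from infective-centre counts
#'
#' Plating washed lysogens with an indicator lawn on ampicillin scores, as
#' plaques, the cells in which the lytic cycle had already initiated. The
#' per-cell induction rate is the infective-centre fraction, with an exact
#' (Clopper-Pearson) binomial 95% interval.
#'
#' @param n_centres Number of infective centres (plaques).
#' @param n_plated Number of plated lysogenic bacteria.
#' @return List with `rate`, `ci95` (length-2), `n_centres`, `n_plated`.
#' @examples
#' infective_centre_rate(34, 1e5)$rate  # 3.4e-4
#' @export
infective_centre_rate <- function(n_centres, n_plated) {
  stopifnot(length(n_centres) == 1, length(n_plated) == 1)
  if (n_plated <= 0) stop("n_plated must be positive", call. = FALSE)
  if (n_centres < 0 || n_centres > n_plated) {
    stop("n_centres must lie in [0, n_plated]", call. = FALSE)
  }
  bt <- stats::binom.test(n_centres, n_plated)
  list(rate = n_centres / n_plated,
       ci95 = as.numeric(bt$conf.int),
       n_centres = n_centres, n_plated = n_plated)
}
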