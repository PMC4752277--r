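#' Small assay dataset container
#'
#' Holds one in-vitro assay series: an unadsorbed-phage decay curve, a
#' single-burst PFU series, an L/S ratio time series, or infective-centre
#' counts.
#'
#' @param kind One of `"adsorption_decay"`, `"single_burst"`,
#'   `"ratio_series"`, `"infective_centre"`.
#' @param data For the series kinds, a data.frame with `time_h`, `value`
#'   (and optionally `mouse_id`); for `"infective_centre"`, a data.frame
#'   with `n_centres`, `n_plated`.
#' @param B Adsorbing bacterial density per ml (adsorption kind only).
#' @param meta Optional named list of provenance (generating values, seed).
#' @return An object of class `assay_dataset`.
#' @export
assay_dataset <- function(kind = c("adsorption_decay", "single_burst",
                                   "ratio_series", "infective_centre"),
                          data, B = NULL, meta = list()) {
  kind <- match.arg(kind)
  if (kind == "infective_centre") {
    stopifnot(all(c("n_centres", "n_plated") %in% names(data)))
  } else {
    stopifnot(all(c("time_h", "value") %in% names(data)))
    if (is.unsorted(data$time_h, strictly = FALSE)) {
      data <- data[order(data$time_h), , drop = FALSE]
    }
    if (any(data$value < 0)) stop("counts must be >= 0", call. = FALSE)
  }
  if (kind == "adsorption_decay" && (is.null(B) || B <= 0)) {
    stop("adsorption assays require the bacterial density B > 0", call. = FALSE)
  }
  structure(list(kind = kind, data = data, B = B, meta = meta),
            class = "assay_dataset")
}

as_assay <- function(data, kind) {
  if (inherits(data, "assay_dataset")) {
    if (data$kind != kind) {
      stop("expected an assay of kind '", kind, "', got '", data$kind, "'",
           call. = FALSE)
    }
    return(data)
  }
  assay_dataset(kind, as.data.frame(data),
                B = attr(data, "B", exact = TRUE))
}

#' Scenario configuration for synthetic mouse experiments
#'
#' Describes one gnotobiotic colonization design: monocolonization with a
#' single strain (`mono`), a lysogen-vs-susceptible competition in a
#' receptor-deletion background (`lamB_competition`, phage cannot adsorb),
#' or the wild-type competition (`wt_competition`).
#'
#' @param scenario One of `"mono"`, `"lamB_competition"`,
#'   `"wt_competition"`.
#' @param n_mice Number of mice (>= 1).
#' @param ratio Initial L:S ratio, `"1:1"`, `"1:10"` or `"1:100"`.
#' @param total0 Total gavage density, cfu/g (default 1e6; split between L
#'   and S by `ratio` for competitions).
#' @param L0,S0 Explicit initial densities overriding the `total0`/`ratio`
#'   split (either may be `NULL`).
#' @param times Sampling times in hours; must include 0. The default
#'   brackets daily sampling with extra points inside the first 48 h where
#'   the dynamics are fast.
#' @param cv Multiplicative lognormal noise CV applied to each count.
#' @param init_cv Inter-mouse lognormal CV on initial densities (biological
#'   variability of the gavage take; rate parameters are shared).
#' @param detection_limit Plating detection limit, counts/g; lower values
#'   are recorded at the limit and flagged censored.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("mono", "lamB_competition",
                                         "wt_competition"),
                            n_mice = 4, ratio = "1:1", total0 = 1e6,
                            L0 = NULL, S0 = NULL,
                            times = c(0, 6, 24, 30, 48, 72, 96, 144, 216),
                            cv = 0.2, init_cv = 0.3,
                            detection_limit = 1e2, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n_mice >= 1, cv >= 0, init_cv >= 0, total0 > 0,
            detection_limit >= 0)
  if (!0 %in% times) stop("sample times must include 0", call. = FALSE)
  times <- sort(unique(times))
  parts <- parse_ratio(ratio)
  if (is.null(L0)) L0 <- total0 * parts[1] / sum(parts)
  if (is.null(S0)) S0 <- total0 * parts[2] / sum(parts)
  structure(list(scenario = scenario, n_mice = n_mice, ratio = ratio,
                 total0 = total0, L0 = L0, S0 = S0, times = times, cv = cv,
                 init_cv = init_cv, detection_limit = detection_limit,
                 seed = seed),
            class = "scenario_config")
}

parse_ratio <- function(ratio) {
  parts <- suppressWarnings(as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 2 || any(!is.finite(parts)) || any(parts <= 0)) {
    stop("ratio must look like 'L:S', e.g. '1:10'", call. = FALSE)
  }
  parts
}

# lognormal multiplier with mean 1 and coefficient of variation cv
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdl^2 / 2, sdl))
}

#' Generate a synthetic fecal observation set
#'
#' Emulates a gnotobiotic mouse experiment: per mouse, initial densities
#' are drawn lognormally around the configured values, the deterministic
#' model is integrated (with `a` forced to 0 in the receptor-deletion
#' scenario), and plate counts are read off at the sampling times with
#' multiplicative lognormal noise and flooring at the detection limit.
#' Latent-cell counts `Q` are reported only for the receptor-deletion
#' scenario, where free phage can be removed before plating.
#'
#' @param config A [scenario_config()].
#' @param params A `phage_params` vector (generating truth).
#' @return A data.frame of class `fecal_observations` in long format
#'   (`mouse_id, time_h, compartment, count_per_g, censored`), with the
#'   config, generating parameters and seed attached as attributes.
#' @export
generate_mouse_experiment <- function(config, params) {
  stopifnot(inherits(config, "scenario_config"))
  p <- validate_params(params)
  sim_p <- if (config$scenario == "lamB_competition") update_params(p, a = 0) else p
  comps <- switch(config$scenario,
                  mono = "S_lineage",
                  lamB_competition = c("L", "S_lineage", "Q"),
                  wt_competition = c("L", "S_lineage", "SL", "V"))
  rows <- with_seed(config$seed, {
    lapply(seq_len(config$n_mice), function(m) {
      init <- switch(config$scenario,
        mono = phage_state(S = config$total0 * lnorm_noise(1, config$init_cv)),
        phage_state(L = config$L0 * lnorm_noise(1, config$init_cv),
                    S = config$S0 * lnorm_noise(1, config$init_cv)))
      tr <- simulate_populations(sim_p, init, config$times)
      obs_list <- lapply(config$times, function(tt) {
        ob <- state_observables(trajectory_state(tr, tt))[comps]
        noisy <- ob * lnorm_noise(length(ob), config$cv)
        cens <- noisy < config$detection_limit
        noisy[cens] <- config$detection_limit
        data.frame(mouse_id = sprintf("m%02d", m), time_h = tt,
                   compartment = comps, count_per_g = unname(noisy),
                   censored = unname(cens))
      })
      do.call(rbind, obs_list)
    })
  })
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  attr(obs, "config") <- config
  attr(obs, "params") <- p
  attr(obs, "detection_limit") <- config$detection_limit
  attr(obs, "seed") <- config$seed
  class(obs) <- c("fecal_observations", "data.frame")
  obs
}

# evaluate expr with a local, restored RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic phage adsorption decay assay
#'
#' Free-phage counts decay exponentially while adsorbing to bacteria at
#' density `B`: `N_t = N0 exp(-B a t)`, optionally Poisson-sampled to
#' emulate plaque counting.
#'
#' @param a Adsorption rate, ml h^-1 (> 0, or 0 for a flat control).
#' @param B Bacterial density per ml.
#' @param N0 Initial free-phage count.
#' @param times Sampling times in hours.
#' @param noise `"none"` or `"poisson"`.
#' @param seed Seed used when `noise = "poisson"`.
#' @return An `assay_dataset` of kind `"adsorption_decay"`.
#' @export
generate_adsorption_assay <- function(a, B, N0 = 500,
                                      times = seq(0, 0.02, by = 0.0025),
                                      noise = c("none", "poisson"), seed = 1) {
  noise <- match.arg(noise)
  stopifnot(a >= 0, B > 0, N0 > 0)
  mu <- N0 * exp(-B * a * times)
  val <- if (noise == "poisson") with_seed(seed, stats::rpois(length(mu), mu)) else mu
  assay_dataset("adsorption_decay",
                data.frame(time_h = times, value = val), B = B,
                meta = list(a = a, B = B, N0 = N0, noise = noise, seed = seed))
}

#' Generate a synthetic single-burst PFU series
#'
#' Step-like one-step growth curve: infective centres at `N0` before the
#' latent period ends, plateau at `y * N0` afterwards, with an optional
#' sigmoidal rise of width `rise`.
#'
#' @param y Burst size (>= 1).
#' @param latency_time Latent period in hours (default 40 min).
#' @param N0 Initial infective-centre count.
#' @param times Sampling times in hours (default every 10 min for 2 h).
#' @param rise Width (h) of the logistic rise around `latency_time`; 0
#'   gives a sharp step.
#' @return An `assay_dataset` of kind `"single_burst"`.
#' @export
generate_burst_assay <- function(y, latency_time = 2 / 3, N0 = 100,
                                 times = seq(0, 2, by = 1 / 6), rise = 0) {
  stopifnot(y >= 1, N0 > 0, latency_time > 0)
  if (rise > 0) {
    frac <- stats::plogis((times - latency_time) / (rise / 4))
    frac[1] <- 0  # the t = 0 count anchors the pre-burst level
  } else {
    frac <- as.numeric(times >= latency_time)
  }
  val <- N0 * (1 + (y - 1) * frac)
  assay_dataset("single_burst", data.frame(time_h = times, value = val),
                meta = list(y = y, latency_time = latency_time, N0 = N0))
}

#' Generate an L/S ratio series declining linearly in generations
#'
#' Emulates the receptor-deletion competition used for the
#' model-independent induction estimate: the log ratio of lysogens to
#' susceptibles declines by `x_per_gen` per bacterial generation, with
#' generations accumulating under the two-phase schedule of
#' [generations_elapsed()].
#'
#' @param x_per_gen Per-generation loss rate of lysogens.
#' @param times Observation times in hours (default daily over 9 days).
#' @param n_mice Number of mice; per-mouse lognormal noise of CV `cv` is
#'   applied to each ratio.
#' @param ratio0 Initial L/S ratio.
#' @param r,d,phase_switch Growth schedule.
#' @param cv Noise CV on the ratio (0 = exact).
#' @param seed Seed.
#' @return An `assay_dataset` of kind `"ratio_series"` with a `mouse_id`
#'   column.
#' @export
generate_ratio_series <- function(x_per_gen, times = seq(0, 216, by = 24),
                                  n_mice = 6, ratio0 = 1, r = 1.1, d = 0.25,
                                  phase_switch = 24, cv = 0, seed = 1) {
  gen <- generations_elapsed(times, r = r, d = d, phase_switch = phase_switch)
  mu <- ratio0 * exp(-x_per_gen * gen)
  df <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_mice), function(m) {
      data.frame(mouse_id = sprintf("m%02d", m), time_h = times,
                 value = mu * lnorm_noise(length(mu), cv))
    }))
  })
  assay_dataset("ratio_series", df,
                meta = list(x_per_gen = x_per_gen, r = r, d = d,
                            phase_switch = phase_switch, cv = cv, seed = seed))
}

#' Generate the full synthetic calibration bundle
#'
#' Produces the three observation sets consumed by the sequential
#' calibration pipeline - monocolonization, receptor-deletion competition
#' (with latent-cell counts) and wild-type competitions at the three
#' initial L:S ratios - plus the late-time (equilibrium) free-phage,
#' latent-cell and total-bacteria densities that feed the adsorption
#' inversion.
#'
#' @param params Generating `phage_params`.
#' @param n_mice Mice per scenario group.
#' @param cv Count noise CV (0 = noiseless).
#' @param init_cv Inter-mouse initial-density CV.
#' @param ratios Initial L:S ratios for the wild-type competitions.
#' @param times Sampling grid.
#' @param eq_horizon Horizon (h) at which the equilibrium observations are
#'   read from the wild-type model.
#' @param seed Seed; sub-seeds for each scenario are derived from it.
#' @return List with elements `mono`, `lamB`, `competition` (observation
#'   sets) and `equilibrium` (named vector `V`, `Q`, `N`).
#' @export
generate_bundle <- function(params, n_mice = 4, cv = 0, init_cv = 0,
                            ratios = c("1:1", "1:10", "1:100"),
                            times = c(0, 6, 24, 30, 36, 48, 72, 96),
                            eq_horizon = 1000, seed = 1) {
  p <- validate_params(params)
  sub <- function(i) (seed * 97 + i * 1009) %% 2147483647
  mono <- generate_mouse_experiment(
    scenario_config("mono", n_mice = n_mice, total0 = 1e6, times = times,
                    cv = cv, init_cv = init_cv, seed = sub(1)), p)
  lamB <- generate_mouse_experiment(
    scenario_config("lamB_competition", n_mice = n_mice, ratio = "1:1",
                    total0 = 2e6, times = times, cv = cv, init_cv = init_cv,
                    seed = sub(2)), p)
  comp <- lapply(seq_along(ratios), function(i) {
    g <- generate_mouse_experiment(
      scenario_config("wt_competition", n_mice = n_mice, ratio = ratios[i],
                      L0 = 1e6, S0 = 1e6 * parse_ratio(ratios[i])[2],
                      times = times, cv = cv, init_cv = init_cv,
                      seed = sub(10 + i)), p)
    g$mouse_id <- paste0("r", i, "_", g$mouse_id)
    g
  })
  competition <- do.call(rbind, comp)
  attr(competition, "config") <- attr(comp[[1]], "config")
  attr(competition, "params") <- p
  attr(competition, "detection_limit") <-
    attr(comp[[1]], "detection_limit", exact = TRUE)
  class(competition) <- c("fecal_observations", "data.frame")
  eq <- find_equilibrium(p, horizon = eq_horizon)
  ob <- state_observables(eq)
  noise <- with_seed(sub(99), lnorm_noise(3, cv))
  equilibrium <- c(V = ob[["V"]] * noise[1], Q = ob[["Q"]] * noise[2],
                   N = (ob[["L"]] + ob[["S_lineage"]]) * noise[3])
  list(mono = mono, lamB = lamB, competition = competition,
       equilibrium = equilibrium)
}
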