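#' Final lysogen-over-susceptible lineage ratio
#'
#' Simulates the model and returns `L/(S+SL)` at the horizon (default
#' 100 h, by which the calibrated system is essentially at equilibrium).
#'
#' @param params A `phage_params` vector.
#' @param init Initial `phage_state`.
#' @param horizon Horizon in hours.
#' @return The scalar ratio; `Inf` with attribute `extinct = TRUE` when
#'   the susceptible lineage is extinct at the horizon.
#' @export
final_lineage_ratio <- function(params, init, horizon = 100) {
  tr <- simulate_populations(params, init, times = c(0, horizon))
  st <- trajectory_state(tr, horizon)
  denom <- st[["S"]] + st[["SL"]]
  if (denom <= 0) {
    return(structure(Inf, extinct = TRUE))
  }
  st[["L"]] / denom
}

ratio_inits <- function(initial_ratios, L0 = 1e6) {
  lapply(initial_ratios, function(rr) {
    parts <- parse_ratio(rr)
    phage_state(L = L0, S = L0 * parts[2] / parts[1])
  })
}

#' One-at-a-time parameter sweep of the final lineage ratio
#'
#' Perturbs a single parameter over a set of values, holding all others at
#' `params`, and records the final `L/(S+SL)` ratio at the horizon for
#' each initial L:S ratio. The default grid spans x0.1 to x10 of the
#' baseline value on 21 log-spaced points.
#'
#' @param params Baseline `phage_params`.
#' @param name One of the eight parameter names.
#' @param values Values to test; default log grid around the baseline
#'   (truncated to [0, 1] for `g`).
#' @param initial_ratios Character vector of initial L:S ratios.
#' @param L0 Lysogen inoculum density, cfu/g.
#' @param horizon Hours.
#' @return A data.frame of class `phage_sweep` with columns
#'   `parameter, value, initial_ratio, final_ratio`.
#' @export
parameter_sweep <- function(params, name, values = NULL,
                            initial_ratios = c("1:1", "1:10", "1:100"),
                            L0 = 1e6, horizon = 100) {
  p <- validate_params(params)
  if (!name %in% PARAM_NAMES) {
    stop("unknown parameter '", name, "'; valid names are ",
         paste(PARAM_NAMES, collapse = ", "), call. = FALSE)
  }
  if (is.null(values)) {
    values <- p[[name]] * 10^seq(-1, 1, length.out = 21)
    if (name == "g") values <- values[values <= 1]
  }
  inits <- ratio_inits(initial_ratios, L0)
  rows <- list()
  for (v in values) {
    pv <- tryCatch(do.call(update_params, stats::setNames(list(p, v), c("params", name))),
                   error = function(e) {
                     stop("value ", v, " invalid for parameter '", name,
                          "': ", conditionMessage(e), call. = FALSE)
                   })
    for (i in seq_along(initial_ratios)) {
      fr <- final_lineage_ratio(pv, inits[[i]], horizon)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = name, value = v, initial_ratio = initial_ratios[i],
        final_ratio = as.numeric(fr))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "horizon") <- horizon
  class(out) <- c("phage_sweep", "data.frame")
  out
}

#' Lysogenization-probability sweep with inverse-proportionality diagnostics
#'
#' Sweeps `g` and reports, alongside the final lineage ratio, the products
#' `final_ratio * g` and `(final_ratio - 1) * g`. If the final advantage
#' of the lysogen lineage is inversely proportional to the lysogenization
#' probability, one of these products is flat across the sweep (which one
#' depends on whether the proportionality includes the neutral offset of
#' 1; both are emitted so the data can decide).
#'
#' @param params Baseline `phage_params`.
#' @param g_values Values in (0, 1]; `g = 0` is excluded with a warning
#'   (the ratio diverges without lysogenization).
#' @param initial_ratios,L0,horizon As in [parameter_sweep()].
#' @return A `phage_sweep` data.frame with extra columns `ratio_times_g`
#'   and `gain_times_g`.
#' @export
gain_vs_g <- function(params, g_values = seq(0.05, 0.5, length.out = 10),
                      initial_ratios = c("1:1", "1:10", "1:100"),
                      L0 = 1e6, horizon = 100) {
  if (any(g_values == 0)) {
    warning("g = 0 excluded: the final ratio diverges without lysogenization")
    g_values <- g_values[g_values != 0]
  }
  stopifnot(all(g_values > 0 & g_values <= 1))
  sw <- parameter_sweep(params, "g", values = g_values,
                        initial_ratios = initial_ratios, L0 = L0,
                        horizon = horizon)
  sw$ratio_times_g <- sw$final_ratio * sw$value
  sw$gain_times_g <- (sw$final_ratio - 1) * sw$value
  sw
}
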