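#' @name estimation
#' @title Sequential calibration of the gut model
#' @description
#' The eight model parameters are calibrated sequentially in four groups,
#' each from the dataset that isolates it: (1) growth parameters `r`, `k`
#' from monocolonization time series with the washout rate `d` fixed;
#' (2) induction and latency `x`, `l` from receptor-deletion competitions
#' where adsorption is impossible (`a = 0`) and latent cells are counted;
#' (3) the adsorption constant `a` from the free-phage steady-state
#' balance, given the burst size `y` measured in vitro; (4) the
#' lysogenization probability `g` from the lysogen-over-susceptible ratio
#' of wild-type competitions at the best-resolved time point (36 h).
#' Residuals are always on log10 densities (plate counts span decades and
#' their noise is multiplicative); censored observations at the detection
#' limit are excluded.
NULL

new_fit <- function(estimates, objective, flags = character(),
                    data_ref = NA_character_, convergence = NA_integer_,
                    ci95 = NULL, n_boot = NULL, seed = NULL, stages = NULL) {
  structure(list(estimates = estimates, objective = objective,
                 ci95 = ci95, n_boot = n_boot, seed = seed,
                 flags = flags, data_ref = data_ref,
                 convergence = convergence, stages = stages),
            class = "phage_fit")
}

#' @export
print.phage_fit <- function(x, ...) {
  cat("Model fit (", x$data_ref, ")\n", sep = "")
  est <- x$estimates
  for (nm in names(est)) {
    line <- sprintf("  %-2s = %g", nm, est[[nm]])
    if (!is.null(x$ci95) && nm %in% rownames(x$ci95)) {
      line <- paste0(line, sprintf("  [%g, %g]",
                                   x$ci95[nm, 1], x$ci95[nm, 2]))
    }
    cat(line, "\n")
  }
  cat("  objective =", x$objective, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

obs_check <- function(obs) {
  obs <- as.data.frame(obs)
  need <- c("mouse_id", "time_h", "compartment", "count_per_g")
  if (!all(need %in% names(obs))) {
    stop("observations need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(obs$censored)) obs$censored <- FALSE
  obs
}

# per-mouse wide table of one compartment (uncensored values, NA otherwise)
obs_value <- function(obs, mouse, time, comp) {
  i <- which(obs$mouse_id == mouse & obs$time_h == time &
               obs$compartment == comp)
  if (length(i) == 0) return(NA_real_)
  if (obs$censored[i[1]]) return(NA_real_)
  obs$count_per_g[i[1]]
}

#' Fit growth parameters from monocolonization data (stage 1)
#'
#' Fits the one-dimensional logistic-with-washout model
#' `dN/dt = r N (1 - N/k) - d N` to the total bacterial density of each
#' mouse, jointly with shared `r` and `k`, by nonlinear least squares on
#' log10 densities. The model has the closed form of a logistic with
#' effective rate `r - d` and effective capacity `k (1 - d/r)`; each
#' mouse's observed time-0 density is used as its initial condition.
#'
#' @param obs A `fecal_observations` data.frame (long format). All
#'   bacterial compartments present (`L`, `S_lineage`, `SL`) are summed
#'   per mouse and time.
#' @param d Fixed washout rate, h^-1.
#' @param n_starts Number of multi-start initializations.
#' @return A `phage_fit` with `estimates["r"]`, `estimates["k"]`. The flag
#'   `"r_nonidentifiable"` is raised when the data contain no growth phase
#'   (all densities already at plateau).
#' @export
fit_growth <- function(obs, d = 0.25, n_starts = 5) {
  obs <- obs_check(obs)
  bact <- obs[obs$compartment %in% c("L", "S_lineage", "SL") & !obs$censored, ]
  tot <- stats::aggregate(count_per_g ~ mouse_id + time_h, data = bact, FUN = sum)
  mice <- unique(tot$mouse_id)
  n0 <- vapply(mice, function(m) {
    v <- tot$count_per_g[tot$mouse_id == m & tot$time_h == 0]
    if (length(v) == 0) NA_real_ else v[1]
  }, numeric(1))
  if (any(is.na(n0))) stop("every mouse needs an uncensored time-0 density",
                           call. = FALSE)
  pts <- tot[tot$time_h > 0, ]
  if (length(unique(c(0, pts$time_h))) < 4) {
    stop("need >= 4 time points spanning growth and plateau", call. = FALSE)
  }
  flags <- character()
  if (max(tot$count_per_g) / min(tot$count_per_g) < 3) {
    flags <- c(flags, "r_nonidentifiable")
  }
  model_logN <- function(rho, k_eff, N0, t) {
    # logistic closed form with effective rate rho = r - d, capacity k_eff
    log10(k_eff / (1 + (k_eff / N0 - 1) * exp(-rho * t)))
  }
  resid_fn <- function(par) {
    rho <- exp(par[1]); k_eff <- 10^par[2]
    pred <- model_logN(rho, k_eff, n0[match(pts$mouse_id, mice)], pts$time_h)
    pred - log10(pts$count_per_g)
  }
  n_max <- max(tot$count_per_g)
  starts <- cbind(log(c(0.5, 0.85, 0.1, 2, 4))[seq_len(n_starts)],
                  log10(n_max * c(1, 2, 1, 5, 0.8))[seq_len(n_starts)])
  best <- multistart_lm(resid_fn, starts)
  rho <- exp(best$par[1]); k_eff <- 10^best$par[2]
  r <- rho + d
  k <- k_eff * r / rho  # invert k_eff = k (1 - d/r)
  new_fit(c(r = r, k = k), objective = best$objective, flags = flags,
          data_ref = "monocolonization", convergence = best$info)
}

multistart_lm <- function(resid_fn, starts, ...) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200),
                         ...),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(fit$fvec^2)
    if (is.null(best) || obj < best$objective) {
      best <- list(par = fit$par, objective = obj, info = fit$info)
    }
  }
  if (is.null(best)) stop("optimizer failed from every start", call. = FALSE)
  best
}

#' Fit induction and latency rates from receptor-deletion data (stage 2)
#'
#' With the phage receptor deleted no adsorption occurs (`a = 0`) and the
#' dynamics reduce to `L`, `S` and the latent pool `Q` fed purely by
#' induction. `x` and `l` are fitted by nonlinear least squares on the
#' log10 densities of all three observed compartments, with `r`, `k`, `d`
#' fixed from stage 1 and each mouse's observed time-0 densities as
#' initial conditions.
#'
#' @param obs Observations containing `L`, `S_lineage` and `Q` series.
#' @param d,r,k Fixed parameters from stage 1.
#' @param n_starts Multi-start count.
#' @return A `phage_fit` with `estimates["x"]`, `estimates["l"]`. If every
#'   latent-cell count is zero/censored, `x` is reported at the boundary 0
#'   with flag `"x_at_boundary"`.
#' @export
fit_induction_latency <- function(obs, d = 0.25, r = 1.1, k = 4.6e9,
                                  n_starts = 5) {
  obs <- obs_check(obs)
  need <- c("L", "S_lineage", "Q")
  if (!all(need %in% unique(obs$compartment))) {
    stop("observations must include L, S_lineage and Q series", call. = FALSE)
  }
  mice <- unique(obs$mouse_id)
  times <- sort(unique(obs$time_h))
  init <- lapply(mice, function(m) {
    L0 <- obs_value(obs, m, 0, "L")
    S0 <- obs_value(obs, m, 0, "S_lineage")
    Q0 <- obs_value(obs, m, 0, "Q")
    if (is.na(L0) || is.na(S0)) {
      stop("mouse ", m, " lacks uncensored time-0 L and S densities",
           call. = FALSE)
    }
    phage_state(S = S0, L = L0, Q = if (is.na(Q0)) 0 else Q0)
  })
  names(init) <- mice
  usable <- obs[!obs$censored & obs$compartment %in% need & obs$time_h > 0, ]
  q_live <- any(usable$compartment == "Q")
  if (!q_live) {
    return(new_fit(c(x = 0, l = NA_real_), objective = NA_real_,
                   flags = "x_at_boundary",
                   data_ref = "lamB_competition"))
  }
  resid_fn <- function(par) {
    x <- 10^par[1]; l <- 10^par[2]
    p <- phage_params(d = d, r = r, k = k, x = x, l = l, y = 0, a = 0, g = 0)
    res <- lapply(mice, function(m) {
      tr <- simulate_populations(p, init[[m]], times)
      um <- usable[usable$mouse_id == m, ]
      pred <- vapply(seq_len(nrow(um)), function(i) {
        st <- trajectory_state(tr, um$time_h[i])
        state_observables(st)[[um$compartment[i]]]
      }, numeric(1))
      log10(pmax(pred, 1e-12)) - log10(um$count_per_g)
    })
    unlist(res)
  }
  starts <- cbind(log10(c(0.01, 0.001, 0.05, 0.1, 0.3))[seq_len(n_starts)],
                  log10(c(0.8, 0.2, 2, 0.05, 5))[seq_len(n_starts)])
  best <- multistart_lm(resid_fn, starts)
  new_fit(c(x = 10^best$par[1], l = 10^best$par[2]),
          objective = best$objective, data_ref = "lamB_competition",
          convergence = best$info)
}

#' Deduce the adsorption constant from the free-phage steady state (stage 3)
#'
#' At equilibrium the free-phage balance `y l Q* = (a N* + d) V*` links the
#' burst size and the adsorption constant linearly. Given `y` from the
#' in-vitro single-burst assay and observed late-time densities, the
#' inversion is
#' `a = (y l Q* - d V*) / (N* V*)`.
#'
#' @param y Burst size.
#' @param V_star,Q_star,N_star Observed equilibrium densities of free
#'   phage, latent cells and total bacteria (per g).
#' @param l Latency rate (stage 2), h^-1.
#' @param d Washout rate, h^-1.
#' @return List with `a` (g h^-1) and `flags` (contains `"clipped"` when
#'   the raw inversion was negative and has been clipped to 0).
#' @export
solve_adsorption <- function(y, V_star, Q_star, N_star, l, d = 0.25) {
  if (!is.finite(V_star) || V_star <= 0 || !is.finite(N_star) || N_star <= 0) {
    stop("equilibrium inversion undefined: V* and N* must be positive",
         call. = FALSE)
  }
  a <- (y * l * Q_star - d * V_star) / (N_star * V_star)
  flags <- character()
  if (a < 0) {
    a <- 0
    flags <- "clipped"
  }
  list(a = a, flags = flags)
}

#' Fit the lysogenization probability from wild-type competitions (stage 4)
#'
#' Bounded scalar least squares on the log lysogen-over-susceptible ratio
#' `L/(S+SL)` at the fitting time (default 36 h, where the competition
#' data resolve `g` best), across mice and initial-ratio groups, with all
#' other parameters fixed.
#'
#' @param obs Wild-type competition observations with `L` and `S_lineage`.
#' @param params Fixed `phage_params` (the fitted `g` replaces the one in
#'   `params`).
#' @param fit_time Fitting time in hours.
#' @param window Half-width (h) of acceptance around `fit_time`; defaults
#'   to the median sampling interval of the data.
#' @param all_times If `TRUE`, fit over every observation time up to 48 h
#'   instead of the single `fit_time`.
#' @return A `phage_fit` with `estimates["g"]`.
#' @export
fit_lysogenization <- function(obs, params, fit_time = 36, window = NULL,
                               all_times = FALSE) {
  obs <- obs_check(obs)
  p <- validate_params(params)
  times_all <- sort(unique(obs$time_h))
  if (is.null(window)) window <- stats::median(diff(times_all))
  use_times <- if (all_times) {
    times_all[times_all > 0 & times_all <= 48]
  } else {
    times_all[abs(times_all - fit_time) <= window & times_all > 0]
  }
  if (length(use_times) == 0) {
    stop("no observations within ", window, " h of t = ", fit_time,
         " h; available times: ", paste(times_all, collapse = ", "),
         call. = FALSE)
  }
  if (!all_times) use_times <- use_times[which.min(abs(use_times - fit_time))]
  mice <- unique(obs$mouse_id)
  cases <- list()
  for (m in mice) {
    L0 <- obs_value(obs, m, 0, "L")
    S0 <- obs_value(obs, m, 0, "S_lineage")
    if (is.na(L0) || is.na(S0)) next
    ratios <- vapply(use_times, function(tt) {
      Lt <- obs_value(obs, m, tt, "L")
      St <- obs_value(obs, m, tt, "S_lineage")
      if (is.na(Lt) || is.na(St) || St <= 0) NA_real_ else Lt / St
    }, numeric(1))
    keep <- !is.na(ratios)
    if (!any(keep)) next
    cases[[m]] <- list(init = phage_state(S = S0, L = L0),
                       times = use_times[keep], ratio = ratios[keep])
  }
  if (length(cases) == 0) stop("no usable mice for the g fit", call. = FALSE)
  objective <- function(g) {
    pg <- update_params(p, g = g)
    sum(vapply(cases, function(cs) {
      tr <- simulate_populations(pg, cs$init, unique(c(0, cs$times)))
      sum(vapply(seq_along(cs$times), function(i) {
        st <- trajectory_state(tr, cs$times[i])
        mod <- st[["L"]] / (st[["S"]] + st[["SL"]])
        (log10(cs$ratio[i]) - log10(mod))^2
      }, numeric(1)))
    }, numeric(1)))
  }
  opt <- stats::optimize(objective, interval = c(1e-4, 1), tol = 1e-6)
  new_fit(c(g = opt$minimum), objective = opt$objective,
          data_ref = "wt_competition")
}

#' Case bootstrap confidence intervals over mice
#'
#' Resamples whole mice with replacement, re-runs the estimator on each
#' replicate and returns percentile 2.5%/97.5% intervals. Replicates in
#' which the estimator fails are dropped and counted; more than 20%
#' failures aborts. Deterministic given the seed.
#'
#' @param estimator Function taking an observation set and returning a
#'   named numeric vector of estimates (or a `phage_fit`, whose
#'   `estimates` are used).
#' @param obs Observation set (long format, >= 3 mice).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param level Interval level (default 0.95).
#' @param type Interval type: `"percentile"` (plain 2.5/97.5 percentiles)
#'   or `"expanded"` (percentiles at levels widened by the
#'   t-versus-normal and (n-1)/n corrections; recommended with few mice,
#'   where the plain percentile interval is anti-conservative).
#' @return List with `ci` (matrix: parameters x lower/upper), `estimates`
#'   (replicate matrix), `n_boot`, `n_failed`, `seed`, `type`.
#' @references Hesterberg, T. (2015) What teachers should know about the
#'   bootstrap. The American Statistician 69(4), 371-386.
#' @export
bootstrap_ci <- function(estimator, obs, n_boot = 1000, seed = 1,
                         level = 0.95, type = c("percentile", "expanded")) {
  type <- match.arg(type)
  obs <- as.data.frame(obs)
  if (is.null(obs$mouse_id)) {
    stop("observations need a mouse_id column to resample over", call. = FALSE)
  }
  mice <- unique(obs$mouse_id)
  if (length(mice) < 3) stop("bootstrap needs >= 3 mice", call. = FALSE)
  split_obs <- split(obs, obs$mouse_id)
  draw <- with_seed(seed, {
    matrix(sample(length(mice), length(mice) * n_boot, replace = TRUE),
           nrow = n_boot)
  })
  reps <- vector("list", n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- draw[b, ]
    res <- lapply(seq_along(idx), function(j) {
      o <- split_obs[[idx[j]]]
      o$mouse_id <- sprintf("b%03d", j)
      o
    })
    ro <- do.call(rbind, res)
    for (at in c("config", "params", "detection_limit")) {
      attr(ro, at) <- attr(obs, at, exact = TRUE)
    }
    est <- tryCatch({
      e <- estimator(ro)
      if (inherits(e, "phage_fit")) e$estimates else e
    }, error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1L else reps[[b]] <- est
  }
  if (n_failed > 0.2 * n_boot) {
    stop("estimator failed in ", n_failed, "/", n_boot,
         " bootstrap replicates", call. = FALSE)
  }
  mat <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  alpha <- (1 - level) / 2
  if (type == "expanded") {
    n <- length(mice)
    alpha <- stats::pnorm(-sqrt(n / (n - 1)) * stats::qt(1 - alpha, n - 1))
  }
  ci <- t(apply(mat, 2, stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, estimates = mat, n_boot = n_boot, n_failed = n_failed,
       seed = seed, type = type)
}

#' Run the full sequential calibration pipeline
#'
#' Threads the four stages in order: growth (`r`, `k`) from
#' monocolonization, induction/latency (`x`, `l`) from receptor-deletion
#' competitions, adsorption (`a`) from the equilibrium free-phage balance,
#' lysogenization (`g`) from wild-type competitions. The washout rate `d`
#' and burst size `y` are fixed inputs (the former a gut-transit constant,
#' the latter measured in vitro).
#'
#' @param datasets List with elements `mono`, `lamB`, `competition`
#'   (observation sets) and `equilibrium` (named vector with `V`, `Q`,
#'   `N`), e.g. from [generate_bundle()].
#' @param d Fixed washout rate, h^-1.
#' @param y Fixed burst size.
#' @param fit_time Stage-4 fitting time, h.
#' @param verbose Log each stage with `message()`.
#' @return A `phage_fit` whose `estimates` is a full `phage_params`, with
#'   per-stage fits under `$stages`.
#' @export
estimate_all <- function(datasets, d = 0.25, y = 12.1, fit_time = 36,
                         verbose = FALSE) {
  need_stage <- function(el, stage, what) {
    if (is.null(datasets[[el]])) {
      stop("stage ", stage, " (", what, ") blocked: dataset '", el,
           "' is missing", call. = FALSE)
    }
    datasets[[el]]
  }
  say <- function(...) if (verbose) message(...)
  mono <- need_stage("mono", 1, "growth")
  st1 <- fit_growth(mono, d = d)
  say("stage 1: r = ", signif(st1$estimates[["r"]], 4),
      ", k = ", signif(st1$estimates[["k"]], 4),
      " (objective ", signif(st1$objective, 3), ")")
  lamB <- need_stage("lamB", 2, "induction/latency")
  st2 <- fit_induction_latency(lamB, d = d, r = st1$estimates[["r"]],
                               k = st1$estimates[["k"]])
  say("stage 2: x = ", signif(st2$estimates[["x"]], 4),
      ", l = ", signif(st2$estimates[["l"]], 4))
  eq <- need_stage("equilibrium", 3, "adsorption")
  if (!all(c("V", "Q", "N") %in% names(eq))) {
    stop("stage 3 (adsorption) blocked: equilibrium observations need ",
         "named elements V, Q, N", call. = FALSE)
  }
  st3 <- solve_adsorption(y = y, V_star = eq[["V"]], Q_star = eq[["Q"]],
                          N_star = eq[["N"]], l = st2$estimates[["l"]], d = d)
  say("stage 3: a = ", signif(st3$a, 4))
  comp <- need_stage("competition", 4, "lysogenization")
  fixed <- phage_params(d = d, r = st1$estimates[["r"]],
                        k = st1$estimates[["k"]], x = st2$estimates[["x"]],
                        l = st2$estimates[["l"]], y = y, a = st3$a, g = 0.5)
  st4 <- fit_lysogenization(comp, fixed, fit_time = fit_time)
  say("stage 4: g = ", signif(st4$estimates[["g"]], 4))
  est <- update_params(fixed, g = st4$estimates[["g"]])
  new_fit(est,
          objective = sum(st1$objective, st2$objective, st4$objective,
                          na.rm = TRUE),
          flags = c(st1$flags, st2$flags, st3$flags, st4$flags),
          data_ref = "sequential pipeline",
          stages = list(growth = st1, induction_latency = st2,
                        adsorption = st3, lysogenization = st4))
}
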