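#' Right-hand side of the five-population gut model
#'
#' Rates of change for susceptibles `S`, resident lysogens `L`, new
#' lysogens `SL`, latent cells `Q` and free phage `V`, with
#' `N = S + L + SL` the growing bacterial total:
#'
#' \deqn{dS/dt  = r S (1 - N/k) - a S V - d S}
#' \deqn{dL/dt  = r L (1 - N/k) - x L - d L}
#' \deqn{dSL/dt = r SL (1 - N/k) + g a S V - x SL - d SL}
#' \deqn{dQ/dt  = (1-g) a S V + x (L + SL) - l Q - d Q}
#' \deqn{dV/dt  = y l Q - a N V - d V}
#'
#' Free phage adsorb onto all bacteria (lysogens adsorb but are immune to
#' superinfection), hence the `-aNV` sink in `dV` while only `-aSV` removes
#' susceptibles. Washout `d` acts on every compartment; latent cells do not
#' divide.
#'
#' @param state A `phage_state` (or named numeric vector `S,L,SL,Q,V`).
#' @param params A `phage_params` vector.
#' @return Named numeric vector of derivatives (densities per hour).
#' @examples
#' phage_derivatives(phage_state(S = 1e6, L = 1e6), default_params())
#' @export
phage_derivatives <- function(state, params) {
  s <- validate_state(state)
  p <- validate_params(params)
  d <- rhs_core(unclass(s), unclass(p))
  names(d) <- STATE_NAMES
  d
}

# unvalidated core shared with the deSolve func (hot path)
rhs_core <- function(s, p) {
  N <- s[[1L]] + s[[2L]] + s[[3L]]
  grow <- p[["r"]] * (1 - N / p[["k"]])
  inf <- p[["a"]] * s[[1L]] * s[[5L]]
  c(grow * s[[1L]] - inf - p[["d"]] * s[[1L]],
    grow * s[[2L]] - (p[["x"]] + p[["d"]]) * s[[2L]],
    grow * s[[3L]] + p[["g"]] * inf - (p[["x"]] + p[["d"]]) * s[[3L]],
    (1 - p[["g"]]) * inf + p[["x"]] * (s[[2L]] + s[[3L]]) -
      (p[["l"]] + p[["d"]]) * s[[4L]],
    p[["y"]] * p[["l"]] * s[[4L]] - p[["a"]] * N * s[[5L]] - p[["d"]] * s[[5L]])
}

desolve_func <- function(t, s, p) list(rhs_core(s, p))

#' Integrate the gut model over a time grid
#'
#' Solves the five-ODE system with `deSolve::ode` in linear space. Small
#' negative excursions within the absolute tolerance are clamped to zero;
#' anything more negative aborts (it would indicate solver failure rather
#' than roundoff).
#'
#' @param params A `phage_params` vector.
#' @param init A `phage_state`: densities at time 0.
#' @param times Numeric grid of output times in hours; must start at 0 and
#'   be strictly increasing.
#' @param rtol,atol Relative / absolute solver tolerances. The absolute
#'   tolerance is in density units (cfu or pfu per gram); the default
#'   1e-2 cfu/g is far below one countable cell.
#' @param method Integration method passed to [deSolve::ode()]; `"lsoda"`
#'   (adaptive, default) or `"rk4"` (fixed step, used for cross-checks).
#' @return A `phage_trajectory`: a data.frame with columns
#'   `time_h, S, L, SL, Q, V`, carrying the parameters and solver settings
#'   as attributes.
#' @examples
#' tr <- simulate_populations(default_params(),
#'                            phage_state(S = 1e6, L = 1e6),
#'                            times = seq(0, 48, by = 1))
#' head(tr)
#' @export
simulate_populations <- function(params, init, times,
                                 rtol = 1e-8, atol = 1e-2,
                                 method = c("lsoda", "rk4")) {
  p <- validate_params(params)
  s0 <- validate_state(init)
  method <- match.arg(method)
  check_time_grid(times)
  out <- deSolve::ode(y = unclass(s0), times = times, func = desolve_func,
                      parms = unclass(p), method = method,
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0) {
    last_t <- out[nrow(out), 1L]
    stop("ODE integration failed (last valid time ", last_t, " h)",
         call. = FALSE)
  }
  as_trajectory(out, p, list(method = method, rtol = rtol, atol = atol))
}

check_time_grid <- function(times, from_zero = TRUE) {
  if (!is.numeric(times) || length(times) < 2) {
    stop("times must be a numeric grid with at least two points", call. = FALSE)
  }
  if (from_zero && times[1] != 0) stop("time grid must start at 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  invisible(times)
}

as_trajectory <- function(out, params, solver) {
  m <- unclass(out)
  atol <- solver$atol %||% 1e-2
  vals <- m[, STATE_NAMES, drop = FALSE]
  too_neg <- vals < -atol
  if (any(too_neg)) {
    stop("integration produced a component below -atol (",
         signif(min(vals), 4), "); reduce tolerances", call. = FALSE)
  }
  vals[vals < 0] <- 0
  tr <- data.frame(time_h = m[, 1L], vals)
  attr(tr, "params") <- params
  attr(tr, "solver") <- solver
  class(tr) <- c("phage_trajectory", "data.frame")
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the state at a given time from a trajectory
#'
#' @param trajectory A `phage_trajectory`.
#' @param time Time in hours; must be one of the trajectory's grid points.
#' @return A `phage_state`.
#' @export
trajectory_state <- function(trajectory, time) {
  i <- match(time, trajectory$time_h)
  if (is.na(i)) {
    stop("time ", time, " h is not on the trajectory grid", call. = FALSE)
  }
  phage_state(S = trajectory$S[i], L = trajectory$L[i], SL = trajectory$SL[i],
              Q = trajectory$Q[i], V = trajectory$V[i])
}

#' Two-phase simulation with a parameter switch
#'
#' Integrates with `params` up to `switch_time`, then continues from the
#' reached state with the overridden parameters. Used e.g. to emulate a
#' switch to a receptor-deletion regime (`a = 0`) at 48 h, or a
#' non-inducible prophage (`x = 2e-7`) in the second phase. The state is
#' continuous at the switch.
#'
#' @param params A `phage_params` vector for phase 1.
#' @param phase2 Named list/vector of parameter overrides for phase 2
#'   (empty means no change).
#' @param switch_time Switch time in hours, inside the range of `times`.
#' @param init Initial `phage_state`.
#' @param times Output time grid (starting at 0, strictly increasing).
#' @param ... Passed to [simulate_populations()] (tolerances, method).
#' @return A `phage_trajectory` on `times`, with attributes
#'   `switch_time` and `switch_state` (the state at the switch).
#' @export
two_phase_simulation <- function(params, phase2, switch_time, init, times, ...) {
  p1 <- validate_params(params)
  check_time_grid(times)
  if (switch_time < times[1] || switch_time > times[length(times)]) {
    stop("switch_time must lie within the time grid range", call. = FALSE)
  }
  p2 <- do.call(update_params, c(list(p1), as.list(phase2)))
  t1 <- unique(c(times[times <= switch_time], switch_time))
  tr1 <- simulate_populations(p1, init, t1, ...)
  s_switch <- trajectory_state(tr1, switch_time)
  t2 <- unique(c(switch_time, times[times > switch_time]))
  if (length(t2) > 1) {
    # integrate phase 2 on a grid shifted to start at the switch
    p2u <- unclass(p2)
    out2 <- deSolve::ode(y = unclass(s_switch), times = t2, func = desolve_func,
                         parms = p2u, rtol = list(...)$rtol %||% 1e-8,
                         atol = list(...)$atol %||% 1e-2)
    tr2 <- as_trajectory(out2, p2, attr(tr1, "solver"))
  } else {
    tr2 <- NULL
  }
  keep1 <- tr1[tr1$time_h %in% times, , drop = FALSE]
  if (!is.null(tr2)) {
    keep2 <- tr2[tr2$time_h %in% times & tr2$time_h > switch_time, , drop = FALSE]
    tr <- rbind(keep1, keep2)
  } else {
    tr <- keep1
  }
  rownames(tr) <- NULL
  attr(tr, "params") <- p1
  attr(tr, "phase2_params") <- p2
  attr(tr, "switch_time") <- switch_time
  attr(tr, "switch_state") <- s_switch
  attr(tr, "solver") <- attr(tr1, "solver")
  class(tr) <- c("phage_trajectory", "data.frame")
  tr
}

#' Find an equilibrium of the gut model
#'
#' Integrates over a long horizon to approach an attractor, then refines
#' the endpoint with a damped Newton iteration on the steady-state system
#' (numerical Jacobian). When growth cannot offset washout (`r <= d`) the
#' washout state (all compartments zero) is returned directly.
#'
#' @param params A `phage_params` vector.
#' @param init Initial `phage_state` guess; defaults to a mixed inoculum of
#'   1e6 cfu/g each of `S` and `L`.
#' @param horizon Integration horizon in hours before refinement.
#' @param tol Relative tolerance on the refined derivatives: each
#'   `|ds_i/dt|` must fall below `tol * max(state, 1)`.
#' @param max_iter Newton iteration cap.
#' @return A `phage_state` with attribute `residual` (max scaled
#'   derivative).
#' @examples
#' eq <- find_equilibrium(default_params())
#' @export
find_equilibrium <- function(params, init = phage_state(S = 1e6, L = 1e6),
                             horizon = 2000, tol = 1e-9, max_iter = 50) {
  p <- validate_params(params)
  if (p[["r"]] <= p[["d"]]) {
    eq <- phage_state()
    attr(eq, "residual") <- 0
    attr(eq, "washout") <- TRUE
    return(eq)
  }
  tr <- simulate_populations(p, init, times = c(0, horizon / 2, horizon))
  s <- unclass(trajectory_state(tr, horizon))
  pu <- unclass(p)
  f <- function(z) rhs_core(z, pu)
  scaled <- function(z) max(abs(f(z)) / pmax(abs(z), 1))
  for (it in seq_len(max_iter)) {
    if (scaled(s) < tol) break
    J <- num_jacobian(f, s)
    step <- tryCatch(solve(J, f(s)), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- s - lam * step
      cand[cand < 0 & cand > -1e-6] <- 0
      if (all(cand >= 0) && scaled(cand) < scaled(s)) { s <- cand; break }
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (lam < 1e-6) break
  }
  if (scaled(s) >= tol) {
    stop("equilibrium refinement did not converge (scaled residual ",
         signif(scaled(s), 3), ")", call. = FALSE)
  }
  s[s < 0] <- 0
  eq <- validate_state(s)
  attr(eq, "residual") <- scaled(unclass(eq))
  attr(eq, "washout") <- all(unclass(eq)[c("S", "L", "SL")] == 0)
  eq
}

num_jacobian <- function(f, x) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(1e-6 * abs(x[j]), 1e-4)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' @export
print.phage_trajectory <- function(x, ...) {
  cat("Phage-bacteria trajectory: ", nrow(x), " time points over [",
      x$time_h[1], ", ", x$time_h[nrow(x)], "] h\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4), ...)
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}
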