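p0 <- calibrated()

noiseless_mono <- function(n_mice = 3, times = c(0, 6, 24, 30, 48, 72, 96)) {
  generate_mouse_experiment(
    scenario_config("mono", n_mice = n_mice, times = times, cv = 0,
                    init_cv = 0, seed = 11), p0)
}

noiseless_lamB <- function(times = c(0, 6, 24, 48, 72, 96), params = p0) {
  generate_mouse_experiment(
    scenario_config("lamB_competition", n_mice = 3, ratio = "1:1",
                    total0 = 2e6, times = times, cv = 0, init_cv = 0,
                    seed = 12), params)
}

test_that("growth fit recovers r and k from noiseless monocolonization", {
  fit <- fit_growth(noiseless_mono(), d = 0.25)
  expect_equal(fit$estimates[["r"]], 1.1, tolerance = 1e-4)
  expect_equal(fit$estimates[["k"]], 4.6e9, tolerance = 1e-4)
  expect_length(fit$flags, 0)
})

test_that("growth fit is scale-equivariant and flags plateau-only data", {
  obs <- noiseless_mono()
  fit1 <- fit_growth(obs, d = 0.25)
  scaled <- obs
  scaled$count_per_g <- scaled$count_per_g * 7
  fit7 <- fit_growth(scaled, d = 0.25)
  expect_equal(fit7$estimates[["r"]], fit1$estimates[["r"]], tolerance = 1e-6)
  expect_equal(fit7$estimates[["k"]], 7 * fit1$estimates[["k"]],
               tolerance = 1e-6)

  plateau <- generate_mouse_experiment(
    scenario_config("mono", n_mice = 3, total0 = 3.5e9,
                    times = c(0, 24, 48, 72, 96), cv = 0, init_cv = 0,
                    seed = 13), p0)
  fitp <- fit_growth(plateau, d = 0.25)
  expect_true("r_nonidentifiable" %in% fitp$flags)
})

test_that("growth fit is accurate under the study's noise level", {
  hits <- 0L
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    obs <- generate_mouse_experiment(
      scenario_config("mono", n_mice = 4, times = c(0, 6, 24, 48, 72, 96),
                      cv = 0.2, init_cv = 0, seed = 100 + s), p0)
    r_hat <- fit_growth(obs, d = 0.25, n_starts = 2)$estimates[["r"]]
    if (r_hat >= 1.0 && r_hat <= 1.2) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("induction/latency fit recovers x and l from receptor-deletion data", {
  fit <- fit_induction_latency(noiseless_lamB(), d = 0.25, r = 1.1, k = 4.6e9)
  expect_equal(fit$estimates[["x"]], 0.016, tolerance = 0.01)
  expect_equal(fit$estimates[["l"]], 0.8, tolerance = 0.05)
})

test_that("zero induction is reported at the boundary with a flag", {
  obs <- noiseless_lamB(params = update_params(p0, x = 0))
  fit <- fit_induction_latency(obs, d = 0.25, r = 1.1, k = 4.6e9)
  expect_lt(fit$estimates[["x"]], 1e-4)
  expect_true("x_at_boundary" %in% fit$flags)
})

test_that("the (x, l) objective surface has its minimum at the truth", {
  obs <- generate_mouse_experiment(
    scenario_config("lamB_competition", n_mice = 1, ratio = "1:1",
                    total0 = 2e6, times = c(0, 6, 24, 48, 72, 96), cv = 0,
                    init_cv = 0, seed = 14), p0)
  usable <- obs[!obs$censored & obs$time_h > 0, ]
  init <- phage_state(
    S = obs$count_per_g[obs$compartment == "S_lineage" & obs$time_h == 0],
    L = obs$count_per_g[obs$compartment == "L" & obs$time_h == 0])
  # independent brute-force scan of the least-squares surface on a lattice
  # containing the generating pair
  xs <- 10^seq(log10(0.016) - 1, log10(0.016) + 1, length.out = 21)
  ls <- 10^seq(log10(0.8) - 1, log10(0.8) + 1, length.out = 21)
  ssr <- matrix(NA_real_, 21, 21)
  for (i in seq_along(xs)) {
    for (j in seq_along(ls)) {
      pp <- phage_params(d = 0.25, r = 1.1, k = 4.6e9, x = xs[i], l = ls[j],
                         y = 0, a = 0, g = 0)
      tr <- simulate_populations(pp, init, sort(unique(obs$time_h)))
      pred <- vapply(seq_len(nrow(usable)), function(rw) {
        state_observables(
          trajectory_state(tr, usable$time_h[rw]))[[usable$compartment[rw]]]
      }, numeric(1))
      ssr[i, j] <- sum((log10(pred) - log10(usable$count_per_g))^2)
    }
  }
  best <- which(ssr == min(ssr), arr.ind = TRUE)
  expect_equal(xs[best[1]], 0.016, tolerance = 1e-9)
  expect_equal(ls[best[2]], 0.8, tolerance = 1e-9)
})

test_that("adsorption inversion closes the equilibrium phage balance", {
  eq <- find_equilibrium(p0)
  N <- eq[["S"]] + eq[["L"]] + eq[["SL"]]
  sol <- solve_adsorption(y = 12.1, V_star = eq[["V"]], Q_star = eq[["Q"]],
                          N_star = N, l = 0.8, d = 0.25)
  expect_equal(sol$a, 2.6e-9, tolerance = 0.01)

  # production balancing washout exactly means no adsorption is needed
  bal <- solve_adsorption(y = 10, V_star = 10 * 0.8 * 100 / 0.25,
                          Q_star = 100, N_star = 1e9, l = 0.8, d = 0.25)
  expect_equal(bal$a, 0)

  # when washout is negligible, a is proportional to y
  s1 <- solve_adsorption(12, 1e7, 5e7, 3e9, l = 0.8, d = 0.25)
  s2 <- solve_adsorption(24, 1e7, 5e7, 3e9, l = 0.8, d = 0.25)
  expect_equal(s2$a / s1$a, 2, tolerance = 0.01)

  expect_error(solve_adsorption(12, 0, 1, 1e9, 0.8), "positive")
  expect_true("clipped" %in%
                solve_adsorption(12, 1e9, 1, 1e9, 0.8, d = 0.25)$flags)
})

wt_bundle_obs <- function(params = p0, cv = 0, seed = 20) {
  generate_bundle(params, n_mice = 2, cv = cv, init_cv = 0, seed = seed)
}

test_that("lysogenization fit recovers g from three-ratio competitions", {
  b <- wt_bundle_obs()
  fit <- fit_lysogenization(b$competition, p0, fit_time = 36)
  expect_equal(fit$estimates[["g"]], 0.19, tolerance = 0.02)

  # boundary recovery when every infection lysogenizes
  b1 <- wt_bundle_obs(params = update_params(p0, g = 1), seed = 21)
  fit1 <- fit_lysogenization(b1$competition, p0, fit_time = 36)
  expect_gt(fit1$estimates[["g"]], 0.98)

  expect_error(fit_lysogenization(b$competition, p0, fit_time = 300,
                                  window = 1), "available times")
})

test_that("the g objective is unimodal with its minimum at the truth", {
  b <- generate_bundle(p0, n_mice = 1, cv = 0, init_cv = 0, seed = 22)
  obs <- b$competition
  mice <- unique(obs$mouse_id)
  # independent grid scan of the 36 h log-ratio objective
  grid <- seq(0.01, 0.99, by = 0.02)
  objs <- vapply(grid, function(g) {
    pg <- update_params(p0, g = g)
    sum(vapply(mice, function(m) {
      L0 <- obs$count_per_g[obs$mouse_id == m & obs$time_h == 0 &
                              obs$compartment == "L"]
      S0 <- obs$count_per_g[obs$mouse_id == m & obs$time_h == 0 &
                              obs$compartment == "S_lineage"]
      L36 <- obs$count_per_g[obs$mouse_id == m & obs$time_h == 36 &
                               obs$compartment == "L"]
      S36 <- obs$count_per_g[obs$mouse_id == m & obs$time_h == 36 &
                               obs$compartment == "S_lineage"]
      tr <- simulate_populations(pg, phage_state(S = S0, L = L0), c(0, 36))
      st <- trajectory_state(tr, 36)
      (log10(L36 / S36) - log10(st[["L"]] / (st[["S"]] + st[["SL"]])))^2
    }, numeric(1)))
  }, numeric(1))
  i_min <- which.min(objs)
  expect_equal(grid[i_min], 0.19, tolerance = 0.011)  # nearest lattice point
  # unimodal: decreasing before the minimum, increasing after
  expect_true(all(diff(objs[1:i_min]) < 0))
  expect_true(all(diff(objs[i_min:length(objs)]) > 0))
})

test_that("bootstrap intervals are deterministic, ordered and tight at zero noise", {
  obs <- noiseless_mono(n_mice = 4)
  est <- function(o) fit_growth(o, d = 0.25, n_starts = 2)
  bs1 <- bootstrap_ci(est, obs, n_boot = 20, seed = 5)
  bs2 <- bootstrap_ci(est, obs, n_boot = 20, seed = 5)
  expect_identical(bs1$ci, bs2$ci)
  expect_true(all(bs1$ci[, "lower"] <= bs1$ci[, "upper"]))
  width <- (bs1$ci[, "upper"] - bs1$ci[, "lower"])
  point <- fit_growth(obs, d = 0.25)$estimates
  expect_true(all(width / abs(point[rownames(bs1$ci)]) < 0.01))
  expect_error(bootstrap_ci(est, obs[obs$mouse_id %in% c("m01", "m02"), ],
                            n_boot = 5, seed = 1), ">= 3 mice")
})

test_that("the sequential pipeline recovers the generating parameters", {
  b <- generate_bundle(p0, n_mice = 3, cv = 0, init_cv = 0, seed = 30)
  fit <- estimate_all(b, d = 0.25, y = 12.1)
  est <- fit$estimates
  for (nm in c("r", "k", "x", "a", "g")) {
    expect_equal(est[[nm]], p0[[nm]], tolerance = 0.05)
  }
  # l is weakly identified (wide interval in the calibration) but should
  # still be recovered on noiseless data
  expect_equal(est[["l"]], 0.8, tolerance = 0.2)
})

test_that("the pipeline errors on a missing dataset and ignores mouse labels", {
  b <- generate_bundle(p0, n_mice = 2, cv = 0, init_cv = 0, seed = 31)
  b_miss <- b
  b_miss$lamB <- NULL
  expect_error(estimate_all(b_miss), "stage 2")
  b_miss2 <- b
  b_miss2$equilibrium <- NULL
  expect_error(estimate_all(b_miss2), "stage 3")

  # relabeling mice changes nothing
  b_perm <- b
  relab <- function(o) {
    ids <- unique(o$mouse_id)
    map <- stats::setNames(rev(ids), ids)
    o$mouse_id <- unname(map[o$mouse_id])
    o
  }
  b_perm$mono <- relab(b$mono)
  b_perm$lamB <- relab(b$lamB)
  b_perm$competition <- relab(b$competition)
  f1 <- estimate_all(b)
  f2 <- estimate_all(b_perm)
  expect_equal(unclass(f1$estimates), unclass(f2$estimates), tolerance = 1e-9)
})

test_that("adding observation time never worsens the noiseless growth fit", {
  short <- noiseless_mono(times = c(0, 6, 24, 48))
  long <- noiseless_mono(times = c(0, 6, 24, 48, 72, 96))
  err <- function(fit) abs(fit$estimates[["r"]] / 1.1 - 1) +
    abs(fit$estimates[["k"]] / 4.6e9 - 1)
  expect_lte(err(fit_growth(long)), err(fit_growth(short)) + 1e-9)
})
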