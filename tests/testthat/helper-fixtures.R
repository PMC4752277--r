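# Shared fixtures: the calibrated parameter set and common inoculum states.
calibrated <- function() default_params()

mixed_inoculum <- function(S = 1e6, L = 1e6) phage_state(S = S, L = L)

# closed form of dN/dt = r N (1 - N/k) - d N: logistic with effective
# rate rho = r - d and capacity k_eff = k (1 - d/r)
logistic_washout <- function(t, N0, r, k, d) {
  rho <- r - d
  k_eff <- k * rho / r
  k_eff / (1 + (k_eff / N0 - 1) * exp(-rho * t))
}

# random valid parameter draw for property tests
random_params <- function() {
  phage_params(d = runif(1, 0, 0.5),
               r = runif(1, 0.3, 2),
               k = 10^runif(1, 8, 10),
               x = 10^runif(1, -4, -1),
               l = runif(1, 0.1, 2),
               y = runif(1, 1, 50),
               a = 10^runif(1, -11, -8),
               g = runif(1, 0, 1))
}

random_state <- function() {
  phage_state(S = 10^runif(1, 0, 7), L = 10^runif(1, 0, 7),
              SL = 10^runif(1, 0, 5), Q = 10^runif(1, 0, 5),
              V = 10^runif(1, 0, 6))
}

lineage_ratio <- function(tr, t) {
  st <- trajectory_state(tr, t)
  st[["L"]] / (st[["S"]] + st[["SL"]])
}
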