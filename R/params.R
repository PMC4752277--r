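#' Model parameters for the phage-bacteria gut model
#'
#' Bundles the eight rates and probabilities governing the five-population
#' dynamics: washout, logistic growth, prophage induction, latency, burst
#' size, adsorption and the lysis-lysogeny decision.
#'
#' @param d Intestinal dilution (washout) rate, per hour. Applies to all
#'   five compartments.
#' @param r Maximal bacterial growth rate, per hour, shared by both
#'   lineages (carrying a prophage is assumed cost-free apart from
#'   induction).
#' @param k Carrying capacity of the gut, cfu per gram of feces.
#' @param x Prophage induction rate, per lysogen per hour.
#' @param l Latency rate, per hour: the rate at which lytically committed
#'   (latent) cells burst.
#' @param y Burst size: phage particles released per lysed cell
#'   (dimensionless, >= 1 whenever phage production is modeled).
#' @param a Adsorption constant, gram x hour^-1: second-order rate of phage
#'   attachment to bacteria.
#' @param g Lysogenization probability: the probability that infection of a
#'   susceptible cell yields a new lysogen rather than a lytic infection.
#'   Must lie in [0, 1].
#'
#' @return A named numeric vector of class `phage_params` with elements
#'   `d, r, k, x, l, y, a, g`.
#' @examples
#' p <- default_params()
#' p["g"]
#' @seealso [default_params()], [read_params()], [simulate_populations()]
#' @export
phage_params <- function(d, r, k, x, l, y, a, g) {
  p <- c(d = d, r = r, k = k, x = x, l = l, y = y, a = a, g = g)
  validate_params(p)
}

PARAM_NAMES <- c("d", "r", "k", "x", "l", "y", "a", "g")

validate_params <- function(p) {
  p <- unclass(p)
  if (!is.numeric(p) || !all(PARAM_NAMES %in% names(p))) {
    stop("parameters must be a named numeric vector with elements ",
         paste(PARAM_NAMES, collapse = ", "), call. = FALSE)
  }
  p <- p[PARAM_NAMES]
  if (any(!is.finite(p))) {
    stop("non-finite parameter value: ",
         paste(PARAM_NAMES[!is.finite(p)], collapse = ", "), call. = FALSE)
  }
  if (any(p < 0)) {
    stop("negative parameter value: ",
         paste(PARAM_NAMES[p < 0], collapse = ", "), call. = FALSE)
  }
  if (p[["g"]] > 1) stop("g is a probability and must lie in [0, 1]", call. = FALSE)
  if (p[["y"]] < 1 && p[["y"]] != 0) {
    stop("burst size y must be >= 1 when phage production is modeled ",
         "(or 0 to disable it)", call. = FALSE)
  }
  structure(p, class = "phage_params")
}

#' Packaged default (calibrated) parameter set
#'
#' Reads the parameter configuration file shipped with the package, holding
#' the calibrated in-vivo values: d = 0.25 h^-1, r = 1.1 h^-1,
#' k = 4.6e9 cfu/g, x = 0.016 h^-1, l = 0.8 h^-1, y = 12.1,
#' a = 2.6e-9 g h^-1, g = 0.19.
#'
#' @return A `phage_params` vector.
#' @export
default_params <- function() {
  read_params(system.file("extdata", "params_default.conf",
                          package = "phagegut", mustWork = TRUE))
}

#' Replace a subset of parameters
#'
#' @param params A `phage_params` vector.
#' @param ... Named scalar replacements, e.g. `a = 0`.
#' @return A validated `phage_params` vector.
#' @export
update_params <- function(params, ...) {
  ov <- c(...)
  if (length(ov) == 0) return(validate_params(params))
  bad <- setdiff(names(ov), PARAM_NAMES)
  if (length(bad) > 0) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         "; valid names are ", paste(PARAM_NAMES, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[names(ov)] <- ov
  validate_params(p)
}

#' @export
print.phage_params <- function(x, ...) {
  cat("Phage-bacteria gut model parameters:\n")
  u <- c(d = "h^-1", r = "h^-1", k = "cfu/g", x = "h^-1", l = "h^-1",
         y = "", a = "g h^-1", g = "")
  for (nm in PARAM_NAMES) {
    cat(sprintf("  %s = %-12g %s\n", nm, x[[nm]], u[[nm]]))
  }
  invisible(x)
}

#' Construct a population state
#'
#' The five compartments tracked per gram of feces: susceptibles `S`,
#' resident lysogens `L`, newly lysogenized susceptibles `SL`, latent
#' (lytically committed) cells `Q` and free phage `V`. The total bacterial
#' population entering the logistic term is `N = S + L + SL` (latent cells
#' do not grow).
#'
#' @param S,L,SL,Q,V Non-negative densities; bacteria in cfu/g, phage in
#'   pfu/g.
#' @return A named numeric vector of class `phage_state`.
#' @export
phage_state <- function(S = 0, L = 0, SL = 0, Q = 0, V = 0) {
  s <- c(S = S, L = L, SL = SL, Q = Q, V = V)
  validate_state(s)
}

STATE_NAMES <- c("S", "L", "SL", "Q", "V")

validate_state <- function(s) {
  s <- unclass(s)
  if (!is.numeric(s) || !all(STATE_NAMES %in% names(s))) {
    stop("state must be a named numeric vector with elements ",
         paste(STATE_NAMES, collapse = ", "), call. = FALSE)
  }
  s <- s[STATE_NAMES]
  if (any(!is.finite(s))) stop("non-finite state component", call. = FALSE)
  if (any(s < 0)) {
    stop("negative state component: ",
         paste(STATE_NAMES[s < 0], collapse = ", "), call. = FALSE)
  }
  structure(s, class = "phage_state")
}

#' Map a model state to what plating measures
#'
#' Fecal plating distinguishes the resident lysogen lineage `L`, the
#' susceptible lineage total `S_lineage = S + SL` (both carry the
#' susceptible strain's marker), new lysogens `SL` (susceptible marker plus
#' prophage marker), free phage `V`, and - in receptor-deletion experiments
#' where free phage are removed by centrifugation - latent cells `Q`.
#'
#' @param state A `phage_state` or named numeric vector.
#' @return Named numeric vector with elements `L`, `S_lineage`, `SL`, `V`,
#'   `Q`.
#' @export
state_observables <- function(state) {
  s <- validate_state(state)
  c(L = s[["L"]], S_lineage = s[["S"]] + s[["SL"]], SL = s[["SL"]],
    V = s[["V"]], Q = s[["Q"]])
}
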