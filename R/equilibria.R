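#' Define a single binding substate
#'
#' A binding substate is one conformational state of the protein with its own
#' dissociation constant, molar binding enthalpy and apparent stoichiometry
#' (sites per protomer). In a two-state model, the apparent stoichiometries
#' are interpreted as the population fractions of protomers occupying each
#' slowly exchanging conformation.
#'
#' @param kd Dissociation constant (molar), must be > 0. Association constants
#'   are derived as `K = 1/kd` wherever the binding polynomial is evaluated.
#' @param dh Molar binding enthalpy (kcal/mol). Either sign is allowed;
#'   endothermic substates occur in practice.
#' @param n Apparent number of sites per protomer, >= 0.
#' @return An object of class `"binding_state"`.
#' @examples
#' binding_state(kd = 917e-9, dh = -2.3, n = 1.18)
#' @export
binding_state <- function(kd, dh, n = 1) {
  stopifnot(is.numeric(kd), length(kd) == 1L, is.finite(kd),
            is.numeric(dh), length(dh) == 1L, is.finite(dh),
            is.numeric(n), length(n) == 1L, is.finite(n))
  if (kd <= 0) stop("'kd' must be a positive molar concentration")
  if (n < 0) stop("'n' must be non-negative")
  structure(list(kd = kd, dh = dh, n = n), class = "binding_state")
}

#' Define a binding model with one or two independent substates
#'
#' Bundles one or two [binding_state()] objects, an optional competitor
#' (inhibitor) parameter set, and the temperature. States are stored in
#' canonical order of ascending `kd` (state 1 = higher affinity); competitor
#' parameters are reordered together with their states.
#'
#' @param states A `binding_state` or a list of one or two of them.
#' @param competitor Optional competitor parameters: a list with numeric
#'   vectors `kd_inh` and `dh_inh`, one entry per state (molar; kcal/mol).
#'   Used by [solve_competitive()] for displacement titrations in which the
#'   protein is pre-saturated with a non-transported blocker.
#' @param temperature Temperature in kelvin.
#' @return An object of class `"binding_model"`.
#' @examples
#' two_state <- binding_model(list(
#'   binding_state(kd = 1.3e-9, dh = -3.3, n = 0.64),
#'   binding_state(kd = 60.8e-9, dh = -7.1, n = 0.22)
#' ), temperature = 288.15)
#' @export
binding_model <- function(states, competitor = NULL, temperature = 288.15) {
  if (inherits(states, "binding_state")) states <- list(states)
  stopifnot(is.list(states))
  if (!length(states) %in% 1:2)
    stop("a binding model has one or two states")
  if (!all(vapply(states, inherits, logical(1), "binding_state")))
    stop("'states' must be binding_state objects")
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  if (!is.null(competitor)) {
    if (!is.list(competitor) ||
        !all(c("kd_inh", "dh_inh") %in% names(competitor)))
      stop("'competitor' needs fields kd_inh and dh_inh")
    if (length(competitor$kd_inh) != length(states) ||
        length(competitor$dh_inh) != length(states))
      stop("one (kd_inh, dh_inh) pair per state is required")
    if (any(competitor$kd_inh <= 0))
      stop("competitor kd_inh must be positive")
  }
  ord <- order(vapply(states, `[[`, numeric(1), "kd"))
  states <- states[ord]
  if (!is.null(competitor)) {
    competitor$kd_inh <- competitor$kd_inh[ord]
    competitor$dh_inh <- competitor$dh_inh[ord]
  }
  structure(list(states = states, competitor = competitor,
                 temperature = temperature),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("Binding model: %d state(s), T = %.2f K\n",
              length(x$states), x$temperature))
  for (i in seq_along(x$states)) {
    s <- x$states[[i]]
    cat(sprintf("  state %d: Kd = %.4g nM, dH = %.4g kcal/mol, n = %.4g\n",
                i, s$kd * 1e9, s$dh, s$n))
  }
  if (!is.null(x$competitor))
    cat(sprintf("  competitor: Kd_inh = %s nM, dH_inh = %s kcal/mol\n",
                paste(signif(x$competitor$kd_inh * 1e9, 4), collapse = ", "),
                paste(signif(x$competitor$dh_inh, 4), collapse = ", ")))
  invisible(x)
}

.kds <- function(model) vapply(model$states, `[[`, numeric(1), "kd")
.dhs <- function(model) vapply(model$states, `[[`, numeric(1), "dh")
.ns  <- function(model) vapply(model$states, `[[`, numeric(1), "n")

#' Binding polynomial of a one- or two-state model
#'
#' The partition function over ligation states for independent, nonidentical
#' sites: `1 + K1*S` for one state and `1 + K1*S + K2*S + K1*K2*S^2` for two,
#' with `Ki = 1/kd_i` and `S` the free substrate concentration.
#'
#' @param model A [binding_model()].
#' @param s_free Free substrate concentration(s), molar, >= 0. Vectorized.
#' @return Dimensionless partition value(s), >= 1.
#' @export
binding_polynomial <- function(model, s_free) {
  stopifnot(inherits(model, "binding_model"), is.numeric(s_free))
  if (any(s_free < 0)) stop("'s_free' must be non-negative")
  K <- 1 / .kds(model)
  if (length(K) == 1L) 1 + K * s_free
  else 1 + K[1] * s_free + K[2] * s_free + K[1] * K[2] * s_free^2
}

#' Bound sites per protomer at a given free substrate concentration
#'
#' Evaluates `[PS]/[P] = sum_i n_i * K_i * S / (1 + K_i * S)`, the expected
#' number of occupied sites per protomer for independent substates. The curve
#' is monotone in `s_free` and saturates at `sum(n_i)`.
#'
#' @inheritParams binding_polynomial
#' @return Bound sites per protomer, in `[0, sum(n)]`. Vectorized over
#'   `s_free`.
#' @export
fraction_bound <- function(model, s_free) {
  stopifnot(inherits(model, "binding_model"), is.numeric(s_free))
  if (any(s_free < 0)) stop("'s_free' must be non-negative")
  K <- 1 / .kds(model)
  n <- .ns(model)
  out <- 0
  for (i in seq_along(K)) out <- out + n[i] * K[i] * s_free / (1 + K[i] * s_free)
  out
}

# Vectorized bracketed bisection for the free-substrate mass balance
#   s + p_total * fraction_bound(s) - s_total = 0  on [0, s_total].
# The residual is strictly increasing in s, so the root is unique. A fixed
# iteration count reaches relative interval width 2^-iters (below `rtol`),
# which is immune to the catastrophic cancellation a Newton step can hit at
# quantitative-binding conditions (c >> 1).
.solve_free_vec <- function(K, n, s_total, p_total, rtol = 1e-12) {
  m <- max(length(s_total), length(p_total))
  s_total <- rep_len(s_total, m)
  p_total <- rep_len(p_total, m)
  lo <- numeric(m)
  hi <- s_total
  iters <- max(8L, ceiling(-log2(rtol)) + 2L)
  for (iter in seq_len(iters)) {
    mid <- (lo + hi) * 0.5
    bound <- 0
    for (i in seq_along(K))
      bound <- bound + n[i] * K[i] * mid / (1 + K[i] * mid)
    up <- mid + p_total * bound - s_total > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
  }
  (lo + hi) * 0.5
}

#' Solve the free-substrate mass balance
#'
#' Finds the free substrate concentration satisfying
#' `s_free + p_total * fraction_bound(model, s_free) = s_total`
#' by bracketed bisection on `[0, s_total]`. The residual is strictly
#' monotone, so the bracketed root is unique.
#'
#' @inheritParams binding_polynomial
#' @param s_total Total substrate concentration(s), molar, >= 0. Vectorized.
#' @param p_total Total protein (protomer) concentration, molar, >= 0.
#' @param rtol Relative tolerance on the bracketing interval.
#' @return Free substrate concentration(s), molar.
#' @examples
#' m <- binding_model(binding_state(kd = 1e-6, dh = -5, n = 1))
#' solve_free_ligand(m, s_total = 5e-6, p_total = 10e-6) # (-6 + sqrt(56))/2 uM
#' @export
solve_free_ligand <- function(model, s_total, p_total, rtol = 1e-12) {
  stopifnot(inherits(model, "binding_model"),
            is.numeric(s_total), is.numeric(p_total))
  if (any(s_total < 0) || any(p_total < 0))
    stop("total concentrations must be non-negative")
  .solve_free_vec(1 / .kds(model), .ns(model), s_total, p_total, rtol)
}

# Per-state occupancies for the three-species (substrate + inhibitor)
# competition: theta_S,i = K_i S / (1 + K_i S + Kinh_i I) and symmetrically
# for the inhibitor. Returns a list of matrices [point, state].
.occupancy_competitive <- function(K, Kinh, n, s_free, i_free) {
  m <- max(length(s_free), length(i_free))
  s_free <- rep_len(s_free, m)
  i_free <- rep_len(i_free, m)
  thS <- thI <- matrix(0, m, length(K))
  for (j in seq_along(K)) {
    den <- 1 + K[j] * s_free + Kinh[j] * i_free
    thS[, j] <- K[j] * s_free / den
    thI[, j] <- Kinh[j] * i_free / den
  }
  list(theta_s = thS, theta_i = thI)
}

#' Solve the coupled substrate/inhibitor mass balances
#'
#' For a model with competitor parameters, solves the two coupled mass
#' balances of a displacement titration (substrate titrated into protein
#' pre-equilibrated with inhibitor). Per-state occupancies are
#' `theta_S,i = K_i*S / (1 + K_i*S + Kinh_i*I)` and symmetrically for the
#' inhibitor. Nested bracketed bisection: the outer loop solves the inhibitor
#' balance over `i_free`, the inner loop the substrate balance.
#'
#' @inheritParams solve_free_ligand
#' @param i_total Total inhibitor concentration(s), molar, >= 0. Vectorized
#'   together with `s_total`.
#' @return A list with molar vectors `s_free` and `i_free`.
#' @export
solve_competitive <- function(model, s_total, i_total, p_total,
                              rtol = 1e-12) {
  stopifnot(inherits(model, "binding_model"))
  if (is.null(model$competitor))
    stop("model has no competitor parameters")
  if (any(s_total < 0) || any(i_total < 0) || any(p_total < 0))
    stop("total concentrations must be non-negative")
  K <- 1 / .kds(model)
  Kinh <- 1 / model$competitor$kd_inh
  n <- .ns(model)
  m <- max(length(s_total), length(i_total), length(p_total))
  s_total <- rep_len(s_total, m)
  i_total <- rep_len(i_total, m)
  p_total <- rep_len(p_total, m)

  # inner: substrate balance at fixed free inhibitor (vectorized bisection)
  inner_s <- function(i_free) {
    lo <- numeric(m)
    hi <- s_total
    for (iter in 1:120) {
      mid <- (lo + hi) / 2
      occ <- .occupancy_competitive(K, Kinh, n, mid, i_free)
      bound <- drop(occ$theta_s %*% n)
      res <- mid + p_total * bound - s_total
      up <- res > 0
      hi[up] <- mid[up]
      lo[!up] <- mid[!up]
      if (all(hi - lo <= rtol * pmax(s_total, 1e-30))) break
    }
    (lo + hi) / 2
  }
  # outer: inhibitor balance; its residual is increasing in i_free
  lo <- numeric(m)
  hi <- i_total
  for (iter in 1:120) {
    mid <- (lo + hi) / 2
    s_free <- inner_s(mid)
    occ <- .occupancy_competitive(K, Kinh, n, s_free, mid)
    res <- mid + p_total * drop(occ$theta_i %*% n) - i_total
    up <- res > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
    if (all(hi - lo <= rtol * pmax(i_total, 1e-30))) break
  }
  i_free <- (lo + hi) / 2
  list(s_free = inner_s(i_free), i_free = i_free)
}
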