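# Gas constant in kcal / (mol K)
.R_KCAL <- 1.987e-3

#' Standard binding free energy from a dissociation constant
#'
#' `dG = R * T * ln(Kd / 1 M)` at the 1 M reference concentration; negative
#' (favourable) for sub-molar Kd.
#'
#' @param kd Dissociation constant(s), molar, > 0.
#' @param temperature Temperature, kelvin, > 0.
#' @return Free energy in kcal/mol.
#' @examples
#' delta_g_from_kd(1.3e-9, 288.15)  # about -11.7 kcal/mol
#' @export
delta_g_from_kd <- function(kd, temperature) {
  stopifnot(is.numeric(kd), is.numeric(temperature))
  if (any(kd <= 0)) stop("'kd' must be positive")
  if (any(temperature <= 0)) stop("'temperature' must be positive")
  .R_KCAL * temperature * log(kd)
}

#' Conformational free energy difference from substate populations
#'
#' Treats the fitted apparent stoichiometries of a two-state fit as the
#' populations of two non-exchanging conformations and converts their ratio
#' `Keq = n1/n2` into the free energy of the state-1 -> state-2 step:
#' `dG = R * T * ln(n1/n2)`. A larger state-1 population therefore makes
#' state 2 higher in free energy (positive dG); equal populations are
#' isoenergetic.
#'
#' @param n1,n2 Substate populations (apparent stoichiometries), > 0.
#' @param temperature Temperature, kelvin.
#' @return Free energy of the 1 -> 2 conformational step, kcal/mol.
#' @examples
#' delta_g_from_populations(0.64, 0.22, 288.15)  # about +0.61 kcal/mol
#' @export
delta_g_from_populations <- function(n1, n2, temperature) {
  stopifnot(is.numeric(n1), is.numeric(n2), is.numeric(temperature))
  if (any(n1 <= 0) || any(n2 <= 0))
    stop("populations must be positive")
  if (any(temperature <= 0)) stop("'temperature' must be positive")
  .R_KCAL * temperature * log(n1 / n2)
}

#' Build the four-edge free-energy ledger of a two-substate binding cycle
#'
#' The thermodynamic square connects apo and substrate-bound forms of the
#' two conformations: the apo conformational edge comes from the fitted
#' populations (`Keq = n1/n2`), the two binding edges from the fitted Kds,
#' and the bound conformational edge is inferred by cycle closure
#' (`dG_conf_apo + dG_bind2 - dG_bind1 - dG_conf_bound = 0`), which holds by
#' construction. Measured edges are marked `"measured"`, the closure edge
#' `"inferred"`.
#'
#' @param fit A two-state [itc_fit()] result (or a two-state
#'   [binding_model()]).
#' @param temperature Temperature in kelvin; defaults to the model's.
#' @return An object of class `"thermo_ledger"` with the four edge energies
#'   (kcal/mol) and their provenance.
#' @export
build_ledger <- function(fit, temperature = NULL) {
  model <- if (inherits(fit, "itc_fit")) fit$model
  else if (inherits(fit, "binding_model")) fit
  else stop("'fit' must be an itc_fit or binding_model")
  if (length(model$states) != 2L)
    stop("the free-energy ledger requires a two-state model")
  Tk <- if (is.null(temperature)) model$temperature else temperature
  kd <- .kds(model)
  n <- .ns(model)
  g_bind1 <- delta_g_from_kd(kd[1], Tk)
  g_bind2 <- delta_g_from_kd(kd[2], Tk)
  g_apo <- delta_g_from_populations(n[1], n[2], Tk)
  g_bound <- g_apo + g_bind2 - g_bind1
  closure <- g_apo + g_bind2 - g_bind1 - g_bound
  stopifnot(abs(closure) < 1e-12)
  structure(list(
    temperature = Tk,
    dg_conf_apo = g_apo,
    dg_bind_state1 = g_bind1,
    dg_bind_state2 = g_bind2,
    dg_conf_bound = g_bound,
    closure = closure,
    provenance = c(dg_conf_apo = "measured", dg_bind_state1 = "measured",
                   dg_bind_state2 = "measured",
                   dg_conf_bound = "inferred"),
    populations = n, kd = kd), class = "thermo_ledger")
}

#' @export
print.thermo_ledger <- function(x, ...) {
  f <- function(v) sprintf("%+.2f", v)
  cat(sprintf("Free-energy ledger at %.2f K (kcal/mol)\n", x$temperature))
  cat(sprintf("  apo:    state1 --[%s, %s]--> state2\n",
              f(x$dg_conf_apo), x$provenance["dg_conf_apo"]))
  cat(sprintf("  bind:   state1 %s   state2 %s (both measured)\n",
              f(x$dg_bind_state1), f(x$dg_bind_state2)))
  cat(sprintf("  bound:  state1 --[%s, %s]--> state2\n",
              f(x$dg_conf_bound), x$provenance["dg_conf_bound"]))
  cat(sprintf("  cycle closure residual: %.2g\n", x$closure))
  invisible(x)
}
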