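#' Published fitted binding parameters used as generating truths
#'
#' Fitted (Kd, dH, n) parameter sets reported for aspartate binding to the
#' outward-facing state of the sodium-coupled aspartate transporter under
#' different salt conditions at 15 C. The 50 mM NaCl condition is
#' single-state; the 500 mM salt conditions resolve two slowly exchanging
#' substates (state 1 = higher affinity, lower exothermic enthalpy). These
#' serve as generating truths for parameter-recovery simulations.
#'
#' @return A named list of [binding_model()] objects:
#'   `nacl_50mM`, `nacl_500mM`, `nacl_1M`, `gluconate_500mM`,
#'   `nano3_500mM`.
#' @export
reference_binding_models <- function() {
  Tk <- 288.15
  list(
    nacl_50mM = binding_model(
      binding_state(kd = 917e-9, dh = -2.3, n = 1.18), temperature = Tk),
    nacl_500mM = binding_model(list(
      binding_state(kd = 1.3e-9, dh = -3.3, n = 0.64),
      binding_state(kd = 60.8e-9, dh = -7.1, n = 0.22)), temperature = Tk),
    nacl_1M = binding_model(list(
      binding_state(kd = 0.5e-9, dh = -3.7, n = 0.77),
      binding_state(kd = 27.4e-9, dh = -8.7, n = 0.38)), temperature = Tk),
    gluconate_500mM = binding_model(list(
      binding_state(kd = 4.4e-9, dh = -2.3, n = 1.00),
      binding_state(kd = 138.3e-9, dh = -5.5, n = 0.28)), temperature = Tk),
    nano3_500mM = binding_model(list(
      binding_state(kd = 0.9e-9, dh = -2.1, n = 0.62),
      binding_state(kd = 34.3e-9, dh = -6.5, n = 0.37)), temperature = Tk))
}

#' Published modal transport fractions used as generating truths
#'
#' Slow-transporter percentages from global shared-rate triexponential fits
#' of single-transporter uptake in three anion conditions (means of three
#' experiments): 87.3% in nitrate, 81.1% in gluconate, 79.5% in chloride.
#' The fast/intermediate split of the remainder and the rate triple are not
#' published; defaults follow the description of modal rates differing by
#' orders of magnitude.
#'
#' @return A list with `fractions` (named list of percentage triples,
#'   fast/intermediate/slow, each summing to 100) and `rates` (1/s).
#' @export
reference_uptake_conditions <- function() {
  list(
    fractions = list(
      NaNO3 = c(fast = 5.0, intermediate = 7.7, slow = 87.3),
      gluconate = c(fast = 7.4, intermediate = 11.5, slow = 81.1),
      NaCl = c(fast = 8.0, intermediate = 12.5, slow = 79.5)),
    rates = c(fast = 0.1, intermediate = 0.01, slow = 0.001))
}
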