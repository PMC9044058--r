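#' Noise specification for the synthetic data generators
#'
#' @param sigma_isotherm Gaussian noise on normalized heats, expressed as a
#'   fraction of the first injection's absolute normalized heat
#'   (default 0.005, i.e. 0.5%).
#' @param sigma_uptake Gaussian noise on the fractional uptake scale
#'   (default 0.02).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(sigma_isotherm = 0.005, sigma_uptake = 0.02,
                       seed = NULL) {
  stopifnot(sigma_isotherm >= 0, sigma_uptake >= 0)
  structure(list(sigma_isotherm = sigma_isotherm,
                 sigma_uptake = sigma_uptake, seed = seed),
            class = "noise_spec")
}

#' Generate a noisy synthetic ITC isotherm
#'
#' Runs the injection-heat forward model and adds seeded Gaussian noise to
#' the normalized heats (standard deviation = `sigma_isotherm` times the
#' first injection's absolute normalized heat). Raw heats are recomputed
#' consistently. Generating parameters and the seed are stored in the
#' isotherm's `provenance` attribute.
#'
#' @inheritParams simulate_injection_heats
#' @param noise A [noise_spec()].
#' @return An [`isotherm`][simulate_injection_heats].
#' @export
generate_isotherm <- function(model, protocol, noise = noise_spec(),
                              dilution_heat = 0,
                              condition = NA_character_) {
  stopifnot(inherits(noise, "noise_spec"))
  iso <- simulate_injection_heats(model, protocol,
                                  dilution_heat = dilution_heat,
                                  condition = condition)
  if (noise$sigma_isotherm > 0) {
    sd_abs <- noise$sigma_isotherm *
      abs(iso$normalized_heat_kcal_per_mol[1])
    eps <- .with_seed(noise$seed, stats::rnorm(nrow(iso), 0, sd_abs))
    iso$normalized_heat_kcal_per_mol <-
      iso$normalized_heat_kcal_per_mol + eps
    iso$raw_heat_ucal <- iso$normalized_heat_kcal_per_mol *
      iso$moles_injected * 1e9
  }
  attr(iso, "provenance") <- list(model = model,
                                  dilution_heat = dilution_heat,
                                  noise = noise)
  iso
}

#' Generate synthetic multi-phase uptake curves
#'
#' Produces per-condition fractional uptake time courses
#' `Y(t) = sum_i f_i (1 - exp(-k_i t)) / 100` plus seeded Gaussian noise,
#' reported in percent of total observable transport — the scale on which
#' normalized single-transporter uptake data are analysed.
#'
#' @param fractions Named list (one entry per condition) of phase
#'   percentages, each summing to 100. Entries are ordered to match `rates`.
#' @param rates Positive rate constants (1/s), one per phase, shared across
#'   conditions.
#' @param times Time grid in seconds.
#' @param noise A [noise_spec()] (`sigma_uptake` applies, fractional scale).
#' @return Data frame with columns `condition`, `time_s`, `uptake_pct` and
#'   a `provenance` attribute carrying the generating values and seed.
#' @examples
#' curves <- generate_uptake_curves(
#'   fractions = list(NaNO3 = c(5.0, 7.7, 87.3)),
#'   rates = c(0.1, 0.01, 0.001),
#'   times = seq(0, 3000, by = 10),
#'   noise = noise_spec(seed = 1))
#' @export
generate_uptake_curves <- function(fractions, rates,
                                   times = seq(0, 3000, by = 5),
                                   noise = noise_spec()) {
  stopifnot(is.list(fractions), length(fractions) >= 1,
            inherits(noise, "noise_spec"))
  if (is.null(names(fractions)) || any(names(fractions) == ""))
    stop("'fractions' must be a named list (names = conditions)")
  if (any(rates <= 0)) stop("rates must be positive")
  for (f in fractions) {
    if (length(f) != length(rates))
      stop("each condition needs one fraction per rate")
    if (any(f < 0) || abs(sum(f) - 100) > 1e-6)
      stop("fractions must be non-negative and sum to 100")
  }
  if (any(times < 0)) stop("times must be non-negative")
  out <- .with_seed(noise$seed, {
    rows <- lapply(names(fractions), function(cond) {
      yy <- .triexp_curve(times, rates, fractions[[cond]] / 100)
      if (noise$sigma_uptake > 0)
        yy <- yy + stats::rnorm(length(times), 0, noise$sigma_uptake)
      data.frame(condition = cond, time_s = times, uptake_pct = 100 * yy)
    })
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  attr(out, "provenance") <- list(fractions = fractions, rates = rates,
                                  noise = noise)
  out
}
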