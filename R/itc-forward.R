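#' Describe an ITC titration protocol
#'
#' Cell and syringe parameters for a perfusion-cell titration. Defaults match
#' a small-volume instrument: a 300 ul active cell, 25 x 2 ul injections, and
#' a syringe concentration reaching about 2.5 molar equivalents of a 40 uM
#' protein solution.
#'
#' @param p_cell Initial protein (protomer) concentration in the cell, molar.
#' @param s_syringe Titrant (substrate) concentration in the syringe, molar.
#' @param cell_volume Active cell volume, liters.
#' @param injection_volumes Ordered injection volumes, liters. At least 5
#'   injections are required.
#' @param temperature Temperature, kelvin.
#' @param i_cell Optional initial inhibitor concentration in the cell, molar
#'   (competition mode: protein pre-saturated with a blocker).
#' @return An object of class `"titration_protocol"`.
#' @export
titration_protocol <- function(p_cell = 40e-6, s_syringe = 600e-6,
                               cell_volume = 300e-6,
                               injection_volumes = rep(2e-6, 25),
                               temperature = 288.15, i_cell = NULL) {
  stopifnot(is.numeric(p_cell), p_cell > 0,
            is.numeric(s_syringe), s_syringe > 0,
            is.numeric(cell_volume), cell_volume > 0,
            is.numeric(injection_volumes), all(injection_volumes > 0),
            is.numeric(temperature), temperature > 0)
  if (length(injection_volumes) < 5L)
    stop("a protocol needs at least 5 injections")
  if (!is.null(i_cell)) stopifnot(is.numeric(i_cell), i_cell > 0)
  structure(list(p_cell = p_cell, s_syringe = s_syringe,
                 cell_volume = cell_volume,
                 injection_volumes = injection_volumes,
                 temperature = temperature, i_cell = i_cell),
            class = "titration_protocol")
}

#' @export
print.titration_protocol <- function(x, ...) {
  cat(sprintf(
    "Titration protocol: %.0f ul cell, %.4g uM protein, %.4g uM syringe\n",
    x$cell_volume * 1e6, x$p_cell * 1e6, x$s_syringe * 1e6))
  cat(sprintf("  %d injections (total %.1f ul), T = %.2f K\n",
              length(x$injection_volumes),
              sum(x$injection_volumes) * 1e6, x$temperature))
  if (!is.null(x$i_cell))
    cat(sprintf("  inhibitor in cell: %.4g uM\n", x$i_cell * 1e6))
  invisible(x)
}

.new_isotherm <- function(df, protocol, condition = NA_character_,
                          dilution_offset = 0, provenance = NULL) {
  structure(df,
            class = c("isotherm", "data.frame"),
            protocol = protocol, condition = condition,
            dilution_offset = dilution_offset, provenance = provenance)
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("ITC isotherm: %d injections%s\n", nrow(x),
              if (is.na(attr(x, "condition"))) ""
              else paste0(" [", attr(x, "condition"), "]")))
  print.data.frame(format(as.data.frame(x), digits = 4), ...)
  off <- attr(x, "dilution_offset")
  if (!is.null(off) && off != 0)
    cat(sprintf("dilution offset subtracted: %.4g kcal/mol\n", off))
  invisible(x)
}

# Perfusion-cell concentration bookkeeping: each injection of volume dv
# displaces an equal volume of cell content, so existing species are diluted
# by (1 - dv/V0) while dv/V0 of the syringe content is added.
.cell_concentrations <- function(protocol) {
  dv <- protocol$injection_volumes
  V0 <- protocol$cell_volume
  k <- length(dv)
  p <- s <- i <- numeric(k)
  pc <- protocol$p_cell
  sc <- 0
  ic <- if (is.null(protocol$i_cell)) 0 else protocol$i_cell
  for (j in seq_len(k)) {
    d <- dv[j] / V0
    pc <- pc * (1 - d)
    ic <- ic * (1 - d)
    sc <- sc * (1 - d) + protocol$s_syringe * d
    p[j] <- pc; s[j] <- sc; i[j] <- ic
  }
  list(p = p, s = s, i = i)
}

#' Simulate per-injection ITC heats
#'
#' Forward model from a binding model and a titration protocol to integrated
#' per-injection heats. The cell is treated as a constant-volume perfusion
#' cell: each injection displaces an equal volume of cell content. The heat
#' content of the cell after injection i is
#' `Q_i = V0 * P_i * sum_j n_j * dH_j * theta_j(s_free_i)` (plus the
#' inhibitor-release term in competition mode), and the measured heat is
#' `q_i = Q_i - Q_{i-1} + (dv_i/V0) * (Q_i + Q_{i-1})/2 + dilution_heat *
#' moles injected`, the middle term compensating heat carried out with the
#' displaced liquid.
#'
#' @param model A [binding_model()]; needs competitor parameters when the
#'   protocol has `i_cell` set.
#' @param protocol A [titration_protocol()].
#' @param dilution_heat Constant heat of titrant dilution, kcal per mole of
#'   injectant.
#' @param condition Optional condition label stored with the isotherm.
#' @return An object of class `"isotherm"`: a data frame with columns
#'   `injection_index`, `injection_volume_ul`, `moles_injected`,
#'   `molar_ratio` (cumulative ligand / protein in the cell), `raw_heat_ucal`
#'   and `normalized_heat_kcal_per_mol`, with the protocol attached as an
#'   attribute.
#' @examples
#' m <- binding_model(binding_state(kd = 917e-9, dh = -2.3, n = 1.18))
#' iso <- simulate_injection_heats(m, titration_protocol())
#' sum(iso$raw_heat_ucal) # approaches V0 * P * n * dH at saturation
#' @export
simulate_injection_heats <- function(model, protocol, dilution_heat = 0,
                                     condition = NA_character_) {
  stopifnot(inherits(model, "binding_model"),
            inherits(protocol, "titration_protocol"))
  competition <- !is.null(protocol$i_cell)
  if (competition && is.null(model$competitor))
    stop("protocol has an inhibitor but the model has no competitor ",
         "parameters")
  V0 <- protocol$cell_volume
  dv <- protocol$injection_volumes
  conc <- .cell_concentrations(protocol)
  n <- .ns(model)
  dh <- .dhs(model)
  K <- 1 / .kds(model)

  if (competition) {
    sol <- solve_competitive(model, conc$s, conc$i, conc$p)
    occ <- .occupancy_competitive(K, 1 / model$competitor$kd_inh, n,
                                  sol$s_free, sol$i_free)
    per_protomer <- drop(occ$theta_s %*% (n * dh)) +
      drop(occ$theta_i %*% (n * model$competitor$dh_inh))
  } else {
    s_free <- solve_free_ligand(model, conc$s, conc$p)
    per_protomer <- 0
    for (j in seq_along(K)) {
      th <- K[j] * s_free / (1 + K[j] * s_free)
      per_protomer <- per_protomer + n[j] * dh[j] * th
    }
  }
  Q <- V0 * conc$p * per_protomer                    # kcal in cell
  # initial cell heat content: inhibitor-bound heat before any substrate
  Q0 <- if (competition) {
    occ0 <- .occupancy_competitive(K, 1 / model$competitor$kd_inh, n,
                                   0, solve_competitive(
                                     model, 0, protocol$i_cell,
                                     protocol$p_cell)$i_free)
    V0 * protocol$p_cell * drop(occ0$theta_i %*% (n * model$competitor$dh_inh))
  } else 0
  Qprev <- c(Q0, Q[-length(Q)])
  moles <- protocol$s_syringe * dv
  q <- Q - Qprev + (dv / V0) * (Q + Qprev) / 2 + dilution_heat * moles

  df <- data.frame(
    injection_index = seq_along(dv),
    injection_volume_ul = dv * 1e6,
    moles_injected = moles,
    molar_ratio = conc$s / conc$p,
    raw_heat_ucal = q * 1e9,
    normalized_heat_kcal_per_mol = q / moles
  )
  .new_isotherm(df, protocol, condition = condition)
}

#' Subtract dilution heats estimated from post-saturation injections
#'
#' Estimates the constant dilution heat as the mean normalized heat of the
#' last `n_tail` injections (assumed past saturation) and subtracts it from
#' every injection. The subtracted constant is recorded in the
#' `dilution_offset` attribute.
#'
#' @param isotherm An [`isotherm`][simulate_injection_heats].
#' @param n_tail Number of tail injections used to estimate the offset; must
#'   be smaller than the number of injections.
#' @return The corrected isotherm.
#' @export
correct_dilution_heats <- function(isotherm, n_tail = 5) {
  stopifnot(inherits(isotherm, "isotherm"))
  k <- nrow(isotherm)
  if (n_tail < 1 || n_tail >= k)
    stop("'n_tail' must be in [1, number of injections - 1]")
  tail_idx <- seq.int(k - n_tail + 1L, k)
  offset <- mean(isotherm$normalized_heat_kcal_per_mol[tail_idx])
  isotherm$normalized_heat_kcal_per_mol <-
    isotherm$normalized_heat_kcal_per_mol - offset
  isotherm$raw_heat_ucal <- isotherm$raw_heat_ucal -
    offset * isotherm$moles_injected * 1e9
  attr(isotherm, "dilution_offset") <-
    attr(isotherm, "dilution_offset") + offset
  isotherm
}
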