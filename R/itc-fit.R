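# Internal fitting engine shared by itc_fit() and scan_identifiability().
#
# Parameterization: log10(kd) for each state (kd spans decades), linear
# enthalpies, stoichiometries bounded to (0, 3], plus a constant dilution
# offset (kcal per mole of injectant). Multistart seeding is uniform in
# log10(kd) over [1e-10, 1e-5] M.

.par_names <- function(type) {
  if (type == "single") c("kd", "dh", "n", "dq")
  else c("kd1", "kd2", "dh1", "dh2", "n1", "n2", "dq")
}

# transformed-scale bounds (lkd, dh, n, dq)
.par_bounds <- function(type) {
  if (type == "single")
    list(lower = c(-13, -Inf, 1e-4, -Inf), upper = c(-2, Inf, 3, Inf))
  else
    list(lower = c(-13, -13, -Inf, -Inf, 1e-4, 1e-4, -Inf),
         upper = c(-2, -2, Inf, Inf, 3, 3, Inf))
}

.to_transformed <- function(par, type) {
  if (type == "single") c(log10(par["kd"]), par["dh"], par["n"], par["dq"])
  else c(log10(par["kd1"]), log10(par["kd2"]), par["dh1"], par["dh2"],
         par["n1"], par["n2"], par["dq"])
}

.from_transformed <- function(theta, type) {
  nm <- .par_names(type)
  out <- theta
  if (type == "single") out[1] <- 10^theta[1] else out[1:2] <- 10^theta[1:2]
  names(out) <- nm
  out
}

# Fast forward prediction of normalized heats; `conc` and `moles` are
# precomputed per protocol so the optimizer does not redo bookkeeping.
.predict_normalized <- function(kds, dhs, ns, conc, moles, V0, dv, dq) {
  K <- 1 / kds
  s_free <- .solve_free_vec(K, ns, conc$s, conc$p)
  per_protomer <- 0
  for (j in seq_along(K)) {
    th <- K[j] * s_free / (1 + K[j] * s_free)
    per_protomer <- per_protomer + ns[j] * dhs[j] * th
  }
  Q <- V0 * conc$p * per_protomer
  Qprev <- c(0, Q[-length(Q)])
  q <- Q - Qprev + (dv / V0) * (Q + Qprev) / 2 + dq * moles
  q / moles
}

.theta_predict <- function(theta, type, conc, moles, V0, dv) {
  p <- .from_transformed(theta, type)
  if (type == "single")
    .predict_normalized(p["kd"], p["dh"], p["n"], conc, moles, V0, dv,
                        p["dq"])
  else
    .predict_normalized(c(p["kd1"], p["kd2"]), c(p["dh1"], p["dh2"]),
                        c(p["n1"], p["n2"]), conc, moles, V0, dv, p["dq"])
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

.make_starts <- function(type, n_starts, obs, p_cell) {
  dh0 <- obs[which.max(abs(obs))]
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1
  starts <- vector("list", n_starts)
  # deterministic heuristic start, then randomized starts in log-kd space
  if (type == "single") {
    starts[[1]] <- c(log10(p_cell / 20), dh0, 1, 0)
    if (n_starts > 1) for (i in 2:n_starts)
      starts[[i]] <- c(stats::runif(1, -10, -5),
                       dh0 * stats::runif(1, 0.3, 2),
                       stats::runif(1, 0.3, 1.5), 0)
  } else {
    starts[[1]] <- c(log10(p_cell / 2000), log10(p_cell / 50),
                     dh0 * 0.6, dh0 * 1.4, 0.6, 0.4, 0)
    if (n_starts > 1) for (i in 2:n_starts) {
      lk <- sort(stats::runif(2, -10, -5))
      starts[[i]] <- c(lk, dh0 * stats::runif(1, 0.3, 2),
                       dh0 * stats::runif(1, 0.3, 2),
                       stats::runif(1, 0.1, 1), stats::runif(1, 0.1, 1), 0)
    }
  }
  starts
}

.fit_itc_engine <- function(obs, protocol, type, fixed = NULL,
                            n_starts = 20, seed = NULL,
                            exclude_first = FALSE, extra_starts = list()) {
  nm <- .par_names(type)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), nm)
    if (length(bad))
      stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  }
  conc <- .cell_concentrations(protocol)
  dv <- protocol$injection_volumes
  V0 <- protocol$cell_volume
  moles <- protocol$s_syringe * dv
  use <- rep(TRUE, length(obs))
  if (exclude_first) use[1] <- FALSE

  fixed_t <- numeric(0)
  if (!is.null(fixed) && length(fixed)) {
    fixed_t <- unlist(fixed)
    kd_like <- grepl("^kd", names(fixed_t))
    fixed_t[kd_like] <- log10(fixed_t[kd_like])
  }
  free_idx <- which(!(nm %in% names(fixed_t)))
  assemble <- function(theta_free) {
    th <- numeric(length(nm))
    names(th) <- nm
    th[free_idx] <- theta_free
    if (length(fixed_t)) th[names(fixed_t)] <- fixed_t
    th
  }
  resid_fn <- function(theta_free) {
    pred <- .theta_predict(assemble(theta_free), type, conc, moles, V0, dv)
    (obs - pred)[use]
  }
  bounds <- .par_bounds(type)

  starts <- .with_seed(seed,
                       .make_starts(type, n_starts, obs[use],
                                    protocol$p_cell))
  # warm starts (e.g. profile-likelihood continuation): full-length
  # transformed vectors whose free components seed extra optimizations
  if (length(extra_starts))
    starts <- c(lapply(extra_starts, function(th) th[free_idx]),
                lapply(starts, function(s)
                  if (length(s) == length(nm)) s[free_idx] else s))
  else starts <- lapply(starts, function(s)
    if (length(s) == length(nm)) s[free_idx] else s)
  n_starts <- length(starts)
  best <- NULL
  rss_all <- rep(NA_real_, n_starts)
  for (i in seq_along(starts)) {
    th0 <- pmin(pmax(starts[[i]], bounds$lower[free_idx]),
                bounds$upper[free_idx])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = th0, fn = resid_fn,
        lower = bounds$lower[free_idx], upper = bounds$upper[free_idx],
        control = minpack.lm::nls.lm.control(
          maxiter = 400, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss_all[i] <- sum(fit$fvec^2)
    if (is.null(best) || rss_all[i] < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best))
    stop("ITC fit failed to converge from any of the ", n_starts,
         " starting points")
  rss <- sum(best$fvec^2)
  n_ok <- sum(is.finite(rss_all))
  near <- sum(is.finite(rss_all) &
                rss_all <= rss + 1e-3 * max(rss, 1e-12))
  theta <- assemble(best$par)

  # approximate standard errors from the Jacobian at the optimum
  se_t <- rep(NA_real_, length(free_idx))
  ndat <- sum(use)
  dof <- ndat - length(free_idx)
  if (dof > 0) {
    J <- tryCatch({
      eps <- pmax(abs(best$par) * 1e-6, 1e-8)
      r0 <- resid_fn(best$par)
      vapply(seq_along(best$par), function(j) {
        pj <- best$par
        pj[j] <- pj[j] + eps[j]
        (resid_fn(pj) - r0) / eps[j]
      }, numeric(length(r0)))
    }, error = function(e) NULL)
    if (!is.null(J)) {
      cv <- tryCatch(solve(crossprod(J)) * rss / dof,
                     error = function(e) NULL)
      if (!is.null(cv)) se_t <- sqrt(pmax(diag(cv), 0))
    }
  }
  se_full <- rep(NA_real_, length(nm))
  se_full[free_idx] <- se_t
  names(se_full) <- nm

  list(theta = theta, se_theta = se_full, rss = rss, ndata = ndat,
       n_free = length(free_idx),
       multistart = list(n_starts = n_starts, n_converged = n_ok,
                         n_near_best = near,
                         rss_range = range(rss_all, na.rm = TRUE)),
       info = best$info)
}

.aicc <- function(rss, n, n_par) {
  k <- n_par + 1  # + residual variance
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a single-state or two-state binding model to an ITC isotherm
#'
#' Least-squares fit of the perfusion-cell injection-heat forward model to
#' observed normalized heats, with multistart optimization (Levenberg-
#' Marquardt on transformed parameters: log10 Kd, linear enthalpy,
#' stoichiometry bounded to (0, 3], constant dilution offset). The two-state
#' model describes two independent, nonidentical binding substates; fitted
#' states are relabelled so that state 1 has the smaller Kd.
#'
#' @param isotherm An [`isotherm`][simulate_injection_heats] (its
#'   `normalized_heat_kcal_per_mol` column is fitted).
#' @param model `"single"` or `"two"`.
#' @param protocol A [titration_protocol()]; defaults to the one attached to
#'   the isotherm.
#' @param n_starts Number of multistart optimizations (default 20; the
#'   two-state model can be strongly degenerate, so multistart matters).
#' @param seed Optional integer seed controlling the randomized starts.
#' @param exclude_first If `TRUE`, drop injection 1 from the objective
#'   (common practice when the first injection is compromised; default keeps
#'   it).
#' @return An object of class `"itc_fit"` with components `model` (fitted
#'   [binding_model()]), `dilution_offset`, `estimates` (parameter table with
#'   approximate standard errors), `rss`, `aicc`, `fitted`, `residuals`,
#'   `multistart`, `flags`, and the data/protocol used.
#' @examples
#' truth <- binding_model(binding_state(kd = 917e-9, dh = -2.3, n = 1.18))
#' iso <- simulate_injection_heats(truth, titration_protocol())
#' fit <- itc_fit(iso, model = "single", n_starts = 5, seed = 1)
#' coef(fit)
#' @export
itc_fit <- function(isotherm, model = c("single", "two"),
                    protocol = attr(isotherm, "protocol"),
                    n_starts = 20, seed = NULL, exclude_first = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(isotherm, "isotherm"))
  if (is.null(protocol))
    stop("no titration protocol supplied or attached to the isotherm")
  stopifnot(inherits(protocol, "titration_protocol"))
  obs <- isotherm$normalized_heat_kcal_per_mol
  n_informative <- length(obs) - exclude_first
  if (n_informative < 8)
    stop("at least 8 informative injections are required")

  eng <- .fit_itc_engine(obs, protocol, model, fixed = NULL,
                         n_starts = n_starts, seed = seed,
                         exclude_first = exclude_first)
  .finish_itc_fit(eng, isotherm, protocol, model, exclude_first,
                  match.call())
}

.finish_itc_fit <- function(eng, isotherm, protocol, type, exclude_first,
                            call) {
  par <- .from_transformed(eng$theta, type)
  se <- eng$se_theta
  # delta method for kd = 10^lkd
  kd_like <- grepl("^kd", names(par))
  se_nat <- se
  se_nat[kd_like] <- se[kd_like] * log(10) * par[kd_like]

  flags <- character(0)
  if (type == "two") {
    # canonical relabelling: state 1 = smaller kd
    if (par["kd1"] > par["kd2"]) {
      sw <- function(v) v[c("kd2", "kd1", "dh2", "dh1", "n2", "n1", "dq")]
      par <- stats::setNames(sw(par), names(par))
      se_nat <- stats::setNames(sw(se_nat), names(se_nat))
    }
    if (par["n2"] < 0.01 || par["n1"] < 0.01)
      flags <- c(flags, "degenerate: one state has vanishing stoichiometry")
    # states count as merged when both Kd and dH are indistinguishable;
    # near-equal Kds with distinct enthalpies are a real two-state fit
    if (par["kd2"] / par["kd1"] < 2 &&
        abs(par["dh1"] - par["dh2"]) <
          0.05 * max(abs(par["dh1"]), abs(par["dh2"])))
      flags <- c(flags, "degenerate: substates merge (effectively single-state)")
    states <- list(
      binding_state(par["kd1"], par["dh1"], par["n1"]),
      binding_state(par["kd2"], par["dh2"], par["n2"]))
  } else {
    states <- list(binding_state(par["kd"], par["dh"], par["n"]))
  }
  bm <- binding_model(states, temperature = protocol$temperature)
  heat_amp <- sum(abs(.ns(bm) * .dhs(bm)))
  if (heat_amp < 1e-3)
    flags <- c(flags, "no detectable binding heat: Kd unidentifiable")

  conc <- .cell_concentrations(protocol)
  pred <- .theta_predict(eng$theta, type, conc,
                         protocol$s_syringe * protocol$injection_volumes,
                         protocol$cell_volume, protocol$injection_volumes)
  obs <- isotherm$normalized_heat_kcal_per_mol

  structure(list(
    model = bm,
    model_type = type,
    dilution_offset = unname(par["dq"]),
    estimates = data.frame(parameter = names(par),
                           estimate = unname(par),
                           std_error = unname(se_nat),
                           row.names = NULL),
    rss = eng$rss,
    aicc = .aicc(eng$rss, eng$ndata, eng$n_free),
    n_data = eng$ndata,
    n_par = eng$n_free,
    fitted = pred,
    residuals = obs - pred,
    convergence = eng$info %in% 1:4,
    multistart = eng$multistart,
    flags = flags,
    isotherm = isotherm,
    protocol = protocol,
    exclude_first = exclude_first,
    call = call), class = "itc_fit")
}
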