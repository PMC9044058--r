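#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("ITC %s-state fit (%d injections, RSS = %.4g, AICc = %.2f)\n",
              x$model_type, x$n_data, x$rss, x$aicc))
  est <- x$estimates
  kd_rows <- grepl("^kd", est$parameter)
  disp <- est
  disp$estimate[kd_rows] <- disp$estimate[kd_rows] * 1e9
  disp$std_error[kd_rows] <- disp$std_error[kd_rows] * 1e9
  disp$parameter[kd_rows] <- paste0(disp$parameter[kd_rows], "_nM")
  print(format(disp, digits = 4), row.names = FALSE)
  cat(sprintf("multistart: %d/%d converged, %d near the optimum\n",
              x$multistart$n_converged, x$multistart$n_starts,
              x$multistart$n_near_best))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  out <- object[c("model_type", "estimates", "rss", "aicc", "n_data",
                  "n_par", "multistart", "flags", "dilution_offset",
                  "convergence")]
  out$sigma <- sqrt(object$rss / max(object$n_data - object$n_par, 1))
  if (object$model_type == "two")
    out$substate_fraction_pct <- substate_fraction(object)
  class(out) <- "summary.itc_fit"
  out
}

#' @export
print.summary.itc_fit <- function(x, ...) {
  cat(sprintf("%s-state ITC fit\n", x$model_type))
  print(format(x$estimates, digits = 4), row.names = FALSE)
  cat(sprintf("RSS %.4g on %d injections (sigma %.4g), AICc %.2f\n",
              x$rss, x$n_data, x$sigma, x$aicc))
  if (!is.null(x$substate_fraction_pct))
    cat(sprintf("lower-affinity substate: %.1f%% of sites\n",
                x$substate_fraction_pct))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$parameter)
}

#' @export
fitted.itc_fit <- function(object, ...) object$fitted

#' @export
residuals.itc_fit <- function(object, ...) object$residuals

#' @export
logLik.itc_fit <- function(object, ...) {
  n <- object$n_data
  val <- -n / 2 * (log(2 * pi) + log(object$rss / n) + 1)
  structure(val, df = object$n_par + 1, nobs = n, class = "logLik")
}

#' Predicted injection heats from a fitted ITC model
#'
#' @param object An [itc_fit()] result.
#' @param protocol Optional new [titration_protocol()]; defaults to the
#'   fitted one.
#' @param include_dilution Include the fitted dilution offset in the
#'   prediction.
#' @param ... Unused.
#' @return An [`isotherm`][simulate_injection_heats] of predicted heats.
#' @export
predict.itc_fit <- function(object, protocol = object$protocol,
                            include_dilution = TRUE, ...) {
  simulate_injection_heats(
    object$model, protocol,
    dilution_heat = if (include_dilution) object$dilution_offset else 0)
}

#' Simulate replicate noisy isotherms from a fitted model
#'
#' Parametric-bootstrap style replicates: the fitted model and protocol are
#' pushed through the forward model and Gaussian noise with the residual
#' standard deviation is added to the normalized heats.
#'
#' @param object An [itc_fit()] result.
#' @param nsim Number of replicate isotherms.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` isotherms.
#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sigma <- sqrt(object$rss / max(object$n_data - object$n_par, 1))
  base <- simulate_injection_heats(object$model, object$protocol,
                                   dilution_heat = object$dilution_offset)
  first <- abs(base$normalized_heat_kcal_per_mol[1])
  frac <- if (first > 0) sigma / first else 0
  .with_seed(seed, lapply(seq_len(nsim), function(i)
    generate_isotherm(object$model, object$protocol,
                      noise = noise_spec(sigma_isotherm = frac),
                      dilution_heat = object$dilution_offset)))
}

#' Plot an ITC isotherm and (optionally) a fitted curve
#'
#' @param x An isotherm or an `itc_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.itc_fit <- function(x, ...) {
  iso <- x$isotherm
  graphics::plot(iso$molar_ratio, iso$normalized_heat_kcal_per_mol,
                 xlab = "molar ratio ([S]tot/[P])",
                 ylab = "normalized heat (kcal/mol injectant)",
                 pch = 19, ...)
  graphics::lines(iso$molar_ratio, x$fitted, col = 2, lwd = 2)
  invisible(x)
}

#' @rdname plot.itc_fit
#' @export
plot.isotherm <- function(x, ...) {
  graphics::plot(x$molar_ratio, x$normalized_heat_kcal_per_mol,
                 xlab = "molar ratio ([S]tot/[P])",
                 ylab = "normalized heat (kcal/mol injectant)",
                 pch = 19, ...)
  invisible(x)
}

#' Compare a single-state and a two-state fit of the same isotherm
#'
#' Reports the corrected-AIC difference and the F-test for the nested pair
#' (the single-state model is the two-state model with one stoichiometry at
#' zero). The more complex model is preferred only when its AICc improves on
#' the simpler one by more than `aicc_margin`.
#'
#' @param fit1,fit2 Two [itc_fit()] results on the same isotherm.
#' @param aicc_margin AICc improvement required to prefer the model with
#'   more parameters (default 2).
#' @return An object of class `"itc_model_comparison"` with the preferred
#'   model type, the AICc difference and the F-test.
#' @export
compare_models <- function(fit1, fit2, aicc_margin = 2) {
  stopifnot(inherits(fit1, "itc_fit"), inherits(fit2, "itc_fit"))
  o1 <- fit1$isotherm$normalized_heat_kcal_per_mol
  o2 <- fit2$isotherm$normalized_heat_kcal_per_mol
  if (length(o1) != length(o2) || !isTRUE(all.equal(o1, o2)))
    stop("the two fits are not on the same isotherm")
  # order by parameter count: simple first
  if (fit1$n_par > fit2$n_par) { tmp <- fit1; fit1 <- fit2; fit2 <- tmp }
  d_aicc <- fit2$aicc - fit1$aicc
  ftest <- NULL
  if (fit2$n_par > fit1$n_par) {
    df1 <- fit1$n_data - fit1$n_par
    df2 <- fit2$n_data - fit2$n_par
    fstat <- ((fit1$rss - fit2$rss) / (df1 - df2)) / (fit2$rss / df2)
    ftest <- list(statistic = fstat, df = c(df1 - df2, df2),
                  p_value = stats::pf(fstat, df1 - df2, df2,
                                      lower.tail = FALSE))
  }
  preferred <- if (d_aicc < -aicc_margin) fit2$model_type else fit1$model_type
  structure(list(preferred = preferred, delta_aicc = d_aicc,
                 f_test = ftest,
                 rss = c(fit1$rss, fit2$rss),
                 types = c(fit1$model_type, fit2$model_type)),
            class = "itc_model_comparison")
}

#' @export
print.itc_model_comparison <- function(x, ...) {
  cat(sprintf("model comparison: %s vs %s\n", x$types[1], x$types[2]))
  cat(sprintf("  RSS %.4g vs %.4g; AICc(%s) - AICc(%s) = %.2f\n",
              x$rss[1], x$rss[2], x$types[2], x$types[1], x$delta_aicc))
  if (!is.null(x$f_test))
    cat(sprintf("  F(%d, %d) = %.3g, p = %.3g\n", x$f_test$df[1],
                x$f_test$df[2], x$f_test$statistic, x$f_test$p_value))
  cat("  preferred:", x$preferred, "\n")
  invisible(x)
}

#' Profile the identifiability of constrained binding parameters
#'
#' Re-optimizes all remaining parameters while one or more parameters are
#' held at each point of a user-supplied grid. A profile whose re-optimized
#' RSS varies by less than `flat_tol` (fractionally) across the grid is
#' flagged as flat, i.e. the constrained parameters are not uniquely
#' determined by the data — the behaviour expected for very high
#' Wiseman-c titrations.
#'
#' @inheritParams itc_fit
#' @param constrained Named list of parameter grids (names among the model's
#'   parameters, e.g. `kd1`; several names give a joint grid evaluated
#'   row-wise, so all grids must have equal length). Kd grids are in molar.
#' @param flat_tol Fractional RSS spread below which the profile is declared
#'   flat (default 0.05).
#' @param n_starts Multistart count per grid point.
#' @return An object of class `"identifiability_scan"`: the grid with
#'   re-optimized RSS per point, the unconstrained RSS, and the flat flag.
#' @export
scan_identifiability <- function(isotherm, protocol = attr(isotherm,
                                                           "protocol"),
                                 model = c("two", "single"), constrained,
                                 flat_tol = 0.05, n_starts = 8,
                                 seed = NULL, exclude_first = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(isotherm, "isotherm"),
            inherits(protocol, "titration_protocol"))
  if (missing(constrained) || !is.list(constrained) ||
      length(constrained) == 0L || any(lengths(constrained) == 0L))
    stop("'constrained' must be a non-empty named list of parameter grids")
  if (is.null(names(constrained)) || any(names(constrained) == ""))
    stop("'constrained' grids must be named after model parameters")
  len <- unique(lengths(constrained))
  if (length(len) != 1L)
    stop("all constrained grids must have the same length")
  bad <- setdiff(names(constrained), .par_names(model))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))

  obs <- isotherm$normalized_heat_kcal_per_mol
  eng0 <- .fit_itc_engine(obs, protocol, model, fixed = NULL,
                          n_starts = max(n_starts, 12), seed = seed,
                          exclude_first = exclude_first)
  rss <- rep(NA_real_, len)
  errors <- character(len)
  warm <- list(eng0$theta)  # continuation: unconstrained optimum, then
                            # the previous grid point's optimum
  for (i in seq_len(len)) {
    fixed <- lapply(constrained, `[[`, i)
    eng <- tryCatch(
      .fit_itc_engine(obs, protocol, model, fixed = fixed,
                      n_starts = n_starts,
                      seed = if (is.null(seed)) NULL else seed + i,
                      exclude_first = exclude_first, extra_starts = warm),
      error = function(e) e)
    if (inherits(eng, "error")) errors[i] <- conditionMessage(eng)
    else {
      rss[i] <- eng$rss
      warm <- list(eng0$theta, eng$theta)
    }
  }
  ok <- is.finite(rss)
  spread <- if (any(ok)) (max(rss[ok]) - min(rss[ok])) /
    max(min(rss[ok]), .Machine$double.eps) else NA_real_
  grid_df <- as.data.frame(constrained)
  grid_df$rss <- rss
  grid_df$error <- errors
  structure(list(grid = grid_df, rss_unconstrained = eng0$rss,
                 flat = isTRUE(spread < flat_tol), rss_spread = spread,
                 flat_tol = flat_tol, model_type = model),
            class = "identifiability_scan")
}

#' @export
print.identifiability_scan <- function(x, ...) {
  cat(sprintf("identifiability scan (%s-state model, %d grid points)\n",
              x$model_type, nrow(x$grid)))
  print(format(x$grid, digits = 4), row.names = FALSE)
  cat(sprintf("unconstrained RSS %.4g; profile spread %.3g (tol %.3g) -> %s\n",
              x$rss_unconstrained, x$rss_spread, x$flat_tol,
              if (x$flat) "FLAT (parameters not uniquely determined)"
              else "informative"))
  invisible(x)
}

#' Percentage of sites in the lower-affinity substate
#'
#' For a two-state fit, `100 * n2 / (n1 + n2)`, the population fraction of
#' the weaker-binding conformation.
#'
#' @param fit A two-state [itc_fit()] result.
#' @return Percentage in `[0, 100]`.
#' @export
substate_fraction <- function(fit) {
  stopifnot(inherits(fit, "itc_fit"))
  if (fit$model_type != "two")
    stop("substate fractions are defined for two-state fits only")
  n <- .ns(fit$model)
  if (sum(n) <= 0) stop("total stoichiometry is zero")
  100 * n[2] / sum(n)
}
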