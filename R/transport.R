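#' Bundle single-transporter uptake traces with video metadata
#'
#' Holds per-trace FRET-efficiency time series (long format) together with
#' per-condition video metadata: how many traces were observed, how many
#' responded (showed transport events), and the buffer-replacement time
#' `t0` at which substrate reached the liposomes (supplied, not computed).
#'
#' @param traces Data frame with columns `trace_id`, `condition`, `time_s`,
#'   `efret` (FRET efficiency in `[0, 1]`) and `responding` (0/1).
#' @param meta Data frame with columns `condition`, `n_total`,
#'   `n_responding`, `t0_s`.
#' @return An object of class `"uptake_traces"`.
#' @export
uptake_trace_set <- function(traces, meta) {
  need_t <- c("trace_id", "condition", "time_s", "efret", "responding")
  need_m <- c("condition", "n_total", "n_responding", "t0_s")
  if (!all(need_t %in% names(traces)))
    stop("'traces' needs columns: ", paste(need_t, collapse = ", "))
  if (!all(need_m %in% names(meta)))
    stop("'meta' needs columns: ", paste(need_m, collapse = ", "))
  if (any(traces$efret < 0 | traces$efret > 1))
    stop("FRET efficiencies must lie in [0, 1]")
  if (!all(traces$responding %in% c(0, 1)))
    stop("'responding' must be 0/1")
  for (id in unique(traces$trace_id)) {
    tt <- traces$time_s[traces$trace_id == id]
    if (any(diff(tt) <= 0))
      stop("times must be strictly increasing within trace ", id)
  }
  if (any(meta$n_responding > meta$n_total) || any(meta$n_total <= 0))
    stop("responding fraction must lie in [0, 1]")
  if (!all(unique(traces$condition) %in% meta$condition))
    stop("every trace condition needs a metadata row")
  structure(list(traces = traces, meta = meta), class = "uptake_traces")
}

#' @export
print.uptake_traces <- function(x, ...) {
  cat(sprintf("uptake trace set: %d traces, %d condition(s)\n",
              length(unique(x$traces$trace_id)), nrow(x$meta)))
  m <- x$meta
  m$responding_fraction <- m$n_responding / m$n_total
  print(format(m, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Normalize uptake traces to per-condition mean fractional uptake
#'
#' Responding traces of each condition are averaged into a mean FRET
#' efficiency time course, normalized so that the first time point is 0%
#' and the first time point + 0.2 (the sensor's saturation change) is 100%,
#' multiplied by the condition's responding fraction, and re-zeroed at the
#' buffer-replacement time `t0`. Values exceeding 100% before scaling are
#' clipped with a warning.
#'
#' @param x An [uptake_trace_set()].
#' @return Data frame with columns `condition`, `time_s` (relative to `t0`)
#'   and `uptake_pct` (percent of total observable transport).
#' @export
normalize_uptake <- function(x) {
  stopifnot(inherits(x, "uptake_traces"))
  out <- NULL
  for (cond in unique(x$meta$condition)) {
    tr <- x$traces[x$traces$condition == cond & x$traces$responding == 1, ]
    if (nrow(tr) == 0L)
      stop("condition '", cond, "' has no responding traces")
    mean_e <- stats::aggregate(efret ~ time_s, data = tr, FUN = mean)
    mean_e <- mean_e[order(mean_e$time_s), ]
    e0 <- mean_e$efret[1]
    pct <- (mean_e$efret - e0) / 0.2 * 100
    if (any(pct > 100 + 1e-9)) {
      warning("condition '", cond,
              "': uptake exceeds the 0.2 saturation span; clipping")
      pct <- pmin(pct, 100)
    }
    m <- x$meta[x$meta$condition == cond, ]
    frac <- sum(m$n_responding) / sum(m$n_total)
    out <- rbind(out, data.frame(
      condition = cond,
      time_s = mean_e$time_s - m$t0_s[1],
      uptake_pct = pct * frac))
  }
  rownames(out) <- NULL
  out
}

# multi-exponential association on the fractional scale:
#   Y(t) = sum_i f_i * (1 - exp(-k_i * t)),  sum f_i = 1,  Y(0) = 0
.triexp_curve <- function(t, rates, fracs) {
  y <- 0
  for (i in seq_along(rates)) y <- y + fracs[i] * (1 - exp(-rates[i] * t))
  y
}

.softmax <- function(z) {
  z <- c(z, 0)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Global multi-exponential fit of uptake curves with shared rates
#'
#' Fits `Y(t) = sum_i f_i (1 - exp(-k_i t))` (three phases by default) to
#' per-condition normalized uptake curves, with the plateau fixed at 100%,
#' `Y(0) = 0`, all rate constants positive, and phase percentages in
#' `[0, 100]` summing to 100 per condition. In shared-rate mode (the
#' default) one rate triple is common to all conditions while the phase
#' percentages are per-condition. Percentages are parameterized through a
#' softmax transform, which enforces the bounds and the sum constraint
#' exactly; rates are optimized on the log scale.
#'
#' @param curves Data frame with columns `condition`, `time_s`,
#'   `uptake_pct` (as produced by [normalize_uptake()] or
#'   [generate_uptake_curves()]).
#' @param shared_rates Share one rate triple across conditions (requires at
#'   least 2 conditions); otherwise each condition gets its own rates.
#' @param n_phases Number of exponential phases (default 3:
#'   fast/intermediate/slow).
#' @param n_starts Multistart count for the rate initialization.
#' @param seed Optional integer seed for the randomized starts.
#' @return An object of class `"uptake_fit"`: ordered rates
#'   (`fast > intermediate > slow`, 1/s), a per-condition percentage matrix
#'   summing to 100, RSS, fitted values and flags.
#' @export
uptake_fit <- function(curves, shared_rates = TRUE, n_phases = 3,
                       n_starts = 10, seed = NULL) {
  need <- c("condition", "time_s", "uptake_pct")
  if (!all(need %in% names(curves)))
    stop("'curves' needs columns: ", paste(need, collapse = ", "))
  conds <- unique(curves$condition)
  if (shared_rates && length(conds) < 2L)
    stop("shared-rate mode needs at least 2 conditions")
  curves <- curves[curves$time_s >= 0, ]
  y <- curves$uptake_pct / 100
  tt <- curves$time_s
  cidx <- match(curves$condition, conds)
  nc <- length(conds)
  np <- n_phases

  # parameter vector: log rates (np, or np*nc unshared), then (np-1)
  # softmax logits per condition
  n_rate <- if (shared_rates) np else np * nc
  unpack <- function(par) {
    lr <- par[seq_len(n_rate)]
    logits <- matrix(par[-seq_len(n_rate)], nrow = np - 1, ncol = nc)
    rates <- if (shared_rates) matrix(exp(lr), np, nc)
    else matrix(exp(lr), np, nc)
    fr <- apply(logits, 2, .softmax)
    list(rates = rates, fracs = fr)
  }
  obj <- function(par) {
    p <- unpack(par)
    pred <- numeric(length(y))
    for (j in seq_len(nc)) {
      sel <- cidx == j
      pred[sel] <- .triexp_curve(tt[sel], p$rates[, j], p$fracs[, j])
    }
    sum((y - pred)^2)
  }

  base_rates <- log(10^seq(-1, -2 * (np - 1) / 2 - 0.5,
                           length.out = np))
  starts <- .with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      jit <- if (i == 1) 0 else stats::rnorm(n_rate, 0, 0.8)
      c(rep(base_rates, length.out = n_rate) + jit,
        rep(0, (np - 1) * nc))
    })
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(stats::nlminb(s, obj,
                                  control = list(iter.max = 2000,
                                                 eval.max = 4000)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("uptake fit failed from every start")
  p <- unpack(best$par)

  # canonical ordering: fast > intermediate > slow, by the shared (or
  # first-condition) rates; applied per condition in unshared mode
  labels <- c("fast", "intermediate", "slow")[seq_len(np)]
  rates_mat <- p$rates
  fr <- p$fracs
  for (j in seq_len(nc)) {
    o <- order(rates_mat[, j], decreasing = TRUE)
    rates_mat[, j] <- rates_mat[o, j]
    fr[, j] <- fr[o, j]
  }
  pct <- t(fr) * 100
  pct <- pct / rowSums(pct) * 100  # exact renormalization
  dimnames(pct) <- list(as.character(conds), labels)
  rates_out <- if (shared_rates) stats::setNames(rates_mat[, 1], labels)
  else stats::setNames(as.vector(rates_mat),
                       paste(rep(labels, nc),
                             rep(as.character(conds), each = np),
                             sep = "."))
  flags <- character(0)
  for (j in seq_len(nc)) {
    r <- sort(rates_mat[, j], decreasing = TRUE)
    if (any(r[-np] / r[-1] < 2))
      flags <- c(flags, "rate collapse: adjacent rate constants within 2x")
  }
  flags <- unique(flags)

  pred <- numeric(length(y))
  for (j in seq_len(nc)) {
    sel <- cidx == j
    pred[sel] <- .triexp_curve(tt[sel], rates_mat[, j], fr[, j])
  }
  structure(list(
    rates = rates_out, percentages = pct, rss = best$objective,
    shared_rates = shared_rates, n_phases = np,
    conditions = as.character(conds),
    fitted = pred * 100, residuals = curves$uptake_pct - pred * 100,
    data = curves, convergence = best$convergence == 0,
    flags = flags), class = "uptake_fit")
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat(sprintf("global %d-phase uptake fit (%s rates, %d conditions)\n",
              x$n_phases, if (x$shared_rates) "shared" else "per-condition",
              length(x$conditions)))
  cat("rates (1/s):\n")
  print(signif(x$rates, 4))
  cat("phase percentages:\n")
  print(round(x$percentages, 1))
  cat(sprintf("RSS = %.4g (fractional scale)\n", x$rss))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.uptake_fit <- function(object, ...) {
  c(object$rates,
    stats::setNames(as.vector(t(object$percentages)),
                    paste(rep(colnames(object$percentages),
                              times = nrow(object$percentages)),
                          rep(rownames(object$percentages),
                              each = ncol(object$percentages)),
                          sep = ".")))
}

#' @export
fitted.uptake_fit <- function(object, ...) object$fitted

#' @export
residuals.uptake_fit <- function(object, ...) object$residuals

#' @export
summary.uptake_fit <- function(object, ...) {
  object$sigma_pct <- sqrt(object$rss /
                             max(nrow(object$data) - length(object$rates) -
                                   length(object$percentages), 1)) * 100
  class(object) <- c("summary.uptake_fit", class(object))
  object
}

#' @export
print.summary.uptake_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("residual sd: %.2f%% of total uptake\n", x$sigma_pct))
  invisible(x)
}

#' @export
plot.uptake_fit <- function(x, ...) {
  d <- x$data
  cols <- seq_along(x$conditions) + 1
  graphics::plot(range(d$time_s), range(c(d$uptake_pct, x$fitted)),
                 type = "n", xlab = "time after buffer replacement (s)",
                 ylab = "uptake (% of total)", ...)
  for (j in seq_along(x$conditions)) {
    sel <- d$condition == x$conditions[j]
    graphics::points(d$time_s[sel], d$uptake_pct[sel], col = cols[j],
                     pch = 20, cex = 0.5)
    graphics::lines(d$time_s[sel], x$fitted[sel], col = cols[j], lwd = 2)
  }
  graphics::legend("bottomright", legend = x$conditions, col = cols,
                   lwd = 2, bty = "n")
  invisible(x)
}
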