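# Shared fixtures: all built in code at test time.

ref_models <- reference_binding_models()
default_proto <- titration_protocol()

# a comfortably conditioned single-state model (Wiseman c ~ 40)
simple_model <- function(kd = 1e-6, dh = -5, n = 1)
  binding_model(binding_state(kd, dh, n))

# random one- or two-state model with c = n * p / kd inside [c_lo, c_hi]
random_model <- function(n_states, p_cell = 40e-6, c_lo = 5, c_hi = 500) {
  draw_state <- function() {
    n <- runif(1, 0.3, 1.2)
    cc <- exp(runif(1, log(c_lo), log(c_hi)))
    binding_state(kd = n * p_cell / cc, dh = runif(1, -10, -1), n = n)
  }
  if (n_states == 1) return(binding_model(draw_state()))
  repeat {
    s1 <- draw_state(); s2 <- draw_state()
    r <- max(s1$kd, s2$kd) / min(s1$kd, s2$kd)
    if (r > 5 && abs(s1$dh - s2$dh) > 1) break
  }
  binding_model(list(s1, s2))
}

# brute-force 2-D grid-refinement oracle for the competitive mass balances:
# geometric grids (the roots can sit many orders of magnitude below the
# totals), refined around the best cell with a generous margin
grid_oracle_competitive <- function(model, s_total, i_total, p_total,
                                    n_zoom = 80, n_grid = 61) {
  K <- 1 / sapply(model$states, `[[`, "kd")
  Kinh <- 1 / model$competitor$kd_inh
  n <- sapply(model$states, `[[`, "n")
  res2 <- function(s, i) {
    bs <- bi <- 0
    for (j in seq_along(K)) {
      den <- 1 + K[j] * s + Kinh[j] * i
      bs <- bs + n[j] * K[j] * s / den
      bi <- bi + n[j] * Kinh[j] * i / den
    }
    (s + p_total * bs - s_total)^2 + (i + p_total * bi - i_total)^2
  }
  axis <- function(lo, hi, total) {
    lo <- max(lo, total * 1e-14)
    exp(seq(log(lo), log(max(hi, lo * (1 + 1e-15))), length.out = n_grid))
  }
  s_lo <- s_total * 1e-14; s_hi <- s_total
  i_lo <- i_total * 1e-14; i_hi <- i_total
  for (z in seq_len(n_zoom)) {
    ss <- axis(s_lo, s_hi, s_total)
    ii <- axis(i_lo, i_hi, i_total)
    g <- outer(ss, ii, res2)
    best <- arrayInd(which.min(g), dim(g))
    w <- n_grid %/% 4  # generous margin: range only halves per zoom
    s_lo <- ss[max(1L, best[1] - w)]
    s_hi <- ss[min(n_grid, best[1] + w)]
    i_lo <- ii[max(1L, best[2] - w)]
    i_hi <- ii[min(n_grid, best[2] + w)]
  }
  list(s_free = sqrt(s_lo * s_hi), i_free = sqrt(i_lo * i_hi))
}
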