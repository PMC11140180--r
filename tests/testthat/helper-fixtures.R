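# shared fixtures for the test suite

# a typical placentome ground truth (mid-physiological)
fix_params <- function(S0 = 100) {
  decide_params(f = 0.25, d = 1.5e-3, d_star = 0.03, T2fb = 90, v = 0.30,
                S0 = S0)
}

# draw a random feasible parameter set (respects all boxes and f + v < 1)
random_feasible_params <- function() {
  repeat {
    f <- stats::runif(1, 0.02, 0.7)
    v <- stats::runif(1, 0.02, 0.7)
    if (f + v < 0.95) break
  }
  decide_params(f = f, v = v,
                d = stats::runif(1, 2e-4, 5e-3),
                d_star = stats::runif(1, 5e-3, 0.2),
                T2fb = stats::runif(1, 20, 140),
                S0 = stats::runif(1, 10, 500))
}

# small repeated-measures fixture: 4 animals x 3 states
fix_rm_table <- function() {
  data.frame(
    animal_id = rep(c("a1", "a2", "a3", "a4"), each = 3),
    state = rep(c("basal", "TAD1", "TAD2"), 4),
    y = c(10.2, 11.5, 12.1,
          9.8, 10.9, 11.8,
          10.5, 11.2, 12.6,
          10.0, 11.0, 12.0))
}
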