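# Independent reference implementation of the Luo-Rudy phase-I (1991)
# kinetics, written directly from the published rate equations in plain R.
# Used only as an oracle against the package's compiled implementation.

oracle_rates <- function(v) {
  am <- if (abs(v + 47.13) < 1e-7) 3.2 else
    0.32 * (v + 47.13) / (1 - exp(-0.1 * (v + 47.13)))
  bm <- 0.08 * exp(-v / 11)
  if (v < -40) {
    ah <- 0.135 * exp(-(80 + v) / 6.8)
    bh <- 3.56 * exp(0.079 * v) + 3.1e5 * exp(0.35 * v)
    aj <- (-1.2714e5 * exp(0.2444 * v) - 3.474e-5 * exp(-0.04391 * v)) *
      (v + 37.78) / (1 + exp(0.311 * (v + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * v) / (1 + exp(-0.1378 * (v + 40.14)))
  } else {
    ah <- 0
    bh <- 1 / (0.13 * (1 + exp(-(v + 10.66) / 11.1)))
    aj <- 0
    bj <- 0.3 * exp(-2.535e-7 * v) / (1 + exp(-0.1 * (v + 32)))
  }
  ad <- 0.095 * exp(-0.01 * (v - 5)) / (1 + exp(-0.072 * (v - 5)))
  bd <- 0.07 * exp(-0.017 * (v + 44)) / (1 + exp(0.05 * (v + 44)))
  af <- 0.012 * exp(-0.008 * (v + 28)) / (1 + exp(0.15 * (v + 28)))
  bf <- 0.0065 * exp(-0.02 * (v + 30)) / (1 + exp(-0.2 * (v + 30)))
  ax <- 0.0005 * exp(0.083 * (v + 50)) / (1 + exp(0.057 * (v + 50)))
  bx <- 0.0013 * exp(-0.06 * (v + 20)) / (1 + exp(-0.04 * (v + 20)))
  c(alpha_m = am, beta_m = bm, alpha_h = ah, beta_h = bh,
    alpha_j = aj, beta_j = bj, alpha_d = ad, beta_d = bd,
    alpha_f = af, beta_f = bf, alpha_X = ax, beta_X = bx)
}

oracle_currents <- function(v, s) {
  RTF <- 8314.472 * 310 / 96485.3415
  EK1 <- RTF * log(5.4 / 145)
  Xi <- if (v <= -100) 1 else if (abs(v + 77) < 1e-6)
    2.837 * 0.04 / exp(0.04 * (v + 35)) else
    2.837 * (exp(0.04 * (v + 77)) - 1) / ((v + 77) * exp(0.04 * (v + 35)))
  ak1 <- 1.02 / (1 + exp(0.2385 * (v - EK1 - 59.215)))
  bk1 <- (0.49124 * exp(0.08032 * (v - EK1 + 5.476)) +
            exp(0.06175 * (v - EK1 - 594.31))) /
    (1 + exp(-0.5143 * (v - EK1 + 4.753)))
  Kp <- 1 / (1 + exp((7.488 - v) / 5.98))
  Esi <- 7.7 - 13.0287 * log(s[["Cai"]])
  c(I_Na = 23 * s[["m"]]^3 * s[["h"]] * s[["j"]] * (v - 54.4),
    I_si = 0.09 * s[["d"]] * s[["f"]] * (v - Esi),
    I_K = 0.282 * s[["X"]] * Xi * (v + 77),
    I_K1 = 0.6047 * ak1 / (ak1 + bk1) * (v - EK1),
    I_Kp = 0.0183 * Kp * (v - EK1),
    I_b = 0.03921 * (v + 59.87))
}

# a mid-action-potential state used in several cross-checks
mid_ap_state <- function() {
  structure(c(m = 0.9, h = 0.01, j = 0.2, d = 0.3, f = 0.6, X = 0.4,
              Cai = 1.5e-3), class = "lr1_state")
}
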