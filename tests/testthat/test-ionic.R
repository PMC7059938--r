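test_that("gate rates match an independent implementation of the kinetics", {
  for (v in c(-120, -84.5, -60.1, -40.0, -39.99, -20, 0, 25.7, 60)) {
    expect_equal(as.numeric(lr1_rates(v)), as.numeric(oracle_rates(v)),
                 tolerance = 1e-12, info = paste("v =", v))
  }
})

test_that("ionic currents match the independent oracle and scale to zero", {
  rest <- lr1_rest_state()
  for (v in c(-84.5, -50, 0, 30)) {
    for (s in list(rest$state, mid_ap_state())) {
      expect_equal(ionic_current(v, s, components = TRUE),
                   oracle_currents(v, s), tolerance = 1e-12)
    }
  }
  expect_equal(ionic_current(-20, mid_ap_state(), scale = rep(0, 6)), 0)
  # scaling only the sodium current removes exactly I_Na
  full <- ionic_current(-20, mid_ap_state(), components = TRUE)
  no_na <- ionic_current(-20, mid_ap_state(), scale = c(0, rep(1, 5)))
  expect_equal(no_na, sum(full) - full[["I_Na"]], tolerance = 1e-12)
})

test_that("rest state is a stationary point with physiological potential", {
  rest <- lr1_rest_state()
  expect_gt(rest$v, -90)
  expect_lt(rest$v, -80)
  expect_lt(abs(ionic_current(rest$v, rest$state)), 1e-2)
  # restarting from rest without stimulus stays put for 1 s
  run <- lr1_run0d(rest$v, rest$state, t_end = 1000, dt = 0.01,
                   stim_amp = 0, record_dt = 10)
  expect_lt(max(abs(run$v - rest$v)), 0.1)
})

test_that("voltage clamp drives each gate to alpha/(alpha+beta)", {
  rest <- lr1_rest_state()
  for (v in c(-70, -20)) {
    w <- step_gates(v, rest$state, dt = 0.005, n_steps = 2e6)  # 10 s clamp
    r <- oracle_rates(v)
    inf <- r[seq(1, 11, 2)] / (r[seq(1, 11, 2)] + r[seq(2, 12, 2)])
    expect_equal(as.numeric(w[1:6]), as.numeric(inf), tolerance = 1e-6,
                 info = paste("v =", v))
    expect_true(all(w[1:6] >= 0 & w[1:6] <= 1))
  }
  # the exponential (Rush-Larsen) integrator reaches the same fixed point
  # in far fewer steps and is exact for clamped potentials
  wrl <- step_gates(-20, rest$state, dt = 1, n_steps = 3e4,
                    method = "rush_larsen")
  r20 <- oracle_rates(-20)
  inf20 <- r20[seq(1, 11, 2)] / (r20[seq(1, 11, 2)] + r20[seq(2, 12, 2)])
  expect_equal(as.numeric(wrl[1:6]), as.numeric(inf20), tolerance = 1e-9)
  expect_error(step_gates(-80, rest$state, dt = 0), "dt")
  # dt -> 0 is the identity
  w0 <- step_gates(-80, rest$state, dt = 1e-12)
  expect_equal(as.numeric(w0), as.numeric(rest$state), tolerance = 1e-9)
})

test_that("a stimulated membrane fires a fast upstroke and is refractory", {
  rest <- lr1_rest_state()
  ap <- lr1_run0d(rest$v, rest$state, t_end = 400, dt = 0.005,
                  stim_amp = 40, stim_start = 1, stim_dur = 2,
                  record_dt = 0.25)
  expect_gt(max(ap$v), 0)            # overshooting action potential
  expect_gt(ap$max_dvdt, 100)        # > 100 V/s upstroke
  expect_lt(ap$v_final, -80)         # fully repolarized after 400 ms
  # premature second stimulus 50 ms after the upstroke fails to re-excite
  half <- lr1_run0d(rest$v, rest$state, t_end = 51, dt = 0.005,
                    stim_amp = 40, stim_start = 1, stim_dur = 2,
                    record_dt = 1)
  again <- lr1_run0d(half$v_final, half$state, t_end = 30, dt = 0.005,
                     stim_amp = 40, stim_start = 1, stim_dur = 2,
                     record_dt = 0.25)
  expect_lt(again$max_dvdt, 100)     # no second fast upstroke
})

test_that("ionic state validation and save/restore round-trip", {
  expect_error(lr1_state(1.2, 0.9, 0.9, 0, 1, 0, 1e-4), "0, 1")
  expect_error(lr1_state(0.5, 0.9, 0.9, 0, 1, 0, -1), "Cai")
  rest <- lr1_rest_state()
  path <- withr::local_tempfile(fileext = ".csv")
  write_state_csv(rest$state, rest$v, path)
  back <- read_state_csv(path)
  expect_equal(back$v, rest$v, tolerance = 1e-12)
  expect_equal(as.numeric(back$state), as.numeric(rest$state),
               tolerance = 1e-12)
})
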