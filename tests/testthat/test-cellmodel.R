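test_that("dual-clamp transjunctional voltage spans one cell on each side", {
  v <- rep(-80, 41)
  expect_equal(junction_vj(v, link = 20, n_div = 10), 0)
  # linear profile with slope s per node: samples are 19 links apart
  s <- 0.7
  vlin <- -80 + s * seq_along(v)
  expect_equal(junction_vj(vlin, 20, 10), 19 * s)
  # reflecting the profile flips the sign
  expect_equal(junction_vj(rev(vlin), 20, 10), -19 * s)
  expect_error(junction_vj(vlin, 13, 10), "intercellular")
})

test_that("link conductivities follow the junction resistance rule", {
  mu <- microstructure("Cx43-Cx43", "clamped", beta = 1)
  expect_equal(local_conductivity(mu, intercellular = FALSE), 0.667)
  # clamped beta = 1: net link conductance equals g_jo = 2.534 uS
  sig <- local_conductivity(mu, intercellular = TRUE)
  link_conductance <- sig * mu$A_cell / (mu$eps / 10)  # mS
  expect_equal(link_conductance, 2.534e-3, tolerance = 1e-12)
  # voltage-gated at Vj = 0 matches clamped within 0.1%
  mug <- microstructure("Cx43-Cx43", "steady_state", beta = 1)
  expect_equal(local_conductivity(mug, TRUE, vj = 0), sig, tolerance = 1e-3)
  # beta = 0 disconnects the link
  mu0 <- microstructure("Cx43-Cx43", "clamped", beta = 0)
  expect_equal(local_conductivity(mu0, TRUE), 0)
})

test_that("uniform rest without stimulus is a fixed point of the solvers", {
  rest <- lr1_rest_state()
  for (model in c("cm_clamped", "cm_gated", "lhm", "nohm")) {
    cfg <- strand_config(model, beta = 1, regime = "instantaneous",
                         stim_amp = 0, out_dt = 0.5,
                         y_grid = seq(-50, 50, 1))
    sim <- simulate_strand(cfg, t_end = 5)
    expect_lt(max(abs(sim$v_final - rest$v)), 1e-6)
    # membrane residual at rest is ~7e-13 uA/cm^2, so drift per ms is tiny
    expect_lt(max(abs(sim$v - rest$v)), 1e-6)
  }
})

test_that("cellular strand discretization bookkeeping", {
  cfg <- strand_config("cm_gated", n_div = 10)
  expect_equal(cfg$n_cells, 64)
  expect_equal(cfg$n_nodes, 641)   # 6.4 mm at 10 um subcellular nodes
  expect_equal(cfg$dx, 0.01)
  sim <- simulate_strand(cfg, t_end = 1)
  expect_equal(length(sim$x), 641)
  expect_equal(max(sim$x), 6.4)
})

test_that("time step validation enforces the explicit stability bound", {
  expect_error(strand_config("cm_gated", dt = 0.005),
               "stability")   # 0.005 ms is unstable at dx = 10 um
  expect_error(strand_config("lhm", dt = 0.02), "stability")
  cfg <- strand_config("lhm")
  expect_lte(cfg$dt, stable_dt(0.1, consistent_mass = TRUE, safety = 1))
})

test_that("retrograde CV equals normal CV for symmetric channels", {
  # instantaneous Cx43-Cx43 at full coupling: the conductance law is nearly
  # even in Vj, so the wave speed must not depend on the pacing end
  nrm <- simulate_strand(strand_config("cm_gated", regime = "instantaneous",
                                       beta = 1, out_dt = 0.1),
                         t_end = 20)
  ret <- simulate_strand(strand_config("cm_gated", regime = "instantaneous",
                                       beta = 1, direction = "retrograde",
                                       out_dt = 0.1),
                         t_end = 20)
  cvn <- conduction_velocity(nrm)$cv
  cvr <- conduction_velocity(ret)$cv
  expect_lt(abs(cvn - cvr) / cvn, 0.01)
})
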