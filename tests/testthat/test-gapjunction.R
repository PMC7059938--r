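test_that("channel registry matches the published clamp fits", {
  ch <- channel_spec("Cx43-Cx43")
  expect_equal(ch$inst$G_neg, 1.99)
  expect_equal(ch$inst$VH_pos, 318.4)
  expect_equal(ch$ss$Vj0_neg, -60.8)
  expect_equal(ch$ss$gmin_pos, 0.25)
  expect_equal(ch$ss$A_neg, -3.4 / 25.7)
  expect_equal(ch$ss$A_pos, 2.9 / 25.7)
  het <- channel_spec("Cx43-Cx45")
  expect_equal(het$ss$p, 0.73)
  expect_equal(het$ss$d, 25)
  expect_error(channel_spec("Cx40-Cx40"), "valid channels")
  # invariants across all channels
  for (nm in channel_names()) {
    ch <- channel_spec(nm)
    expect_true(ch$inst$G_neg > 0 && ch$inst$G_pos > 0)
    expect_true(ch$ss$Vj0_neg < 0, info = nm)
    expect_true(ch$ss$Vj0_pos > 0, info = nm)
    expect_true(ch$ss$A_neg < 0 && ch$ss$A_pos > 0)
    expect_true(ch$ss$gmin_neg > 0 && ch$ss$gmin_neg < 1)
  }
})

test_that("instantaneous conductance matches direct evaluation", {
  # frozen values computed by hand from the branch formula
  # G * (2*cosh(Vj/VH) - 1) / mean(G-, G+)
  expect_equal(gj_inst(0, "Cx43-Cx43"), 1.99 / 2.00, tolerance = 1e-12)
  expect_equal(gj_inst(-100, "Cx43-Cx43"),
               1.99 * (2 * cosh(100 / 175.8) - 1) / 2.00, tolerance = 1e-12)
  expect_equal(gj_inst(-100, "Cx43-Cx43"), 1.3257, tolerance = 1e-4)
  # branch mismatch at 0 is |G- - G+| / mean for every channel
  for (nm in channel_names()) {
    ch <- channel_spec(nm)
    gap <- abs(gj_inst(-1e-12, nm) - gj_inst(1e-9, nm))
    expect_lt(gap, 0.036)
    expect_equal(gap, abs(ch$inst$G_neg - ch$inst$G_pos) /
                   mean(c(ch$inst$G_neg, ch$inst$G_pos)), tolerance = 1e-6)
  }
  # bounded and positive over a wide voltage range
  vj <- seq(-300, 300, by = 2.5)
  for (nm in channel_names()) {
    g <- gj_inst(vj, nm)
    expect_true(all(is.finite(g) & g > 0))
  }
})

test_that("steady-state conductance is a gated Boltzmann bell", {
  expect_equal(gj_ss(0, "Cx43-Cx43"), 0.9998, tolerance = 1e-4)
  expect_equal(gj_ss(-150, "Cx43-Cx43"), 0.260, tolerance = 1e-3)
  # continuity at the branch offset d: the Table-1 branch parameters are
  # independent fits, so the curves meet to ~5e-3 (worst case Cx45-Cx45)
  for (nm in channel_names()) {
    d <- channel_spec(nm)$ss$d
    expect_lt(abs(gj_ss(d, nm) - gj_ss(d + 1e-9, nm)), 5e-3)
  }
  expect_equal(gj_ss(25, "Cx43-Cx45"), 1.29, tolerance = 5e-3)
  # Boltzmann limits: gmin on each side
  ch <- channel_spec("Cx45-Cx45")
  expect_equal(gj_ss(-1000, ch), ch$ss$gmin_neg, tolerance = 1e-9)
  expect_equal(gj_ss(1000, ch), ch$ss$gmin_pos, tolerance = 1e-9)
  # near-symmetry of homotypic channels: tight near 0, to within 13% on
  # the steep flank around |Vj| ~ 70 mV where the fitted +/- gating
  # valences of Cx43-Cx43 differ most (computed from the Table-1 fits)
  vj <- seq(0.5, 100, by = 0.5)
  for (nm in c("Cx43-Cx43", "Cx45-Cx45")) {
    rel <- abs(gj_ss(vj, nm) - gj_ss(-vj, nm)) / gj_ss(-vj, nm)
    expect_lt(max(rel[vj <= 40]), 0.02)
    expect_lt(max(rel), 0.13)
  }
  # bounded between min(gmin) and the global max; decays beyond the peak
  for (nm in channel_names()) {
    ch <- channel_spec(nm)
    g <- gj_ss(seq(-300, 300, by = 1), ch)
    expect_true(all(g >= min(ch$ss$gmin_neg, ch$ss$gmin_pos) - 1e-12))
    left <- gj_ss(seq(-300, -150, by = 5), ch)
    expect_true(all(diff(left) >= -1e-12))  # rising back toward the peak
  }
})

test_that("junctional conductance scales by beta and regime", {
  expect_equal(gj_conductance(37, 0, "steady_state", "Cx43-Cx43"), 0)
  expect_equal(gj_conductance(-120, 0.1, "clamped", "Cx43-Cx43"), 0.1)
  expect_equal(gj_conductance(0, 1, "ss", "Cx43-Cx43"), 0.9998,
               tolerance = 1e-4)
  # clamped regime is constant in Vj
  expect_equal(gj_conductance(seq(-200, 200, 50), 0.3, "clamped", "Cx45-Cx45"),
               rep(0.3, 9))
  expect_error(gj_conductance(0, 1.2, "ss", "Cx43-Cx43"), "beta")
  expect_error(gj_conductance(0, -0.1, "ss", "Cx43-Cx43"), "beta")
  expect_error(gj_conductance(0, 1, "bogus", "Cx43-Cx43"), "regime")
})

test_that("compiled conductance laws agree with the R implementation", {
  vj <- seq(-250, 250, by = 0.7)
  for (nm in channel_names()) {
    gjp <- gjcable:::pack_gj_params(nm)
    expect_equal(gjcable:::gj_eval_cpp(vj, 1L, gjp), gj_inst(vj, nm),
                 tolerance = 1e-14)
    expect_equal(gjcable:::gj_eval_cpp(vj, 2L, gjp), gj_ss(vj, nm),
                 tolerance = 1e-14)
    expect_equal(gjcable:::gj_eval_cpp(vj, 0L, gjp), rep(1, length(vj)))
  }
})

test_that("channel registry round-trips through the plain-text format", {
  path <- withr::local_tempfile(fileext = ".yml")
  write_channel_registry(path)
  back <- read_channel_registry(path)
  for (nm in channel_names()) {
    orig <- channel_spec(nm)
    expect_equal(back[[nm]]$inst, orig$inst)
    expect_equal(back[[nm]]$ss, orig$ss, tolerance = 1e-12)
  }
  curve <- gj_curve("Cx43-Cx45", seq(-50, 50, 10))
  expect_s3_class(curve, "tbl_df")
  expect_named(curve, c("channel", "vj_mV", "g_inst", "g_ss"))
})
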