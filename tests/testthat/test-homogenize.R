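test_that("microstructure derives the disc conductivity from g_jo", {
  mu <- microstructure()
  expect_equal(mu$delta_sigma_g, 2.534e-3 * 1e-4 * 0.1 / 380e-6,
               tolerance = 1e-12)
  expect_equal(mu$delta_sigma_g, 6.67e-5, tolerance = 1e-3)
  expect_equal(mu$sigma_g, mu$delta_sigma_g / mu$delta)
  expect_error(microstructure(beta = 2), "beta")
})

test_that("linear effective conductivity is the laminate harmonic mean", {
  mu <- microstructure(regime = "clamped", beta = 1)
  expect_equal(lhm_sigma(mu), 0.3335, tolerance = 1e-3)
  # matches 1/((1-delta)/sigma_c + 1/(beta sigma_g)) for several betas
  for (b in c(1, 0.4, 0.05)) {
    mu <- microstructure(regime = "clamped", beta = b)
    expect_equal(lhm_sigma(mu),
                 1 / ((1 - mu$delta) / mu$sigma_c + 1 / (b * mu$sigma_g)),
                 tolerance = 1e-12)
  }
  expect_warning(s0 <- lhm_sigma(microstructure(beta = 0)), "beta = 0")
  expect_equal(s0, 0)
  # no junction resistance -> cytoplasmic conductivity
  mu_inf <- microstructure(regime = "clamped", beta = 1, g_jo = 1e9)
  expect_equal(lhm_sigma(mu_inf), mu_inf$sigma_c / (1 - mu_inf$delta),
               tolerance = 1e-6)
})

test_that("clamped non-Ohmic conductivity is identically the linear value", {
  for (b in c(1, 0.25, 0.01)) {
    mu <- microstructure(regime = "clamped", beta = b)
    y <- seq(-2000, 2000, by = 100)
    expect_identical(nohm_sigma(y, mu), rep(lhm_sigma(mu), length(y)))
  }
})

test_that("non-Ohmic solve agrees with a brute-force residual scan", {
  # independent oracle: exhaustive bisection on the scalar residual
  brute <- function(y, mu) {
    Ffun <- function(s) {
      Nj <- -(1 - mu$delta) * (s / mu$sigma_c - 1) * y
      B <- mu$beta * gj_ss(mu$S * mu$eps * Nj, mu$channel)
      mu$sigma_c * B / (mu$sigma_c / mu$sigma_g + (1 - mu$delta) * B)
    }
    grid <- seq(1e-9, mu$sigma_c, length.out = 20000)
    r <- vapply(grid, function(s) s - Ffun(s), numeric(1))
    i <- which(r[-1] * r[-length(r)] <= 0)[1]
    uniroot(function(s) s - Ffun(s), c(grid[i], grid[i + 1]),
            tol = 1e-14)$root
  }
  mu <- microstructure("Cx45-Cx45", "steady_state", beta = 1)
  expect_equal(nohm_sigma(-60, mu), brute(-60, mu), tolerance = 1e-8)
  mu2 <- microstructure("Cx43-Cx43", "steady_state", beta = 0.2)
  expect_equal(nohm_sigma(35, mu2), brute(35, mu2), tolerance = 1e-8)
  expect_error(nohm_sigma(Inf, mu), "finite")
})

test_that("sigma(y) respects bounds, symmetry and beta-monotonicity", {
  y <- seq(-1500, 1500, by = 25)
  for (nm in c("Cx43-Cx43", "Cx45-Cx45")) {
    mu <- microstructure(nm, "steady_state", beta = 1)
    s <- sigma_at(sigma_table(mu, seq(-1600, 1600, 5)), y)
    expect_true(all(s > 0 & s <= mu$sigma_c))
    # homotypic channels: even in y at moderate gradients, where the
    # junction jump stays in the range where the +/- Boltzmann branches
    # agree; on the steep flanks the Table-1 branch fits differ by >10%
    # and the collapse region amplifies that, so evenness is only local
    srev <- rev(s)
    mod <- abs(y) <= 250
    expect_lt(max((abs(s - srev) / s)[mod]), 0.01)
  }
  # heterotypic channel is direction-dependent
  muh <- microstructure("Cx43-Cx45", "steady_state", beta = 1)
  expect_gt(abs(nohm_sigma(100, muh) - nohm_sigma(-100, muh)),
            0.01 * muh$sigma_c)
  # monotone non-decreasing in beta at fixed gradient
  for (yy in c(0, -80, 150)) {
    vals <- vapply(c(0.05, 0.2, 0.5, 1), function(b) {
      nohm_sigma(yy, microstructure("Cx45-Cx45", "steady_state", beta = b))
    }, numeric(1))
    expect_true(all(diff(vals) > -1e-12), info = paste("y =", yy))
  }
})

test_that("tabulated map interpolates the direct solve", {
  mu <- microstructure("Cx43-Cx45", "steady_state", beta = 0.5)
  map <- sigma_table(mu, seq(-400, 400, by = 1))
  expect_error(sigma_table(mu, numeric(0)), "empty")
  # grid points reproduce the direct continuation solve exactly
  expect_equal(sigma_at(map, c(-100, 0, 100)),
               map$sigma[match(c(-100, 0, 100), map$y)])
  # midpoint interpolation error for 1 mV/mm spacing
  ymid <- c(-55.5, 30.5, 120.5)
  direct <- vapply(ymid, function(y) {
    gjcable:::nohm_sigma_scalar(y, mu, 1e-10, 200,
                                sigma_at(map, round(y)))
  }, numeric(1))
  expect_lt(max(abs(sigma_at(map, ymid) - direct)), 1e-3 * mu$sigma_c)
  # queries outside the grid fall back to a direct solve
  expect_equal(sigma_at(map, 450), nohm_sigma(450, mu, sigma_init = map$sigma[length(map$y)]),
               tolerance = 1e-9)
})

test_that("series-circuit oracle reproduces the homogenized conductivity", {
  # clamped: pure series resistors equal the linear value
  mu <- microstructure(regime = "clamped", beta = 0.5)
  res <- micro_strand_steady(mu, dV = 10, n_cells = 16)
  expect_false(res$blocked)
  expect_equal(res$sigma_eff, lhm_sigma(mu), tolerance = 1e-8)
  # voltage-gated: matches sigma(y) at the applied mean gradient
  mu2 <- microstructure("Cx43-Cx43", "steady_state", beta = 1)
  dV <- 80
  n <- 32
  res2 <- micro_strand_steady(mu2, dV = dV, n_cells = n)
  y <- -dV / (n * mu2$eps)
  expect_equal(res2$sigma_eff, nohm_sigma(y, mu2), tolerance = 1e-6)
  # exact antisymmetry for the (voltage-insensitive) clamped junction,
  # near-antisymmetry for the homotypic gated one
  res_c <- micro_strand_steady(mu, dV = 10, n_cells = 16)
  res_cn <- micro_strand_steady(mu, dV = -10, n_cells = 16)
  expect_equal(res_cn$profile$u, -res_c$profile$u, tolerance = 1e-9)
  res_neg <- micro_strand_steady(mu2, dV = -dV, n_cells = n)
  expect_equal(res_neg$profile$u, -res2$profile$u, tolerance = 1e-2)
})

test_that("microscopic profile converges linearly to the homogenized line", {
  mu_of <- function(eps) microstructure("Cx45-Cx45", "steady_state",
                                        beta = 0.3, eps = eps)
  L <- 3.2
  dV <- 40
  sup_err <- vapply(c(0.1, 0.05, 0.025), function(eps) {
    res <- micro_strand_steady(mu_of(eps), dV = dV, n_cells = round(L / eps))
    lin <- dV * (1 - res$profile$x / L)   # homogenized linear profile
    max(abs(res$profile$u - lin))
  }, numeric(1))
  expect_true(all(diff(sup_err) < 0))
  ratio <- sup_err[-length(sup_err)] / sup_err[-1]
  expect_true(all(ratio > 1.5 & ratio < 3), info = paste(ratio, collapse = " "))
})

test_that("heavily suppressed junctions flag a blocked series solution", {
  mu <- microstructure("Cx45-Cx45", "steady_state", beta = 0.02)
  res <- micro_strand_steady(mu, dV = 300, n_cells = 8)
  expect_true(res$blocked)
})
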