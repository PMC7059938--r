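#' Linear homogenized (Ohmic) effective conductivity
#'
#' Effective conductivity of the periodic cytoplasm / gap laminate when the
#' gap conductivity is voltage-insensitive: the harmonic series combination
#' of the cytoplasm (length fraction `1 - delta`, conductivity `sigma_c`)
#' and the coupled gap (`beta * sigma_g`). This is exactly the fixed point
#' of the non-Ohmic map [nohm_sigma()] when the junction conductance is
#' clamped at 1, and reduces to `1/(1/sigma_c + 1/(beta*sigma_g))` as
#' `delta -> 0`.
#'
#' @param micro a [microstructure()].
#' @return conductivity in mS/mm; `0` (with a warning) when `beta = 0`.
#' @examples
#' lhm_sigma(microstructure(beta = 1))  # ~0.3335 mS/mm
#' @export
lhm_sigma <- function(micro) {
  stopifnot(inherits(micro, "microstructure"))
  b <- micro$beta
  if (b == 0) {
    warning("beta = 0: uncoupled strand, effective conductivity is 0")
    return(0)
  }
  sc <- micro$sigma_c
  # written as the clamped fixed point so the identity with nohm_sigma()
  # holds bitwise, not just algebraically
  sc * b / (sc / micro$sigma_g + (1 - micro$delta) * b)
}

#' Non-Ohmic effective conductivity at a macroscopic potential gradient
#'
#' Solves the implicit homogenized relation for the gradient-dependent
#' effective conductivity: `sigma = sigma_c * B / (sigma_c/sigma_g +
#' (1-delta) * B)` where `B = beta * g_j(S * eps * N)` and the junction
#' jump density is `N(y) = -(1-delta) * (sigma/sigma_c - 1) * y`. The
#' argument of the conductance law, `S * eps * N`, is the scaled junction
#' voltage jump in mV. The solver is a damped fixed-point iteration started
#' from the linear value (or `sigma_init` for continuation in `y`), with a
#' bisection fallback on the residual over (0, sigma_c]; when the residual
#' has several zeros the root closest to the continuation value is taken
#' (the branch continuous from `y = 0`).
#'
#' @param y macroscopic potential gradient, mV/mm (vectorized).
#' @param micro a [microstructure()].
#' @param tol convergence tolerance relative to `sigma_c`.
#' @param max_iter maximum fixed-point iterations before falling back to
#'   bisection.
#' @param sigma_init optional starting value (continuation).
#' @return effective conductivity in mS/mm, in (0, sigma_c].
#' @export
nohm_sigma <- function(y, micro, tol = 1e-10, max_iter = 200,
                       sigma_init = NULL) {
  stopifnot(inherits(micro, "microstructure"))
  if (any(!is.finite(y))) stop("gradient y must be finite", call. = FALSE)
  vapply(y, nohm_sigma_scalar, numeric(1), micro = micro, tol = tol,
         max_iter = max_iter, sigma_init = sigma_init)
}

#' @keywords internal
#' @noRd
nohm_sigma_scalar <- function(y, micro, tol, max_iter, sigma_init) {
  sc <- micro$sigma_c
  if (micro$beta == 0) return(0)
  Ffun <- function(s) {
    Njump <- -(1 - micro$delta) * (s / sc - 1) * y
    B <- micro$beta * micro_gj(micro$S * micro$eps * Njump, micro)
    sc * B / (sc / micro$sigma_g + (1 - micro$delta) * B)
  }
  ref <- if (is.null(sigma_init)) {
    suppressWarnings(lhm_sigma(micro))
  } else {
    sigma_init
  }
  atol <- tol * sc

  s <- ref
  damp <- 1
  prev_step <- 0
  for (it in seq_len(max_iter)) {
    fs <- Ffun(s)
    step <- fs - s
    if (abs(step) < atol) return(fs)
    if (prev_step != 0 && sign(step) != sign(prev_step)) {
      damp <- max(damp * 0.5, 0.05)
    }
    s <- s + damp * step
    s <- min(max(s, 1e-12), sc)
    prev_step <- step
  }

  # bisection fallback on the residual over (0, sigma_c]
  resid <- function(s) s - Ffun(s)
  grid <- seq(sc / 512, sc, length.out = 512)
  rg <- vapply(grid, resid, numeric(1))
  flips <- which(rg[-1] * rg[-length(rg)] <= 0)
  if (length(flips) == 0) {
    stop(sprintf(paste0("nohm_sigma did not converge at y = %g mV/mm ",
                        "(beta = %g, channel %s, regime %s): no residual ",
                        "sign change on (0, sigma_c]"),
                 y, micro$beta, micro$channel$name, micro$regime),
         call. = FALSE)
  }
  roots <- vapply(flips, function(i) {
    stats::uniroot(resid, lower = grid[i], upper = grid[i + 1],
                   tol = atol / 10)$root
  }, numeric(1))
  roots[which.min(abs(roots - ref))]
}

#' Tabulate the non-Ohmic effective conductivity over a gradient grid
#'
#' Builds an interpolation table of `sigma(y)` by continuation: the solve
#' marches outward from `y = 0`, starting each solve from the previous
#' root, so the tabulated branch is the one continuous from the linear
#' value at zero gradient. Queries between grid points use linear
#' interpolation; queries outside the grid fall back to a direct solve.
#'
#' @param micro a [microstructure()].
#' @param y_grid gradient grid in mV/mm; must be non-empty and should be
#'   symmetric about 0 and cover the gradients the simulation will visit.
#' @param tol solver tolerance passed to [nohm_sigma()].
#' @return an object of class `sigma_map`.
#' @export
sigma_table <- function(micro, y_grid = seq(-2000, 2000, by = 1),
                        tol = 1e-10) {
  stopifnot(inherits(micro, "microstructure"))
  if (length(y_grid) == 0) stop("y_grid is empty", call. = FALSE)
  y_grid <- sort(unique(y_grid))
  sig <- numeric(length(y_grid))
  i0 <- which.min(abs(y_grid))
  s_prev <- nohm_sigma(y_grid[i0], micro, tol = tol)
  sig[i0] <- s_prev
  if (i0 < length(y_grid)) {
    for (i in (i0 + 1):length(y_grid)) {
      sig[i] <- nohm_sigma_scalar(y_grid[i], micro, tol = tol,
                                  max_iter = 200, sigma_init = sig[i - 1])
    }
  }
  if (i0 > 1) {
    for (i in (i0 - 1):1) {
      sig[i] <- nohm_sigma_scalar(y_grid[i], micro, tol = tol,
                                  max_iter = 200, sigma_init = sig[i + 1])
    }
  }
  structure(list(micro = micro, y = y_grid, sigma = sig, tol = tol),
            class = "sigma_map")
}

#' @export
print.sigma_map <- function(x, ...) {
  cat(sprintf("<sigma_map> %d points, y in [%g, %g] mV/mm, sigma in [%.4g, %.4g] mS/mm\n",
              length(x$y), min(x$y), max(x$y), min(x$sigma), max(x$sigma)))
  invisible(x)
}

#' Query a tabulated effective-conductivity map
#'
#' @param map a `sigma_map` from [sigma_table()].
#' @param y gradients to query, mV/mm.
#' @return conductivities in mS/mm (linear interpolation inside the grid,
#'   direct solves outside).
#' @export
sigma_at <- function(map, y) {
  stopifnot(inherits(map, "sigma_map"))
  out <- numeric(length(y))
  inside <- y >= map$y[1] & y <= map$y[length(map$y)]
  if (any(inside)) {
    out[inside] <- stats::approx(map$y, map$sigma, xout = y[inside])$y
  }
  if (any(!inside)) {
    edge <- ifelse(y[!inside] < map$y[1], map$sigma[1],
                   map$sigma[length(map$sigma)])
    out[!inside] <- mapply(function(yy, s0) {
      nohm_sigma_scalar(yy, map$micro, tol = map$tol, max_iter = 200,
                        sigma_init = s0)
    }, y[!inside], edge)
  }
  out
}

#' Tidy view of a conductivity map
#' @param map a `sigma_map`.
#' @return tibble with columns `y_mV_per_mm`, `sigma_mS_per_mm`.
#' @export
sigma_map_tbl <- function(map) {
  stopifnot(inherits(map, "sigma_map"))
  tibble::tibble(y_mV_per_mm = map$y, sigma_mS_per_mm = map$sigma)
}

#' Microscale series-circuit steady state (validation oracle)
#'
#' Solves the microscopic steady conduction problem on a finite chain of
#' cells directly, as a series circuit: Ohmic cytoplasmic resistances in
#' series with non-linear junction elements whose current is
#' `I = beta * g_jo * g_j(S * Vj) * Vj` (with `Vj` the junction jump,
#' sampled downstream minus upstream). Given end potentials `Delta_V` apart,
#' the series current is found by 1-D root finding with continuation from
#' `I = 0` along the rising branch of the junction I-V curve; if the
#' demanded current exceeds the branch maximum the result is flagged as
#' blocked rather than raising an error.
#'
#' @param micro a [microstructure()].
#' @param dV potential difference across the chain (left minus right), mV.
#' @param n_cells number of cells (>= 2).
#' @return a list with `profile` (tibble of `x` in mm and potential `u` in
#'   mV sampled at both ends of every cell), `sigma_eff` (mS/mm),
#'   `current` (uA), `vj` (per-junction jump, mV) and `blocked`.
#' @export
micro_strand_steady <- function(micro, dV, n_cells) {
  stopifnot(inherits(micro, "microstructure"), n_cells >= 2,
            is.finite(dV))
  eps <- micro$eps
  A <- micro$A_cell
  L <- n_cells * eps
  # one junction per periodic unit (cell + disc), so the finite chain is an
  # integer number of periods and carries no edge term
  n_j <- n_cells
  R_cyt <- (1 - micro$delta) * eps / (micro$sigma_c * A)  # 1/mS per cell

  if (dV == 0) {
    prof <- tibble::tibble(
      x = as.vector(rbind((0:(n_cells - 1)) * eps, (1:n_cells) * eps)),
      u = 0)
    return(list(profile = prof, sigma_eff = NA_real_, current = 0,
                vj = rep(0, n_j), blocked = FALSE))
  }

  sgn <- sign(dV)
  # junction current as a function of the (signed) drop D = u_up - u_down:
  # Vj = -D, current flows down the potential drop
  jcur <- function(D) {
    micro$beta * micro$g_jo * micro_gj(-micro$S * D, micro) * D
  }
  # rising branch from D = 0 in the direction of the applied drop
  Dgrid <- seq(0, sgn * 400, length.out = 8001)
  Ig <- jcur(Dgrid)
  mono <- which(diff(sgn * Ig) <= 0)
  i_max <- if (length(mono) == 0) length(Dgrid) else mono[1]
  D_max <- Dgrid[i_max]
  I_max <- Ig[i_max]

  D_of_I <- function(I) {
    if (I == 0) return(0)
    stats::uniroot(function(D) jcur(D) - I,
                   lower = min(0, D_max), upper = max(0, D_max),
                   tol = 1e-12)$root
  }
  total_drop <- function(I) n_cells * I * R_cyt + n_j * D_of_I(I)

  blocked <- FALSE
  if (sgn * total_drop(I_max) < sgn * dV) {
    blocked <- TRUE
    I <- I_max
  } else {
    I <- stats::uniroot(function(I) total_drop(I) - dV,
                        lower = min(0, I_max), upper = max(0, I_max),
                        tol = 1e-14)$root
  }
  D <- D_of_I(I)

  # assemble the potential profile; u(0) = dV, u(L) = dV - total drop
  drop_cell <- I * R_cyt
  u_left <- dV - (0:(n_cells - 1)) * (drop_cell + D)
  u_right <- u_left - drop_cell
  prof <- tibble::tibble(
    x = as.vector(rbind((0:(n_cells - 1)) * eps, (1:n_cells) * eps)),
    u = as.vector(rbind(u_left, u_right)))
  list(profile = prof,
       sigma_eff = I * L / (A * dV),
       current = I, vj = rep(-D, n_j), blocked = blocked)
}
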