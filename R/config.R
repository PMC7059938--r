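#' Surface-to-volume ratio of the strand membrane (1/mm)
#' @keywords internal
#' @noRd
surface_to_volume <- function(r_cell = 0.011, rcg = 2) 2 * rcg / r_cell

#' Largest stable explicit time step for a given spacing
#'
#' Explicit diffusion bound `dt <= dx^2 * Am * Cm / (2 * sigma_max)`, with
#' the cytoplasmic conductivity as the worst case, times a safety factor.
#'
#' @param dx node spacing, mm.
#' @param sigma_max largest link/element conductivity, mS/mm.
#' @param Am surface-to-volume ratio, 1/mm.
#' @param Cm membrane capacitance, uF/mm^2.
#' @param safety fraction of the bound to use.
#' @param consistent_mass use the (stricter) consistent-mass bound
#'   `dx^2*Am*Cm/(6*sigma)` instead of the lumped `dx^2*Am*Cm/(2*sigma)`.
#' @return time step in ms.
#' @export
stable_dt <- function(dx, sigma_max = 0.667, Am = surface_to_volume(),
                      Cm = 0.01, safety = 0.7, consistent_mass = FALSE) {
  denom <- if (consistent_mass) 6 else 2
  safety * dx^2 * Am * Cm / (denom * sigma_max)
}

#' Configure a strand conduction simulation
#'
#' Assembles geometry, microstructure, membrane constants, discretization
#' and pacing for one of the four conduction models:
#' \describe{
#'   \item{`cm_clamped`}{discrete cellular model, voltage-insensitive
#'     junctions (conductance `beta * g_jo`).}
#'   \item{`cm_gated`}{discrete cellular model, junction conductance
#'     `beta * g_jo * g_j(Vj)` under the chosen regime.}
#'   \item{`lhm`}{linear homogenized cable (constant effective
#'     conductivity).}
#'   \item{`nohm`}{non-Ohmic homogenized cable (gradient-dependent
#'     effective conductivity).}
#' }
#' Cellular models are discretized at `n_div` subcellular nodes per cell
#' (spacing `eps/n_div`); continuum models on a uniform mesh of spacing
#' `h` with `round(L/h) + 1` nodes. The default time step is computed from
#' the explicit stability bound and capped at 0.005 ms (cellular) /
#' 0.01 ms (continuum). Pacing is a square current pulse of `stim_amp`
#' uA/mm^2 for `stim_dur` ms every `cl` ms at the left end (`direction =
#' "normal"`) or right end (`"retrograde"`).
#'
#' @param model one of `"cm_clamped"`, `"cm_gated"`, `"lhm"`, `"nohm"`.
#' @param channel channel type name or [channel_spec()].
#' @param regime conductance regime for the voltage-gated models
#'   (`"instantaneous"` or `"steady_state"`; `"clamped"` degenerates to the
#'   voltage-insensitive models and is forced for `cm_clamped`/`lhm`).
#' @param beta coupling fraction in \[0, 1\].
#' @param direction `"normal"` (left-to-right) or `"retrograde"`.
#' @param L strand length, mm.
#' @param eps cell length, mm.
#' @param n_div subcellular divisions per cell (cellular models).
#' @param h mesh spacing, mm (continuum models).
#' @param dt time step, ms (`NULL` = automatic from the stability bound).
#' @param stim_amp stimulus amplitude, uA/mm^2 (axial current density at
#'   the paced boundary).
#' @param stim_dur stimulus duration, ms.
#' @param cl pacing cycle length, ms.
#' @param n_beats number of paced beats.
#' @param out_dt recording stride, ms.
#' @param sigma_c,g_jo,delta,A_cell,S microstructure overrides, see
#'   [microstructure()].
#' @param r_cell cell radius, mm (sets the surface-to-volume ratio
#'   `Am = 2*RCG/r_cell` with `RCG = 2`).
#' @param Cm membrane capacitance, uF/mm^2.
#' @param y_grid gradient grid for the non-Ohmic conductivity table,
#'   mV/mm.
#' @param mass capacitive mass treatment of the continuum (Galerkin)
#'   models: `"consistent"` (tridiagonal mass matrix, the default) or
#'   `"lumped"` (diagonal). Ignored by the cellular models, whose node
#'   balance is a finite-difference (diagonal) scheme by construction.
#' @param sigma_gradient gradient estimate fed to the non-Ohmic
#'   conductivity: `"recovered"` (nodal-averaged, default; keeps the
#'   coarse-mesh solution on the h-converged branch through steep
#'   wavefronts) or `"element"` (raw per-element one-point gradient).
#' @return an object of class `strand_config`.
#' @export
strand_config <- function(model = c("nohm", "lhm", "cm_gated", "cm_clamped"),
                          channel = "Cx43-Cx43", regime = "instantaneous",
                          beta = 1, direction = c("normal", "retrograde"),
                          L = 6.4, eps = 0.1, n_div = 10, h = 0.1,
                          dt = NULL, stim_amp = 30, stim_dur = 2,
                          cl = 800, n_beats = 1, out_dt = 0.25,
                          sigma_c = 0.667, g_jo = 2.534e-3, delta = 1e-4,
                          A_cell = 380e-6, S = 2, r_cell = 0.011,
                          Cm = 0.01, y_grid = seq(-2000, 2000, by = 1),
                          mass = c("consistent", "lumped"),
                          sigma_gradient = c("recovered", "element")) {
  model <- match.arg(model)
  direction <- match.arg(direction)
  mass <- match.arg(mass)
  sigma_gradient <- match.arg(sigma_gradient)
  regime <- normalize_regime(regime)
  if (model %in% c("cm_clamped", "lhm")) regime <- "clamped"
  micro <- microstructure(channel = channel, regime = regime, beta = beta,
                          eps = eps, delta = delta, sigma_c = sigma_c,
                          g_jo = g_jo, r_cell = r_cell, A_cell = A_cell,
                          S = S)
  Am <- surface_to_volume(r_cell)
  cellular <- model %in% c("cm_clamped", "cm_gated")
  if (cellular) {
    stopifnot(n_div >= 1, abs(L / eps - round(L / eps)) < 1e-9)
    n_cells <- as.integer(round(L / eps))
    dx <- eps / n_div
    n_nodes <- n_cells * n_div + 1L
  } else {
    n_cells <- as.integer(round(L / eps))
    dx <- h
    n_nodes <- as.integer(round(L / h)) + 1L
    if (abs((n_nodes - 1L) * h - L) > 1e-9)
      stop("mesh spacing h must divide the strand length L", call. = FALSE)
  }
  consistent <- !cellular && mass == "consistent"
  dt_max <- stable_dt(dx, sigma_c, Am, Cm, safety = 1,
                      consistent_mass = consistent)
  if (is.null(dt)) {
    dt <- min(0.005, stable_dt(dx, sigma_c, Am, Cm,
                               consistent_mass = consistent))
  } else if (dt > dt_max) {
    stop(sprintf("dt = %g ms violates the explicit stability bound %.3g ms at spacing %g mm",
                 dt, dt_max, dx), call. = FALSE)
  }
  stopifnot(stim_dur > 0, cl > 0, n_beats >= 1, out_dt > 0)
  structure(list(model = model, micro = micro, direction = direction,
                 L = L, n_cells = n_cells, n_div = as.integer(n_div),
                 h = h, dx = dx, n_nodes = n_nodes, dt = dt,
                 Am = Am, Cm = Cm,
                 stim_amp = stim_amp, stim_dur = stim_dur, cl = cl,
                 n_beats = n_beats, out_dt = out_dt, y_grid = y_grid,
                 mass = mass, sigma_gradient = sigma_gradient),
            class = "strand_config")
}

#' @export
print.strand_config <- function(x, ...) {
  cat("<strand_config>", x$model, "\n")
  cat(sprintf("  channel %s, regime %s, beta = %g, direction %s\n",
              x$micro$channel$name, x$micro$regime, x$micro$beta,
              x$direction))
  cat(sprintf("  L = %g mm, %d nodes (spacing %g mm), dt = %g ms\n",
              x$L, x$n_nodes, x$dx, x$dt))
  cat(sprintf("  pacing: %g uA/mm^2 x %g ms, CL = %g ms, %d beat(s)\n",
              x$stim_amp, x$stim_dur, x$cl, x$n_beats))
  invisible(x)
}

#' Write / read a strand configuration as YAML
#'
#' Round-trips all scalar configuration fields; the file is a plain-text
#' key-value document.
#'
#' @param config a [strand_config()].
#' @param path file path.
#' @return `write_config_yaml` returns `path` invisibly; `read_config_yaml`
#'   returns a `strand_config`.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "strand_config"))
  m <- config$micro
  lst <- list(model = config$model, channel = m$channel$name,
              regime = m$regime, beta = m$beta,
              direction = config$direction,
              L = config$L, eps = m$eps, n_div = config$n_div,
              h = config$h, dt = config$dt,
              stim_amp = config$stim_amp, stim_dur = config$stim_dur,
              cl = config$cl, n_beats = config$n_beats,
              out_dt = config$out_dt,
              sigma_c = m$sigma_c, g_jo = m$g_jo, delta = m$delta,
              A_cell = m$A_cell, S = m$S, r_cell = m$r_cell,
              Cm = config$Cm,
              mass = config$mass,
              sigma_gradient = config$sigma_gradient,
              y_min = min(config$y_grid), y_max = max(config$y_grid),
              y_step = if (length(config$y_grid) > 1)
                config$y_grid[2] - config$y_grid[1] else 1)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  z <- yaml::read_yaml(path)
  strand_config(model = z$model, channel = z$channel, regime = z$regime,
                beta = z$beta, direction = z$direction, L = z$L,
                eps = z$eps, n_div = z$n_div, h = z$h, dt = z$dt,
                stim_amp = z$stim_amp, stim_dur = z$stim_dur, cl = z$cl,
                n_beats = z$n_beats, out_dt = z$out_dt, mass = z$mass,
                sigma_gradient = z$sigma_gradient,
                sigma_c = z$sigma_c, g_jo = z$g_jo, delta = z$delta,
                A_cell = z$A_cell, S = z$S, r_cell = z$r_cell, Cm = z$Cm,
                y_grid = seq(z$y_min, z$y_max, by = z$y_step))
}
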