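.gjcable_cache <- new.env(parent = emptyenv())

#' Construct a Luo-Rudy I ionic state
#'
#' Gating variables (dimensionless, in \[0,1\]) and intracellular calcium
#' (mM, > 0) at one node. The order `(m, h, j, d, f, X, Cai)` is the one
#' the solvers use.
#'
#' @param m,h,j fast-sodium activation and (fast/slow) inactivation gates.
#' @param d,f slow-inward activation / inactivation gates.
#' @param X time-dependent potassium activation gate.
#' @param Cai intracellular calcium, mM.
#' @return a named numeric vector of class `lr1_state`.
#' @export
lr1_state <- function(m, h, j, d, f, X, Cai) {
  s <- c(m = m, h = h, j = j, d = d, f = f, X = X, Cai = Cai)
  validate_lr1_state(s)
  structure(s, class = "lr1_state")
}

#' @keywords internal
#' @noRd
validate_lr1_state <- function(s) {
  if (length(s) != 7 || any(!is.finite(s)))
    stop("ionic state must be 7 finite values (m, h, j, d, f, X, Cai)",
         call. = FALSE)
  if (any(s[1:6] < 0 | s[1:6] > 1))
    stop("gating variables must lie in [0, 1]", call. = FALSE)
  if (s[7] <= 0) stop("Cai must be positive", call. = FALSE)
  invisible(s)
}

#' Total transmembrane ionic current (Luo-Rudy I)
#'
#' Sum of the six phase-I currents (fast sodium, slow inward, time-dependent
#' potassium, time-independent potassium, plateau potassium, background) at
#' a transmembrane potential `v` and ionic state `w`. `scale` multiplies the
#' individual currents (e.g. all zeros gives 0), in the order
#' `I_Na, I_si, I_K, I_K1, I_Kp, I_b`.
#'
#' @param v transmembrane potential, mV.
#' @param w an [lr1_state()] (or named 7-vector in the same order).
#' @param scale optional length-6 multipliers of the maximal conductances.
#' @param components if `TRUE`, return the named vector of the six currents
#'   instead of their sum.
#' @return current density in uA/cm^2 (the solvers convert to uA/mm^2 at
#'   the membrane boundary).
#' @export
ionic_current <- function(v, w, scale = rep(1, 6), components = FALSE) {
  validate_lr1_state(unclass(w))
  stopifnot(length(scale) == 6, is.finite(v))
  comp <- lr1_currents_cpp(v, as.numeric(w)) * scale
  if (components) comp else sum(comp)
}

#' Advance the Luo-Rudy I gating variables and calcium
#'
#' Forward-Euler update of the alpha/beta first-order gate kinetics and the
#' intracellular-calcium ODE at a (fixed) potential `v`, with gates clipped
#' to \[0, 1\]. Repeated `n_steps` times.
#'
#' @inheritParams ionic_current
#' @param dt time step, ms (> 0).
#' @param n_steps number of Euler steps.
#' @param method `"euler"` (forward Euler on the rate equations, default)
#'   or `"rush_larsen"` (exponential integrator using the closed-form
#'   relaxation of each first-order gate; exact for clamped `v`).
#' @return the updated state.
#' @export
step_gates <- function(v, w, dt, n_steps = 1L,
                       method = c("euler", "rush_larsen")) {
  method <- match.arg(method)
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("dt must be a positive time step in ms", call. = FALSE)
  validate_lr1_state(unclass(w))
  out <- lr1_step_gates_cpp(v, as.numeric(w), dt, as.integer(n_steps),
                            method == "rush_larsen")
  names(out) <- c("m", "h", "j", "d", "f", "X", "Cai")
  structure(out, class = "lr1_state")
}

#' Gate opening/closing rates at a potential
#'
#' @param v transmembrane potential, mV.
#' @return named vector of the alpha/beta rates (1/ms) of the six gates.
#' @export
lr1_rates <- function(v) {
  stopifnot(is.finite(v))
  lr1_rates_cpp(v)
}

#' Resting state of the Luo-Rudy I membrane
#'
#' The unstimulated fixed point, computed once per session by relaxing a
#' 0-D membrane for 20 s of model time and cached. The resting potential
#' lies in \[-90, -80\] mV and the residual total ionic current is below
#' 1e-2 uA/cm^2.
#'
#' @param refresh recompute instead of using the cached value.
#' @return a list with `v` (mV) and `state` (an [lr1_state()]).
#' @export
lr1_rest_state <- function(refresh = FALSE) {
  if (!refresh && !is.null(.gjcable_cache$rest)) return(.gjcable_cache$rest)
  w0 <- c(0.002, 0.98, 0.99, 0.003, 0.999, 0.006, 2e-4)
  run <- lr1_run0d_cpp(-84, w0, dt = 0.01, t_end = 20000,
                       stim_amp = 0, stim_start = -1, stim_dur = 0,
                       record_dt = 1000)
  v <- run$v_final
  s <- as.numeric(run$state)
  resid <- abs(sum(lr1_currents_cpp(v, s)))
  if (!is.finite(v) || v < -90 || v > -80 || resid > 1e-2)
    stop(sprintf("rest-state relaxation failed (v = %.2f mV, |I_ion| = %.3g uA/cm^2)",
                 v, resid), call. = FALSE)
  names(s) <- c("m", "h", "j", "d", "f", "X", "Cai")
  rest <- list(v = v, state = structure(s, class = "lr1_state"))
  .gjcable_cache$rest <- rest
  rest
}

#' Integrate an isolated (0-D) Luo-Rudy I membrane
#'
#' Forward-Euler run of a single membrane patch, optionally with a square
#' current pulse. Useful for action-potential and refractoriness checks.
#'
#' @param v0 initial potential, mV.
#' @param w initial [lr1_state()].
#' @param t_end duration, ms.
#' @param dt time step, ms.
#' @param stim_amp stimulus amplitude, uA/cm^2 (depolarizing when > 0).
#' @param stim_start,stim_dur pulse window, ms.
#' @param record_dt output stride, ms.
#' @return list with `time`, `v`, final `state` and `max_dvdt` (mV/ms).
#' @export
lr1_run0d <- function(v0, w, t_end, dt = 0.01, stim_amp = 0,
                      stim_start = 0, stim_dur = 1, record_dt = 0.5) {
  validate_lr1_state(unclass(w))
  stopifnot(dt > 0, t_end > 0)
  out <- lr1_run0d_cpp(v0, as.numeric(w), dt, t_end, stim_amp, stim_start,
                       stim_dur, record_dt)
  s <- as.numeric(out$state)
  names(s) <- c("m", "h", "j", "d", "f", "X", "Cai")
  list(time = out$time, v = out$v, v_final = out$v_final,
       state = structure(s, class = "lr1_state"), max_dvdt = out$max_dvdt)
}

#' Save / load an ionic state as a flat CSV record
#' @param w an [lr1_state()] (with the node potential `v` stored alongside).
#' @param v transmembrane potential, mV.
#' @param path file path.
#' @return `write_state_csv` returns `path` invisibly; `read_state_csv`
#'   returns a list with `v` and `state`.
#' @export
write_state_csv <- function(w, v, path) {
  df <- data.frame(name = c("v", names(w)), value = c(v, as.numeric(w)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_state_csv
#' @export
read_state_csv <- function(path) {
  df <- utils::read.csv(path)
  vals <- stats::setNames(df$value, df$name)
  s <- vals[c("m", "h", "j", "d", "f", "X", "Cai")]
  list(v = unname(vals["v"]), state = structure(s, class = "lr1_state"))
}
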