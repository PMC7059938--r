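#' Activation time of a single-site voltage trace
#'
#' First upward crossing of the threshold, located by linear interpolation
#' between the bracketing samples. Returns `NA` when the trace never
#' crosses; a trace that starts at or above threshold activates at its
#' first sample.
#'
#' @param time sample times, ms (uniformly increasing).
#' @param v potential samples, mV (same length as `time`).
#' @param threshold activation threshold, mV.
#' @return activation time in ms, or `NA_real_`.
#' @export
activation_time <- function(time, v, threshold = 0) {
  if (length(v) == 0 || length(time) == 0)
    stop("empty trace", call. = FALSE)
  stopifnot(length(time) == length(v))
  if (!any(v < threshold)) return(time[1])  # suprathreshold throughout
  above <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  frac <- (threshold - v[i]) / (v[i + 1] - v[i])
  time[i] + frac * (time[i + 1] - time[i])
}

#' Nearest node index to a position
#' @keywords internal
#' @noRd
nearest_node <- function(x_nodes, x) which.min(abs(x_nodes - x))

#' Conduction velocity between two strand sites
#'
#' Activation times at the sites nearest `x1` and `x2` (defaults: 20% and
#' 80% of the strand, ordered along the propagation direction so `x1` is
#' the proximal site) give `cv = |x2 - x1| / (t2 - t1)`, the wave speed in
#' cm/s along the propagation direction. The run is classified as blocked
#' when either site never activates or the distal site does not activate
#' after the proximal one.
#'
#' @param sim a `strand_sim`.
#' @param x1,x2 measurement sites, mm; defaults depend on the configured
#'   propagation direction.
#' @param threshold activation threshold, mV.
#' @param t_window optional `c(t_min, t_max)` restricting the traces (used
#'   by the restitution driver to isolate one beat).
#' @return a one-row tibble: `t1`, `t2` (ms), `cv` (cm/s, `NA` when
#'   blocked), `blocked`, `x1`, `x2`.
#' @export
conduction_velocity <- function(sim, x1 = NULL, x2 = NULL, threshold = 0,
                                t_window = NULL) {
  stopifnot(inherits(sim, "strand_sim"))
  L <- max(sim$x)
  retro <- identical(sim$config$direction, "retrograde")
  if (is.null(x1)) x1 <- if (retro) 0.8 * L else 0.2 * L
  if (is.null(x2)) x2 <- if (retro) 0.2 * L else 0.8 * L
  i1 <- nearest_node(sim$x, x1)
  i2 <- nearest_node(sim$x, x2)
  tt <- sim$time
  v1 <- sim$v[, i1]
  v2 <- sim$v[, i2]
  if (!is.null(t_window)) {
    keep <- tt >= t_window[1] & tt <= t_window[2]
    tt <- tt[keep]; v1 <- v1[keep]; v2 <- v2[keep]
  }
  t1 <- activation_time(tt, v1, threshold)
  t2 <- activation_time(tt, v2, threshold)
  dxm <- abs(sim$x[i2] - sim$x[i1])
  blocked <- is.na(t1) || is.na(t2) || t2 <= t1
  cv <- if (blocked) NA_real_ else 100 * dxm / (t2 - t1)  # mm/ms -> cm/s
  tibble::tibble(t1 = t1, t2 = t2, cv = cv, blocked = blocked,
                 x1 = sim$x[i1], x2 = sim$x[i2])
}

#' Conduction velocity versus gap-junctional coupling
#'
#' Runs one paced beat per coupling fraction and measures CV between the
#' 20%/80% sites; rows whose distal site never activates are flagged
#' blocked.
#'
#' @param config a [strand_config()]; its `beta` is overridden per row.
#' @param betas coupling fractions in (0, 1\].
#' @param t_end simulated window per run, ms (long enough to classify slow
#'   propagation as conducted rather than blocked).
#' @param threshold activation threshold, mV.
#' @return a tibble with columns `model`, `direction`, `beta`, `cv`,
#'   `blocked`.
#' @export
cv_beta_sweep <- function(config, betas, t_end = 500, threshold = 0) {
  stopifnot(inherits(config, "strand_config"),
            all(betas > 0), all(betas <= 1))
  rows <- lapply(betas, function(b) {
    cfg <- reconfig(config, beta = b)
    sim <- simulate_strand(cfg, t_end = min(t_end, cfg$cl))
    res <- conduction_velocity(sim, threshold = threshold)
    tibble::tibble(model = config$model, direction = config$direction,
                   beta = b, cv = res$cv, blocked = res$blocked)
  })
  do.call(rbind, rows)
}

#' Rebuild a config with some fields replaced
#' @keywords internal
#' @noRd
reconfig <- function(config, ...) {
  m <- config$micro
  args <- list(model = config$model, channel = m$channel$name,
               regime = m$regime,
               beta = m$beta, direction = config$direction,
               L = config$L, eps = m$eps, n_div = config$n_div,
               h = config$h, dt = config$dt,
               stim_amp = config$stim_amp, stim_dur = config$stim_dur,
               cl = config$cl, n_beats = config$n_beats,
               out_dt = config$out_dt, sigma_c = m$sigma_c,
               g_jo = m$g_jo, delta = m$delta, A_cell = m$A_cell,
               S = m$S, r_cell = m$r_cell, Cm = config$Cm,
               y_grid = config$y_grid, mass = config$mass,
               sigma_gradient = config$sigma_gradient)
  repl <- list(...)
  args[names(repl)] <- repl
  do.call(strand_config, args)
}

#' Largest coupling fraction with conduction block
#'
#' Runs the configured model over a descending coupling grid and reports
#' the largest fraction whose beat fails to reach the distal measurement
#' site.
#'
#' @inheritParams cv_beta_sweep
#' @param beta_grid coupling fractions (sorted internally in descending
#'   order).
#' @return the largest blocked fraction, or `NA_real_` when every run
#'   propagates; the sweep table is attached as attribute `"sweep"`.
#' @export
block_threshold <- function(config, beta_grid, t_end = 500, threshold = 0) {
  beta_grid <- sort(beta_grid, decreasing = TRUE)
  tab <- cv_beta_sweep(config, beta_grid, t_end = t_end,
                       threshold = threshold)
  blocked <- tab$beta[tab$blocked]
  out <- if (length(blocked) == 0) NA_real_ else max(blocked)
  attr(out, "sweep") <- tab
  out
}

#' Conduction-velocity restitution
#'
#' Dynamic pacing-down protocol: for each cycle length the strand is paced
#' `n_beats` times, continuing from the state left by the previous train,
#' and CV is measured on the last beat. Capture requires the distal site to
#' activate within that beat's window. By default the schedule stops at the
#' first cycle length that loses propagation.
#'
#' @param config a [strand_config()].
#' @param cl_schedule decreasing cycle lengths, ms.
#' @param n_beats beats per cycle length.
#' @param threshold activation threshold, mV.
#' @param stop_at_loss stop pacing after the first uncaptured cycle length.
#' @return a tibble with columns `cl`, `cv`, `captured`.
#' @export
restitution <- function(config, cl_schedule = restitution_schedule(),
                        n_beats = 5, threshold = 0, stop_at_loss = TRUE) {
  stopifnot(inherits(config, "strand_config"),
            all(diff(cl_schedule) < 0))
  v0 <- NULL
  w0 <- NULL
  sigma_map <- if (config$model == "nohm")
    sigma_table(config$micro, config$y_grid) else NULL
  rows <- vector("list", length(cl_schedule))
  for (k in seq_along(cl_schedule)) {
    cl <- cl_schedule[k]
    cfg <- reconfig(config, cl = cl, n_beats = n_beats)
    sim <- simulate_strand(cfg, t_end = n_beats * cl, v0 = v0, w0 = w0,
                           sigma_map = sigma_map)
    v0 <- sim$v_final
    w0 <- sim$w_final
    res <- conduction_velocity(sim, threshold = threshold,
                               t_window = c((n_beats - 1) * cl,
                                            n_beats * cl))
    rows[[k]] <- tibble::tibble(cl = cl, cv = res$cv,
                                captured = !res$blocked)
    if (stop_at_loss && res$blocked) {
      rows <- rows[seq_len(k)]
      break
    }
  }
  do.call(rbind, rows)
}

#' Default pacing-down schedule for restitution, ms
#'
#' Starts at the baseline cycle length of 800 ms, steps through
#' intermediate lengths and then decrements by 10 ms below 400 ms.
#' @return numeric vector of cycle lengths.
#' @export
restitution_schedule <- function() {
  c(800, 600, 500, 450, 400, seq(390, 250, by = -10))
}

#' Conduction velocity versus mesh size
#'
#' Repeats a single-beat CV measurement over a list of spatial resolutions.
#' For continuum models the resolution is the mesh spacing `h`; for
#' cellular models it is the subcellular segment length (so `eps/h` must be
#' a whole number of divisions per cell; coarser-than-cell spacings are
#' skipped with a warning).
#'
#' @param config a [strand_config()].
#' @param h_list spacings to test, mm; defaults to
#'   `c(0.01, 0.02, 0.05, 0.1)` for cellular models and
#'   `c(0.02, 0.05, 0.1, 0.2)` for continuum models (whose finest stable
#'   level is limited by the consistent-mass explicit time-step bound).
#' @param t_end simulated window per run, ms.
#' @param threshold activation threshold, mV.
#' @param stim_dur stimulus duration for these runs, ms. Coarse
#'   subcellular chains present a stronger diffusive sink at the paced
#'   node, so a longer pulse (at the same amplitude) is needed to excite
#'   them; CV is independent of the pulse once the beat is elicited.
#' @return a tibble with columns `model`, `h`, `cv`, `blocked`.
#' @export
mesh_study <- function(config, h_list = NULL, t_end = 60, threshold = 0,
                       stim_dur = 4) {
  stopifnot(inherits(config, "strand_config"))
  cellular <- config$model %in% c("cm_clamped", "cm_gated")
  if (is.null(h_list))
    h_list <- if (cellular) c(0.01, 0.02, 0.05, 0.1) else c(0.02, 0.05, 0.1, 0.2)
  eps <- config$micro$eps
  rows <- lapply(h_list, function(h) {
    if (cellular) {
      ndiv <- eps / h
      if (abs(ndiv - round(ndiv)) > 1e-9 || ndiv < 1) {
        warning(sprintf("spacing %g mm is not a subcellular division of the %g mm cell; skipped",
                        h, eps))
        return(tibble::tibble(model = config$model, h = h,
                              cv = NA_real_, blocked = NA))
      }
      cfg <- reconfig(config, n_div = round(ndiv), dt = NULL,
                      stim_dur = stim_dur)
    } else {
      cfg <- reconfig(config, h = h, dt = NULL, stim_dur = stim_dur)
    }
    sim <- simulate_strand(cfg, t_end = min(t_end, cfg$cl))
    res <- conduction_velocity(sim, threshold = threshold)
    tibble::tibble(model = config$model, h = h, cv = res$cv,
                   blocked = res$blocked)
  })
  do.call(rbind, rows)
}
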