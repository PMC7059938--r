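#' Microstructure of the periodic cell / intercalated-disc lattice
#'
#' Geometric and electrical constants of the one-dimensional strand
#' microstructure: cells of length `eps` whose intercalated discs occupy a
#' length fraction `delta`, cytoplasmic conductivity `sigma_c`, and a
#' representative disc conductance `g_jo`. The representative disc
#' conductivity is derived as `delta_sigma_g = g_jo * delta * eps / A_cell`
#' and the gap conductivity as `sigma_g = delta_sigma_g / delta`.
#'
#' Internal units: mm, ms, mV, mS/mm (1 mS/mm = 1 S/m), uA/mm^2, uF/mm^2.
#'
#' @param channel channel type (name or `channel_spec`).
#' @param regime conductance regime: `"instantaneous"`, `"steady_state"` or
#'   `"clamped"` (voltage-insensitive).
#' @param beta gap-junctional coupling fraction in \[0, 1\].
#' @param eps cell length, mm.
#' @param delta intercalated-disc length ratio (dimensionless).
#' @param sigma_c cytoplasmic conductivity, mS/mm.
#' @param g_jo representative junction conductance, mS (2.534e-3 mS =
#'   2.534 uS).
#' @param r_cell cell radius, mm (used only to derive `A_cell` when the
#'   latter is not supplied).
#' @param A_cell cross-sectional area, mm^2; default is the rounded
#'   380 um^2 implied by `r_cell` = 11 um.
#' @param S jump-scaling factor multiplying the junction voltage jump
#'   before the conductance law is evaluated (dimensionless).
#' @return an object of class `microstructure` with the derived fields
#'   `delta_sigma_g` and `sigma_g`.
#' @examples
#' mu <- microstructure()
#' mu$delta_sigma_g  # 6.67e-5 mS/mm
#' @export
microstructure <- function(channel = "Cx43-Cx43", regime = "steady_state",
                           beta = 1, eps = 0.1, delta = 1e-4,
                           sigma_c = 0.667, g_jo = 2.534e-3,
                           r_cell = 0.011, A_cell = 380e-6, S = 2) {
  stopifnot(eps > 0, delta > 0, delta < 1, sigma_c > 0, g_jo > 0,
            A_cell > 0, S > 0)
  if (!is.numeric(beta) || length(beta) != 1 || is.na(beta) ||
      beta < 0 || beta > 1) {
    stop("beta must be a single value in [0, 1]", call. = FALSE)
  }
  ch <- channel_spec(channel)
  regime <- normalize_regime(regime)
  delta_sigma_g <- g_jo * delta * eps / A_cell
  structure(list(channel = ch, regime = regime, beta = beta,
                 eps = eps, delta = delta, sigma_c = sigma_c,
                 g_jo = g_jo, r_cell = r_cell, A_cell = A_cell, S = S,
                 delta_sigma_g = delta_sigma_g,
                 sigma_g = delta_sigma_g / delta),
            class = "microstructure")
}

#' @export
print.microstructure <- function(x, ...) {
  cat("<microstructure>\n")
  cat(sprintf("  channel %s, regime %s, beta = %g\n",
              x$channel$name, x$regime, x$beta))
  cat(sprintf("  eps = %g mm, delta = %g, sigma_c = %g mS/mm\n",
              x$eps, x$delta, x$sigma_c))
  cat(sprintf("  g_jo = %g uS, A_cell = %g um^2, delta_sigma_g = %.3g mS/mm, S = %g\n",
              x$g_jo * 1e3, x$A_cell * 1e6, x$delta_sigma_g, x$S))
  invisible(x)
}

#' Normalized junction conductance for a microstructure's regime
#' @keywords internal
#' @noRd
micro_gj <- function(vj, micro) {
  switch(micro$regime,
         clamped = rep(1, length(vj)),
         instantaneous = gj_inst(vj, micro$channel),
         steady_state = gj_ss(vj, micro$channel))
}
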