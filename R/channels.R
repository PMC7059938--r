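#' Gap-junction channel parameter registry
#'
#' Connexin channel parameters for the two limiting conductance regimes:
#' the instantaneous law (conductance immediately after a transjunctional
#' voltage step) and the steady-state law (after full gating relaxation,
#' a Boltzmann distribution in Vj). Values are the published dual
#' voltage-clamp fits for homotypic Cx43-Cx43 and Cx45-Cx45 channels and
#' the heterotypic Cx43-Cx45 channel; the heterotypic steady-state law is
#' a modified Boltzmann with shape parameter `p` and offset `d` (mV).
#'
#' The gating-sensitivity slopes are `A = z / kT` in 1/mV, with the gating
#' valence `z` and `kT = 25.7` meV.
#' @keywords internal
#' @noRd
.channel_registry <- list(
  "Cx43-Cx43" = list(
    inst = list(G_neg = 1.99, G_pos = 2.01, VH_neg = -175.8, VH_pos = 318.4),
    ss = list(Vj0_neg = -60.8, Vj0_pos = 62.9, gmin_neg = 0.26,
              gmin_pos = 0.25, z_neg = -3.4, z_pos = 2.9, p = 1, d = 0)
  ),
  "Cx45-Cx45" = list(
    inst = list(G_neg = 1.99, G_pos = 2.02, VH_neg = -112.7, VH_pos = 135.0),
    ss = list(Vj0_neg = -38.9, Vj0_pos = 38.5, gmin_neg = 0.16,
              gmin_pos = 0.17, z_neg = -2.5, z_pos = 2.7, p = 1, d = 0)
  ),
  "Cx43-Cx45" = list(
    inst = list(G_neg = 1.93, G_pos = 2.0, VH_neg = -130.0, VH_pos = 404.0),
    ss = list(Vj0_neg = -15.9, Vj0_pos = 149.3, gmin_neg = 0.05,
              gmin_pos = 0.05, z_neg = -2.1, z_pos = 0.7, p = 0.73, d = 25)
  )
)

#' Boltzmann constant times temperature used for gating slopes (meV)
#' @keywords internal
#' @noRd
.kT_meV <- 25.7

#' Create a gap-junction channel specification
#'
#' Builds the parameter bundle for one connexin channel type: the
#' instantaneous-conductance parameters (scale factors `G_neg`/`G_pos` and
#' half-widths `VH_neg`/`VH_pos` in mV) and the steady-state Boltzmann
#' parameters (`Vj0` half-inactivation voltages in mV, residual
#' conductances `gmin` in (0,1), gating valences `z`, shape `p`, offset `d`
#' in mV). The slopes `A_neg`, `A_pos` (1/mV) are precomputed as `z / kT`
#' with `kT = 25.7` meV.
#'
#' @param name one of `"Cx43-Cx43"`, `"Cx45-Cx45"`, `"Cx43-Cx45"`.
#' @return an object of class `channel_spec`.
#' @examples
#' ch <- channel_spec("Cx43-Cx43")
#' ch$ss$Vj0_neg  # -60.8 mV
#' @export
channel_spec <- function(name) {
  if (inherits(name, "channel_spec")) return(name)
  if (!is.character(name) || length(name) != 1 ||
      !name %in% names(.channel_registry)) {
    stop("unknown channel '", paste(name, collapse = ","), "'; valid channels: ",
         paste(names(.channel_registry), collapse = ", "), call. = FALSE)
  }
  pars <- .channel_registry[[name]]
  ss <- pars$ss
  ss$A_neg <- ss$z_neg / .kT_meV
  ss$A_pos <- ss$z_pos / .kT_meV
  structure(list(name = name, inst = pars$inst, ss = ss),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat("<channel_spec>", x$name, "\n")
  cat(sprintf("  instantaneous: G = %.2f/%.2f, VH = %.1f/%.1f mV\n",
              x$inst$G_neg, x$inst$G_pos, x$inst$VH_neg, x$inst$VH_pos))
  cat(sprintf("  steady-state:  Vj0 = %.1f/%.1f mV, gmin = %.2f/%.2f, z = %.1f/%.1f, p = %.2f, d = %.0f mV\n",
              x$ss$Vj0_neg, x$ss$Vj0_pos, x$ss$gmin_neg, x$ss$gmin_pos,
              x$ss$z_neg, x$ss$z_pos, x$ss$p, x$ss$d))
  invisible(x)
}

#' Names of the available channel types
#' @return character vector of channel names.
#' @export
channel_names <- function() names(.channel_registry)

#' Instantaneous normalized gap-junction conductance
#'
#' Conductance immediately after a voltage step, normalized so that
#' `gj_inst(0) ~ 1`. Each polarity branch evaluates
#' `G * (2*cosh(Vj/VH) - 1)` and the result is divided by the `Vj = 0`
#' value `(G_neg + G_pos)/2`. The branch is selected by the sign of `Vj`
#' (the tie at 0 uses the negative branch).
#'
#' @param vj transjunctional voltage, mV (vectorized).
#' @param channel a `channel_spec` or channel name.
#' @return normalized conductance (dimensionless, > 0).
#' @export
gj_inst <- function(vj, channel) {
  ch <- channel_spec(channel)
  stopifnot(all(is.finite(vj)))
  p <- ch$inst
  norm <- (p$G_neg + p$G_pos) / 2
  G <- ifelse(vj <= 0, p$G_neg, p$G_pos)
  VH <- ifelse(vj <= 0, p$VH_neg, p$VH_pos)
  G * (2 * cosh(vj / VH) - 1) / norm
}

#' Steady-state normalized gap-junction conductance
#'
#' Boltzmann distribution of the fully gating-relaxed conductance:
#' `g = (1 - gmin)/(p + exp(A*(Vj - Vj0))) + gmin`, with the
#' negative-polarity parameter set for `Vj <= d` and the positive-polarity
#' set for `Vj > d`. For homotypic channels (`d = 0`, near-symmetric
#' parameters) the curve is a symmetric bell with `g(0) ~ 1`; the
#' heterotypic Cx43-Cx45 distribution is strongly asymmetric, which is the
#' microscopic source of direction-dependent conduction.
#'
#' @inheritParams gj_inst
#' @return normalized conductance (dimensionless), bounded below by the
#'   branch `gmin`.
#' @export
gj_ss <- function(vj, channel) {
  ch <- channel_spec(channel)
  stopifnot(all(is.finite(vj)))
  p <- ch$ss
  neg <- vj <= p$d
  gmin <- ifelse(neg, p$gmin_neg, p$gmin_pos)
  A <- ifelse(neg, p$A_neg, p$A_pos)
  V0 <- ifelse(neg, p$Vj0_neg, p$Vj0_pos)
  (1 - gmin) / (p$p + exp(A * (vj - V0))) + gmin
}

#' Normalize a conductance-regime name
#' @keywords internal
#' @noRd
normalize_regime <- function(regime) {
  r <- tolower(gsub("[-_ ]", "", regime))
  if (r %in% c("clamped", "ohmic", "none")) return("clamped")
  if (r %in% c("instantaneous", "inst")) return("instantaneous")
  if (r %in% c("steadystate", "ss", "steady")) return("steady_state")
  stop("unknown conductance regime '", regime,
       "'; use 'clamped', 'instantaneous' or 'steady_state'", call. = FALSE)
}

#' Junctional conductance scale beta * g_j(Vj)
#'
#' The dimensionless factor that multiplies the representative disc
#' conductivity to give the local gap conductivity: `beta * g_j(Vj)` for
#' the voltage-gated regimes and `beta` for the clamped (Ohmic) regime.
#' `beta` is the gap-junctional coupling fraction (1 = normal coupling).
#'
#' @inheritParams gj_inst
#' @param beta coupling fraction in \[0, 1\].
#' @param regime `"instantaneous"`, `"steady_state"` or `"clamped"`.
#' @return `beta * g_j(vj)` (or `beta` when clamped), vectorized over `vj`.
#' @export
gj_conductance <- function(vj, beta, regime, channel) {
  if (!is.numeric(beta) || length(beta) != 1 || is.na(beta) ||
      beta < 0 || beta > 1) {
    stop("beta must be a single value in [0, 1]", call. = FALSE)
  }
  regime <- normalize_regime(regime)
  switch(regime,
         clamped = rep(beta, length(vj)),
         instantaneous = beta * gj_inst(vj, channel),
         steady_state = beta * gj_ss(vj, channel))
}

#' Pack channel parameters for the compiled solvers
#' @keywords internal
#' @noRd
pack_gj_params <- function(channel) {
  ch <- channel_spec(channel)
  c(ch$inst$G_neg, ch$inst$G_pos, ch$inst$VH_neg, ch$inst$VH_pos,
    ch$ss$gmin_neg, ch$ss$gmin_pos, ch$ss$A_neg, ch$ss$A_pos,
    ch$ss$Vj0_neg, ch$ss$Vj0_pos, ch$ss$p, ch$ss$d)
}

#' Integer code of a conductance regime for the compiled solvers
#' @keywords internal
#' @noRd
regime_code <- function(regime) {
  switch(normalize_regime(regime),
         clamped = 0L, instantaneous = 1L, steady_state = 2L)
}

#' Tabulate normalized conductance curves over a voltage grid
#'
#' @param channel a `channel_spec` or channel name.
#' @param vj voltage grid in mV.
#' @return a tibble with columns `vj_mV`, `g_inst`, `g_ss`.
#' @export
gj_curve <- function(channel, vj = seq(-150, 150, by = 1)) {
  ch <- channel_spec(channel)
  tibble::tibble(channel = ch$name, vj_mV = vj,
                 g_inst = gj_inst(vj, ch), g_ss = gj_ss(vj, ch))
}

#' Write / read the channel registry as a plain-text (YAML) file
#'
#' @param path file path.
#' @param channels channel names to include (default: all).
#' @return `write_channel_registry` returns `path` invisibly;
#'   `read_channel_registry` returns a named list of `channel_spec`s.
#' @export
write_channel_registry <- function(path, channels = channel_names()) {
  specs <- lapply(channels, function(nm) {
    ch <- channel_spec(nm)
    list(inst = ch$inst, ss = ch$ss)
  })
  names(specs) <- channels
  yaml::write_yaml(specs, path, precision = 15)
  invisible(path)
}

#' @rdname write_channel_registry
#' @export
read_channel_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(names(raw), function(nm) {
    structure(list(name = nm, inst = raw[[nm]]$inst, ss = raw[[nm]]$ss),
              class = "channel_spec")
  }) -> out
  names(out) <- names(raw)
  out
}
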